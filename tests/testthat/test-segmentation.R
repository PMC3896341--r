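# Background modeling, masking and connected-component extraction.

test_that("background model is the per-pixel maximum over frames", {
  f1 <- matrix(10L, 3, 3); f2 <- matrix(200L, 3, 3)
  f2[2, 2] <- 5L
  bg <- buildBackground(stackOf(f1, f2))
  expect_identical(bg, pmax(f1, f2))       # elementwise max oracle
  expect_equal(bg[1, 1], 200)
  expect_equal(bg[2, 2], 10)

  # constant stack: background equals the common frame
  expect_identical(buildBackground(stackOf(f1, f1, f1)), f1)
  # single frame: background equals that frame
  expect_identical(buildBackground(stackOf(f2)), f2)
})

test_that("a FrameStack cannot be empty", {
  expect_error(FrameStack(array(0L, dim = c(4, 4, 0))), "at least one frame")
})

test_that("foreground mask thresholds the clamped difference", {
  bg <- matrix(100L, 2, 2)
  fr <- matrix(c(100L, 58L, 57L, 56L), 2, 2)  # differences 0, 42, 43, 44
  expect_identical(as.vector(foregroundMask(fr, bg, 43)),
                   c(FALSE, FALSE, TRUE, TRUE))
  # frame equal to background: empty mask
  expect_false(any(foregroundMask(bg, bg, 43)))
  # pixels brighter than the background are clamped, never foreground
  brighter <- matrix(250L, 2, 2)
  expect_false(any(foregroundMask(brighter, bg, 1)))
  expect_error(foregroundMask(matrix(0L, 2, 3), bg), "sizes differ")
})

test_that("raising the threshold never adds a mask pixel", {
  set.seed(11)
  bg <- matrix(200L, 20, 20)
  for (rep in 1:5) {
    fr <- matrix(as.integer(runif(400, 0, 255)), 20, 20)
    prev <- foregroundMask(fr, bg, 0)
    for (th in seq(5, 200, by = 5)) {
      cur <- foregroundMask(fr, bg, th)
      expect_false(any(cur & !prev))
      prev <- cur
    }
  }
})

test_that("regions match hand-computed features", {
  m <- matrix(FALSE, 6, 6)
  expect_equal(nrow(extractRegions(m)), 0)

  m[1:2, 1:2] <- TRUE  # 2x2 square at the origin
  r <- extractRegions(m)
  expect_equal(nrow(r), 1)
  expect_equal(r$area, 4)
  expect_equal(c(r$x, r$y), c(0.5, 0.5))

  # two diagonally touching pixels: one region under 8-connectivity,
  # two under 4-connectivity
  d <- matrix(FALSE, 5, 5); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(nrow(extractRegions(d, connectivity = 8)), 1)
  expect_equal(nrow(extractRegions(d, connectivity = 4)), 2)
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(7)
  for (rep in 1:25) {
    nr <- sample(3:32, 1); nc <- sample(3:32, 1)
    m <- randomMask(nr, nc, fill = runif(1, 0.15, 0.6))
    for (eight in c(TRUE, FALSE)) {
      reg <- extractRegions(m, connectivity = if (eight) 8 else 4)
      oracle <- floodFillLabels(m, eight = eight)
      expect_equal(nrow(reg), max(oracle))
      # identical partition of foreground pixels
      if (nrow(reg) > 0) {
        got <- lapply(reg$pixels, sort)
        want <- unname(split(which(oracle > 0), oracle[oracle > 0]))
        expect_setequal(vapply(got, paste, character(1), collapse = ","),
                        vapply(want, paste, character(1), collapse = ","))
      }
      # conservation: region areas sum to the mask's foreground count
      expect_equal(sum(reg$area), sum(m))
    }
  }
})

test_that("moment axes recover a rendered ellipse's body axes", {
  m <- matrix(30L, 60, 60)
  fr <- beetrack:::fillEllipse(m, 30, 30, 7.5, 3.5, pi / 6, 255L)
  reg <- extractRegions(fr == 255L)
  expect_equal(nrow(reg), 1)
  expect_lt(abs(reg$major - 15), 0.6)
  expect_lt(abs(reg$minor - 7), 0.6)
})

test_that("threshold sweep reports perfect completeness at moderate thresholds", {
  sim <- simulateArena(agentConfig(nAgents = 2, nFrames = 40,
                                   frameSize = c(150, 150), arenaRadius = 60,
                                   noiseSD = 0, seed = 3))
  sweep <- suppressWarnings(
    thresholdSweep(sim$stack, sim$truth, c(20, 43, 120, 171)))
  expect_equal(nrow(sweep), 4)
  # contrast is 170 gray levels: moderate thresholds track perfectly,
  # beyond-contrast thresholds find nothing
  expect_equal(sweep$mean_tcf[sweep$threshold %in% c(20, 43, 120)],
               rep(1, 3))
  expect_equal(sweep$mean_tcf[sweep$threshold == 171], 0)

  one <- suppressWarnings(thresholdSweep(sim$stack, sim$truth, 43))
  expect_equal(nrow(one), 1)
  expect_error(thresholdSweep(sim$stack, sim$truth, numeric(0)), "empty")
})
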