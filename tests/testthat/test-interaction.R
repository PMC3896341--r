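# Encounter detection and interaction classification.

test_that("distant parallel tracks produce no encounters", {
  tab <- rbind(lineTrack(1, 1:50, 0, 0, dx = 1),
               lineTrack(2, 1:50, 0, 50, dx = 1))
  expect_equal(nrow(detectEncounters(tab, 15)), 0)
})

test_that("a close crossing yields one episode containing the contact frame", {
  # tracks meet at frame 40 (both at x = 40 then), 5 px apart vertically
  tab <- rbind(lineTrack(1, 1:80, 1, 20, dx = 1),
               lineTrack(2, 1:80, 80, 25, dx = -1))
  eps <- detectEncounters(tab, 15)
  expect_equal(nrow(eps), 1)
  expect_true(eps$start <= 40 & 40 <= eps$end)
  expect_equal(eps$T1, eps$start)
  expect_equal(eps$participants[[1]], c(1, 2))
})

test_that("two stationary bees within contact distance meet continuously", {
  tab <- rbind(lineTrack(1, 1:30, 0, 0), lineTrack(2, 1:30, 10, 0))
  eps <- detectEncounters(tab, 15)
  expect_equal(nrow(eps), 1)
  expect_equal(c(eps$start, eps$end), c(1, 30))
})

test_that("pair episodes sharing a bee merge into one multi-participant episode", {
  tab <- rbind(lineTrack(1, 1:20, 0, 0), lineTrack(2, 1:20, 10, 0),
               lineTrack(3, 1:20, 10, 10))  # 3 close to 2 but 14.1 px from 1
  eps <- detectEncounters(tab, 12)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$participants[[1]], c(1, 2, 3))
})

syntheticEpisodeTable <- function(turnA = 0, turnB = 0, merged = FALSE,
                                  stopB = FALSE, headA0 = 0, headB0 = pi,
                                  a0 = c(0, 96), b0 = c(164, 104),
                                  turnAt = 42) {
  # two bees approach, meet, then depart; headings are piecewise constant
  # with optional turns of the given angles at frame `turnAt` (the meeting)
  mk <- function(id, x0, y0, h0, turn, stopFrames = integer(0)) {
    n <- 84
    h <- c(rep(h0, turnAt - 1), rep(h0 + turn, n - turnAt + 1))
    x <- numeric(n); y <- numeric(n); x[1] <- x0; y[1] <- y0
    for (k in 2:n) {
      sp <- if (k %in% stopFrames) 0 else 2
      x[k] <- x[k - 1] + sp * cos(h[k]); y[k] <- y[k - 1] + sp * sin(h[k])
    }
    data.frame(frame = 1:n, id = id, x = x, y = y)
  }
  a <- mk(1, a0[1], a0[2], headA0, turnA)
  b <- mk(2, b0[1], b0[2], headB0, turnB, if (stopB) 38:84 else integer(0))
  tab <- trajectoryTable(rbind(a, b), fps = 25)
  tab$merged <- merged & tab$frame %in% 40:44
  tab
}

test_that("classification separates the five two-bee prototypes", {
  cls <- function(tab) {
    eps <- detectEncounters(tab, 15)
    expect_equal(nrow(eps), 1)
    classifyInteraction(eps[1, ], tab, bodyLen = 15, fps = 25)
  }
  expect_equal(cls(syntheticEpisodeTable()), "crossing")
  expect_equal(cls(syntheticEpisodeTable(merged = TRUE)), "overlapping")
  # opposite incoming directions, A veers south and B veers north after T1
  expect_equal(cls(syntheticEpisodeTable(turnA = pi / 2, turnB = pi / 2)),
               "passing")
  # same incoming direction (40 deg apart), both veer off after the touch
  sameDir <- syntheticEpisodeTable(turnA = pi / 2, turnB = -pi / 2,
                                   headA0 = pi / 9, headB0 = -pi / 9,
                                   a0 = c(0, 80), b0 = c(0, 112),
                                   turnAt = 25)
  expect_equal(cls(sameDir), "touching")
  expect_equal(cls(syntheticEpisodeTable(stopB = TRUE)), "waiting")
})

test_that("three or more participants classify as multiple", {
  tab <- rbind(lineTrack(1, 1:20, 0, 0), lineTrack(2, 1:20, 10, 0),
               lineTrack(3, 1:20, 10, 10))
  tab <- trajectoryTable(tab, fps = 25)
  eps <- detectEncounters(tab, 12)
  expect_equal(classifyInteraction(eps[1, ], tab), "multiple")
})

test_that("distance-speed reports track the focal bee's neighbourhood", {
  solo <- trajectoryTable(lineTrack(9, 1:10, 0, 0, dx = 1), fps = 25)
  rep1 <- distanceSpeedReport(solo, 9)
  expect_equal(nrow(rep1), 0)
  expect_error(distanceSpeedReport(solo, 4), "unknown focal id")

  sc <- scriptedScenario("waiting")
  tt <- trajectoryTable(truthTable(sc$truth), fps = 25)
  ev <- truthEvents(sc$truth)
  rep2 <- distanceSpeedReport(tt[tt$id %in% 1:2, ], focalId = 2,
                              contactDist = 15)
  during <- rep2$frame >= ev$T1 & rep2$frame <= ev$end
  expect_true(all(rep2$speed[during] <= 0.1 * 15, na.rm = TRUE))
  expect_true(any(rep2$contact[during]))
})

test_that("episode classification is total over generated encounters", {
  sim <- simulateArena(agentConfig(nAgents = 5, nFrames = 150,
                                   frameSize = c(200, 200), arenaRadius = 85,
                                   noiseSD = 0, seed = 14))
  tt <- trajectoryTable(truthTable(sim$truth), fps = 25)
  eps <- detectEncounters(tt, 15)
  if (nrow(eps) > 0) {
    eps <- classifyInteractions(eps, tt, bodyLen = 15)
    expect_true(all(eps$category %in% c("crossing", "touching", "passing",
                                        "overlapping", "waiting", "multiple")))
  }
  # every close pair of frames is covered by exactly one episode
  ids <- unique(tt$id)
  for (f in unique(tt$frame)) {
    g <- tt[tt$frame == f, ]
    if (nrow(g) < 2) next
    d <- as.matrix(stats::dist(cbind(g$x, g$y)))
    close <- which(d < 15 & upper.tri(d), arr.ind = TRUE)
    for (k in seq_len(nrow(close))) {
      pair <- g$id[c(close[k, 1], close[k, 2])]
      covering <- sum(vapply(seq_len(nrow(eps)), function(e)
        all(pair %in% eps$participants[[e]]) &&
          eps$start[e] <= f && f <= eps$end[e], logical(1)))
      expect_equal(covering, 1)
    }
  }
})
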