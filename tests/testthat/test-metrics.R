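# Association, TFF/TCF, centroid errors, swaps and false rates.

perfectPair <- function(n = 40, k = 3) {
  truth <- do.call(rbind, lapply(seq_len(k), function(i)
    lineTrack(i, 1:n, 30 * i, 10, dx = 1, dy = 0.5)))
  list(system = truth, truth = truth)
}

test_that("self-comparison gives full coverage, unit factors, zero error", {
  p <- perfectPair()
  map <- associateTracks(p$system, p$truth, r = 15)
  tff <- computeTFF(map)
  tcf <- computeTCF(map)
  expect_true(all(tff$perTrack$tff == 1))
  expect_true(all(tcf$perTrack$tcf == 1))
  expect_equal(tff$mean, 1)
  expect_equal(tcf$mean, 1)
  expect_equal(unname(centroidErrors(map)), c(0, 0, 0))
  expect_equal(countIdentitySwaps(map), 0)
})

test_that("systems offset beyond the radius never associate", {
  p <- perfectPair()
  far <- p$system
  far$y <- far$y + 40  # offset 40 px > r = 15 from every truth point
  map <- associateTracks(far, p$truth, r = 15)
  expect_equal(nrow(map@matches), 0)
  expect_warning(tff <- computeTFF(map), "no coverage")
  expect_equal(nrow(tff$perTrack), 0)
  expect_equal(computeTCF(map)$perTrack$tcf, c(0, 0, 0))
  expect_error(centroidErrors(map), "empty association")
})

test_that("a fragmented truth track counts every covering system track", {
  truth <- lineTrack(1, 1:100, 0, 0, dx = 1)
  system <- rbind(lineTrack(10, 1:50, 0, 0, dx = 1),
                  lineTrack(20, 51:100, 50, 0, dx = 1))
  map <- associateTracks(system, truth, r = 5)
  expect_equal(sort(map@assignment$truth_id), c(1, 1))  # both assigned to it
  tff <- computeTFF(map)
  expect_equal(tff$perTrack$tff, 2)
  tcf <- computeTCF(map)
  expect_equal(tcf$perTrack$tcf, 1)  # fragmented but complete

  half <- associateTracks(lineTrack(10, 1:50, 0, 0, dx = 1), truth, r = 5)
  expect_equal(computeTCF(half)$perTrack$tcf, 0.5)
})

test_that("constant-offset systems report the Pythagorean error", {
  truth <- lineTrack(1, 1:30, 0, 0, dx = 1)
  system <- truth
  system$x <- system$x + 3; system$y <- system$y + 4
  map <- associateTracks(system, truth, r = 15)
  expect_equal(unname(centroidErrors(map)), c(5, 5, 5))
})

test_that("completeness never decreases with the association radius", {
  set.seed(77)
  truth <- do.call(rbind, lapply(1:3, function(i)
    lineTrack(i, 1:40, 25 * i, 5 * i, dx = 1)))
  system <- truth
  system$x <- system$x + rnorm(nrow(system), 0, 4)
  system$y <- system$y + rnorm(nrow(system), 0, 4)
  prev <- 0
  for (r in c(1, 2, 5, 10, 20)) {
    cur <- computeTCF(associateTracks(system, truth, r))$mean
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("persistent identity exchanges are counted as swaps", {
  # one system track follows truth 1 for 50 frames, then truth 2
  truth <- rbind(lineTrack(1, 1:100, 0, 0, dx = 1),
                 lineTrack(2, 1:100, 0, 30, dx = 1))
  system <- rbind(lineTrack(5, 1:50, 0, 0, dx = 1),
                  lineTrack(5, 51:100, 50, 30, dx = 1))
  map <- associateTracks(system, truth, r = 10)
  expect_equal(countIdentitySwaps(map), 1)
  # a 3-frame flicker is not a swap
  flick <- rbind(lineTrack(5, 1:50, 0, 0, dx = 1),
                 lineTrack(5, 51:53, 50, 30, dx = 1),
                 lineTrack(5, 54:100, 53, 0, dx = 1))
  map2 <- associateTracks(flick, truth, r = 10)
  expect_equal(countIdentitySwaps(map2), 0)
})

test_that("event failures require broken identity coverage", {
  truth <- rbind(lineTrack(1, 1:100, 0, 0, dx = 1),
                 lineTrack(2, 1:100, 0, 30, dx = 1))
  events <- data.frame(start = 40, T1 = 40, end = 60, category = "passing")
  events$participants <- list(c(1, 2))

  ok <- eventFailures(associateTracks(truth, truth, r = 10), events)
  expect_false(ok$failed)

  # truth 2's coverage breaks inside the event: the event fails
  broken <- rbind(lineTrack(1, 1:100, 0, 0, dx = 1),
                  lineTrack(7, 1:50, 0, 30, dx = 1),
                  lineTrack(8, 51:100, 50, 30, dx = 1))
  bad <- eventFailures(associateTracks(broken, truth, r = 10), events)
  expect_true(bad$failed)
})

test_that("false-rate tables follow the occurrences/failures arithmetic", {
  fr <- falseRateSummary(rep("waiting", 10), rep(FALSE, 10))
  expect_equal(fr$false_rate[fr$category == "waiting"], 0)

  mixed <- falseRateSummary(c(rep("passing", 18), rep("multiple", 9)),
                            c(rep(c(TRUE, rep(FALSE, 17)), 1),
                              TRUE, rep(FALSE, 8)))
  expect_equal(mixed$false_rate[mixed$category == "passing"], 5.6)
  expect_equal(mixed$false_rate[mixed$category == "multiple"], 11.1)
  expect_equal(mixed$occurrences[mixed$category == "Sum"], 27)
})
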