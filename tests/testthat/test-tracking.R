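# Identification rules: overlap classes, prediction, regional matching and
# the per-frame tracker.

test_that("overlap classes count previous identities by pixel intersection", {
  nbr <- countOverlaps(1:4, list())
  expect_equal(nbr$class, "NBR")
  expect_length(nbr$ids, 0)

  obr <- countOverlaps(1:4, list(`5` = 4:6, `9` = 10:12))
  expect_equal(obr$class, "OBR")
  expect_equal(obr$ids, 5L)

  tbr <- countOverlaps(c(3L, 4L, 10L), list(`7` = 10:12, `3` = 4:6))
  expect_equal(tbr$class, "TBR")
  expect_equal(tbr$ids, c(3L, 7L))
})

test_that("linear motion prediction extrapolates constant velocity", {
  expect_equal(predictPosition(rbind(c(10, 10), c(10, 10))), c(10, 10))
  expect_equal(predictPosition(rbind(c(0, 0), c(3, 4))), c(6, 8))
  expect_equal(predictPosition(rbind(c(5, 5))), c(5, 5))
  expect_error(predictPosition(matrix(numeric(0), ncol = 2)), "empty")
})

test_that("regional matching splits the 10x4 two-parent toy exactly", {
  dimHW <- c(20L, 20L)
  nr <- 20L
  idxOf <- function(cols, rows) {
    as.integer(outer(rows + 1L, cols * nr, `+`))
  }
  region <- idxOf(3:12, 5:8)           # 10x4 rectangle
  left <- idxOf(3:7, 5:8)              # previous left half
  right <- idxOf(8:12, 5:8)            # previous right half
  parents <- list(
    list(id = 1L, pixels = left, predicted = c(mean(3:7), mean(5:8))),
    list(id = 2L, pixels = right, predicted = c(mean(8:12), mean(5:8))))
  sp <- splitMergedRegion(region, parents, bodyLen = 15, dimHW = dimHW)
  expect_length(sp$unmatched, 0)
  expect_setequal(sp$masks[["1"]], left)
  expect_setequal(sp$masks[["2"]], right)
  # masks disjoint, union contained in (here: equal to) the region
  expect_length(intersect(sp$masks[["1"]], sp$masks[["2"]]), 0)
  expect_setequal(c(sp$masks[["1"]], sp$masks[["2"]]), region)

  # each parent's claimed overlap matches the exhaustive-search oracle
  avail <- logical(prod(dimHW)); avail[region] <- TRUE
  for (p in parents)
    expect_equal(bruteBestOverlap(p$pixels, p$predicted, avail, dimHW, 15),
                 length(p$pixels))

  # degenerate single claimant: whole region attaches to it
  one <- splitMergedRegion(region, parents[1], bodyLen = 15, dimHW = dimHW)
  expect_setequal(one$masks[["1"]], region)
})

test_that("split masks are always disjoint and inside the region", {
  set.seed(31)
  dimHW <- c(30L, 30L)
  for (rep in 1:10) {
    m <- matrix(FALSE, 30, 30)
    m[10:20, 8:24] <- runif(11 * 17) < 0.8
    region <- which(m)
    if (length(region) < 20) next
    pick <- function() sort(sample(region, 25))
    parents <- list(
      list(id = 1L, pixels = pick(), predicted = c(12, 14)),
      list(id = 2L, pixels = pick(), predicted = c(20, 16)),
      list(id = 3L, pixels = pick(), predicted = c(16, 12)))
    sp <- splitMergedRegion(region, parents, bodyLen = 10, dimHW = dimHW)
    all_px <- unlist(sp$masks)
    expect_equal(anyDuplicated(all_px), 0)
    expect_true(all(all_px %in% region))
  }
})

trackSim <- function(...) {
  sim <- simulateArena(agentConfig(...))
  tr <- suppressWarnings(trackMovie(sim$stack))
  list(sim = sim, tracks = tr, table = trackTable(tr))
}

test_that("first frame assigns fresh consecutive identities to single bees", {
  r <- trackSim(nAgents = 3, nFrames = 20, frameSize = c(150, 150),
                arenaRadius = 60, noiseSD = 0, seed = 21)
  f1 <- r$table[r$table$frame == 1, ]
  expect_setequal(f1$id, 1:3)
  # no contacts in this clip: the three identities persist over all frames
  expect_equal(unique(table(r$table$id)), 20L)
})

test_that("identities persist across a scripted merge and split", {
  sc <- scriptedScenario("crossing")
  tr <- trackMovie(sc$stack, trackConfig(calibFrames = sc$leadIn))
  tt <- trackTable(tr)
  expect_setequal(unique(tt$id), 1:2)        # no fragmentation, no new ids
  map <- associateTracks(tt, truthTable(sc$truth), r = bodyLength(tr@rss))
  expect_equal(countIdentitySwaps(map), 0)
  expect_equal(computeTCF(map)$perTrack$tcf, c(1, 1))
})

test_that("identity inheritance requires spatial overlap across frames", {
  # a blob that teleports farther than its own extent gets a fresh identity
  stack <- rectStack(list(rbind(c(2, 2, 4, 4)),
                          rbind(c(2, 2, 4, 4)),
                          rbind(c(30, 30, 4, 4))))
  rss <- SizeRange(16, 16, 16, 5.2)
  tr <- trackMovie(stack, trackConfig(rss = rss,
                                      background = matrix(200L, 40, 40)))
  tt <- trackTable(tr)
  expect_equal(tt$id[tt$frame == 2], 1)
  expect_equal(tt$id[tt$frame == 3], 2)      # reappearance = new identity
  st <- trackStatus(tr)
  expect_equal(st$status[st$id == 1], "dormant")
  expect_equal(st$status[st$id == 2], "active")
})

test_that("identities claimed per frame are unique and masks disjoint", {
  sc <- scriptedScenario("overlapping")
  bg <- buildBackground(sc$stack)
  rss <- calibrateRSS(sc$stack, background = bg, nFrames = sc$leadIn)
  state <- newTrackerState(dim(bg))
  for (t in seq_len(nFrames(sc$stack))) {
    mask <- foregroundMask(getFrame(sc$stack, t), bg)
    state <- stepTracker(state, extractRegions(mask), rss, frame = t)
    masks <- lapply(Filter(function(tr) tr$status == "active", state$tracks),
                    `[[`, "mask")
    px <- unlist(masks)
    expect_equal(anyDuplicated(px), 0)       # resolved masks never share pixels
  }
  tt <- trackTable(beetrack:::finishTracking(state, rss, 25))
  expect_equal(anyDuplicated(tt[c("frame", "id")]), 0)
  expect_true(any(tt$merged))                # the full-overlap frame happened
})

test_that("tracker output is identical across repeated runs", {
  a <- trackSim(nAgents = 2, nFrames = 30, frameSize = c(150, 150),
                arenaRadius = 60, noiseSD = 2, seed = 13)
  b <- trackSim(nAgents = 2, nFrames = 30, frameSize = c(150, 150),
                arenaRadius = 60, noiseSD = 2, seed = 13)
  expect_identical(a$table, b$table)
})

test_that("an empty movie tracks to an empty result", {
  sim <- simulateArena(agentConfig(nAgents = 0, nFrames = 10,
                                   frameSize = c(100, 100), arenaRadius = 40,
                                   noiseSD = 0, seed = 1))
  tr <- suppressWarnings(trackMovie(sim$stack))
  expect_equal(nrow(trackTable(tr)), 0)
})

test_that("stitching bridges a short gap and flags interpolated rows", {
  tab <- data.frame(frame = c(1:5, 9:12), id = c(rep(1, 5), rep(7, 4)),
                    x = c(1:5, 9:12), y = 0, area = 20, label = 1,
                    merged = FALSE)
  bt <- new("BeeTracks", table = tab,
            status = data.frame(id = c(1, 7), birth = c(1, 9),
                                lastSeen = c(5, 12),
                                status = c("dormant", "active")),
            rss = NULL, fps = 25)
  st <- stitchTracks(bt, maxGap = 5, maxDist = 10)
  tt <- trackTable(st)
  expect_setequal(unique(tt$id), 1)
  expect_equal(tt$frame, 1:12)
  expect_equal(tt$x[tt$frame %in% 6:8], c(6, 7, 8))
  expect_equal(sum(tt$interpolated), 3)
})
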