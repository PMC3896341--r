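# Process B: per-frame identification. Size class x overlap class rules,
# with linear-motion prediction through single-bee-sized merges and
# translational regional matching through plural-bee-sized merges.

#' Tracker configuration
#'
#' All tunables of the tracking pipeline with their defaults.
#'
#' @param threshold binarization threshold (gray levels), default 43.
#' @param calibFrames frames used for RSS calibration, default 500.
#' @param binWidth,modeWindow,rssMargin calibration tunables, see
#'   \code{\link{calibrateRSS}}.
#' @param connectivity component connectivity (8 or 4).
#' @param cleanup logical; apply a 3x3 binary opening to each mask.
#' @param searchRadiusFactor regional-matching search radius as a multiple of
#'   the calibrated body length.
#' @param stitch logical; post-hoc stitching of interrupted tracks (off by
#'   default: a reappearing bee otherwise simply receives a fresh ID).
#' @param maxGap maximal frame gap the stitcher may bridge.
#' @param background optional pre-recorded empty-arena image (integer
#'   matrix); when NULL the per-pixel maximum model is built from the movie.
#' @param rss optional externally supplied \linkS4class{SizeRange}; skips
#'   calibration.
#' @return a named list of class \code{trackConfig}.
#' @export
trackConfig <- function(threshold = 43, calibFrames = 500, binWidth = 4,
                        modeWindow = c(0.5, 1.5), rssMargin = 0,
                        connectivity = 8, cleanup = FALSE,
                        searchRadiusFactor = 1, stitch = FALSE, maxGap = 12,
                        background = NULL, rss = NULL) {
  structure(list(threshold = threshold, calibFrames = calibFrames,
                 binWidth = binWidth, modeWindow = modeWindow,
                 rssMargin = rssMargin, connectivity = connectivity,
                 cleanup = cleanup, searchRadiusFactor = searchRadiusFactor,
                 stitch = stitch, maxGap = maxGap, background = background,
                 rss = rss),
            class = "trackConfig")
}

#' Count previous-frame identities overlapping a region
#'
#' Overlap means a nonempty pixel-set intersection between the current region
#' and a previous frame's resolved per-identity mask. The overlap class is
#' \code{NBR} for zero overlapping identities, \code{OBR} for one and
#' \code{TBR} for two or more.
#'
#' @param regionPixels integer vector of linear pixel indices of the current
#'   region.
#' @param prevMasks named list (names = identity numbers) of linear pixel
#'   index vectors from the previous frame.
#' @return a list with \code{class} (\code{"NBR"/"OBR"/"TBR"}) and \code{ids}
#'   (sorted integer vector of overlapping identities).
#' @examples
#' countOverlaps(1:4, list(`3` = 4:6, `7` = 10:12))
#' @export
countOverlaps <- function(regionPixels, prevMasks) {
  hit <- vapply(prevMasks, function(m) any(m %in% regionPixels), logical(1))
  ids <- sort(as.integer(names(prevMasks)[hit]))
  cls <- if (length(ids) == 0L) "NBR" else if (length(ids) == 1L) "OBR" else "TBR"
  list(class = cls, ids = ids)
}

#' Predict the next position of a track by the linear motion assumption
#'
#' With at least two recorded centroids the next position is the constant
#' velocity extrapolation \code{2 p(t-1) - p(t-2)}; with a single record the
#' last position is returned.
#'
#' @param history a numeric matrix or data.frame of centroids in time order,
#'   columns (x, y); at least one row.
#' @return numeric length-2 vector (x, y).
#' @examples
#' predictPosition(rbind(c(0, 0), c(3, 4)))  # c(6, 8)
#' @export
predictPosition <- function(history) {
  if (is.data.frame(history)) history <- as.matrix(history[, c("x", "y")])
  if (!is.matrix(history)) history <- matrix(history, ncol = 2, byrow = TRUE)
  n <- nrow(history)
  if (n == 0L) stop("empty track: cannot predict")
  if (n == 1L) return(as.numeric(history[1, ]))
  as.numeric(2 * history[n, ] - history[n - 1, ])
}

# Best rigid translation of `pixels` (previous mask) maximizing overlap with
# the available pixels (`avail`, logical over the full frame), searching
# integer offsets that keep the translated centroid within `radius` of
# `predicted`. Returns list(score, idx of overlapped pixels).
bestTranslation <- function(pixels, predicted, avail, dimHW, radius) {
  nr <- dimHW[1]; nc <- dimHW[2]
  xy <- idxToXY(pixels, nr)
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  base <- c(predicted[1] - cx, predicted[2] - cy)
  dxs <- seq.int(floor(base[1] - radius), ceiling(base[1] + radius))
  dys <- seq.int(floor(base[2] - radius), ceiling(base[2] + radius))
  cand <- expand.grid(dx = dxs, dy = dys)
  d2 <- (cand$dx - base[1])^2 + (cand$dy - base[2])^2
  keep <- d2 <= radius^2
  cand <- cand[keep, , drop = FALSE]
  d2 <- d2[keep]
  ord <- order(d2, cand$dx, cand$dy)  # prefer offsets nearest the prediction
  cand <- cand[ord, , drop = FALSE]
  best <- list(score = 0L, idx = integer(0))
  for (k in seq_len(nrow(cand))) {
    nx <- xy[, 1] + cand$dx[k]; ny <- xy[, 2] + cand$dy[k]
    ok <- nx >= 0 & nx < nc & ny >= 0 & ny < nr
    if (!any(ok)) next
    idx <- xyToIdx(nx[ok], ny[ok], nr)
    idx <- idx[avail[idx]]
    if (length(idx) > best$score) best <- list(score = length(idx), idx = idx)
  }
  best
}

#' Split a plural-bee region among its parent identities
#'
#' Regional matching: each parent's previous-frame mask is rigidly translated
#' over a search window of radius \code{bodyLen} centered on its predicted
#' position so as to maximize pixel overlap with the not-yet-claimed part of
#' the region. Parents are processed in decreasing order of their best
#' achievable score (ties to the lowest identity); contested pixels go to the
#' earlier-claimed parent; leftover region pixels are attached to the nearest
#' claimed mask. A parent that achieves zero overlap anywhere in its window
#' is reported as unmatched.
#'
#' @param regionPixels integer vector of linear pixel indices of the region.
#' @param parents list of parents, each a list with elements \code{id}
#'   (integer), \code{pixels} (previous-frame mask indices) and
#'   \code{predicted} (numeric (x, y) predicted position).
#' @param bodyLen search radius in px (the calibrated body length).
#' @param dimHW frame dimensions \code{c(height, width)}.
#' @return a list with \code{masks} (named list id -> disjoint pixel index
#'   vectors whose union is contained in the region) and \code{unmatched}
#'   (integer vector of parent ids left unmatched).
#' @export
splitMergedRegion <- function(regionPixels, parents, bodyLen, dimHW) {
  nr <- dimHW[1]
  avail <- logical(prod(dimHW))
  avail[regionPixels] <- TRUE

  ids <- vapply(parents, `[[`, integer(1), "id")
  ord <- order(-vapply(parents, function(p)
    bestTranslation(p$pixels, p$predicted, avail, dimHW, bodyLen)$score,
    integer(1)), ids)

  masks <- list()
  unmatched <- integer(0)
  for (p in parents[ord]) {
    b <- bestTranslation(p$pixels, p$predicted, avail, dimHW, bodyLen)
    if (b$score == 0L) {
      unmatched <- c(unmatched, p$id)
      next
    }
    masks[[as.character(p$id)]] <- b$idx
    avail[b$idx] <- FALSE
  }

  leftover <- regionPixels[avail[regionPixels]]
  if (length(leftover) > 0L && length(masks) > 0L) {
    lxy <- idxToXY(leftover, nr)
    midv <- sort(as.integer(names(masks)))
    dmat <- vapply(midv, function(id) {
      mxy <- idxToXY(masks[[as.character(id)]], nr)
      vapply(seq_len(nrow(lxy)), function(i)
        min((mxy[, 1] - lxy[i, 1])^2 + (mxy[, 2] - lxy[i, 2])^2), numeric(1))
    }, numeric(nrow(lxy)))
    dmat <- matrix(dmat, nrow = nrow(lxy))
    owner <- midv[max.col(-dmat, ties.method = "first")]
    for (id in unique(owner)) {
      key <- as.character(id)
      masks[[key]] <- sort(c(masks[[key]], leftover[owner == id]))
    }
  }
  list(masks = masks, unmatched = sort(unmatched))
}

#' Fresh tracker state
#'
#' @param dimHW frame dimensions \code{c(height, width)}.
#' @return a \code{TrackerState} object (list with reference semantics for
#'   the record accumulator), to be advanced by \code{\link{stepTracker}}.
#' @export
newTrackerState <- function(dimHW) {
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  structure(list(tracks = list(), nextId = 1L, frame = 0L,
                 dimHW = as.integer(dimHW), acc = acc),
            class = "TrackerState")
}

# Record one resolved identity at the current frame.
recordHit <- function(state, frame, id, x, y, area, label, merged, mask) {
  key <- as.character(id)
  tr <- state$tracks[[key]]
  if (is.null(tr)) {
    tr <- list(id = id, histX = numeric(0), histY = numeric(0),
               birth = frame, status = "active", lastSeen = frame,
               mask = NULL)
  }
  tr$histX <- c(tail(tr$histX, 1L), x)
  tr$histY <- c(tail(tr$histY, 1L), y)
  tr$mask <- mask
  tr$status <- "active"
  tr$lastSeen <- frame
  state$tracks[[key]] <- tr
  state$acc$rows[[length(state$acc$rows) + 1L]] <-
    list(frame = frame, id = id, x = x, y = y, area = area, label = label,
         merged = merged)
  state
}

# Partition a single-bee-sized merged blob's pixels among identities for
# next-frame overlap bookkeeping: nearest predicted position (Voronoi); if
# predictions (nearly) coincide, nearest previous mask instead. Ties go to
# the lowest id.
partitionBlob <- function(regionPixels, preds, prevMasks, ids, nr) {
  xy <- idxToXY(regionPixels, nr)
  k <- length(ids)
  degenerate <- FALSE
  if (k > 1) {
    pd <- as.matrix(stats::dist(do.call(rbind, preds)))
    degenerate <- min(pd[upper.tri(pd)]) < 0.5
  }
  dmat <- if (!degenerate) {
    vapply(seq_len(k), function(i)
      (xy[, 1] - preds[[i]][1])^2 + (xy[, 2] - preds[[i]][2])^2,
      numeric(nrow(xy)))
  } else {
    vapply(seq_len(k), function(i) {
      mxy <- idxToXY(prevMasks[[i]], nr)
      vapply(seq_len(nrow(xy)), function(p)
        min((mxy[, 1] - xy[p, 1])^2 + (mxy[, 2] - xy[p, 2])^2), numeric(1))
    }, numeric(nrow(xy)))
  }
  dmat <- matrix(dmat, nrow = nrow(xy))
  owner <- max.col(-dmat, ties.method = "first")  # first = lowest id (sorted)
  lapply(seq_len(k), function(i) regionPixels[owner == i])
}

#' Advance the tracker by one frame
#'
#' Applies the identification rules to the regions of the current frame:
#' a single-bee-sized region overlapping no previous identity starts a new
#' one; overlapping exactly one, it inherits that identity; a
#' single-bee-sized region overlapping several identities hosts them all at
#' their predicted positions (constrained into the region); a
#' plural-bee-sized region overlapping several identities is divided by
#' regional matching (\code{\link{splitMergedRegion}}). All other
#' combinations claim no identity. Identities claimed by no region become
#' dormant at their last position and take no further part in overlap tests.
#'
#' When one previous identity overlaps several current regions (a separating
#' blob), it is first assigned to the single region whose centroid is nearest
#' its predicted position; the per-region overlap classes are then computed
#' from the assigned identities.
#'
#' @param state a \code{TrackerState} from \code{\link{newTrackerState}}.
#' @param regions region table of the current frame from
#'   \code{\link{extractRegions}}.
#' @param rss the calibrated \linkS4class{SizeRange}.
#' @param config a \code{\link{trackConfig}}.
#' @param frame frame index; defaults to the next frame.
#' @return the updated state.
#' @export
stepTracker <- function(state, regions, rss, config = trackConfig(),
                        frame = NULL) {
  if (is.null(frame)) frame <- state$frame + 1L
  nr <- state$dimHW[1]
  bodyLen <- bodyLength(rss) * config$searchRadiusFactor

  active <- Filter(function(tr) tr$status == "active", state$tracks)
  prevMasks <- lapply(active, `[[`, "mask")
  names(prevMasks) <- vapply(active, function(tr) as.character(tr$id),
                             character(1))

  nReg <- nrow(regions)
  regionIds <- rep(list(integer(0)), max(nReg, 0L))
  if (nReg > 0 && length(prevMasks) > 0) {
    # ownership image of previous resolved masks
    owner <- integer(prod(state$dimHW))
    for (key in names(prevMasks)) owner[prevMasks[[key]]] <- as.integer(key)
    hits <- lapply(seq_len(nReg), function(r) {
      ids <- unique(owner[regions$pixels[[r]]])
      sort(ids[ids > 0L])
    })
    # resolve identities claimed by more than one region: nearest predicted
    # position to region centroid wins (ties to the lowest region label)
    allIds <- sort(unique(unlist(hits)))
    for (id in allIds) {
      rs <- which(vapply(hits, function(h) id %in% h, logical(1)))
      if (length(rs) <= 1L) next
      tr <- state$tracks[[as.character(id)]]
      pred <- predictPosition(cbind(x = tr$histX, y = tr$histY))
      d <- (regions$x[rs] - pred[1])^2 + (regions$y[rs] - pred[2])^2
      keep <- rs[which.min(d)]
      for (r in setdiff(rs, keep)) hits[[r]] <- setdiff(hits[[r]], id)
    }
    regionIds <- hits
  }

  claimed <- integer(0)
  if (nReg > 0) {
    sizeCls <- classifySize(regions$area, rss)
    for (r in seq_len(nReg)) {
      ids <- regionIds[[r]]
      pix <- regions$pixels[[r]]
      cls <- sizeCls[r]
      if (cls == "SBS" && length(ids) == 0L) {
        id <- state$nextId
        state$nextId <- state$nextId + 1L
        state <- recordHit(state, frame, id, regions$x[r], regions$y[r],
                           regions$area[r], regions$label[r], FALSE, pix)
        claimed <- c(claimed, id)
      } else if (cls == "SBS" && length(ids) == 1L) {
        state <- recordHit(state, frame, ids, regions$x[r], regions$y[r],
                           regions$area[r], regions$label[r], FALSE, pix)
        claimed <- c(claimed, ids)
      } else if (cls == "SBS" && length(ids) >= 2L) {
        # merged single-bee-sized blob: identities ride their predictions
        preds <- lapply(ids, function(id) {
          tr <- state$tracks[[as.character(id)]]
          predictPosition(cbind(x = tr$histX, y = tr$histY))
        })
        xy <- idxToXY(pix, nr)
        parts <- partitionBlob(pix, preds, prevMasks[as.character(ids)],
                               ids, nr)
        for (i in seq_along(ids)) {
          p <- preds[[i]]
          d2 <- (xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2
          nearest <- which.min(d2)
          pos <- if (d2[nearest] <= 1) p else as.numeric(xy[nearest, ])
          msk <- parts[[i]]
          if (length(msk) == 0L) msk <- pix[nearest]
          state <- recordHit(state, frame, ids[i], pos[1], pos[2],
                             regions$area[r], regions$label[r], TRUE, msk)
          claimed <- c(claimed, ids[i])
        }
      } else if (cls == "PBS" && length(ids) >= 2L) {
        parents <- lapply(ids, function(id) {
          tr <- state$tracks[[as.character(id)]]
          list(id = id, pixels = tr$mask,
               predicted = predictPosition(cbind(x = tr$histX, y = tr$histY)))
        })
        sp <- splitMergedRegion(pix, parents, bodyLen, state$dimHW)
        for (key in names(sp$masks)) {
          msk <- sp$masks[[key]]
          mxy <- idxToXY(msk, nr)
          state <- recordHit(state, frame, as.integer(key), mean(mxy[, 1]),
                             mean(mxy[, 2]), length(msk), regions$label[r],
                             FALSE, msk)
          claimed <- c(claimed, as.integer(key))
        }
      }
      # all other combinations: no processing
    }
  }

  for (key in names(state$tracks)) {
    tr <- state$tracks[[key]]
    if (tr$status == "active" && !(tr$id %in% claimed)) {
      tr$status <- "dormant"
      tr$mask <- NULL
      state$tracks[[key]] <- tr
    }
  }
  state$frame <- frame
  state
}

# Collect the accumulated records into a BeeTracks object.
finishTracking <- function(state, rss, fps) {
  rows <- state$acc$rows
  if (length(rows) == 0L) {
    table <- data.frame(frame = integer(), id = integer(), x = numeric(),
                        y = numeric(), area = numeric(), label = integer(),
                        merged = logical())
  } else {
    table <- data.frame(
      frame = vapply(rows, `[[`, numeric(1), "frame"),
      id = vapply(rows, `[[`, numeric(1), "id"),
      x = vapply(rows, `[[`, numeric(1), "x"),
      y = vapply(rows, `[[`, numeric(1), "y"),
      area = vapply(rows, `[[`, numeric(1), "area"),
      label = vapply(rows, `[[`, numeric(1), "label"),
      merged = vapply(rows, `[[`, logical(1), "merged"))
    table <- table[order(table$frame, table$id), ]
    rownames(table) <- NULL
  }
  status <- if (length(state$tracks) == 0L) {
    data.frame(id = integer(), birth = integer(), lastSeen = integer(),
               status = character())
  } else {
    data.frame(
      id = vapply(state$tracks, `[[`, numeric(1), "id"),
      birth = vapply(state$tracks, `[[`, numeric(1), "birth"),
      lastSeen = vapply(state$tracks, `[[`, numeric(1), "lastSeen"),
      status = vapply(state$tracks, `[[`, character(1), "status"))
  }
  status <- status[order(status$id), ]
  rownames(status) <- NULL
  new("BeeTracks", table = table, status = status, rss = rss, fps = fps)
}

#' Track a whole movie
#'
#' Full pipeline: background model, per-frame foreground masks and regions,
#' RSS calibration on the initial frames, then the per-frame identification
#' rules over all frames. Deterministic.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param config a \code{\link{trackConfig}}.
#' @return a \linkS4class{BeeTracks}.
#' @examples
#' sim <- simulateArena(agentConfig(nAgents = 2, nFrames = 30,
#'                                  frameSize = c(150, 150), arenaRadius = 60,
#'                                  noiseSD = 0, seed = 3))
#' tr <- suppressWarnings(trackMovie(sim$stack))
#' head(trackTable(tr))
#' @export
trackMovie <- function(stack, config = trackConfig()) {
  stopifnot(is(stack, "FrameStack"))
  bg <- if (is.null(config$background)) buildBackground(stack)
        else config$background
  rss <- if (is.null(config$rss)) {
    tryCatch(
      calibrateRSS(stack, background = bg, threshold = config$threshold,
                   nFrames = config$calibFrames, binWidth = config$binWidth,
                   modeWindow = config$modeWindow, margin = config$rssMargin,
                   connectivity = config$connectivity),
      error = function(e) {
        # an entirely empty movie tracks to an empty result; anything else
        # is a genuine calibration failure
        anyFG <- any(vapply(seq_len(nFrames(stack)), function(t)
          any(foregroundMask(stack@frames[, , t], bg, config$threshold)),
          logical(1)))
        if (anyFG) stop(e)
        NULL
      })
  } else config$rss
  if (is.null(rss))
    return(finishTracking(newTrackerState(dim(bg)), NULL, fps(stack)))
  state <- newTrackerState(dim(bg))
  for (t in seq_len(nFrames(stack))) {
    regions <- frameRegions(stack, t, bg, config$threshold,
                            config$connectivity, config$cleanup)
    state <- stepTracker(state, regions, rss, config, frame = t)
  }
  out <- finishTracking(state, rss, fps(stack))
  if (isTRUE(config$stitch))
    out <- stitchTracks(out, maxGap = config$maxGap,
                        maxDist = bodyLength(rss))
  out
}

#' Post-hoc stitching of interrupted tracks
#'
#' Joins a track that starts shortly after another one ended nearby (gap at
#' most \code{maxGap} frames, distance at most \code{maxDist} px), giving the
#' continuation the earlier identity and linearly interpolating the bridged
#' gap. Interpolated rows are flagged in an \code{interpolated} column. Off
#' by default in \code{\link{trackConfig}}.
#'
#' @param tracks a \linkS4class{BeeTracks}.
#' @param maxGap maximal bridgeable gap in frames.
#' @param maxDist maximal end-to-start distance in px.
#' @return a \linkS4class{BeeTracks} with stitched identities.
#' @export
stitchTracks <- function(tracks, maxGap = 12, maxDist = 15) {
  tab <- trackTable(tracks)
  if (nrow(tab) == 0L) return(tracks)
  tab$interpolated <- FALSE
  repeat {
    ids <- sort(unique(tab$id))
    ends <- do.call(rbind, lapply(ids, function(i) {
      ti <- tab[tab$id == i, ]
      data.frame(id = i, first = min(ti$frame), last = max(ti$frame),
                 x0 = ti$x[which.min(ti$frame)], y0 = ti$y[which.min(ti$frame)],
                 x1 = ti$x[which.max(ti$frame)], y1 = ti$y[which.max(ti$frame)])
    }))
    done <- TRUE
    for (i in seq_len(nrow(ends))) {
      a <- ends[i, ]
      cand <- ends[ends$first > a$last & ends$first - a$last <= maxGap + 1, ]
      if (nrow(cand) == 0L) next
      d <- sqrt((cand$x0 - a$x1)^2 + (cand$y0 - a$y1)^2)
      if (min(d) > maxDist) next
      b <- cand[which.min(d), ]
      gapFrames <- setdiff(seq.int(a$last + 1L, b$first - 1L), integer(0))
      if (length(gapFrames) > 0L) {
        w <- seq_along(gapFrames) / (length(gapFrames) + 1)
        bridge <- data.frame(frame = gapFrames, id = a$id,
                             x = a$x1 + w * (b$x0 - a$x1),
                             y = a$y1 + w * (b$y0 - a$y1),
                             area = NA_real_, label = NA_integer_,
                             merged = FALSE, interpolated = TRUE)
        tab <- rbind(tab, bridge)
      }
      tab$id[tab$id == b$id] <- a$id
      done <- FALSE
      break
    }
    if (done) break
  }
  tab <- tab[order(tab$frame, tab$id), ]
  rownames(tab) <- NULL
  st <- tracks@status[tracks@status$id %in% tab$id, ]
  new("BeeTracks", table = tab, status = st, rss = tracks@rss,
      fps = tracks@fps)
}
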