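# Independent oracles and small fixture builders used across the suite.

# Brute-force flood fill: connected components by BFS over a logical mask.
# Returns an integer label matrix; labels numbered in column-major order of
# first discovery, matching no particular implementation detail beyond that.
floodFillLabels <- function(mask, eight = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (eight) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  k <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    k <- k + 1L
    queue <- list(c(i, j))
    lab[i, j] <- k
    while (length(queue) > 0L) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[q, 1]; cc <- p[2] + nbr[q, 2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- k
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# Exhaustive translation-search oracle for regional matching: best overlap of
# `maskIdx` translated anywhere (all offsets within `radius` of the centroid
# shift toward `predicted`), against availability vector `avail`.
bruteBestOverlap <- function(maskIdx, predicted, avail, dimHW, radius) {
  nr <- dimHW[1]; nc <- dimHW[2]
  r <- (maskIdx - 1L) %% nr; c <- (maskIdx - 1L) %/% nr
  cx <- mean(c); cy <- mean(r)
  base <- c(predicted[1] - cx, predicted[2] - cy)
  best <- 0L
  for (dx in seq.int(floor(base[1] - radius), ceiling(base[1] + radius)))
    for (dy in seq.int(floor(base[2] - radius), ceiling(base[2] + radius))) {
      if ((dx - base[1])^2 + (dy - base[2])^2 > radius^2) next
      nx <- c + dx; ny <- r + dy
      ok <- nx >= 0 & nx < nc & ny >= 0 & ny < nr
      if (!any(ok)) next
      idx <- ny[ok] + 1L + nx[ok] * nr
      sc <- sum(avail[idx])
      if (sc > best) best <- sc
    }
  best
}

# A FrameStack holding the given matrices (integer 0-255).
stackOf <- function(..., fps = 25) {
  FrameStack(lapply(list(...), function(m) {
    storage.mode(m) <- "integer"
    m
  }), fps = fps)
}

# Stack of `n` frames, each bright background with dark filled rectangles:
# rects is a list per frame of rbind(c(row0, col0, height, width), ...)
# (1-based, inclusive).
rectStack <- function(rectsPerFrame, dimHW = c(40, 40), bg = 200L, fg = 30L,
                      fps = 25) {
  frames <- lapply(rectsPerFrame, function(rects) {
    m <- matrix(bg, dimHW[1], dimHW[2])
    if (!is.null(rects)) for (k in seq_len(nrow(rects))) {
      r <- rects[k, ]
      m[r[1]:(r[1] + r[3] - 1), r[2]:(r[2] + r[4] - 1)] <- fg
    }
    storage.mode(m) <- "integer"
    m
  })
  FrameStack(frames, fps = fps)
}

# Random logical mask with roughly the given fill fraction.
randomMask <- function(nr, nc, fill = 0.3) {
  matrix(runif(nr * nc) < fill, nr, nc)
}

# Straight-line trajectory table for metric tests.
lineTrack <- function(id, frames, x0, y0, dx = 0, dy = 0) {
  data.frame(frame = frames, id = id,
             x = x0 + dx * (seq_along(frames) - 1),
             y = y0 + dy * (seq_along(frames) - 1))
}
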