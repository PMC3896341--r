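# Process A: background modeling, subtraction, binarization and
# connected-component region extraction.

#' Build a background model by per-pixel maximum
#'
#' The animals are darker than the arena, so under stable lighting the
#' brightest value ever seen at a pixel is the background. If an empty-arena
#' image is available it can be passed to the downstream functions directly
#' instead.
#'
#' @param stack a \linkS4class{FrameStack} with at least one frame.
#' @return an integer matrix of the same size as the frames, with
#'   \code{background[p] >= frame[p]} for every frame and pixel.
#' @examples
#' fs <- FrameStack(list(matrix(10L, 3, 3), matrix(200L, 3, 3)))
#' buildBackground(fs)[1, 1]  # 200
#' @export
buildBackground <- function(stack) {
  stopifnot(is(stack, "FrameStack"))
  n <- nFrames(stack)
  bg <- stack@frames[, , 1]
  if (n > 1) for (t in 2:n) bg <- pmax(bg, stack@frames[, , t])
  storage.mode(bg) <- "integer"
  bg
}

#' Foreground mask by background subtraction and thresholding
#'
#' A pixel is foreground iff \code{background - frame >= threshold};
#' negative differences (pixels brighter than the background model) are
#' clamped to zero, so only dark-on-bright objects are detected.
#'
#' @param frame,background integer matrices of identical size.
#' @param threshold gray-level difference threshold (>= 0). The default 43 is
#'   the binarization threshold used for the reference recordings this
#'   package targets.
#' @return a logical matrix.
#' @examples
#' bg <- matrix(200L, 4, 4); fr <- bg; fr[2, 2] <- 30L
#' sum(foregroundMask(fr, bg))  # 1
#' @export
foregroundMask <- function(frame, background, threshold = 43) {
  if (!identical(dim(frame), dim(background)))
    stop("frame and background sizes differ")
  stopifnot(threshold >= 0)
  diffim <- background - frame
  diffim[diffim < 0] <- 0L
  diffim >= threshold
}

#' Extract labeled regions from a binary mask
#'
#' Labels 8-connected foreground components and computes per-region features:
#' pixel count, centroid (mean of member pixel coordinates, 0-based), bounding
#' box, and the major/minor axis lengths of the moment-equivalent ellipse
#' (from second-order central moments).
#'
#' @param mask a logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return a data.frame with one row per component: \code{label, area, x, y,
#'   major, minor, xmin, ymin, xmax, ymax} and a list column \code{pixels}
#'   of linear (column-major) pixel indices. Zero rows for an empty mask.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
#' extractRegions(m)[, c("area", "x", "y")]  # area 4, centroid (0.5, 0.5)
#' @export
extractRegions <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask)
  lab <- .cc_label(mask, eight = connectivity == 8)
  fg <- which(lab > 0L)
  out <- data.frame(label = integer(), area = integer(), x = numeric(),
                    y = numeric(), major = numeric(), minor = numeric(),
                    xmin = numeric(), ymin = numeric(), xmax = numeric(),
                    ymax = numeric())
  out$pixels <- list()
  if (length(fg) == 0L) return(out)
  labs <- lab[fg]
  pix <- split(fg, labs)
  xy <- idxToXY(fg, nr)
  k <- length(pix)
  feat <- matrix(0, k, 8)
  for (g in seq_len(k)) {
    sel <- labs == g
    px <- xy[sel, 1]; py <- xy[sel, 2]
    mx <- mean(px); my <- mean(py)
    mu20 <- mean(px^2) - mx^2
    mu02 <- mean(py^2) - my^2
    mu11 <- mean(px * py) - mx * my
    common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    l1 <- (mu20 + mu02) / 2 + common
    l2 <- max(0, (mu20 + mu02) / 2 - common)
    feat[g, ] <- c(mx, my, 4 * sqrt(l1), 4 * sqrt(l2),
                   min(px), min(py), max(px), max(py))
  }
  out <- data.frame(label = seq_len(k), area = lengths(pix),
                    x = feat[, 1], y = feat[, 2], major = feat[, 3],
                    minor = feat[, 4], xmin = feat[, 5], ymin = feat[, 6],
                    xmax = feat[, 7], ymax = feat[, 8])
  out$pixels <- unname(pix)
  attr(out, "dim_hw") <- dim(mask)
  out
}

# Regions of one frame of a stack (internal convenience).
frameRegions <- function(stack, t, background, threshold = 43,
                         connectivity = 8, cleanup = FALSE) {
  mask <- foregroundMask(stack@frames[, , t], background, threshold)
  if (cleanup) mask <- binaryOpen(mask)
  extractRegions(mask, connectivity)
}

# 3x3 binary opening (erosion then dilation); optional cleanup step, off by
# default.
binaryOpen <- function(mask) {
  er <- shiftAnd(mask)
  shiftOr(er)
}

shiftAnd <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & shiftMat(m, dr, dc, fill = FALSE)
  }
  out
}

shiftOr <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shiftMat(m, dr, dc, fill = FALSE)
  }
  out
}

shiftMat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Tracking robustness over a range of binarization thresholds
#'
#' Runs the full tracker once per threshold and reports the mean trajectory
#' completeness factor (TCF) against ground truth, supporting robustness
#' curves over the threshold.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param truth the matching \linkS4class{GroundTruth}.
#' @param thresholds numeric vector of thresholds to evaluate (non-empty).
#' @param config base tracker configuration (\code{\link{trackConfig}});
#'   its threshold entry is replaced per run.
#' @param radius association radius in px; default: the body length
#'   calibrated in each run.
#' @return a data.frame with columns \code{threshold} and \code{mean_tcf}.
#' @export
thresholdSweep <- function(stack, truth, thresholds, config = trackConfig(),
                           radius = NULL) {
  if (length(thresholds) == 0L) stop("empty threshold list")
  res <- vapply(thresholds, function(th) {
    cfg <- config
    cfg$threshold <- th
    tracks <- tryCatch(trackMovie(stack, cfg), error = function(e) NULL)
    if (is.null(tracks) || nrow(trackTable(tracks)) == 0L) return(0)
    r <- if (is.null(radius)) bodyLength(tracks@rss) else radius
    map <- associateTracks(trackTable(tracks), truthTable(truth), r)
    computeTCF(map)$mean
  }, numeric(1))
  data.frame(threshold = thresholds, mean_tcf = res)
}
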