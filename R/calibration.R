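# Calibration of the Range of Single-bee Size (RSS) and body length from
# the initial movie frames.

#' Calibrate the range of single-bee sizes (RSS)
#'
#' Collects the areas of all foreground regions over the initial movie frames
#' (default 500 frames = 20 s at 25 fps), locates the modal area \eqn{m} by a
#' histogram, keeps areas inside the mode window \eqn{[0.5m, 1.5m]} as
#' single-bee candidates (the window rejects merged, roughly double-sized
#' blobs and small specks), and returns the candidate min/max as the RSS
#' together with the mean major-axis length (body length) of the candidate
#' regions.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param background optional background image; computed by
#'   \code{\link{buildBackground}} from the whole stack when NULL.
#' @param threshold binarization threshold, see \code{\link{foregroundMask}}.
#' @param nFrames number of initial frames used (default 500). If the movie
#'   is shorter, all frames are used with a warning.
#' @param binWidth histogram bin width in px^2 for locating the mode.
#' @param modeWindow multiplicative window around the modal area within which
#'   areas count as single bees.
#' @param margin optional relative widening of the RSS (default 0), e.g. 0.05
#'   widens both bounds by 5\% to absorb pose-dependent area changes.
#' @param connectivity component connectivity, 8 or 4.
#' @return a \linkS4class{SizeRange}.
#' @export
calibrateRSS <- function(stack, background = NULL, threshold = 43,
                         nFrames = 500, binWidth = 4,
                         modeWindow = c(0.5, 1.5), margin = 0,
                         connectivity = 8) {
  stopifnot(is(stack, "FrameStack"))
  nAvail <- nFrames(stack)
  if (nAvail < nFrames) {
    warning("movie shorter than ", nFrames, " frames; using all ", nAvail)
    nFrames <- nAvail
  }
  if (is.null(background)) background <- buildBackground(stack)
  areas <- vector("list", nFrames)
  majors <- vector("list", nFrames)
  for (t in seq_len(nFrames)) {
    reg <- frameRegions(stack, t, background, threshold, connectivity)
    areas[[t]] <- reg$area
    majors[[t]] <- reg$major
  }
  areas <- unlist(areas); majors <- unlist(majors)
  if (length(areas) == 0L)
    stop("calibration error: no foreground regions in the calibration window")

  # modal area: midpoint-insensitive -- median of the areas in the fullest bin
  breaks <- seq(0, max(areas) + binWidth, by = binWidth)
  bins <- cut(areas, breaks, include.lowest = TRUE, labels = FALSE)
  modalBin <- as.integer(names(which.max(table(bins))))
  m <- stats::median(areas[bins == modalBin])

  keep <- areas >= modeWindow[1] * m & areas <= modeWindow[2] * m
  cand <- areas[keep]
  rssMin <- min(cand) * (1 - margin)
  rssMax <- max(cand) * (1 + margin)
  SizeRange(minArea = rssMin, maxArea = rssMax, modalArea = m,
            bodyLength = mean(majors[keep]), nSamples = sum(keep))
}

#' Classify a region area against the RSS
#'
#' Size classes partition all possible areas: \code{SBS} (single bee size)
#' iff the area lies inside the closed RSS interval, \code{PBS} (plural bee
#' size) above its maximum, \code{NBS} (no bee size) below its minimum.
#'
#' @param area numeric vector of region areas in px^2 (a region row from
#'   \code{\link{extractRegions}} also works via its \code{area} column).
#' @param rss a \linkS4class{SizeRange}.
#' @return character vector of \code{"SBS"}, \code{"PBS"}, \code{"NBS"}.
#' @examples
#' rss <- SizeRange(50, 80, 60, 15)
#' classifySize(c(49, 50, 60, 80, 81), rss)
#' @export
classifySize <- function(area, rss) {
  stopifnot(is(rss, "SizeRange"))
  if (is.data.frame(area)) area <- area$area
  ifelse(area < rss@minArea, "NBS",
         ifelse(area > rss@maxArea, "PBS", "SBS"))
}

#' Write a calibration report as JSON
#'
#' @param rss a \linkS4class{SizeRange}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCalibration <- function(rss, path) {
  jsonlite::write_json(
    list(min_area = rss@minArea, max_area = rss@maxArea,
         modal_area = rss@modalArea, body_length = rss@bodyLength,
         n_samples = rss@nSamples),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
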