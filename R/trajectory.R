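# Process C: centroid trajectories, kinematics and exports.

#' Per-frame kinematics of one track
#'
#' Speed is the centroid displacement between consecutive records times the
#' frame rate (px/s); acceleration is the discrete difference of speed times
#' the frame rate (px/s^2); heading is the direction of the displacement
#' (radians). Values that need more history than available (the first record
#' for speed/heading, the first two for acceleration) are missing (NA), not
#' zero: zeros would fake resting.
#'
#' @param track data.frame with columns \code{frame, x, y} for a single
#'   identity, ordered by frame.
#' @param fps frames per second.
#' @return a data.frame \code{frame, speed, acceleration, heading}.
#' @examples
#' tr <- data.frame(frame = 1:3, x = c(0, 3, 6), y = c(0, 4, 8))
#' kinematics(tr, fps = 25)$speed  # NA 125 125
#' @export
kinematics <- function(track, fps) {
  n <- nrow(track)
  speed <- rep(NA_real_, n)
  heading <- rep(NA_real_, n)
  if (n >= 2) {
    dx <- diff(track$x); dy <- diff(track$y); df <- diff(track$frame)
    speed[-1] <- sqrt(dx^2 + dy^2) / df * fps
    heading[-1] <- atan2(dy, dx)
  }
  acceleration <- rep(NA_real_, n)
  if (n >= 3) acceleration[-(1:2)] <- diff(speed[-1]) * fps
  data.frame(frame = track$frame, speed = speed,
             acceleration = acceleration, heading = heading)
}

#' Total distance moved by a track
#'
#' Sum of consecutive centroid displacements (polyline length), in px.
#'
#' @param track data.frame with columns \code{x, y} in frame order.
#' @return numeric(1).
#' @examples
#' sq <- data.frame(x = c(0, 10, 10, 0, 0), y = c(0, 0, 10, 10, 0))
#' totalDistance(sq)  # 40
#' @export
totalDistance <- function(track) {
  if (nrow(track) < 2) return(0)
  sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
}

#' Trajectory table from tracking results
#'
#' Long-format table with one row per identity per frame it was resolved in:
#' \code{frame, id, x, y, area, speed, heading} (speed in px/s, heading in
#' radians; missing where undefined). Frames where an identity was dormant
#' are not emitted (its position is unknown). The \code{merged} flag of the
#' tracker is carried along when present.
#'
#' @param tracks a \linkS4class{BeeTracks}, or a data.frame already holding
#'   \code{frame, id, x, y} (e.g. a ground-truth table), in which case
#'   \code{fps} must be given.
#' @param fps frames per second (taken from \code{tracks} when possible).
#' @return a data.frame as described.
#' @export
trajectoryTable <- function(tracks, fps = NULL) {
  if (is(tracks, "BeeTracks")) {
    tab <- trackTable(tracks)
    fps <- tracks@fps
  } else {
    tab <- tracks
    if (is.null(fps)) stop("fps must be given for a plain data.frame")
  }
  if (nrow(tab) == 0L)
    return(data.frame(frame = integer(), id = integer(), x = numeric(),
                      y = numeric(), area = numeric(), speed = numeric(),
                      heading = numeric()))
  if (is.null(tab$area)) tab$area <- NA_real_
  tab <- tab[order(tab$id, tab$frame), ]
  pieces <- lapply(split(tab, tab$id), function(ti) {
    kin <- kinematics(ti, fps)
    out <- data.frame(frame = ti$frame, id = ti$id, x = ti$x, y = ti$y,
                      area = ti$area, speed = kin$speed,
                      heading = kin$heading)
    if (!is.null(ti$merged)) out$merged <- ti$merged
    out
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$frame, out$id), ]
  rownames(out) <- NULL
  out
}

#' Export / read a trajectory table as CSV
#'
#' Writes UTF-8 comma-separated values with the header
#' \code{frame,id,x,y,area,speed,heading}; numeric values are written with 6
#' decimals, so a re-import reproduces the table exactly at that precision.
#' Missing kinematics are empty fields.
#'
#' @param table a trajectory table (see \code{\link{trajectoryTable}}).
#' @param path output CSV path.
#' @return \code{exportTrajectories}: the path, invisibly.
#' @export
exportTrajectories <- function(table, path) {
  cols <- c("frame", "id", "x", "y", "area", "speed", "heading")
  out <- table[intersect(cols, names(table))]
  for (nm in c("x", "y", "area", "speed", "heading"))
    if (!is.null(out[[nm]])) out[[nm]] <- round(out[[nm]], 6)
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8",
            na = "")
  invisible(path)
}

#' @rdname exportTrajectories
#' @export
readTrajectories <- function(path) {
  read.csv(path, fileEncoding = "UTF-8")
}

#' Render overlay frames
#'
#' Draws each track's polyline up to the current frame, with the identity
#' number at the current position, on top of the source frame, and writes one
#' PNG per frame (\code{frame_\%06d.png}) into \code{outdir}.
#'
#' @param stack the source \linkS4class{FrameStack}.
#' @param tracks a \linkS4class{BeeTracks} or trajectory table.
#' @param outdir output directory (created if needed).
#' @param frames which frames to render (default: all).
#' @return the output directory, invisibly.
#' @export
renderOverlay <- function(stack, tracks, outdir, frames = seq_len(nFrames(stack))) {
  tab <- if (is(tracks, "BeeTracks")) trackTable(tracks) else tracks
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ids <- sort(unique(tab$id))
  pal <- grDevices::rainbow(max(length(ids), 1L))
  w <- frameSize(stack)["width"]; h <- frameSize(stack)["height"]
  for (t in frames) {
    fn <- file.path(outdir, sprintf("frame_%06d.png", t))
    grDevices::png(fn, width = w, height = h)
    graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
    graphics::plot(NA, xlim = c(-0.5, w - 0.5), ylim = c(h - 0.5, -0.5),
                   axes = FALSE, xlab = "", ylab = "", asp = 1)
    graphics::rasterImage(grDevices::as.raster(getFrame(stack, t) / 255),
                          -0.5, h - 0.5, w - 0.5, -0.5)
    for (k in seq_along(ids)) {
      ti <- tab[tab$id == ids[k] & tab$frame <= t, ]
      if (nrow(ti) == 0L) next
      graphics::lines(ti$x, ti$y, col = pal[k], lwd = 2)
      if (max(ti$frame) == t) {
        cur <- ti[which.max(ti$frame), ]
        graphics::text(cur$x, cur$y - 6, labels = ids[k], col = pal[k],
                       cex = 1.2, font = 2)
      }
    }
    grDevices::dev.off()
  }
  invisible(outdir)
}
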