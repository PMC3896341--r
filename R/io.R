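# File interfaces: numbered frame directories (PNG/TIFF), ground-truth CSV
# and event JSON.

#' Read a numbered frame directory as a FrameStack
#'
#' Reads all PNG (or TIFF, if the tiff package is available) files of a
#' directory in lexicographic order. Color images are converted to grayscale
#' by standard luminance weighting (0.299 R + 0.587 G + 0.114 B).
#'
#' @param dir directory of frames.
#' @param fps frames per second to attach.
#' @param pattern file name regexp, default PNG/TIFF extensions.
#' @return a \linkS4class{FrameStack}.
#' @export
readFrames <- function(dir, fps = 25, pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(dir, pattern = pattern, ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop("no frame files in ", dir)
  readOne <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is needed for TIFF input")
      tiff::readTIFF(f)
    }
    if (length(dim(img)) == 3L) {
      # luminance weighting; an alpha channel, if present, is ignored
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    }
    m <- round(img * 255)
    storage.mode(m) <- "integer"
    m
  }
  FrameStack(lapply(files, readOne), fps = fps)
}

#' Write a FrameStack as a numbered PNG directory
#'
#' Frames are written as 8-bit grayscale \code{frame_\%06d.png}.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeFrames <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_len(nFrames(stack)))
    png::writePNG(getFrame(stack, t) / 255,
                  file.path(dir, sprintf("frame_%06d.png", t)))
  invisible(dir)
}

#' Write / read ground truth
#'
#' Positions go to CSV (\code{frame,id,x,y,heading,state}); scripted events,
#' if any, to JSON next to it.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param csvPath positions CSV path.
#' @param jsonPath events JSON path (optional; default: csvPath with
#'   \code{.events.json}).
#' @return \code{writeGroundTruth}: \code{csvPath}, invisibly.
#' @export
writeGroundTruth <- function(truth, csvPath, jsonPath = NULL) {
  pos <- truthTable(truth)
  for (nm in c("x", "y", "heading")) pos[[nm]] <- round(pos[[nm]], 6)
  write.csv(pos, csvPath, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  ev <- truthEvents(truth)
  if (nrow(ev) > 0L) {
    if (is.null(jsonPath)) jsonPath <- sub("\\.csv$", ".events.json", csvPath)
    writeEvents(ev, jsonPath)
  }
  invisible(csvPath)
}

#' @rdname writeGroundTruth
#' @param csvPath positions CSV path to read.
#' @export
readGroundTruth <- function(csvPath, jsonPath = NULL) {
  pos <- read.csv(csvPath, fileEncoding = "UTF-8")
  if (is.null(jsonPath)) {
    guess <- sub("\\.csv$", ".events.json", csvPath)
    jsonPath <- if (file.exists(guess)) guess else NULL
  }
  events <- emptyTruthEvents()
  if (!is.null(jsonPath)) {
    lst <- jsonlite::read_json(jsonPath, simplifyVector = FALSE)
    if (length(lst) > 0L) {
      events <- data.frame(
        start = vapply(lst, function(e) as.integer(e$start), integer(1)),
        T1 = vapply(lst, function(e) as.integer(e$T1), integer(1)),
        end = vapply(lst, function(e) as.integer(e$end), integer(1)),
        category = vapply(lst, function(e) as.character(e$category),
                          character(1)))
      events$participants <- lapply(lst, function(e)
        as.integer(unlist(e$participants)))
      events <- events[c("participants", "start", "T1", "end", "category")]
    }
  }
  GroundTruth(positions = pos, events = events)
}
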