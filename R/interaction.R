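# Encounter detection from inter-individual distance and classification into
# the interaction categories crossing / touching / passing / overlapping /
# waiting, plus "multiple" for three or more participants.

#' Interaction classification parameters
#'
#' @param theta direction-change threshold in degrees: a bee "changed
#'   direction" if its mean heading before vs after the episode differs by
#'   more than this.
#' @param phi same-direction cone in degrees: incoming headings closer than
#'   this count as "coming from the same direction".
#' @param vStop stop speed in body lengths per second: below it a bee counts
#'   as stopped.
#' @param window number of frames before/after the episode over which mean
#'   headings are taken.
#' @return a named list.
#' @export
interactionParams <- function(theta = 45, phi = 90, vStop = 0.1, window = 12) {
  list(theta = theta, phi = phi, vStop = vStop, window = window)
}

#' Detect encounter episodes from a trajectory table
#'
#' An encounter is a maximal run of consecutive frames in which two
#' identities' centroid distance stays below \code{contactDist} (one body
#' length; 15 px reproduces the reference setting for honeybees). Pairwise
#' episodes that share a participant and overlap in time are merged into one
#' multi-participant episode. T1 is the first contact frame of the episode.
#'
#' @param table a trajectory table (\code{frame, id, x, y, ...}).
#' @param contactDist contact distance in px.
#' @return a data.frame with list column \code{participants} and columns
#'   \code{start, T1, end}; zero rows when nothing meets.
#' @export
detectEncounters <- function(table, contactDist = 15) {
  stopifnot(contactDist > 0)
  empty <- emptyTruthEvents()[c("participants", "start", "T1", "end")]
  ids <- sort(unique(table$id))
  if (length(ids) < 2) return(empty)
  eps <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    ti <- table[table$id == ids[i], c("frame", "x", "y")]
    for (j in (i + 1):length(ids)) {
      tj <- table[table$id == ids[j], c("frame", "x", "y")]
      m <- merge(ti, tj, by = "frame", suffixes = c("_i", "_j"))
      if (nrow(m) == 0L) next
      d <- sqrt((m$x_i - m$x_j)^2 + (m$y_i - m$y_j)^2)
      fr <- sort(m$frame[d < contactDist])
      if (length(fr) == 0L) next
      brk <- c(0L, which(diff(fr) > 1L), length(fr))
      for (k in seq_len(length(brk) - 1L)) {
        run <- fr[(brk[k] + 1L):brk[k + 1L]]
        eps[[length(eps) + 1L]] <- list(participants = c(ids[i], ids[j]),
                                        start = min(run), end = max(run))
      }
    }
  }
  if (length(eps) == 0L) return(empty)
  # merge episodes sharing a participant within overlapping frame spans
  repeat {
    mergedAny <- FALSE
    for (a in seq_along(eps)) {
      for (b in seq_along(eps)) {
        if (b <= a) next
        ea <- eps[[a]]; eb <- eps[[b]]
        if (length(intersect(ea$participants, eb$participants)) > 0L &&
            ea$start <= eb$end && eb$start <= ea$end) {
          eps[[a]] <- list(
            participants = sort(unique(c(ea$participants, eb$participants))),
            start = min(ea$start, eb$start), end = max(ea$end, eb$end))
          eps[[b]] <- NULL
          mergedAny <- TRUE
          break
        }
      }
      if (mergedAny) break
    }
    if (!mergedAny) break
  }
  out <- data.frame(start = vapply(eps, `[[`, numeric(1), "start"),
                    T1 = vapply(eps, `[[`, numeric(1), "start"),
                    end = vapply(eps, `[[`, numeric(1), "end"))
  out$participants <- lapply(eps, `[[`, "participants")
  out <- out[order(out$start), c("participants", "start", "T1", "end")]
  rownames(out) <- NULL
  out
}

# Mean movement heading of one id over a frame window; NA if it barely moved.
meanHeading <- function(table, id, frames) {
  ti <- table[table$id == id & table$frame %in% frames, ]
  if (nrow(ti) < 2) return(NA_real_)
  ti <- ti[order(ti$frame), ]
  dx <- sum(diff(ti$x)); dy <- sum(diff(ti$y))
  if (sqrt(dx^2 + dy^2) < 1e-6) return(NA_real_)
  atan2(dy, dx)
}

#' Classify one encounter episode
#'
#' Rules, in precedence order: three or more participants give
#' \code{multiple}; exactly one participant stopped from T1 until separation
#' gives \code{waiting}; if the two resolved regions merged into one
#' single-bee-sized component during the episode (full body overlap) and
#' neither bee changed direction, \code{overlapping}; if neither changed
#' direction (without such a merge), \code{crossing}; otherwise
#' \code{touching} when the incoming headings differ by less than \code{phi}
#' and \code{passing} when they differ by at least \code{phi}. Direction
#' change compares mean headings over \code{window} frames before and after
#' the episode against \code{theta}.
#'
#' @param episode one row of \code{\link{detectEncounters}} output (or a list
#'   with \code{participants, start, T1, end}).
#' @param table the trajectory table the episode came from; a \code{merged}
#'   column (as produced by the tracker) signals full-overlap merges, and is
#'   taken as all-FALSE when absent.
#' @param params see \code{\link{interactionParams}}.
#' @param bodyLen body length in px (scales the stop speed).
#' @param fps frames per second of the table.
#' @return a single category string.
#' @export
classifyInteraction <- function(episode, table, params = interactionParams(),
                                bodyLen = 15, fps = 25) {
  if (is.data.frame(episode)) {
    stopifnot(nrow(episode) == 1L)
    episode <- list(participants = episode$participants[[1]],
                    start = episode$start, T1 = episode$T1,
                    end = episode$end)
  }
  if (episode$end < episode$start) stop("empty episode")
  ids <- episode$participants
  if (length(ids) >= 3L) return("multiple")
  if (length(ids) < 2L) stop("an episode needs at least two participants")

  vStopPx <- params$vStop * bodyLen  # px/s
  during <- seq.int(episode$T1, episode$end)
  stopped <- vapply(ids, function(id) {
    sp <- table$speed[table$id == id & table$frame %in% during]
    sp <- sp[!is.na(sp)]
    length(sp) > 0 && all(sp <= vStopPx)
  }, logical(1))
  if (sum(stopped) == 1L) return("waiting")

  merged <- FALSE
  if (!is.null(table$merged))
    merged <- any(table$merged[table$id %in% ids &
                               table$frame >= episode$start &
                               table$frame <= episode$end])

  W <- params$window
  pre <- seq.int(episode$start - W, episode$start - 1L)
  post <- seq.int(episode$end + 1L, episode$end + W)
  thetaRad <- deg2rad(params$theta)
  hPre <- vapply(ids, function(id) meanHeading(table, id, pre), numeric(1))
  hPost <- vapply(ids, function(id) meanHeading(table, id, post), numeric(1))
  changed <- !is.na(hPre) & !is.na(hPost) &
    angDiff(hPre, hPost) > thetaRad

  if (!any(changed)) return(if (merged) "overlapping" else "crossing")
  # at least one direction change: separate same- vs different-direction
  inDiff <- if (any(is.na(hPre))) NA_real_ else angDiff(hPre[1], hPre[2])
  if (!is.na(inDiff) && inDiff < deg2rad(params$phi)) "touching" else "passing"
}

#' Classify all episodes of a table
#'
#' @param episodes output of \code{\link{detectEncounters}}.
#' @param table,params,bodyLen,fps see \code{\link{classifyInteraction}}.
#' @return \code{episodes} with an added \code{category} column.
#' @export
classifyInteractions <- function(episodes, table,
                                 params = interactionParams(), bodyLen = 15,
                                 fps = 25) {
  episodes$category <- vapply(seq_len(nrow(episodes)), function(i)
    classifyInteraction(episodes[i, ], table, params, bodyLen, fps),
    character(1))
  episodes
}

#' Distances and speed around one focal bee
#'
#' Emits the data behind distance/speed encounter plots: the per-frame
#' Euclidean distance from the focal bee to every other identity, the focal
#' bee's speed, and a below-threshold flag.
#'
#' @param table a trajectory table.
#' @param focalId the focal identity.
#' @param contactDist threshold distance in px.
#' @return a data.frame \code{frame, other, distance, speed, contact}.
#' @export
distanceSpeedReport <- function(table, focalId, contactDist = 15) {
  tf <- table[table$id == focalId, ]
  if (nrow(tf) == 0L) stop("unknown focal id: ", focalId)
  others <- setdiff(unique(table$id), focalId)
  out <- lapply(others, function(o) {
    to <- table[table$id == o, c("frame", "x", "y")]
    m <- merge(tf[, c("frame", "x", "y", "speed")], to, by = "frame",
               suffixes = c("_f", "_o"))
    if (nrow(m) == 0L) return(NULL)
    d <- sqrt((m$x_f - m$x_o)^2 + (m$y_f - m$y_o)^2)
    data.frame(frame = m$frame, other = o, distance = d, speed = m$speed,
               contact = d < contactDist)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(), other = integer(),
                      distance = numeric(), speed = numeric(),
                      contact = logical())
  out[order(out$frame, out$other), ]
}

#' Event export and per-category summary
#'
#' \code{writeEvents} exports classified episodes as JSON (participants,
#' frames, category); \code{eventSummary} tabulates counts per category.
#'
#' @param events classified episodes (with \code{category}).
#' @param path output JSON path.
#' @return \code{writeEvents}: the path, invisibly; \code{eventSummary}: a
#'   data.frame \code{category, n}.
#' @export
writeEvents <- function(events, path) {
  lst <- lapply(seq_len(nrow(events)), function(i)
    list(participants = events$participants[[i]],
         start = events$start[i], T1 = events$T1[i], end = events$end[i],
         category = if (!is.null(events$category)) events$category[i] else NA))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEvents
#' @export
eventSummary <- function(events) {
  if (nrow(events) == 0L)
    return(data.frame(category = character(), n = integer()))
  tab <- table(events$category)
  data.frame(category = names(tab), n = as.integer(tab))
}
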