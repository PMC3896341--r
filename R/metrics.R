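# Evaluation of tracking output against ground truth: association,
# trajectory fragmentation (TFF) and completeness (TCF) factors, centroid
# errors, identity swaps and event false rates.

#' Associate system tracks with ground-truth tracks
#'
#' Per frame, every system point is matched to the nearest truth point within
#' radius \code{r}, greedily by distance (one-to-one; ties to the lowest truth
#' id, then the lowest system id). Each system track is then assigned to the
#' truth track it matches in the majority of its matched frames (ties to the
#' lowest truth id).
#'
#' @param system data.frame of computed trajectories (\code{frame, id, x, y}).
#' @param truth data.frame of ground-truth trajectories (same columns).
#' @param r association radius in px (> 0); one body length by convention.
#' @return an \linkS4class{AssociationMap}.
#' @export
associateTracks <- function(system, truth, r = 15) {
  stopifnot(r > 0)
  frames <- intersect(unique(system$frame), unique(truth$frame))
  matches <- vector("list", length(frames))
  sysSplit <- split(system[, c("frame", "id", "x", "y")], system$frame)
  truSplit <- split(truth[, c("frame", "id", "x", "y")], truth$frame)
  for (k in seq_along(frames)) {
    f <- as.character(frames[k])
    s <- sysSplit[[f]]; g <- truSplit[[f]]
    d <- outer(seq_len(nrow(s)), seq_len(nrow(g)), function(i, j)
      sqrt((s$x[i] - g$x[j])^2 + (s$y[i] - g$y[j])^2))
    cand <- which(d <= r, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    ord <- order(d[cand], g$id[cand[, 2]], s$id[cand[, 1]])
    cand <- cand[ord, , drop = FALSE]
    usedS <- logical(nrow(s)); usedG <- logical(nrow(g))
    rows <- list()
    for (p in seq_len(nrow(cand))) {
      i <- cand[p, 1]; j <- cand[p, 2]
      if (usedS[i] || usedG[j]) next
      usedS[i] <- TRUE; usedG[j] <- TRUE
      rows[[length(rows) + 1L]] <- c(frames[k], s$id[i], g$id[j], d[i, j])
    }
    matches[[k]] <- do.call(rbind, rows)
  }
  m <- do.call(rbind, matches)
  matches <- if (is.null(m)) {
    data.frame(frame = integer(), system_id = integer(), truth_id = integer(),
               dist = numeric())
  } else {
    data.frame(frame = m[, 1], system_id = m[, 2], truth_id = m[, 3],
               dist = m[, 4])
  }
  assignment <- if (nrow(matches) == 0L) {
    data.frame(system_id = integer(), truth_id = integer(), n = integer())
  } else {
    do.call(rbind, lapply(split(matches, matches$system_id), function(ms) {
      tab <- table(ms$truth_id)
      best <- names(tab)[which.max(tab)]  # ties: first = lowest truth id
      data.frame(system_id = ms$system_id[1], truth_id = as.integer(best),
                 n = as.integer(max(tab)))
    }))
  }
  rownames(assignment) <- NULL
  tf <- as.data.frame(table(truth$id), stringsAsFactors = FALSE)
  truthFrames <- data.frame(id = as.integer(tf$Var1), n = as.integer(tf$Freq))
  new("AssociationMap", matches = matches, assignment = assignment,
      truthFrames = truthFrames, radius = as.numeric(r))
}

#' Trajectory fragmentation factor (TFF)
#'
#' TFF of a truth track is the number of system tracks needed to draw it,
#' i.e. the number of system tracks assigned to it; 1 is ideal. Truth tracks
#' covered by no system track have undefined TFF and are excluded with a
#' warning. The mean is reported at 2 decimals, the printed precision of this
#' metric.
#'
#' @param map an \linkS4class{AssociationMap}.
#' @return a list with \code{perTrack} (data.frame \code{truth_id, tff}) and
#'   \code{mean}.
#' @export
computeTFF <- function(map) {
  cov <- table(map@assignment$truth_id)
  uncovered <- setdiff(map@truthFrames$id, as.integer(names(cov)))
  if (length(uncovered) > 0L)
    warning("truth track(s) with no coverage excluded from TFF: ",
            paste(uncovered, collapse = ", "))
  perTrack <- data.frame(truth_id = as.integer(names(cov)),
                         tff = as.integer(cov))
  list(perTrack = perTrack,
       mean = round(mean(perTrack$tff), 2))
}

#' Trajectory completeness factor (TCF)
#'
#' TCF of a truth track is the fraction of its frames covered by the system
#' tracks assigned to it, in [0, 1]; 1 is ideal and uncovered tracks score 0.
#' The mean is reported at 2 decimals.
#'
#' @param map an \linkS4class{AssociationMap}.
#' @param truthSubset optional data.frame \code{frame, id} restricting which
#'   truth records count (e.g. frames away from the arena wall).
#' @return a list with \code{perTrack} (data.frame \code{truth_id, tcf}) and
#'   \code{mean}.
#' @export
computeTCF <- function(map, truthSubset = NULL) {
  mm <- merge(map@matches, map@assignment[c("system_id", "truth_id")],
              by = c("system_id", "truth_id"))
  totals <- map@truthFrames
  if (!is.null(truthSubset)) {
    key <- paste(mm$frame, mm$truth_id)
    keep <- key %in% paste(truthSubset$frame, truthSubset$id)
    mm <- mm[keep, ]
    tt <- as.data.frame(table(truthSubset$id), stringsAsFactors = FALSE)
    totals <- data.frame(id = as.integer(tt$Var1), n = as.integer(tt$Freq))
  }
  covered <- table(factor(mm$truth_id, levels = totals$id))
  perTrack <- data.frame(truth_id = totals$id,
                         tcf = as.integer(covered) / totals$n)
  list(perTrack = perTrack, mean = round(mean(perTrack$tcf), 2))
}

#' Pool per-movie metric values
#'
#' Averages movie-level metric values (TFF, TCF, ...) and reports at the
#' metric's printed precision.
#'
#' @param values numeric vector of per-movie values.
#' @param digits decimals to report (2 for TFF/TCF).
#' @return numeric(1).
#' @examples
#' poolMetric(c(1.00, 1.13, 1.75))  # 1.29
#' @export
poolMetric <- function(values, digits = 2) round(mean(values), digits)

#' Centroid position errors
#'
#' Euclidean distances between associated system and truth positions over all
#' matched frame pairs.
#'
#' @param map an \linkS4class{AssociationMap} with at least one match.
#' @return named numeric vector \code{min, max, mean} in px.
#' @export
centroidErrors <- function(map) {
  if (nrow(map@matches) == 0L) stop("empty association: no centroid errors")
  d <- map@matches$dist
  c(min = min(d), max = max(d), mean = mean(d))
}

#' Count identity swaps
#'
#' An identity swap is a system track persistently following a different
#' truth track than before: within each system track's frame-ordered match
#' sequence, every change of matched truth identity that persists for at
#' least \code{minRun} frames counts as one swap (short flickers during
#' occlusions do not).
#'
#' @param map an \linkS4class{AssociationMap}.
#' @param minRun minimal persistence in frames.
#' @return integer(1).
#' @export
countIdentitySwaps <- function(map, minRun = 10) {
  m <- map@matches[order(map@matches$system_id, map@matches$frame), ]
  swaps <- 0L
  for (ms in split(m, m$system_id)) {
    r <- rle(ms$truth_id)
    persistent <- r$values[r$lengths >= minRun]
    persistent <- persistent[c(TRUE, diff(persistent) != 0)]
    if (length(persistent) > 1L) swaps <- swaps + length(persistent) - 1L
  }
  swaps
}

#' Judge ground-truth events against the tracking result
#'
#' An event fails when the participants' identities are not all preserved
#' across it: for each participant there must be one system track, assigned
#' to that truth track, that matches it both at/before the contact frame T1
#' and at/after the episode end.
#'
#' @param map an \linkS4class{AssociationMap}.
#' @param truthEvents events table (list column \code{participants},
#'   \code{T1}, \code{end}, \code{category}).
#' @return \code{truthEvents} with a logical \code{failed} column.
#' @export
eventFailures <- function(map, truthEvents) {
  mm <- merge(map@matches, map@assignment[c("system_id", "truth_id")],
              by = c("system_id", "truth_id"))
  truthEvents$failed <- vapply(seq_len(nrow(truthEvents)), function(i) {
    ev <- truthEvents[i, ]
    ok <- vapply(ev$participants[[1]], function(g) {
      ms <- mm[mm$truth_id == g, ]
      any(vapply(split(ms, ms$system_id), function(s)
        any(s$frame <= ev$T1) && any(s$frame >= ev$end), logical(1)))
    }, logical(1))
    !all(ok)
  }, logical(1))
  truthEvents
}

#' Per-category false-rate summary
#'
#' Tabulates event occurrences and failures per category, with the false rate
#' (failures / occurrences x 100, 1 decimal) and the complementary accuracy.
#' Categories with zero occurrences report a blank (NA) rate. A \code{Sum}
#' row aggregates all categories.
#'
#' @param categories character vector of event categories (one per event), or
#'   a data.frame from \code{\link{eventFailures}} (columns \code{category},
#'   \code{failed}), in which case \code{failed} may be omitted.
#' @param failed logical vector marking failed events.
#' @return data.frame \code{category, occurrences, failures, false_rate,
#'   accuracy}.
#' @examples
#' falseRateSummary(rep("waiting", 84), c(rep(TRUE, 7), rep(FALSE, 77)))
#' @export
falseRateSummary <- function(categories, failed = NULL) {
  if (is.data.frame(categories)) {
    failed <- categories$failed
    categories <- categories$category
  }
  stopifnot(length(categories) == length(failed))
  cats <- unique(categories)
  per <- do.call(rbind, lapply(cats, function(cc) {
    occ <- sum(categories == cc)
    fl <- sum(failed[categories == cc])
    data.frame(category = cc, occurrences = occ, failures = fl)
  }))
  per <- rbind(per, data.frame(category = "Sum",
                               occurrences = length(categories),
                               failures = sum(failed)))
  per$false_rate <- ifelse(per$occurrences > 0,
                           round(100 * per$failures / per$occurrences, 1),
                           NA_real_)
  per$accuracy <- ifelse(per$occurrences > 0,
                         round(100 * (per$occurrences - per$failures) /
                               per$occurrences, 1), NA_real_)
  per
}

#' Write an evaluation report as JSON
#'
#' @param report a named list (e.g. TFF/TCF means, centroid errors, swap
#'   counts, false-rate tables).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEvaluation <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
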