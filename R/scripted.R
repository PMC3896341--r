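# Scripted two- and three-agent interaction fixtures with exact ground
# truth, one per interaction category. Each scenario starts with a
# contact-free "lead-in" in which every agent walks one full circle (all
# body orientations appear, so size calibration on the lead-in sees the
# whole single-bee area range), ending exactly at its scripted start
# position and heading. The interaction phase then plays out the category
# definition verbatim.

# Positions/headings of a full-circle lead-in of L steps at the given speed,
# ending at `end` with heading `headingEnd`. `turn` = +1 walks the circle
# counterclockwise (in screen coordinates, y down), -1 clockwise.
leadInCircle <- function(end, headingEnd, L, speed, turn = 1) {
  r <- L * speed / (2 * pi)
  phiEnd <- headingEnd - turn * pi / 2
  center <- c(end[1] - r * cos(phiEnd), end[2] - r * sin(phiEnd))
  k <- seq_len(L)
  phi <- phiEnd - turn * 2 * pi * (L - k) / L
  list(x = center[1] + r * cos(phi),
       y = center[2] + r * sin(phi),
       heading = wrapAngle(phi + turn * pi / 2))
}

# Piecewise-linear interaction path: start point, then per-frame headings.
# `headings` has length P (heading used for the step INTO each frame; the
# first entry is the heading AT the start frame). speed 0 encodes a stop.
walkPath <- function(start, headings, speeds) {
  P <- length(headings)
  x <- numeric(P); y <- numeric(P)
  x[1] <- start[1]; y[1] <- start[2]
  for (k in 2:P) {
    x[k] <- x[k - 1] + speeds[k] * cos(headings[k])
    y[k] <- y[k - 1] + speeds[k] * sin(headings[k])
  }
  list(x = x, y = y, heading = headings)
}

scenarioCategories <- function() {
  c("crossing", "touching", "passing", "overlapping", "waiting", "multiple")
}

#' Scripted interaction scenario with ground truth
#'
#' Builds a short noise-free movie of two (three for \code{"multiple"})
#' agents whose motion realizes one interaction category: \describe{
#'   \item{crossing}{the two touch at T1 and neither changes direction;}
#'   \item{touching}{they come from similar directions, touch at T1 and both
#'     turn;}
#'   \item{passing}{they come from different directions, touch at T1 and both
#'     turn;}
#'   \item{overlapping}{they pass straight through each other, fully
#'     overlapping at T1, neither changes direction;}
#'   \item{waiting}{one agent stays stopped from before T1 until the other
#'     has passed a body length away;}
#'   \item{multiple}{three agents converge and touch simultaneously.}}
#' Each scenario starts with a contact-free circular lead-in (see Details).
#'
#' @details The first \code{leadIn} frames have every agent walking one full
#' circle far from the others, ending at its scripted start pose. Size
#' calibration for these clips should therefore use the lead-in
#' (\code{trackConfig(calibFrames = leadIn(...))}), mirroring the practice of
#' calibrating on initial contact-free footage. Per-frame displacement never
#' exceeds \code{speed}.
#'
#' @param category one of \code{crossing, touching, passing, overlapping,
#'   waiting, multiple}.
#' @param bodyAxes full (major, minor) body axes in px.
#' @param speed walking speed in px/frame.
#' @param fps frames per second.
#' @param leadIn length of the circular lead-in in frames.
#' @param beeGray,backgroundGray,noiseSD rendering parameters as in
#'   \code{\link{agentConfig}}.
#' @param seed RNG seed (used only when \code{noiseSD > 0}).
#' @return a list with \code{stack} (\linkS4class{FrameStack}), \code{truth}
#'   (\linkS4class{GroundTruth} whose events table holds the scripted
#'   episode), and \code{leadIn} (frames to use for calibration).
#' @examples
#' sc <- scriptedScenario("crossing")
#' truthEvents(sc$truth)$category
#' @export
scriptedScenario <- function(category, bodyAxes = c(15, 7), speed = 2,
                             fps = 25, leadIn = 100, beeGray = 30,
                             backgroundGray = 200, noiseSD = 0, seed = 1) {
  category <- match.arg(category, scenarioCategories())
  P <- 81L  # interaction-phase length (frames)
  v <- speed
  m <- c(130, 130)  # scene center

  # interaction-phase paths per category ------------------------------------
  paths <- switch(category,
    crossing = {
      hA <- rep(0, P)
      hB <- rep(-pi / 2, P)
      list(walkPath(c(58, 126), hA, rep(v, P)),
           walkPath(c(134, 202), hB, rep(v, P)))
    },
    touching = {
      tau <- 39L  # first step taken with the outgoing heading
      hA <- c(rep(deg2rad(30), tau - 1), rep(deg2rad(130), P - tau + 1))
      hB <- c(rep(deg2rad(-30), tau - 1), rep(deg2rad(-130), P - tau + 1))
      sA <- c(130 - 72 * cos(deg2rad(30)), 128 - 72 * sin(deg2rad(30)))
      sB <- c(130 - 72 * cos(deg2rad(30)), 132 + 72 * sin(deg2rad(30)))
      list(walkPath(sA, hA, rep(v, P)), walkPath(sB, hB, rep(v, P)))
    },
    passing = {
      tau <- 39L
      hA <- c(rep(0, tau - 1), rep(deg2rad(70), P - tau + 1))
      hB <- c(rep(pi, tau - 1), rep(deg2rad(-110), P - tau + 1))
      list(walkPath(c(58, 128), hA, rep(v, P)),
           walkPath(c(202, 132), hB, rep(v, P)))
    },
    overlapping = {
      list(walkPath(c(58, 130), rep(0, P), rep(v, P)),
           walkPath(c(202, 130), rep(pi, P), rep(v, P)))
    },
    waiting = {
      # A walks past; B rests (body horizontal, offset so the masks never
      # merge) until A is more than one body length away, then departs west.
      hA <- rep(0, P)
      A <- walkPath(c(58, 130), hA, rep(v, P))
      bRest <- c(134, 118)
      dAB <- sqrt((A$x - bRest[1])^2 + (A$y - bRest[2])^2)
      firstFar <- which(dAB > bodyAxes[1] & A$x > bRest[1])[1]
      spB <- c(rep(0, firstFar), rep(v, P - firstFar))
      hB <- rep(pi, P)
      B <- walkPath(bRest, hB, spB)
      list(A, B)
    },
    multiple = {
      # three agents 120 deg apart walk 72 px inward (center distance 8 px,
      # pairwise 8*sqrt(3) ~ 13.9 px < one body length), pause in contact,
      # then retreat outward.
      ang <- deg2rad(c(90, 210, 330))
      inwardSteps <- 36L; pause <- 20L
      lapply(ang, function(a) {
        hin <- wrapAngle(a + pi)
        s <- c(m[1] + 80 * cos(a), m[2] + 80 * sin(a))
        nRetreat <- P - 1L - inwardSteps - pause
        h <- c(rep(hin, 1L + inwardSteps + pause), rep(a, nRetreat))
        sp <- c(0, rep(v, inwardSteps), rep(0, pause), rep(v, nRetreat))
        walkPath(s, h, sp)
      })
    })

  n <- length(paths)
  # lead-in circles, alternating turn direction to keep them apart ----------
  turns <- switch(category, multiple = c(-1, 1, -1), waiting = c(-1, -1),
                  c(-1, 1))
  leads <- lapply(seq_len(n), function(i) {
    p <- paths[[i]]
    leadInCircle(c(p$x[1], p$y[1]), p$heading[1], leadIn, v, turns[i])
  })

  nf <- leadIn + P
  xs <- vapply(seq_len(n), function(i) c(leads[[i]]$x, paths[[i]]$x),
               numeric(nf))
  ys <- vapply(seq_len(n), function(i) c(leads[[i]]$y, paths[[i]]$y),
               numeric(nf))
  hs <- vapply(seq_len(n), function(i) c(leads[[i]]$heading,
                                         paths[[i]]$heading), numeric(nf))

  cfg <- agentConfig(nAgents = n, arenaRadius = 130, frameSize = c(260, 260),
                     fps = fps, nFrames = nf, bodyAxes = bodyAxes,
                     speed = speed, beeGray = beeGray,
                     backgroundGray = backgroundGray, noiseSD = noiseSD,
                     seed = seed)
  frames <- array(0L, dim = c(260, 260, nf))
  renderAll <- function() {
    for (t in seq_len(nf))
      frames[, , t] <<- renderFrame(cbind(xs[t, ], ys[t, ]), hs[t, ], cfg)
  }
  if (noiseSD > 0) withSeed(seed, renderAll()) else renderAll()

  # ground truth -------------------------------------------------------------
  moving <- rbind(TRUE, abs(diff(xs)) + abs(diff(ys)) > 1e-9)
  positions <- data.frame(
    frame = rep(seq_len(nf), each = n), id = rep(seq_len(n), nf),
    x = as.numeric(t(xs)), y = as.numeric(t(ys)), heading = as.numeric(t(hs)),
    state = ifelse(as.logical(t(moving)), "moving", "resting"))

  # scripted episode boundaries from the generated geometry
  contact <- bodyAxes[1]
  inContact <- rep(FALSE, nf)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((xs[, i] - xs[, j])^2 + (ys[, i] - ys[, j])^2)
    inContact <- inContact | d < contact
  }
  cf <- which(inContact)
  if (length(cf) == 0L)
    stop("internal error: scripted scenario produced no contact")
  events <- data.frame(start = min(cf), T1 = min(cf), end = max(cf),
                       category = category)
  events$participants <- list(seq_len(n))
  events <- events[c("participants", "start", "T1", "end", "category")]

  list(stack = new("FrameStack", frames = frames, fps = fps),
       truth = GroundTruth(positions = positions, events = events),
       leadIn = as.integer(leadIn))
}
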