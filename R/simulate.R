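# Synthetic arena simulator: BEECLUST-inspired agents rendered as dark
# ellipses on a bright frame, with exact ground truth.

# Fill an ellipse into an integer matrix. (cx, cy) are 0-based real
# coordinates, a/b the semi-axes, theta the major-axis angle. A pixel is
# filled iff its center lies inside the ellipse (hard fill, no antialiasing,
# so segmentation ground truth is unambiguous).
fillEllipse <- function(mat, cx, cy, a, b, theta, value) {
  nr <- nrow(mat); nc <- ncol(mat)
  j0 <- max(1L, floor(cx - a) + 1L); j1 <- min(nc, ceiling(cx + a) + 1L)
  i0 <- max(1L, floor(cy - a) + 1L); i1 <- min(nr, ceiling(cy + a) + 1L)
  if (j0 > j1 || i0 > i1) return(mat)
  xs <- (j0:j1) - 1; ys <- (i0:i1) - 1
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  dy <- matrix(ys - cy, length(ys), length(xs))
  ct <- cos(theta); st <- sin(theta)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  sub <- mat[i0:i1, j0:j1, drop = FALSE]
  sub[u * u + v * v <= 1] <- value
  mat[i0:i1, j0:j1] <- sub
  mat
}

# Render one frame: bright background, agents as dark filled ellipses,
# then additive Gaussian noise (if any), clamped to [0, 255].
renderFrame <- function(xy, headings, cfg) {
  w <- cfg@frameSize[1]; h <- cfg@frameSize[2]
  fr <- matrix(cfg@backgroundGray, h, w)
  a <- cfg@bodyAxes[1] / 2; b <- cfg@bodyAxes[2] / 2
  n <- if (is.null(nrow(xy))) 0L else nrow(xy)
  for (i in seq_len(n))
    fr <- fillEllipse(fr, xy[i, 1], xy[i, 2], a, b, headings[i], cfg@beeGray)
  if (cfg@noiseSD > 0) {
    fr <- fr + round(rnorm(length(fr), 0, cfg@noiseSD))
    fr[fr < 0] <- 0; fr[fr > 255] <- 255
  }
  storage.mode(fr) <- "integer"
  fr
}

# Place agents uniformly in the arena disc with a minimum mutual spacing.
placeAgents <- function(cfg, maxTries = 10000L) {
  n <- cfg@nAgents
  cx <- cfg@frameSize[1] / 2; cy <- cfg@frameSize[2] / 2
  maxR <- cfg@arenaRadius - cfg@bodyAxes[1] / 2
  minSep <- 2 * cfg@bodyAxes[1]
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("could not place ", n, " agents without overlap after ",
           maxTries, " tries")
    r <- maxR * sqrt(runif(1)); ang <- runif(1, -pi, pi)
    p <- c(cx + r * cos(ang), cy + r * sin(ang))
    if (placed > 0L) {
      d <- sqrt((pos[seq_len(placed), 1] - p[1])^2 +
                (pos[seq_len(placed), 2] - p[2])^2)
      if (min(d) < minSep) next
    }
    placed <- placed + 1L
    pos[placed, ] <- p
  }
  pos
}

#' Simulate an arena movie with exact ground truth
#'
#' Generates a grayscale movie of elliptical dark agents walking on a
#' brighter circular arena, together with per-frame ground-truth positions,
#' headings and behavioral states. Motion follows a simplified
#' honeybee-inspired collision-and-wait rule: agents walk straight with small
#' heading noise, reflect (with jitter) off the arena wall, stop for a
#' sampled wait when within one body length of another agent and then turn
#' away, and occasionally rest spontaneously. Output is deterministic for a
#' fixed seed.
#'
#' @param config an \linkS4class{AgentConfig}.
#' @return a list with elements \code{stack} (\linkS4class{FrameStack}) and
#'   \code{truth} (\linkS4class{GroundTruth}; empty events table).
#' @examples
#' sim <- simulateArena(agentConfig(nAgents = 2, nFrames = 40,
#'                                  frameSize = c(150, 150), arenaRadius = 60,
#'                                  noiseSD = 0, seed = 7))
#' sim$stack
#' head(truthTable(sim$truth))
#' @export
simulateArena <- function(config) {
  stopifnot(is(config, "AgentConfig"))
  validObject(config)
  withSeed(config@seed, {
    n <- config@nAgents
    nf <- config@nFrames
    w <- config@frameSize[1]; h <- config@frameSize[2]
    bodyLen <- config@bodyAxes[1]
    centerX <- w / 2; centerY <- h / 2
    maxR <- config@arenaRadius - bodyLen / 2
    turnSD <- deg2rad(config@turnNoiseDeg)

    frames <- array(0L, dim = c(h, w, nf))
    if (n == 0L) {
      for (t in seq_len(nf))
        frames[, , t] <- renderFrame(NULL, numeric(0), config)
      return(list(stack = new("FrameStack", frames = frames, fps = config@fps),
                  truth = GroundTruth()))
    }

    pos <- placeAgents(config)
    heading <- runif(n, -pi, pi)
    wait <- integer(n)            # remaining stop frames
    state <- rep("moving", n)
    cooldown <- rep(FALSE, n)     # suppress re-triggering contact right away

    recF <- vector("list", nf); recX <- vector("list", nf)
    recY <- vector("list", nf); recH <- vector("list", nf)
    recS <- vector("list", nf)

    for (t in seq_len(nf)) {
      frames[, , t] <- renderFrame(pos, heading, config)
      recF[[t]] <- rep.int(t, n); recX[[t]] <- pos[, 1]; recY[[t]] <- pos[, 2]
      recH[[t]] <- heading; recS[[t]] <- state

      if (t == nf) break
      for (i in seq_len(n)) {
        if (wait[i] > 0L) {
          wait[i] <- wait[i] - 1L
          if (wait[i] == 0L) {
            if (state[i] == "stopped") {
              # leave the encounter: head away from the nearest neighbour
              d2 <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2
              d2[i] <- Inf
              j <- which.min(d2)
              away <- atan2(pos[i, 2] - pos[j, 2], pos[i, 1] - pos[j, 1])
              heading[i] <- wrapAngle(away + runif(1, -pi / 3, pi / 3))
              cooldown[i] <- TRUE
            }
            state[i] <- "moving"
          }
          next
        }
        dOther <- if (n > 1) {
          dd <- sqrt((pos[-i, 1] - pos[i, 1])^2 + (pos[-i, 2] - pos[i, 2])^2)
          min(dd)
        } else Inf
        if (cooldown[i] && dOther > 1.2 * bodyLen) cooldown[i] <- FALSE
        if (!cooldown[i] && dOther < bodyLen) {
          state[i] <- "stopped"
          wait[i] <- sampleInt(config@waitOnContact)
          next
        }
        if (runif(1) < config@stopProb) {
          state[i] <- "resting"
          wait[i] <- sampleInt(config@stopDuration)
          next
        }
        state[i] <- "moving"
        heading[i] <- wrapAngle(heading[i] + rnorm(1, 0, turnSD))
        cand <- pos[i, ] + config@speed * c(cos(heading[i]), sin(heading[i]))
        if (sqrt((cand[1] - centerX)^2 + (cand[2] - centerY)^2) > maxR) {
          # specular reflection off the wall plus jitter (wall-following)
          nrm <- c(pos[i, 1] - centerX, pos[i, 2] - centerY)
          nrm <- nrm / sqrt(sum(nrm^2))
          v <- c(cos(heading[i]), sin(heading[i]))
          v <- v - 2 * sum(v * nrm) * nrm
          heading[i] <- wrapAngle(atan2(v[2], v[1]) + runif(1, -pi / 12, pi / 12))
          cand <- pos[i, ] + config@speed * c(cos(heading[i]), sin(heading[i]))
          if (sqrt((cand[1] - centerX)^2 + (cand[2] - centerY)^2) > maxR)
            next  # stay put this frame rather than leave the arena
        }
        pos[i, ] <- cand
      }
    }

    positions <- data.frame(
      frame = unlist(recF), id = rep.int(seq_len(n), nf),
      x = unlist(recX), y = unlist(recY), heading = unlist(recH),
      state = unlist(recS))
    positions <- positions[order(positions$frame, positions$id), ]
    rownames(positions) <- NULL
    list(stack = new("FrameStack", frames = frames, fps = config@fps),
         truth = GroundTruth(positions = positions))
  })
}
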