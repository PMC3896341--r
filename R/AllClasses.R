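#' FrameStack: an ordered grayscale image sequence
#'
#' Container for a movie as an 8-bit grayscale frame stack with its frame
#' rate. Frames are stored as an integer array of dimension
#' \code{height x width x n} with values in [0, 255].
#'
#' @slot frames integer array, \code{height x width x nframes}, values 0-255.
#' @slot fps numeric(1), frames per second.
#'
#' @export
setClass("FrameStack",
  representation(frames = "array", fps = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@frames)
    if (length(d) != 3L) msg <- c(msg, "'frames' must be a 3-d array (height x width x n)")
    else if (d[3] < 1L) msg <- c(msg, "a FrameStack needs at least one frame")
    if (length(object@fps) != 1L || object@fps <= 0)
      msg <- c(msg, "'fps' must be a single positive number")
    rng <- suppressWarnings(range(object@frames))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 255))
      msg <- c(msg, "frame values must lie in [0, 255]")
    if (is.null(msg)) TRUE else msg
  }
)

#' GroundTruth: exact per-frame agent states and scripted events
#'
#' Ground truth accompanying a synthetic movie: one record per agent per
#' frame plus a (possibly empty) table of scripted interaction events.
#'
#' @slot positions data.frame with columns \code{frame, id, x, y, heading,
#'   state}; one row per agent per frame.
#' @slot events data.frame with columns \code{participants} (list column of
#'   integer vectors), \code{start}, \code{T1}, \code{end}, \code{category}.
#'
#' @export
setClass("GroundTruth",
  representation(positions = "data.frame", events = "data.frame"),
  validity = function(object) {
    msg <- NULL
    need <- c("frame", "id", "x", "y", "heading", "state")
    if (!all(need %in% names(object@positions)))
      msg <- c(msg, paste("positions must have columns:", paste(need, collapse = ", ")))
    if (nrow(object@positions) > 0 &&
        anyDuplicated(object@positions[c("frame", "id")]) > 0)
      msg <- c(msg, "positions must hold one record per agent per frame")
    if (nrow(object@events) > 0) {
      neede <- c("participants", "start", "T1", "end", "category")
      if (!all(neede %in% names(object@events)))
        msg <- c(msg, paste("events must have columns:", paste(neede, collapse = ", ")))
      else if (with(object@events, any(start > T1 | T1 > end)))
        msg <- c(msg, "events must satisfy start <= T1 <= end")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' SizeRange: the calibrated range of single-bee sizes (RSS)
#'
#' Valid area interval for one bee, with the modal area and the mean body
#' length (major axis) of single-bee regions, estimated from the initial
#' movie frames.
#'
#' @slot minArea,maxArea numeric(1), inclusive area bounds in px^2.
#' @slot modalArea numeric(1), modal single-bee area in px^2.
#' @slot bodyLength numeric(1), mean major-axis length of single-bee
#'   regions in px.
#' @slot nSamples integer(1), number of regions the calibration used.
#'
#' @export
setClass("SizeRange",
  representation(minArea = "numeric", maxArea = "numeric",
                 modalArea = "numeric", bodyLength = "numeric",
                 nSamples = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!(object@minArea > 0)) msg <- c(msg, "minArea must be > 0")
    if (!(object@minArea <= object@modalArea && object@modalArea <= object@maxArea))
      msg <- c(msg, "need minArea <= modalArea <= maxArea")
    if (!(object@bodyLength > 0)) msg <- c(msg, "bodyLength must be > 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' BeeTracks: per-identity tracking results
#'
#' Result of running the tracker over a movie: a long-format table of
#' per-frame records for every identity, per-track status, and the
#' calibration used.
#'
#' @slot table data.frame with columns \code{frame, id, x, y, area, label,
#'   merged}; \code{label} is the connected-component label the record came
#'   from (internal, frame-local) and \code{merged} flags frames where the
#'   identity shared a single-bee-sized component with another identity.
#' @slot status data.frame with columns \code{id, birth, lastSeen, status}
#'   (\code{"active"} or \code{"dormant"}).
#' @slot rss the \linkS4class{SizeRange} used, or NULL if supplied externally.
#' @slot fps numeric(1), frames per second of the source movie.
#'
#' @export
setClass("BeeTracks",
  representation(table = "data.frame", status = "data.frame",
                 rss = "ANY", fps = "numeric"),
  validity = function(object) {
    msg <- NULL
    need <- c("frame", "id", "x", "y", "area", "label", "merged")
    if (!all(need %in% names(object@table)))
      msg <- c(msg, paste("table must have columns:", paste(need, collapse = ", ")))
    else if (nrow(object@table) > 0) {
      if (anyDuplicated(object@table[c("frame", "id")]) > 0)
        msg <- c(msg, "(frame, id) pairs must be unique")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' AssociationMap: frame-wise matching of system tracks to ground truth
#'
#' Greedy nearest-neighbour association between a computed trajectory table
#' and a ground-truth table within a radius, plus the majority-vote
#' assignment of each system track to one truth track.
#'
#' @slot matches data.frame with columns \code{frame, system_id, truth_id,
#'   dist}; at most one match per system point and per truth point per frame.
#' @slot assignment data.frame with columns \code{system_id, truth_id, n}
#'   (majority-vote assignment and its supporting frame count).
#' @slot truthFrames data.frame with columns \code{id, n}: total frames of
#'   each truth track.
#' @slot radius numeric(1), the association radius in px.
#'
#' @export
setClass("AssociationMap",
  representation(matches = "data.frame", assignment = "data.frame",
                 truthFrames = "data.frame", radius = "numeric"),
  validity = function(object) {
    if (object@radius <= 0) "radius must be > 0" else TRUE
  }
)

#' AgentConfig: parameters of the synthetic arena simulator
#'
#' Study conditions for a simulated movie of elliptical dark agents walking
#' on a brighter circular arena, driven by a simplified honeybee-inspired
#' collision-and-wait (BEECLUST-style) motion rule.
#'
#' @slot nAgents integer(1), number of agents.
#' @slot arenaRadius numeric(1), arena radius in px.
#' @slot frameSize integer(2), frame (width, height) in px.
#' @slot fps numeric(1), frames per second.
#' @slot nFrames integer(1), number of frames.
#' @slot bodyAxes numeric(2), full (major, minor) ellipse axes in px.
#' @slot speed numeric(1), walking speed in px/frame.
#' @slot stopProb numeric(1), per-frame probability of a spontaneous rest.
#' @slot stopDuration numeric(2), (min, max) rest duration in frames.
#' @slot turnNoiseDeg numeric(1), sd of per-frame heading noise in degrees.
#' @slot waitOnContact numeric(2), (min, max) contact wait in frames.
#' @slot beeGray,backgroundGray numeric(1), 0-255 gray levels; the
#'   background must be brighter than the agents.
#' @slot noiseSD numeric(1), sd of additive pixel noise in gray levels.
#' @slot seed integer(1), RNG seed; fixed seed gives identical output.
#'
#' @export
setClass("AgentConfig",
  representation(nAgents = "integer", arenaRadius = "numeric",
                 frameSize = "integer", fps = "numeric", nFrames = "integer",
                 bodyAxes = "numeric", speed = "numeric", stopProb = "numeric",
                 stopDuration = "numeric", turnNoiseDeg = "numeric",
                 waitOnContact = "numeric", beeGray = "numeric",
                 backgroundGray = "numeric", noiseSD = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nAgents < 0) msg <- c(msg, "nAgents must be >= 0")
    if (object@nFrames < 1) msg <- c(msg, "nFrames must be >= 1")
    if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
    if (length(object@frameSize) != 2 || any(object@frameSize < 1))
      msg <- c(msg, "frameSize must be two positive integers")
    if (!(object@backgroundGray > object@beeGray))
      msg <- c(msg, "backgroundGray must exceed beeGray (dark animals on a bright arena)")
    if (any(c(object@beeGray, object@backgroundGray) < 0) ||
        any(c(object@beeGray, object@backgroundGray) > 255))
      msg <- c(msg, "gray levels must lie in [0, 255]")
    if (object@speed < 0) msg <- c(msg, "speed must be >= 0")
    if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
    if (length(object@bodyAxes) != 2 || any(object@bodyAxes <= 0) ||
        object@bodyAxes[1] < object@bodyAxes[2])
      msg <- c(msg, "bodyAxes must be (major, minor) with major >= minor > 0")
    if (object@stopProb < 0 || object@stopProb > 1)
      msg <- c(msg, "stopProb must be a probability")
    if (is.null(msg)) TRUE else msg
  }
)
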