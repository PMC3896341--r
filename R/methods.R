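# Constructors, accessors and show methods for the S4 containers.

#' Create a FrameStack
#'
#' @param frames an integer array \code{height x width x n}, a single matrix
#'   (taken as one frame), or a list of equally sized matrices, values 0-255.
#' @param fps frames per second.
#' @return a \linkS4class{FrameStack}.
#' @examples
#' fs <- FrameStack(matrix(200L, 8, 8), fps = 25)
#' nFrames(fs)
#' @export
FrameStack <- function(frames, fps = 25) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
      stop("all frames must share one size")
    frames <- array(unlist(frames, use.names = FALSE), dim = c(d, length(frames)))
  }
  storage.mode(frames) <- "integer"
  new("FrameStack", frames = frames, fps = as.numeric(fps))
}

#' @rdname FrameStack-class
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[3])

#' @rdname FrameStack-class
#' @export
setMethod("frameSize", "FrameStack",
          function(x) c(width = dim(x@frames)[2], height = dim(x@frames)[1]))

#' @rdname FrameStack-class
#' @export
setMethod("fps", "FrameStack", function(x) x@fps)

#' @rdname FrameStack-class
#' @export
setMethod("getFrame", "FrameStack", function(x, i) {
  stopifnot(i >= 1, i <= nFrames(x))
  x@frames[, , i]
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d frame(s), %d x %d px (w x h), %g fps\n",
              d[3], d[2], d[1], object@fps))
})

#' @rdname GroundTruth-class
#' @param positions,events see the class slots.
#' @export
GroundTruth <- function(positions = emptyTruthPositions(),
                        events = emptyTruthEvents()) {
  new("GroundTruth", positions = positions, events = events)
}

emptyTruthPositions <- function() {
  data.frame(frame = integer(), id = integer(), x = numeric(), y = numeric(),
             heading = numeric(), state = character())
}

emptyTruthEvents <- function() {
  out <- data.frame(start = integer(), T1 = integer(), end = integer(),
                    category = character())
  out$participants <- list()
  out[c("participants", "start", "T1", "end", "category")]
}

#' @rdname GroundTruth-class
#' @param object,x a \linkS4class{GroundTruth}.
#' @export
setMethod("truthTable", "GroundTruth", function(x) x@positions)

#' @rdname GroundTruth-class
#' @export
setMethod("truthEvents", "GroundTruth", function(x) x@events)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d agent(s), %d frame(s), %d scripted event(s)\n",
              length(unique(object@positions$id)),
              length(unique(object@positions$frame)),
              nrow(object@events)))
})

#' @rdname SizeRange-class
#' @param minArea,maxArea,modalArea,bodyLength,nSamples see the class slots.
#' @export
SizeRange <- function(minArea, maxArea, modalArea, bodyLength, nSamples = 0L) {
  new("SizeRange", minArea = as.numeric(minArea), maxArea = as.numeric(maxArea),
      modalArea = as.numeric(modalArea), bodyLength = as.numeric(bodyLength),
      nSamples = as.integer(nSamples))
}

#' @rdname SizeRange-class
#' @param object,x a \linkS4class{SizeRange}.
#' @export
setMethod("minArea", "SizeRange", function(x) x@minArea)

#' @rdname SizeRange-class
#' @export
setMethod("maxArea", "SizeRange", function(x) x@maxArea)

#' @rdname SizeRange-class
#' @export
setMethod("modalArea", "SizeRange", function(x) x@modalArea)

#' @rdname SizeRange-class
#' @export
setMethod("bodyLength", "SizeRange", function(x) x@bodyLength)

setMethod("show", "SizeRange", function(object) {
  cat(sprintf(
    "SizeRange (RSS): area [%.1f, %.1f] px^2, modal %.1f px^2, body length %.2f px (n = %d)\n",
    object@minArea, object@maxArea, object@modalArea, object@bodyLength,
    object@nSamples))
})

#' @rdname BeeTracks-class
#' @param object,x a \linkS4class{BeeTracks}.
#' @export
setMethod("trackTable", "BeeTracks", function(x) x@table)

#' @rdname BeeTracks-class
#' @export
setMethod("trackIds", "BeeTracks", function(x) sort(unique(x@table$id)))

#' @rdname BeeTracks-class
#' @export
setMethod("trackStatus", "BeeTracks", function(x) x@status)

setMethod("show", "BeeTracks", function(object) {
  cat(sprintf("BeeTracks: %d track(s) over %d frame(s), %d record(s)\n",
              length(unique(object@table$id)),
              length(unique(object@table$frame)), nrow(object@table)))
  if (is(object@rss, "SizeRange")) show(object@rss)
})

#' @rdname BeeTracks-class
#' @param row.names,optional,... passed on conventionally (unused).
#' @export
setMethod("as.data.frame", "BeeTracks",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "AssociationMap", function(object) {
  cat(sprintf(
    "AssociationMap: %d matched point(s), %d system track(s) -> %d truth track(s), r = %g px\n",
    nrow(object@matches), nrow(object@assignment), nrow(object@truthFrames),
    object@radius))
})

#' Create an AgentConfig
#'
#' Defaults emulate the recorded arena setting this package targets: a
#' 600 x 600 px frame at 25 fps for 1500 frames (one minute), sixteen
#' bee-sized elliptical agents (15 x 7 px body axes) on a circular arena,
#' walking with small heading noise, resting occasionally, and stopping for a
#' sampled wait when they come within one body length of another agent.
#'
#' @param nAgents number of agents.
#' @param arenaRadius arena radius in px.
#' @param frameSize frame (width, height) in px.
#' @param fps frames per second.
#' @param nFrames number of frames.
#' @param bodyAxes full (major, minor) body axes in px.
#' @param speed walking speed in px/frame (must not exceed one body length).
#' @param stopProb per-frame probability of a spontaneous rest.
#' @param stopDuration (min, max) rest duration in frames.
#' @param turnNoiseDeg sd of per-frame heading noise, degrees.
#' @param waitOnContact (min, max) contact wait duration in frames.
#' @param beeGray,backgroundGray agent and arena gray levels (0-255).
#' @param noiseSD sd of additive pixel noise, gray levels.
#' @param seed RNG seed.
#' @return an \linkS4class{AgentConfig}.
#' @examples
#' cfg <- agentConfig(nAgents = 2, nFrames = 50, frameSize = c(120, 120),
#'                    arenaRadius = 50)
#' @export
agentConfig <- function(nAgents = 16, arenaRadius = 290,
                        frameSize = c(600, 600), fps = 25, nFrames = 1500,
                        bodyAxes = c(15, 7), speed = 2.5, stopProb = 0.002,
                        stopDuration = c(25, 250), turnNoiseDeg = 3,
                        waitOnContact = c(12, 75), beeGray = 30,
                        backgroundGray = 200, noiseSD = 2, seed = 1) {
  new("AgentConfig", nAgents = as.integer(nAgents),
      arenaRadius = as.numeric(arenaRadius),
      frameSize = as.integer(frameSize), fps = as.numeric(fps),
      nFrames = as.integer(nFrames), bodyAxes = as.numeric(bodyAxes),
      speed = as.numeric(speed), stopProb = as.numeric(stopProb),
      stopDuration = as.numeric(stopDuration),
      turnNoiseDeg = as.numeric(turnNoiseDeg),
      waitOnContact = as.numeric(waitOnContact), beeGray = as.numeric(beeGray),
      backgroundGray = as.numeric(backgroundGray),
      noiseSD = as.numeric(noiseSD), seed = as.integer(seed))
}

setMethod("show", "AgentConfig", function(object) {
  cat(sprintf(
    "AgentConfig: %d agent(s), %d x %d px, %g fps, %d frames, seed %d\n",
    object@nAgents, object@frameSize[1], object@frameSize[2], object@fps,
    object@nFrames, object@seed))
})
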