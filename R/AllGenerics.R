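#' @rdname FrameStack-class
#' @param object,x a \linkS4class{FrameStack} (or other object).
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameStack-class
#' @export
setGeneric("frameSize", function(x) standardGeneric("frameSize"))

#' @rdname FrameStack-class
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname FrameStack-class
#' @param i frame index (1-based).
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname GroundTruth-class
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname GroundTruth-class
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))

#' @rdname BeeTracks-class
#' @export
setGeneric("trackTable", function(x) standardGeneric("trackTable"))

#' @rdname BeeTracks-class
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))

#' @rdname BeeTracks-class
#' @export
setGeneric("trackStatus", function(x) standardGeneric("trackStatus"))

#' @rdname SizeRange-class
#' @export
setGeneric("minArea", function(x) standardGeneric("minArea"))

#' @rdname SizeRange-class
#' @export
setGeneric("maxArea", function(x) standardGeneric("maxArea"))

#' @rdname SizeRange-class
#' @export
setGeneric("modalArea", function(x) standardGeneric("modalArea"))

#' @rdname SizeRange-class
#' @export
setGeneric("bodyLength", function(x) standardGeneric("bodyLength"))
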