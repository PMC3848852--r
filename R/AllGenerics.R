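#' @include utils.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the cine / segmentation / trajectory /
#' strain containers.  Use these rather than reaching into slots.
#'
#' @param object an object of one of the package's S4 classes
#' @param ... further arguments for methods
#' @return the accessed component; see the class documentation
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object, ...) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameMs", function(object, ...) standardGeneric("frameMs"))

#' @rdname accessors
#' @export
setGeneric("pixelMm", function(object, ...) standardGeneric("pixelMm"))

#' @rdname accessors
#' @export
setGeneric("venc", function(object, ...) standardGeneric("venc"))

#' @rdname accessors
#' @export
setGeneric("velocity", function(object, ...) standardGeneric("velocity"))

#' @rdname accessors
#' @export
setGeneric("magnitude", function(object, ...) standardGeneric("magnitude"))

#' @rdname accessors
#' @export
setGeneric("segmentMap", function(object, ...) standardGeneric("segmentMap"))

#' @rdname accessors
#' @export
setGeneric("myoMask", function(object, ...) standardGeneric("myoMask"))

#' @rdname accessors
#' @export
setGeneric("lvCenter", function(object, ...) standardGeneric("lvCenter"))

#' @rdname accessors
#' @export
setGeneric("nSegments", function(object, ...) standardGeneric("nSegments"))

#' @rdname accessors
#' @export
setGeneric("trajPaths", function(object, ...) standardGeneric("trajPaths"))

#' @rdname accessors
#' @export
setGeneric("validPaths", function(object, ...) standardGeneric("validPaths"))

#' @rdname accessors
#' @export
setGeneric("originFrame", function(object, ...) standardGeneric("originFrame"))

#' @rdname accessors
#' @export
setGeneric("sc", function(object, ...) standardGeneric("sc"))

#' @rdname accessors
#' @export
setGeneric("globalSc", function(object, ...) standardGeneric("globalSc"))

#' @rdname accessors
#' @export
setGeneric("regionalCurves", function(object, ...)
  standardGeneric("regionalCurves"))

#' @rdname accessors
#' @export
setGeneric("globalCurve", function(object, ...) standardGeneric("globalCurve"))

#' @rdname accessors
#' @export
setGeneric("timeMs", function(object, ...) standardGeneric("timeMs"))
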