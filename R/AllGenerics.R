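#' Accessor generics
#'
#' Small accessor family for the package's S4 containers. Each returns the
#' slot content; none of them expose slots for writing.
#'
#' @param object an astroNVC S4 object.
#' @return the requested component (a data.frame, matrix or scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rois", function(object) standardGeneric("rois"))

#' @rdname accessors
#' @export
setGeneric("labelImage", function(object) standardGeneric("labelImage"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("fovArea", function(object) standardGeneric("fovArea"))

#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("rasterMatrix", function(object) standardGeneric("rasterMatrix"))

#' @rdname accessors
#' @export
setGeneric("binRate", function(object) standardGeneric("binRate"))

#' @rdname accessors
#' @export
setGeneric("pairTable", function(object) standardGeneric("pairTable"))

#' @rdname accessors
#' @export
setGeneric("velocityBins", function(object) standardGeneric("velocityBins"))

#' @rdname accessors
#' @export
setGeneric("strengthLevels", function(object) standardGeneric("strengthLevels"))

#' @rdname accessors
#' @export
setGeneric("curveParameters", function(object) standardGeneric("curveParameters"))
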