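#' Accessors for ACSASeries and PhantomSpec objects
#'
#' @param x an \linkS4class{ACSASeries} or \linkS4class{PhantomSpec}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("areas", function(x) standardGeneric("areas"))

#' @rdname accessors
#' @export
setGeneric("sliceSpacing", function(x) standardGeneric("sliceSpacing"))

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname accessors
#' @export
setGeneric("phantomLength", function(x) standardGeneric("phantomLength"))

#' Evaluate a phantom's area profile
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param z positions in cm within [0, phantomLength(spec)].
#' @return areas A(z) in cm^2.
#' @export
setGeneric("areaAt", function(spec, z) standardGeneric("areaAt"))
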