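#' @include AllClasses.R
NULL

#' Accessors for rootSSM objects
#'
#' @param object A rootSSM S4 object.
#' @param ... Further arguments (unused).
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("forcingData", function(object, ...) standardGeneric("forcingData"))

#' @rdname accessors
#' @export
setGeneric("productionAssay",
           function(object, ...) standardGeneric("productionAssay"))

#' @rdname accessors
#' @export
setGeneric("observationTable",
           function(object, ...) standardGeneric("observationTable"))

#' @rdname accessors
#' @export
setGeneric("trajectoryScalars",
           function(object, ...) standardGeneric("trajectoryScalars"))

#' @rdname accessors
#' @export
setGeneric("standingArea", function(object, ...) standardGeneric("standingArea"))

#' @rdname accessors
#' @export
setGeneric("meanProductionPath",
           function(object, ...) standardGeneric("meanProductionPath"))

#' Extract draws of a path parameter or scalar from a fit
#'
#' @param object A [PosteriorDraws-class].
#' @param name Parameter base name, e.g. \code{"betaSt"}, \code{"p"},
#'   \code{"gamma"}.
#' @return For path parameters a draws x T matrix (columns in time order);
#'   for scalars a numeric vector of draws.
#' @export
setGeneric("paramDraws", function(object, name) standardGeneric("paramDraws"))

#' @rdname accessors
#' @export
setGeneric("rhatValues", function(object, ...) standardGeneric("rhatValues"))

#' @rdname accessors
#' @export
setGeneric("chainIndex", function(object, ...) standardGeneric("chainIndex"))

#' @rdname accessors
#' @export
setGeneric("pointwiseLogLik",
           function(object, ...) standardGeneric("pointwiseLogLik"))

#' @rdname accessors
#' @export
setGeneric("waicValue", function(object, ...) standardGeneric("waicValue"))
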