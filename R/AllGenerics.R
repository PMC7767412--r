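#' Accessor generics
#'
#' Small accessor generics for the pipeline's S4 objects; every slot is read
#' through one of these rather than by direct `@` access.
#'
#' @param object an object of the appropriate class
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname accessors
#' @export
setGeneric("absorbance", function(object) standardGeneric("absorbance"))

#' @rdname accessors
#' @export
setGeneric("specMeta", function(object) standardGeneric("specMeta"))

#' @rdname accessors
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))

#' @rdname accessors
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("residualSd", function(object) standardGeneric("residualSd"))

#' @rdname accessors
#' @export
setGeneric("standardErrors", function(object) standardGeneric("standardErrors"))

#' @rdname accessors
#' @export
setGeneric("fitMode", function(object) standardGeneric("fitMode"))

#' @rdname accessors
#' @export
setGeneric("ratioConfig", function(object) standardGeneric("ratioConfig"))

#' @rdname accessors
#' @export
setGeneric("composition", function(object) standardGeneric("composition"))
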