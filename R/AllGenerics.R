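#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the rheology and imaging containers. Slot
#' access through these accessors is the supported interface; the slot
#' layout itself is not part of the API.
#'
#' @param x an object of one of the package's S4 classes.
#' @return The corresponding field: numeric vectors for array-valued fields
#'   (\code{omega}, \code{gPrime}, ...), scalars for metadata.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("omega", function(x) standardGeneric("omega"))

#' @rdname accessors
#' @export
setGeneric("gPrime", function(x) standardGeneric("gPrime"))

#' @rdname accessors
#' @export
setGeneric("gDoublePrime", function(x) standardGeneric("gDoublePrime"))

#' @rdname accessors
#' @export
setGeneric("sweepDirection", function(x) standardGeneric("sweepDirection"))

#' @rdname accessors
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' @rdname accessors
#' @export
setGeneric("strainValues", function(x) standardGeneric("strainValues"))

#' @rdname accessors
#' @export
setGeneric("shearRate", function(x) standardGeneric("shearRate"))

#' @rdname accessors
#' @export
setGeneric("viscosity", function(x) standardGeneric("viscosity"))

#' @rdname accessors
#' @export
setGeneric("shearStress", function(x) standardGeneric("shearStress"))

#' @rdname accessors
#' @export
setGeneric("elasticModulus", function(x) standardGeneric("elasticModulus"))

#' @rdname accessors
#' @export
setGeneric("quasiProperty", function(x) standardGeneric("quasiProperty"))

#' @rdname accessors
#' @export
setGeneric("fractionalOrder", function(x) standardGeneric("fractionalOrder"))

#' @rdname accessors
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))

#' @rdname accessors
#' @export
setGeneric("nmPerPx", function(x) standardGeneric("nmPerPx"))

#' @rdname accessors
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))

#' @rdname accessors
#' @export
setGeneric("poreData", function(x) standardGeneric("poreData"))
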