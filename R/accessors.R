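#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("omega", "OscillatorySweep", function(x) x@omega)

#' @rdname accessors
#' @export
setMethod("gPrime", "OscillatorySweep", function(x) x@gPrime)

#' @rdname accessors
#' @export
setMethod("gDoublePrime", "OscillatorySweep", function(x) x@gDoublePrime)

#' @rdname accessors
#' @export
setMethod("sweepDirection", "OscillatorySweep", function(x) x@direction)

#' @rdname accessors
#' @export
setMethod("sampleLabel", "OscillatorySweep", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("gPrime", "AmplitudeSweep", function(x) x@gPrime)

#' @rdname accessors
#' @export
setMethod("gDoublePrime", "AmplitudeSweep", function(x) x@gDoublePrime)

#' @rdname accessors
#' @export
setMethod("strainValues", "AmplitudeSweep", function(x) x@strain)

#' @rdname accessors
#' @export
setMethod("shearRate", "FlowCurve", function(x) x@shearRate)

#' @rdname accessors
#' @export
setMethod("viscosity", "FlowCurve", function(x) x@viscosity)

#' @rdname accessors
#' @export
setMethod("shearStress", "FlowCurve", function(x) x@stress)

#' @rdname accessors
#' @export
setMethod("gPrime", "SeriesTable", function(x) x@gPrime)

#' @rdname accessors
#' @export
setMethod("gDoublePrime", "SeriesTable", function(x) x@gDoublePrime)

#' @rdname accessors
#' @export
setMethod("viscosity", "SeriesTable", function(x) x@viscosity)

#' Doses of a series table
#' @param x a \code{SeriesTable}.
#' @return numeric dose vector, in \code{x@doseUnit}.
#' @export
doses <- function(x) {
  stopifnot(methods::is(x, "SeriesTable"))
  x@dose
}

#' @rdname accessors
#' @export
setMethod("elasticModulus", "FKVMParams", function(x) x@G)

#' @rdname accessors
#' @export
setMethod("quasiProperty", "FKVMParams", function(x) x@etaAlpha)

#' @rdname accessors
#' @export
setMethod("fractionalOrder", "FKVMParams", function(x) x@alpha)

#' @rdname accessors
#' @export
setMethod("fitParams", "FitResult", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("elasticModulus", "FitResult", function(x) x@params@G)

#' @rdname accessors
#' @export
setMethod("quasiProperty", "FitResult", function(x) x@params@etaAlpha)

#' @rdname accessors
#' @export
setMethod("fractionalOrder", "FitResult", function(x) x@params@alpha)

#' @rdname accessors
#' @export
setMethod("nmPerPx", "CalibratedImage", function(x) x@nmPerPx)

#' @rdname accessors
#' @export
setMethod("imagePixels", "CalibratedImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("nmPerPx", "PoreTable", function(x) x@nmPerPx)

#' @rdname accessors
#' @export
setMethod("poreData", "PoreTable", function(x) x@pores)

setMethod("length", "OscillatorySweep", function(x) length(x@omega))
setMethod("length", "FlowCurve", function(x) length(x@shearRate))
setMethod("length", "AmplitudeSweep", function(x) length(x@strain))

setMethod("show", "OscillatorySweep", function(object) {
  cat(sprintf(
    "OscillatorySweep '%s': %d points, %.3g-%.3g rad/s, direction %s\n",
    object@label, length(object@omega), min(object@omega),
    max(object@omega), object@direction))
  cat(sprintf("  G' %.3g-%.3g Pa, G'' %.3g-%.3g Pa, strain %.3g\n",
    min(object@gPrime), max(object@gPrime), min(object@gDoublePrime),
    max(object@gDoublePrime), object@strainAmplitude))
})

setMethod("show", "FlowCurve", function(object) {
  cat(sprintf("FlowCurve '%s': %d points, %.3g-%.3g 1/s\n",
    object@label, length(object@shearRate), min(object@shearRate),
    max(object@shearRate)))
})

setMethod("show", "FKVMParams", function(object) {
  cat(sprintf(
    "FKVMParams: G = %.4g Pa, eta_alpha = %.4g Pa.s^alpha, alpha = %.4g\n",
    object@G, object@etaAlpha, object@alpha))
})

setMethod("show", "FitResult", function(object) {
  p <- object@params
  se <- object@stderr
  cat(sprintf("FKVM fit%s (%s):\n",
    if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
    if (object@converged) "converged" else "NOT converged"))
  cat(sprintf("  G         = %.4g +/- %.2g Pa\n", p@G, se[["G"]]))
  cat(sprintf("  eta_alpha = %.4g +/- %.2g Pa.s^alpha\n",
    p@etaAlpha, se[["etaAlpha"]]))
  cat(sprintf("  alpha     = %.4g +/- %.2g\n", p@alpha, se[["alpha"]]))
  cat(sprintf("  objective = %.4g; %d values used, %d above %g rad/s\n",
    object@objective, object@nUsed, object@nExcluded, object@cutoff))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf(
    "PowerLawFit: exponent = %.4g +/- %.2g, prefactor = %.4g, R2 = %.4f (n = %d)\n",
    object@exponent, object@exponentStderr, object@prefactor,
    object@rSquared, object@nUsed))
})

setMethod("show", "YieldStressEstimate", function(object) {
  cat(sprintf("YieldStressEstimate (%s): sigma_y = %.4g Pa%s\n",
    object@method, object@sigmaY,
    if (object@noPlateau) " [no plateau detected]" else ""))
})

setMethod("show", "CalibratedImage", function(object) {
  cat(sprintf("CalibratedImage '%s': %d x %d px at %.4g nm/px\n",
    object@label, nrow(object@pixels), ncol(object@pixels),
    object@nmPerPx))
})

setMethod("show", "PoreTable", function(object) {
  p <- object@pores
  cat(sprintf("PoreTable '%s': %d pores (%d edge-touching) at %.4g nm/px\n",
    object@label, nrow(p), sum(p$touchesEdge), object@nmPerPx))
})

setMethod("show", "PoreStats", function(object) {
  cat(sprintf(
    "PoreStats '%s': n = %d, min-Feret mean %.3g nm (sd %.3g), median %.3g [%.3g, %.3g]\n",
    object@label, object@nPores, object@mean, object@sd, object@median,
    object@q25, object@q75))
})
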