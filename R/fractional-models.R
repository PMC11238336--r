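#' @include AllClasses.R
NULL

# Forward evaluation of the fractional Kelvin-Voigt model and derived
# viscoelastic quantities. The complex modulus of a spring (G) in parallel
# with a spring-pot (eta_alpha, alpha) is
#   G*(omega) = G + eta_alpha * (i omega)^alpha        (principal branch)
# so that
#   G'(omega)  = G + eta_alpha * omega^alpha * cos(pi alpha / 2)
#   G''(omega) =     eta_alpha * omega^alpha * sin(pi alpha / 2).
# alpha = 0 degenerates to two parallel springs (G'' = 0); alpha = 1 gives
# the classical Kelvin-Voigt element (G' = G, G'' = eta_alpha * omega).

#' Storage and loss moduli of the fractional Kelvin-Voigt model
#'
#' Evaluates G'(omega) and G''(omega) for a spring of modulus \code{G} in
#' parallel with a spring-pot of quasi-property \code{etaAlpha} and
#' fractional order \code{alpha}. At low frequency G' plateaus at G; at
#' high frequency both moduli grow as omega^alpha and their ratio
#' G''/G' tends to tan(pi alpha / 2).
#'
#' @param params an \code{\link{FKVMParams}} object.
#' @param omega angular frequency grid, rad/s, strictly positive.
#' @return A list with numeric components \code{gPrime} and
#'   \code{gDoublePrime} (Pa), each the length of \code{omega}.
#' @examples
#' p <- FKVMParams(G = 2, etaAlpha = 1.5, alpha = 0.7)
#' fkvmModuli(p, omega = c(0.5, 5, 50))
#' @export
fkvmModuli <- function(params, omega) {
  stopifnot(methods::is(params, "FKVMParams"))
  methods::validObject(params)
  omega <- as.numeric(omega)
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("omega must be finite and strictly positive")
  wa <- omega^params@alpha
  half <- pi * params@alpha / 2
  list(gPrime = params@G + params@etaAlpha * wa * cos(half),
       gDoublePrime = params@etaAlpha * wa * sin(half))
}

#' Phase angle from the loss tangent
#'
#' delta = atan2(G'', G') in degrees: 0 for a fully elastic response,
#' 90 for a fully viscous one, 45 where the moduli are equal.
#'
#' @param gPrime storage modulus, Pa, >= 0 (vectorised).
#' @param gDoublePrime loss modulus, Pa, >= 0 (vectorised).
#' @return Phase angle(s) in degrees, in [0, 90].
#' @examples
#' phaseAngle(1, 0)   # 0:  purely elastic
#' phaseAngle(0, 1)   # 90: purely viscous
#' phaseAngle(1, 1)   # 45: boundary
#' @export
phaseAngle <- function(gPrime, gDoublePrime) {
  if (any(gPrime < 0) || any(gDoublePrime < 0))
    stop("moduli must be non-negative")
  if (any(gPrime == 0 & gDoublePrime == 0))
    stop("phase angle undefined when both moduli are zero")
  atan2(gDoublePrime, gPrime) * 180 / pi
}

#' Complex viscosity
#'
#' eta* = |G*| / omega = sqrt(G'^2 + G''^2) / omega, in Pa s.
#'
#' @param gPrime storage modulus, Pa.
#' @param gDoublePrime loss modulus, Pa.
#' @param omega angular frequency, rad/s, > 0.
#' @return Complex viscosity, Pa s.
#' @examples
#' complexViscosity(3, 4, 10)  # 0.5
#' @export
complexViscosity <- function(gPrime, gDoublePrime, omega) {
  if (any(omega <= 0)) stop("omega must be > 0")
  sqrt(gPrime^2 + gDoublePrime^2) / omega
}

#' Classify a parameter point against its classical limits
#'
#' @param params an \code{FKVMParams} object.
#' @return \code{"spring"} when the spring-pot degenerates to a spring
#'   (alpha = 0 or etaAlpha = 0), \code{"kelvin-voigt"} when it is a
#'   dashpot (alpha = 1), otherwise \code{"fkvm"}.
#' @examples
#' classicalLimits(FKVMParams(1, 0.5, 1))    # "kelvin-voigt"
#' classicalLimits(FKVMParams(1, 0.5, 0.7))  # "fkvm"
#' @export
classicalLimits <- function(params) {
  stopifnot(methods::is(params, "FKVMParams"))
  if (params@alpha == 0 || params@etaAlpha == 0) return("spring")
  if (params@alpha == 1) return("kelvin-voigt")
  "fkvm"
}

#' Derived viscoelastic spectra of a sweep
#'
#' Per-frequency phase angle, complex viscosity and moduli ratio of an
#' oscillatory sweep.
#'
#' @param sweep an \code{\link{OscillatorySweep}}.
#' @return A data.frame with columns \code{omega} (rad/s), \code{delta_deg},
#'   \code{etaStar_Pas} and \code{ratio} (G'/G'').
#' @export
deriveSpectra <- function(sweep) {
  stopifnot(methods::is(sweep, "OscillatorySweep"))
  data.frame(
    omega = sweep@omega,
    delta_deg = phaseAngle(sweep@gPrime, sweep@gDoublePrime),
    etaStar_Pas = complexViscosity(sweep@gPrime, sweep@gDoublePrime,
                                   sweep@omega),
    ratio = sweep@gPrime / sweep@gDoublePrime)
}
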