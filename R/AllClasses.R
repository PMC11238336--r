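# S4 containers for oscillatory rheology, steady shear, scaling fits and
# calibrated micrograph morphometry. All frequencies are stored in rad/s;
# Hz appears only at I/O boundaries.

.sweep_directions <- c("up", "down", "unspecified")

.check_monotone <- function(omega, direction) {
  d <- diff(omega)
  switch(direction,
    up = all(d > 0),
    down = all(d < 0),
    unspecified = all(d > 0) || all(d < 0))
}

#' Oscillatory frequency sweep
#'
#' A frequency-indexed record of the storage modulus G' and loss modulus G''
#' from a small-amplitude oscillatory shear experiment. Frequencies are
#' angular (rad/s); moduli are in Pa. The container validates itself on
#' construction: at least three points, strictly positive finite moduli and
#' a strictly monotone frequency grid consistent with the sweep direction.
#'
#' @slot omega angular frequency grid, rad/s, strictly positive.
#' @slot gPrime storage modulus, Pa.
#' @slot gDoublePrime loss modulus, Pa.
#' @slot strainAmplitude strain amplitude as a fraction (0.01 is 1\%).
#' @slot direction \code{"up"}, \code{"down"} or \code{"unspecified"}.
#' @slot temperature sample temperature, degrees C (may be \code{NA}).
#' @slot label free-text sample or batch identifier.
#' @export
setClass("OscillatorySweep",
  representation(
    omega = "numeric",
    gPrime = "numeric",
    gDoublePrime = "numeric",
    strainAmplitude = "numeric",
    direction = "character",
    temperature = "numeric",
    label = "character"),
  validity = function(object) {
    n <- length(object@omega)
    if (n < 3L)
      return("a sweep needs at least 3 frequency points")
    if (length(object@gPrime) != n || length(object@gDoublePrime) != n)
      return("omega, gPrime and gDoublePrime must have equal length")
    if (!all(is.finite(object@omega)) || any(object@omega <= 0))
      return("omega must be finite and strictly positive")
    m <- c(object@gPrime, object@gDoublePrime)
    if (!all(is.finite(m)) || any(m <= 0))
      return("moduli must be finite and strictly positive")
    if (!object@direction %in% .sweep_directions)
      return("direction must be one of up/down/unspecified")
    if (!.check_monotone(object@omega, object@direction))
      return("omega must be strictly monotone and consistent with direction")
    TRUE
  })

#' Construct an OscillatorySweep
#'
#' @param omega angular frequency, rad/s.
#' @param gPrime storage modulus, Pa.
#' @param gDoublePrime loss modulus, Pa.
#' @param strainAmplitude strain amplitude (fraction), default 0.01 (1\%).
#' @param direction sweep direction, \code{"up"}, \code{"down"} or
#'   \code{"unspecified"}.
#' @param temperature temperature in degrees C, optional.
#' @param label free-text identifier.
#' @return A validated \code{OscillatorySweep}.
#' @examples
#' sw <- OscillatorySweep(omega = c(0.5, 5, 50),
#'                        gPrime = c(2.1, 2.6, 4.0),
#'                        gDoublePrime = c(1.0, 2.4, 6.5))
#' omega(sw)
#' @export
OscillatorySweep <- function(omega, gPrime, gDoublePrime,
                             strainAmplitude = 0.01,
                             direction = c("unspecified", "up", "down"),
                             temperature = NA_real_, label = "") {
  direction <- match.arg(direction)
  methods::new("OscillatorySweep",
    omega = as.numeric(omega),
    gPrime = as.numeric(gPrime),
    gDoublePrime = as.numeric(gDoublePrime),
    strainAmplitude = as.numeric(strainAmplitude),
    direction = direction,
    temperature = as.numeric(temperature),
    label = as.character(label))
}

#' Strain amplitude sweep
#'
#' G' and G'' versus strain amplitude at constant frequency, as used to
#' locate the linear viscoelastic (LVE) region.
#'
#' @slot strain strain amplitude, fraction, strictly increasing.
#' @slot gPrime storage modulus, Pa.
#' @slot gDoublePrime loss modulus, Pa.
#' @slot frequency the constant oscillation frequency, Hz.
#' @slot label free-text identifier.
#' @export
setClass("AmplitudeSweep",
  representation(
    strain = "numeric",
    gPrime = "numeric",
    gDoublePrime = "numeric",
    frequency = "numeric",
    label = "character"),
  validity = function(object) {
    n <- length(object@strain)
    if (length(object@gPrime) != n || length(object@gDoublePrime) != n)
      return("strain, gPrime, gDoublePrime must have equal length")
    if (any(object@strain <= 0) || any(diff(object@strain) <= 0))
      return("strain must be positive and strictly increasing")
    if (!all(is.finite(c(object@gPrime, object@gDoublePrime))))
      return("moduli must be finite")
    TRUE
  })

#' @param strain strain amplitude array (fraction).
#' @param gPrime,gDoublePrime moduli arrays, Pa.
#' @param frequency constant frequency, Hz.
#' @param label free-text identifier.
#' @rdname AmplitudeSweep-class
#' @export
AmplitudeSweep <- function(strain, gPrime, gDoublePrime, frequency = 1,
                           label = "") {
  methods::new("AmplitudeSweep", strain = as.numeric(strain),
    gPrime = as.numeric(gPrime), gDoublePrime = as.numeric(gDoublePrime),
    frequency = as.numeric(frequency), label = as.character(label))
}

#' Steady-shear flow curve
#'
#' Viscosity versus shear rate; the shear stress is carried alongside and
#' must equal viscosity times shear rate.
#'
#' @slot shearRate shear rate, 1/s, strictly positive.
#' @slot viscosity shear viscosity, Pa s.
#' @slot stress shear stress, Pa (viscosity times shear rate).
#' @slot direction sweep direction.
#' @slot label free-text identifier.
#' @export
setClass("FlowCurve",
  representation(
    shearRate = "numeric",
    viscosity = "numeric",
    stress = "numeric",
    direction = "character",
    label = "character"),
  validity = function(object) {
    n <- length(object@shearRate)
    if (length(object@viscosity) != n || length(object@stress) != n)
      return("shearRate, viscosity and stress must have equal length")
    if (any(object@shearRate <= 0) || !all(is.finite(object@shearRate)))
      return("shearRate must be finite and strictly positive")
    if (!all(is.finite(object@viscosity)) || any(object@viscosity <= 0))
      return("viscosity must be finite and positive")
    rel <- abs(object@stress - object@viscosity * object@shearRate) /
      pmax(object@stress, .Machine$double.xmin)
    if (any(rel > 1e-6))
      return("stress must equal viscosity * shearRate")
    if (!object@direction %in% .sweep_directions)
      return("direction must be one of up/down/unspecified")
    TRUE
  })

#' @param shearRate shear rate array, 1/s.
#' @param viscosity viscosity array, Pa s.
#' @param stress optional stress array, Pa; computed from
#'   \code{viscosity * shearRate} when omitted.
#' @param direction sweep direction.
#' @param label free-text identifier.
#' @rdname FlowCurve-class
#' @export
FlowCurve <- function(shearRate, viscosity, stress = NULL,
                      direction = c("unspecified", "up", "down"),
                      label = "") {
  direction <- match.arg(direction)
  shearRate <- as.numeric(shearRate)
  viscosity <- as.numeric(viscosity)
  if (is.null(stress)) stress <- viscosity * shearRate
  methods::new("FlowCurve", shearRate = shearRate, viscosity = viscosity,
    stress = as.numeric(stress), direction = direction,
    label = as.character(label))
}

#' Dose-response series at representative conditions
#'
#' One row per dose (e.g. mucin concentration or additive concentration)
#' holding G' and G'' at a reference frequency and the shear viscosity at a
#' reference shear rate -- the representative-point convention used for
#' power-law scaling plots.
#'
#' @slot dose dose array, strictly increasing, in \code{doseUnit}.
#' @slot doseUnit unit string (\code{"g/L"}, \code{"mM"}, ...).
#' @slot gPrime G' at the reference frequency, Pa.
#' @slot gDoublePrime G'' at the reference frequency, Pa.
#' @slot viscosity shear viscosity at the reference shear rate, Pa s.
#' @slot referenceFrequency Hz.
#' @slot referenceShearRate 1/s.
#' @export
setClass("SeriesTable",
  representation(
    dose = "numeric",
    doseUnit = "character",
    gPrime = "numeric",
    gDoublePrime = "numeric",
    viscosity = "numeric",
    referenceFrequency = "numeric",
    referenceShearRate = "numeric"),
  validity = function(object) {
    n <- length(object@dose)
    if (any(diff(object@dose) <= 0))
      return("dose must be strictly increasing")
    if (length(object@gPrime) != n || length(object@gDoublePrime) != n ||
        length(object@viscosity) != n)
      return("one response record per dose is required")
    if (length(object@referenceFrequency) != 1L ||
        length(object@referenceShearRate) != 1L)
      return("reference frequency and shear rate must be scalars")
    TRUE
  })

#' @param dose dose array (strictly increasing).
#' @param gPrime,gDoublePrime moduli at the reference frequency, Pa.
#' @param viscosity viscosity at the reference shear rate, Pa s.
#' @param doseUnit unit string for dose.
#' @param referenceFrequency reference frequency, Hz (default 1).
#' @param referenceShearRate reference shear rate, 1/s (default 1).
#' @rdname SeriesTable-class
#' @export
SeriesTable <- function(dose, gPrime, gDoublePrime, viscosity,
                        doseUnit = "g/L", referenceFrequency = 1,
                        referenceShearRate = 1) {
  methods::new("SeriesTable", dose = as.numeric(dose),
    doseUnit = as.character(doseUnit), gPrime = as.numeric(gPrime),
    gDoublePrime = as.numeric(gDoublePrime),
    viscosity = as.numeric(viscosity),
    referenceFrequency = as.numeric(referenceFrequency),
    referenceShearRate = as.numeric(referenceShearRate))
}

#' Fractional Kelvin-Voigt parameters
#'
#' The three parameters of the fractional Kelvin-Voigt model: a spring of
#' elastic modulus G (Pa) in parallel with a spring-pot of quasi-property
#' eta_alpha (Pa s^alpha) and fractional order alpha in [0, 1]. alpha = 0
#' degenerates the spring-pot to a second spring, alpha = 1 to a dashpot
#' (classical Kelvin-Voigt).
#'
#' @slot G elastic modulus, Pa, non-negative.
#' @slot etaAlpha quasi-property, Pa s^alpha, non-negative.
#' @slot alpha fractional order, dimensionless, in [0, 1].
#' @export
setClass("FKVMParams",
  representation(G = "numeric", etaAlpha = "numeric", alpha = "numeric"),
  validity = function(object) {
    if (length(object@G) != 1L || length(object@etaAlpha) != 1L ||
        length(object@alpha) != 1L)
      return("G, etaAlpha and alpha must be scalars")
    if (!is.finite(object@alpha) || object@alpha < 0 || object@alpha > 1)
      return("alpha must lie in [0, 1]")
    if (!is.finite(object@G) || object@G < 0)
      return("G must be finite and >= 0")
    if (!is.finite(object@etaAlpha) || object@etaAlpha < 0)
      return("etaAlpha must be finite and >= 0")
    if (object@G == 0 && object@etaAlpha == 0)
      return("G and etaAlpha must not both be zero")
    TRUE
  })

#' @param G elastic modulus, Pa.
#' @param etaAlpha quasi-property, Pa s^alpha.
#' @param alpha fractional order in [0, 1].
#' @rdname FKVMParams-class
#' @export
FKVMParams <- function(G, etaAlpha, alpha) {
  methods::new("FKVMParams", G = as.numeric(G),
    etaAlpha = as.numeric(etaAlpha), alpha = as.numeric(alpha))
}

#' Result of a fractional Kelvin-Voigt fit
#'
#' @slot params fitted \code{FKVMParams}.
#' @slot stderr named numeric: 1-sigma standard errors for G, etaAlpha and
#'   alpha (may be \code{NA} when the covariance is singular).
#' @slot objective final minimised sum of squared log residuals.
#' @slot nUsed number of modulus values entering the fit (both moduli).
#' @slot nExcluded number of modulus values above the frequency cutoff.
#' @slot cutoff angular frequency cutoff, rad/s.
#' @slot converged logical convergence flag.
#' @slot seed integer seed used for restart jitter.
#' @slot label sample label carried over from the sweep.
#' @export
setClass("FitResult",
  representation(
    params = "FKVMParams",
    stderr = "numeric",
    objective = "numeric",
    nUsed = "integer",
    nExcluded = "integer",
    cutoff = "numeric",
    converged = "logical",
    seed = "integer",
    label = "character"),
  validity = function(object) {
    if (object@objective < 0) return("objective must be >= 0")
    if (object@nUsed < 0 || object@nExcluded < 0)
      return("point counts must be non-negative")
    TRUE
  })

#' Power-law fit of y against x
#'
#' @slot exponent fitted exponent (slope of ln y on ln x).
#' @slot prefactor fitted prefactor (exp of intercept), units of y at x = 1.
#' @slot exponentStderr standard error of the exponent.
#' @slot rSquared coefficient of determination in log-log space.
#' @slot xRange the x window actually used.
#' @slot nUsed number of points used.
#' @export
setClass("PowerLawFit",
  representation(
    exponent = "numeric",
    prefactor = "numeric",
    exponentStderr = "numeric",
    rSquared = "numeric",
    xRange = "numeric",
    nUsed = "integer"),
  validity = function(object) {
    if (object@nUsed < 2L) return("a power-law fit needs >= 2 points")
    if (!is.finite(object@exponent) || !is.finite(object@prefactor))
      return("exponent and prefactor must be finite")
    TRUE
  })

#' Yield stress estimate from a flow curve
#'
#' @slot sigmaY yield stress, Pa, non-negative.
#' @slot sigmaYStderr standard error of sigmaY (NA when unavailable).
#' @slot K Herschel-Bulkley consistency, Pa s^n.
#' @slot n Herschel-Bulkley flow index, in (0, 1].
#' @slot method method tag (\code{"herschel-bulkley"} or
#'   \code{"stress-plateau"}).
#' @slot window shear-rate window used, 1/s.
#' @slot noPlateau TRUE when the fitted yield stress is indistinguishable
#'   from zero.
#' @export
setClass("YieldStressEstimate",
  representation(
    sigmaY = "numeric",
    sigmaYStderr = "numeric",
    K = "numeric",
    n = "numeric",
    method = "character",
    window = "numeric",
    noPlateau = "logical"),
  validity = function(object) {
    if (!is.finite(object@sigmaY) || object@sigmaY < 0)
      return("sigmaY must be finite and >= 0")
    TRUE
  })

#' Calibrated grayscale micrograph
#'
#' @slot pixels numeric matrix of intensities (rows = y, columns = x).
#' @slot nmPerPx physical pixel size, nm per pixel, > 0.
#' @slot label free-text identifier.
#' @export
setClass("CalibratedImage",
  representation(pixels = "matrix", nmPerPx = "numeric",
                 label = "character"),
  validity = function(object) {
    if (nrow(object@pixels) < 16L || ncol(object@pixels) < 16L)
      return("image must be at least 16 x 16 pixels")
    if (!all(is.finite(object@pixels)))
      return("intensities must be finite")
    if (!is.finite(object@nmPerPx) || object@nmPerPx <= 0)
      return("nmPerPx must be finite and > 0")
    TRUE
  })

#' @param pixels numeric intensity matrix.
#' @param nmPerPx nm per pixel.
#' @param label free-text identifier.
#' @rdname CalibratedImage-class
#' @export
CalibratedImage <- function(pixels, nmPerPx, label = "") {
  storage.mode(pixels) <- "double"
  methods::new("CalibratedImage", pixels = pixels,
    nmPerPx = as.numeric(nmPerPx), label = as.character(label))
}

#' Per-pore geometry table
#'
#' One row per labelled pore: area, Feret diameters (nm), edge flag and
#' centroid in pixel coordinates. Edge-touching pores are retained in the
#' table but excluded from all statistics.
#'
#' @slot pores data.frame with columns \code{poreId}, \code{area_nm2},
#'   \code{minFeret_nm}, \code{maxFeret_nm}, \code{touchesEdge},
#'   \code{centroidRow}, \code{centroidCol}.
#' @slot nmPerPx calibration used, nm per pixel.
#' @slot label image label.
#' @export
setClass("PoreTable",
  representation(pores = "data.frame", nmPerPx = "numeric",
                 label = "character"),
  validity = function(object) {
    need <- c("poreId", "area_nm2", "minFeret_nm", "maxFeret_nm",
              "touchesEdge", "centroidRow", "centroidCol")
    if (!all(need %in% names(object@pores)))
      return(paste("pores must have columns:", paste(need, collapse = ", ")))
    p <- object@pores
    if (nrow(p) && any(p$minFeret_nm > p$maxFeret_nm + 1e-9))
      return("minFeret must not exceed maxFeret")
    if (nrow(p) && any(p$area_nm2 <= 0))
      return("areas must be positive")
    TRUE
  })

#' Summary statistics of a pore population
#'
#' Computed over non-edge pores only.
#'
#' @slot nPores number of non-edge pores summarised.
#' @slot mean,sd,median,q25,q75 summary of the minimum Feret diameter, nm;
#'   \code{sd} is \code{NA} for a single pore.
#' @slot label provenance label.
#' @export
setClass("PoreStats",
  representation(nPores = "integer", mean = "numeric", sd = "numeric",
                 median = "numeric", q25 = "numeric", q75 = "numeric",
                 label = "character"),
  validity = function(object) {
    if (object@nPores < 1L) return("stats need at least one non-edge pore")
    qs <- c(object@q25, object@median, object@q75)
    if (any(diff(qs) < -1e-12)) return("quantiles must be ordered")
    TRUE
  })
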