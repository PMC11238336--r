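#' @include AllClasses.R
NULL

# Power-law scaling of moduli and viscosity against concentration or
# additive dose, shear-thinning exponents, Herschel-Bulkley yield-stress
# estimation, LVE-region detection and sweep-comparison ratios.

#' Power-law fit by ordinary least squares in log-log space
#'
#' Fits y = prefactor * x^exponent by regressing ln y on ln x. Exact (to
#' rounding) on noiseless power-law data, and exactly unit-covariant:
#' rescaling x by k leaves the exponent unchanged and rescales the
#' prefactor by k^(-exponent).
#'
#' @param x,y positive numeric vectors of equal length.
#' @param window optional length-2 x-range; only points inside (inclusive)
#'   are used.
#' @return A \code{\link{PowerLawFit}}.
#' @examples
#' powerLawFit(c(1, 2, 4, 8), 3 * c(1, 2, 4, 8)^2)  # exponent 2, prefactor 3
#' @export
powerLawFit <- function(x, y, window = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- rep(TRUE, length(x))
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    keep <- x >= min(window) & x <= max(window)
  }
  if (any(x[keep] <= 0) || any(y[keep] <= 0))
    stop("domain error: non-positive values inside the fit window")
  if (sum(keep) < 2L)
    stop("insufficient data: a power-law fit needs >= 2 points in window")
  lx <- log(x[keep]); ly <- log(y[keep])
  fit <- stats::lm(ly ~ lx)
  cf <- stats::coef(fit)
  # summary.lm warns on exact power laws ("essentially perfect fit");
  # that is a legitimate input here, not a problem
  sm <- suppressWarnings(summary(fit))
  se <- if (sum(keep) > 2L) sm$coefficients["lx", "Std. Error"]
        else NA_real_
  r2 <- if (stats::var(ly) > 0) sm$r.squared else 1
  methods::new("PowerLawFit",
    exponent = unname(cf[["lx"]]),
    prefactor = exp(unname(cf[["(Intercept)"]])),
    exponentStderr = se,
    rSquared = r2,
    xRange = range(x[keep]),
    nUsed = as.integer(sum(keep)))
}

#' Shear-thinning exponent of a flow curve
#'
#' Power-law fit of viscosity against shear rate inside an explicit
#' shear-rate window; the shear-thinning exponent is reported as the
#' magnitude of the (negative) log-log slope. A Newtonian curve gives 0.
#'
#' @param curve a \code{\link{FlowCurve}}.
#' @param window length-2 shear-rate range, 1/s. Mandatory: reported
#'   exponents depend on the window, so it is never guessed.
#' @return A \code{PowerLawFit} whose \code{exponent} slot holds the signed
#'   log-log slope; attribute \code{thinningExponent} holds its magnitude.
#' @export
shearThinningExponent <- function(curve, window) {
  stopifnot(methods::is(curve, "FlowCurve"))
  if (missing(window)) stop("an explicit shear-rate window is required")
  fit <- powerLawFit(curve@shearRate, curve@viscosity, window = window)
  attr(fit, "thinningExponent") <- abs(fit@exponent)
  fit
}

#' Yield stress from a Herschel-Bulkley fit of the stress curve
#'
#' Fits sigma(gammadot) = sigma_y + K * gammadot^n on the low-shear half of
#' the curve (in log shear rate) by bounded nonlinear least squares on
#' log sigma. When the fitted sigma_y is indistinguishable from zero (its
#' standard error exceeds its value, or it collapses onto the lower bound)
#' the estimate is flagged \code{noPlateau}.
#'
#' @param curve a \code{\link{FlowCurve}} spanning >= 2 decades of shear
#'   rate.
#' @param method \code{"herschel-bulkley"} (default) or
#'   \code{"stress-plateau"} (median stress over the lowest decade of
#'   shear rate; a transparent non-parametric alternative).
#' @param window optional explicit shear-rate window; default is the
#'   low-shear half of the data.
#' @return A \code{\link{YieldStressEstimate}}.
#' @export
yieldStressEstimate <- function(curve,
                                method = c("herschel-bulkley",
                                           "stress-plateau"),
                                window = NULL) {
  stopifnot(methods::is(curve, "FlowCurve"))
  method <- match.arg(method)
  lgd <- log10(curve@shearRate)
  if (diff(range(lgd)) < 2)
    stop("curve must span at least 2 decades of shear rate")
  if (is.null(window)) {
    mid <- min(lgd) + diff(range(lgd)) / 2
    window <- c(10^min(lgd), 10^mid)
  }
  keep <- curve@shearRate >= min(window) & curve@shearRate <= max(window)
  gd <- curve@shearRate[keep]; sg <- curve@stress[keep]

  if (method == "stress-plateau") {
    low <- gd <= min(gd) * 10
    sy <- stats::median(sg[low])
    return(methods::new("YieldStressEstimate", sigmaY = sy,
      sigmaYStderr = NA_real_, K = NA_real_, n = NA_real_,
      method = method, window = range(gd), noPlateau = FALSE))
  }

  if (length(gd) < 4L)
    stop("estimation error: too few points in window for a 3-parameter fit")
  # start: sigma_y from the lowest stresses, n and K from the upper end
  sy0 <- max(min(sg) * 0.5, .Machine$double.eps)
  hi <- gd >= stats::median(gd)
  n0 <- tryCatch(max(min(stats::coef(stats::lm(
    log(pmax(sg[hi] - sy0, 1e-12)) ~ log(gd[hi])))[[2]], 1), 0.05),
    error = function(e) 0.5)
  K0 <- max((max(sg) - sy0) / max(gd)^n0, 1e-12)
  lower <- c(0, 1e-12, 1e-3)
  upper <- c(Inf, Inf, 1)
  fit <- tryCatch(minpack.lm::nls.lm(
    par = c(sy0, K0, n0), lower = lower, upper = upper,
    fn = function(p) log(pmax(p[1] + p[2] * gd^p[3], 1e-300)) - log(sg),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)),
    error = function(e) stop("estimation error: ", conditionMessage(e)))
  p <- fit$par
  se <- tryCatch({
    s2 <- fit$deviance / max(length(fit$fvec) - 3, 1)
    sqrt(pmax(diag(s2 * solve(fit$hessian)), 0))[1]
  }, error = function(e) NA_real_)
  no_plateau <- p[1] <= 2 * lower[1] + 1e-12 ||
    (is.finite(se) && se >= p[1]) || !is.finite(se)
  methods::new("YieldStressEstimate", sigmaY = p[1], sigmaYStderr = se,
    K = p[2], n = p[3], method = method, window = range(gd),
    noPlateau = no_plateau)
}

#' Critical strain bounding the linear viscoelastic region
#'
#' The G' plateau is estimated as the mean over the lowest-strain third of
#' the sweep; the critical strain is the first strain at which G' departs
#' from that plateau by more than \code{tolerance} (relative). If no point
#' departs, the largest strain is returned and flagged.
#'
#' @param sweep an \code{\link{AmplitudeSweep}} with >= 5 points.
#' @param tolerance relative departure from the plateau defining the end of
#'   the LVE region (default 0.10).
#' @return The critical strain (fraction) with attributes \code{plateau}
#'   (Pa), \code{noDeparture} (logical) and \code{lowConfidence} (logical;
#'   set when G' decays monotonically so no plateau is resolved).
#' @export
lveRegion <- function(sweep, tolerance = 0.10) {
  stopifnot(methods::is(sweep, "AmplitudeSweep"))
  n <- length(sweep@strain)
  if (n < 5L) stop("insufficient data: need >= 5 strain points")
  third <- seq_len(max(ceiling(n / 3), 2L))
  plateau <- mean(sweep@gPrime[third])
  dev <- abs(sweep@gPrime - plateau) / plateau
  idx <- which(dev > tolerance)
  no_dep <- length(idx) == 0L
  crit <- if (no_dep) sweep@strain[n] else sweep@strain[min(idx)]
  # a monotone decay with no flat stretch means the "plateau" is not a
  # plateau at all; flag rather than guess
  d <- diff(sweep@gPrime)
  low_conf <- all(d < 0) && dev[length(third) + 1] > tolerance / 2
  attr(crit, "plateau") <- plateau
  attr(crit, "noDeparture") <- no_dep
  attr(crit, "lowConfidence") <- isTRUE(low_conf)
  crit
}

# linear interpolation in ln-ln space onto grid w
.loglog_interp <- function(w, w0, y0) {
  exp(stats::approx(log(w0), log(y0), xout = log(w))$y)
}

#' Per-frequency ratios between two oscillatory sweeps
#'
#' Computes G'a/G'b and G''a/G''b on a common frequency grid (the overlap
#' of the two grids; sweep b is interpolated in log-log space when the
#' grids differ), plus each sweep's own G'/G'' ratio.
#'
#' @param a,b \code{OscillatorySweep}s with overlapping frequency ranges.
#' @return A data.frame with columns \code{omega}, \code{ratio_gPrime},
#'   \code{ratio_gDoublePrime}, \code{ratio_a} (G'/G'' of a),
#'   \code{ratio_b}; attribute \code{summary} holds min/max of the
#'   cross-sweep ratios.
#' @export
sweepRatios <- function(a, b) {
  stopifnot(methods::is(a, "OscillatorySweep"),
            methods::is(b, "OscillatorySweep"))
  lo <- max(min(a@omega), min(b@omega))
  hi <- min(max(a@omega), max(b@omega))
  if (lo > hi) stop("alignment error: disjoint frequency ranges")
  keep <- a@omega >= lo & a@omega <= hi
  w <- a@omega[keep]
  gp_b <- .loglog_interp(w, b@omega, b@gPrime)
  gpp_b <- .loglog_interp(w, b@omega, b@gDoublePrime)
  out <- data.frame(
    omega = w,
    ratio_gPrime = a@gPrime[keep] / gp_b,
    ratio_gDoublePrime = a@gDoublePrime[keep] / gpp_b,
    ratio_a = a@gPrime[keep] / a@gDoublePrime[keep],
    ratio_b = gp_b / gpp_b)
  attr(out, "summary") <- c(
    min = min(out$ratio_gPrime, out$ratio_gDoublePrime),
    max = max(out$ratio_gPrime, out$ratio_gDoublePrime))
  out
}

#' Scaling report for a dose series
#'
#' Power-law fits of G', G'' and viscosity against dose at the series'
#' representative conditions.
#'
#' @param series a \code{\link{SeriesTable}}.
#' @param window optional dose window passed to each fit.
#' @return A data.frame with one row per response (gPrime, gDoublePrime,
#'   viscosity): exponent, stderr, prefactor, r-squared, window and n;
#'   attribute \code{fits} holds the \code{PowerLawFit} objects.
#' @export
scalingReport <- function(series, window = NULL) {
  stopifnot(methods::is(series, "SeriesTable"))
  fits <- list(
    gPrime = powerLawFit(series@dose, series@gPrime, window),
    gDoublePrime = powerLawFit(series@dose, series@gDoublePrime, window),
    viscosity = powerLawFit(series@dose, series@viscosity, window))
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(response = nm, exponent = f@exponent,
               exponent_se = f@exponentStderr, prefactor = f@prefactor,
               r_squared = f@rSquared, x_min = f@xRange[1],
               x_max = f@xRange[2], n = f@nUsed)
  }))
  attr(out, "fits") <- fits
  out
}
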