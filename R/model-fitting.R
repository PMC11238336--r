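#' @include AllClasses.R fractional-models.R
NULL

# Simultaneous fit of G' and G'' to the fractional Kelvin-Voigt model.
# Both moduli enter one residual vector of log ratios,
#   r = [ln(G'_model/G'_data), ln(G''_model/G''_data)],
# so every point counts equally although the moduli span decades. Only
# angular frequencies below the cutoff (default 50 rad/s) enter the fit;
# higher frequencies are prone to instrument/sample inertia artifacts and
# are excluded outright. The optimiser works in transformed coordinates
# (ln G, ln eta_alpha, logit alpha) so the box constraints are smooth.

.fkvm_logres <- function(par, w, lgp, lgpp, relative = FALSE) {
  # par = (lnG, lnEta, logit alpha)
  G <- exp(par[1]); eta <- exp(par[2])
  a <- stats::plogis(par[3])
  wa <- w^a; half <- pi * a / 2
  mp <- G + eta * wa * cos(half)
  mpp <- eta * wa * sin(half)
  if (relative) {
    c(mp / exp(lgp) - 1, mpp / exp(lgpp) - 1)
  } else {
    c(log(mp) - lgp, log(mpp) - lgpp)
  }
}

.fit_included <- function(sweep, cutoff) {
  inc <- sweep@omega < cutoff
  if (sum(inc) < 3L)
    stop("insufficient data: fewer than 3 points below cutoff of ",
         cutoff, " rad/s")
  inc
}

#' Log-residual objective of the fractional Kelvin-Voigt fit
#'
#' The minimised quantity: the sum over all included frequency points of
#' the squared log residuals of both moduli,
#' sum(ln(G'_model/G'_data)^2) + sum(ln(G''_model/G''_data)^2).
#' Points at or above the frequency cutoff contribute nothing.
#'
#' @param params an \code{\link{FKVMParams}} object.
#' @param sweep an \code{\link{OscillatorySweep}}.
#' @param cutoff angular frequency cutoff, rad/s (default 50).
#' @return Non-negative scalar; 0 iff the model reproduces every included
#'   point exactly.
#' @export
fkvmObjective <- function(params, sweep, cutoff = 50) {
  stopifnot(methods::is(params, "FKVMParams"),
            methods::is(sweep, "OscillatorySweep"))
  inc <- .fit_included(sweep, cutoff)
  mod <- fkvmModuli(params, sweep@omega[inc])
  sum(log(mod$gPrime / sweep@gPrime[inc])^2) +
    sum(log(mod$gDoublePrime / sweep@gDoublePrime[inc])^2)
}

# Asymptote-based starting point: alpha from the log-log slope of G'' over
# the top included decade, eta_alpha from G'' at the highest included
# frequency, G from G' at the lowest frequency minus the spring-pot part.
.fkvm_init <- function(w, gp, gpp) {
  top <- w >= max(w) / 10
  if (sum(top) < 2L) top <- rank(-w) <= 2
  a0 <- stats::coef(stats::lm(log(gpp[top]) ~ log(w[top])))[[2]]
  a0 <- min(max(a0, 0.05), 0.95)
  i_hi <- which.max(w)
  eta0 <- gpp[i_hi] / (w[i_hi]^a0 * sin(pi * a0 / 2))
  i_lo <- which.min(w)
  G0 <- gp[i_lo] - eta0 * w[i_lo]^a0 * cos(pi * a0 / 2)
  G0 <- max(G0, 1e-3 * gp[i_lo])
  c(log(G0), log(eta0), stats::qlogis(a0))
}

.fkvm_bounds_t <- function(bounds) {
  # transform the natural-parameter box to the optimiser coordinates
  lower <- c(log(max(bounds$G[1], 1e-12)), log(max(bounds$etaAlpha[1], 1e-12)),
             stats::qlogis(bounds$alpha[1]))
  upper <- c(log(bounds$G[2]), log(bounds$etaAlpha[2]),
             stats::qlogis(bounds$alpha[2]))
  list(lower = lower, upper = upper)
}

#' Fit the fractional Kelvin-Voigt model to an oscillatory sweep
#'
#' Simultaneous nonlinear least-squares fit of G' and G'' with the
#' log-residual objective (see \code{\link{fkvmObjective}}), a frequency
#' cutoff, asymptote-based initialisation and a deterministic seeded
#' multi-start. Standard errors come from the Jacobian-based covariance of
#' the log-residual fit, propagated to the natural parameters.
#'
#' @param sweep an \code{\link{OscillatorySweep}}.
#' @param cutoff angular frequency cutoff, rad/s; points at or above it are
#'   excluded, never down-weighted. Default 50.
#' @param bounds list with elements \code{G}, \code{etaAlpha}, \code{alpha},
#'   each a length-2 numeric range. Defaults: G in [0, Inf), etaAlpha in
#'   (0, Inf), alpha in (0.01, 0.99).
#' @param nRestarts number of seeded jittered restarts around the
#'   asymptote-based start (default 5).
#' @param seed integer seed controlling the restart jitter.
#' @param objective \code{"log"} (default) or \code{"relative"}
#'   ((model - data)/data residuals, for sensitivity checks).
#' @return A \code{\link{FitResult}}.
#' @examples
#' p <- FKVMParams(G = 2, etaAlpha = 1.5, alpha = 0.7)
#' w <- exp(seq(log(0.3), log(45), length.out = 30))
#' m <- fkvmModuli(p, w)
#' fit <- fitFKVM(OscillatorySweep(w, m$gPrime, m$gDoublePrime))
#' fractionalOrder(fit)
#' @export
fitFKVM <- function(sweep, cutoff = 50,
                    bounds = list(G = c(0, Inf), etaAlpha = c(1e-12, Inf),
                                  alpha = c(0.01, 0.99)),
                    nRestarts = 5, seed = 1,
                    objective = c("log", "relative")) {
  stopifnot(methods::is(sweep, "OscillatorySweep"))
  objective <- match.arg(objective)
  inc <- .fit_included(sweep, cutoff)
  w <- sweep@omega[inc]
  lgp <- log(sweep@gPrime[inc]); lgpp <- log(sweep@gDoublePrime[inc])
  relative <- objective == "relative"

  p0 <- .fkvm_init(w, sweep@gPrime[inc], sweep@gDoublePrime[inc])
  bt <- .fkvm_bounds_t(bounds)
  clamp <- function(p) pmin(pmax(p, bt$lower + 1e-9), bt$upper - 1e-9)

  nj <- max(nRestarts - 1, 0)
  jitter <- .with_seed(seed,
    matrix(stats::rnorm(3 * nj, sd = rep(c(1, 1, 0.75), nj)), nrow = 3))
  starts <- c(list(clamp(p0)),
              lapply(seq_len(nj), function(i) clamp(p0 + jitter[, i])))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = bt$lower, upper = bt$upper,
                         fn = .fkvm_logres, w = w, lgp = lgp, lgpp = lgpp,
                         relative = relative,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("convergence error: all ", length(starts), " restarts failed")

  par <- best$par
  G <- exp(par[1]); eta <- exp(par[2]); a <- stats::plogis(par[3])
  # delta-method propagation from (lnG, lnEta, logit a) to (G, eta, a)
  se <- rep(NA_real_, 3)
  cov_t <- tryCatch({
    s2 <- best$deviance / max(length(best$fvec) - 3, 1)
    s2 * solve(best$hessian)
  }, error = function(e) NULL)
  if (!is.null(cov_t)) {
    jac <- c(G, eta, a * (1 - a))
    se <- sqrt(pmax(diag(cov_t), 0)) * jac
  }
  names(se) <- c("G", "etaAlpha", "alpha")

  converged <- best$info %in% 1:4 && all(is.finite(par))
  methods::new("FitResult",
    params = FKVMParams(G, eta, a),
    stderr = se,
    objective = if (relative)
      fkvmObjective(FKVMParams(G, eta, a), sweep, cutoff)
    else best$deviance,
    nUsed = 2L * sum(inc),
    nExcluded = 2L * sum(!inc),
    cutoff = cutoff,
    converged = converged,
    seed = as.integer(seed),
    label = sweep@label)
}

#' Fit the fractional Kelvin-Voigt model across a dose series
#'
#' Applies \code{\link{fitFKVM}} with shared settings to each sweep of a
#' concentration or additive series. Per-sweep failures are flagged and do
#' not abort the batch.
#'
#' @param sweeps list of \code{OscillatorySweep} objects.
#' @param dose numeric dose labels, one per sweep.
#' @param ... passed to \code{\link{fitFKVM}}.
#' @return A data.frame sorted by dose with columns \code{dose}, \code{G},
#'   \code{etaAlpha}, \code{alpha}, the three standard errors,
#'   \code{objective}, \code{nUsed}, \code{nExcluded}, \code{converged},
#'   \code{failed} and \code{label}; attribute \code{fits} holds the
#'   \code{FitResult} objects (NULL where failed).
#' @export
fitSeries <- function(sweeps, dose = seq_along(sweeps), ...) {
  if (length(sweeps) < 1L) stop("at least one sweep is required")
  if (length(dose) != length(sweeps))
    stop("one dose label per sweep is required")
  ord <- order(dose)
  sweeps <- sweeps[ord]; dose <- dose[ord]
  fits <- lapply(sweeps, function(s)
    tryCatch(fitFKVM(s, ...), error = function(e) e))
  row <- function(f, d, lab) {
    if (methods::is(f, "FitResult")) {
      data.frame(dose = d, G = f@params@G, etaAlpha = f@params@etaAlpha,
                 alpha = f@params@alpha, G_se = f@stderr[["G"]],
                 etaAlpha_se = f@stderr[["etaAlpha"]],
                 alpha_se = f@stderr[["alpha"]], objective = f@objective,
                 nUsed = f@nUsed, nExcluded = f@nExcluded,
                 converged = f@converged, failed = FALSE, label = f@label)
    } else {
      data.frame(dose = d, G = NA_real_, etaAlpha = NA_real_,
                 alpha = NA_real_, G_se = NA_real_, etaAlpha_se = NA_real_,
                 alpha_se = NA_real_, objective = NA_real_, nUsed = NA_integer_,
                 nExcluded = NA_integer_, converged = FALSE, failed = TRUE,
                 label = lab)
    }
  }
  labs <- vapply(sweeps, function(s) s@label, character(1))
  out <- do.call(rbind, Map(row, fits, dose, labs))
  rownames(out) <- NULL
  attr(out, "fits") <- lapply(fits, function(f)
    if (methods::is(f, "FitResult")) f else NULL)
  out
}

#' Serialise a FitResult to a JSON file
#'
#' @param fit a \code{FitResult}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFitResult <- function(fit, path) {
  stopifnot(methods::is(fit, "FitResult"))
  jsonlite::write_json(list(
    label = fit@label,
    params = list(G_Pa = fit@params@G,
                  etaAlpha_Pa_s_alpha = fit@params@etaAlpha,
                  alpha = fit@params@alpha),
    stderr = as.list(fit@stderr),
    objective = fit@objective,
    n_used = fit@nUsed, n_excluded = fit@nExcluded,
    cutoff_rad_s = fit@cutoff,
    converged = fit@converged, seed = fit@seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
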