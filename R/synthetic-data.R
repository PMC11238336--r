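#' @include AllClasses.R fractional-models.R utils.R
NULL

# Seeded generators for every input class the pipeline consumes, each
# returning the generated object together with its ground truth. Defaults
# are centred on the regime of soft mucin gels: fractional Kelvin-Voigt
# spectra with moduli of a few Pa and alpha around 0.70, concentration
# scaling exponents near 2, mPa-scale yield stresses, and pore populations
# with minimum Feret diameters mainly between 10 and 80 nm. Noise is
# multiplicative lognormal (rheometer errors scale with signal),
# parameterised by its coefficient of variation.

#' Generate a synthetic oscillatory sweep from the FKVM forward model
#'
#' @param params ground-truth \code{\link{FKVMParams}} (default G = 2 Pa,
#'   etaAlpha = 1.5 Pa s^alpha, alpha = 0.70).
#' @param omegaRange angular frequency range, rad/s (default 0.3 to 300).
#' @param nPoints number of log-spaced grid points (default 30).
#' @param noiseCv coefficient of variation of the multiplicative lognormal
#'   noise, independent across points and moduli (default 0 = noiseless).
#' @param seed integer seed.
#' @param label sample label.
#' @return A list: \code{sweep} (an \code{OscillatorySweep}) and
#'   \code{truth} (params, noiseCv, seed).
#' @examples
#' g <- generateSweep(noiseCv = 0.05, seed = 7)
#' fitFKVM(g$sweep, cutoff = 50)
#' @export
generateSweep <- function(params = FKVMParams(2, 1.5, 0.70),
                          omegaRange = c(0.3, 300), nPoints = 30,
                          noiseCv = 0, seed = 1, label = "synthetic") {
  stopifnot(methods::is(params, "FKVMParams"), nPoints >= 3)
  w <- exp(seq(log(omegaRange[1]), log(omegaRange[2]),
               length.out = nPoints))
  m <- fkvmModuli(params, w)
  noise <- .with_seed(seed, .lognormal_noise(2 * nPoints, noiseCv))
  sweep <- OscillatorySweep(
    omega = w,
    gPrime = m$gPrime * noise[seq_len(nPoints)],
    gDoublePrime = m$gDoublePrime * noise[nPoints + seq_len(nPoints)],
    direction = "up", label = label)
  list(sweep = sweep,
       truth = list(params = params, noiseCv = noiseCv, seed = seed))
}

#' Generate a synthetic amplitude sweep with a known LVE region
#'
#' G' is flat at \code{plateauG} up to \code{criticalStrain} and then
#' decays as (strain/criticalStrain)^(-decayExponent); G'' follows the
#' same shape from \code{plateauGpp}.
#'
#' @param plateauG,plateauGpp plateau moduli, Pa.
#' @param criticalStrain end of the linear regime (fraction).
#' @param decayExponent post-critical power-law decay exponent.
#' @param strainRange strain range (fraction), log-spaced.
#' @param nPoints number of points.
#' @param noiseCv multiplicative noise CV.
#' @param seed integer seed.
#' @return A list: \code{sweep} (an \code{AmplitudeSweep}) and
#'   \code{truth}.
#' @export
generateAmplitudeSweep <- function(plateauG = 2, plateauGpp = 4,
                                   criticalStrain = 0.05,
                                   decayExponent = 1,
                                   strainRange = c(1e-4, 1), nPoints = 25,
                                   noiseCv = 0, seed = 1) {
  strain <- exp(seq(log(strainRange[1]), log(strainRange[2]),
                    length.out = nPoints))
  shape <- ifelse(strain <= criticalStrain, 1,
                  (strain / criticalStrain)^(-decayExponent))
  noise <- .with_seed(seed, .lognormal_noise(2 * nPoints, noiseCv))
  sweep <- AmplitudeSweep(strain = strain,
    gPrime = plateauG * shape * noise[seq_len(nPoints)],
    gDoublePrime = plateauGpp * shape * noise[nPoints + seq_len(nPoints)],
    frequency = 1)
  list(sweep = sweep,
       truth = list(plateauG = plateauG, criticalStrain = criticalStrain,
                    decayExponent = decayExponent, noiseCv = noiseCv,
                    seed = seed))
}

#' Generate a synthetic concentration series with known scaling exponents
#'
#' Per-dose FKVM parameters scale as dose^exponentG (both G and etaAlpha,
#' so every modulus scales exactly with that exponent while alpha stays
#' constant); the representative-point viscosity scales as
#' dose^exponentEta. The representative table reports G' and G'' at the
#' reference frequency (1 Hz) and viscosity at the reference shear rate
#' (1 1/s).
#'
#' @param doses dose grid, g/L (default 10, 20, 60, 100, 140).
#' @param exponentG moduli scaling exponent (default 2.0).
#' @param exponentEta viscosity scaling exponent (default 2.2).
#' @param alpha fractional order, constant across doses (default 0.70).
#' @param referenceDose dose at which the reference parameters apply.
#' @param referenceParams \code{FKVMParams} at the reference dose.
#' @param referenceViscosity viscosity at the reference dose and reference
#'   shear rate, Pa s.
#' @param omegaRange,nPoints sweep grid passed to
#'   \code{\link{generateSweep}}.
#' @param noiseCv multiplicative noise CV applied to sweeps and to the
#'   representative table.
#' @param seed integer seed.
#' @return A list: \code{series} (a \code{\link{SeriesTable}}),
#'   \code{sweeps} (list of per-dose \code{OscillatorySweep}s) and
#'   \code{truth} (per-dose parameters and the exponents).
#' @export
generateConcentrationSeries <- function(doses = c(10, 20, 60, 100, 140),
                                        exponentG = 2.0, exponentEta = 2.2,
                                        alpha = 0.70, referenceDose = 100,
                                        referenceParams =
                                          FKVMParams(2, 1.5, 0.70),
                                        referenceViscosity = 0.5,
                                        omegaRange = c(0.3, 300),
                                        nPoints = 30, noiseCv = 0,
                                        seed = 1) {
  stopifnot(all(diff(doses) > 0), all(doses > 0))
  scale_g <- (doses / referenceDose)^exponentG
  params <- lapply(scale_g, function(s)
    FKVMParams(referenceParams@G * s, referenceParams@etaAlpha * s, alpha))
  seeds <- .with_seed(seed,
                      sample.int(.Machine$integer.max, length(doses) + 1))
  gens <- Map(function(p, s, d)
    generateSweep(p, omegaRange, nPoints, noiseCv, seed = s,
                  label = sprintf("%g g/L", d)),
    params, seeds[-1], doses)
  w_ref <- 2 * pi  # 1 Hz
  rep_mod <- lapply(params, fkvmModuli, omega = w_ref)
  eta_ref <- referenceViscosity * (doses / referenceDose)^exponentEta
  noise <- .with_seed(seeds[1], .lognormal_noise(3 * length(doses), noiseCv))
  n <- length(doses)
  series <- SeriesTable(
    dose = doses,
    gPrime = vapply(rep_mod, `[[`, numeric(1), "gPrime") *
      noise[seq_len(n)],
    gDoublePrime = vapply(rep_mod, `[[`, numeric(1), "gDoublePrime") *
      noise[n + seq_len(n)],
    viscosity = eta_ref * noise[2 * n + seq_len(n)],
    doseUnit = "g/L", referenceFrequency = 1, referenceShearRate = 1)
  list(series = series,
       sweeps = lapply(gens, `[[`, "sweep"),
       truth = list(doses = doses, params = params,
                    exponentG = exponentG, exponentEta = exponentEta,
                    alpha = alpha, noiseCv = noiseCv, seed = seed))
}

#' Generate a synthetic Herschel-Bulkley flow curve
#'
#' Stress sigma = sigmaY + K * gammadot^n; viscosity eta = sigma/gammadot
#' carries the multiplicative noise and the stress is kept consistent with
#' the noisy viscosity.
#'
#' @param sigmaY yield stress, Pa (default 0.001, i.e. 1 mPa).
#' @param K consistency, Pa s^n (default 0.3).
#' @param n flow index in (0, 1] (default 0.75; eta then thins as
#'   gammadot^(n-1)).
#' @param shearRateRange 1/s (default 0.1 to 1000).
#' @param nPoints log-spaced points (default 30).
#' @param noiseCv multiplicative noise CV.
#' @param seed integer seed.
#' @return A list: \code{curve} (a \code{\link{FlowCurve}}) and
#'   \code{truth}.
#' @export
generateFlowCurve <- function(sigmaY = 0.001, K = 0.3, n = 0.75,
                              shearRateRange = c(0.1, 1000), nPoints = 30,
                              noiseCv = 0, seed = 1) {
  stopifnot(sigmaY >= 0, K > 0, n > 0, n <= 1)
  gd <- exp(seq(log(shearRateRange[1]), log(shearRateRange[2]),
                length.out = nPoints))
  sigma <- sigmaY + K * gd^n
  noise <- .with_seed(seed, .lognormal_noise(nPoints, noiseCv))
  eta <- sigma / gd * noise
  curve <- FlowCurve(shearRate = gd, viscosity = eta, direction = "up",
                     label = "synthetic")
  list(curve = curve,
       truth = list(sigmaY = sigmaY, K = K, n = n, noiseCv = noiseCv,
                    seed = seed))
}

#' Generate a synthetic porous-network phantom image
#'
#' Dark elliptical pores on a bright, optionally textured background.
#' Ellipses are placed by rejection sampling so that no two overlap
#' (bounding circles separated by \code{marginPx}) and none touches the
#' border. The ground-truth table stores each pore's exact Feret
#' diameters from the analytic ellipse parameters (min Feret = minor
#' axis, max Feret = major axis). Intensities are quantised to the 8-bit
#' grid so the image round-trips losslessly through PNG.
#'
#' @param sizePx image side length in pixels (square image, default 512).
#' @param nPores number of pores (default 40).
#' @param meanlogFeret,sdlogFeret lognormal parameters of the minimum
#'   Feret diameter in nm; defaults (log(35), 0.4) put most pores between
#'   10 and 80 nm.
#' @param nmPerPx calibration, nm per pixel (default 2, a typical
#'   high-magnification SEM scale).
#' @param aspectMax maximum ellipse aspect ratio (default 1.6).
#' @param poreIntensity,fiberIntensity intensities of the two classes.
#' @param textureSd Gaussian texture added to the background (default 0).
#' @param blurSigma optional Gaussian blur (pixels; 0 = none).
#' @param marginPx minimum gap between pore bounding circles and to the
#'   border (default 3).
#' @param maxTries rejection-sampling budget per pore.
#' @param seed integer seed.
#' @return A list: \code{image} (a \code{\link{CalibratedImage}}) and
#'   \code{truth} (data.frame with per-pore centre, axes, orientation and
#'   analytic Feret diameters in nm).
#' @export
generatePorePhantom <- function(sizePx = 512, nPores = 40,
                                meanlogFeret = log(35), sdlogFeret = 0.4,
                                nmPerPx = 2, aspectMax = 1.6,
                                poreIntensity = 0.15,
                                fiberIntensity = 0.85, textureSd = 0,
                                blurSigma = 0, marginPx = 3,
                                maxTries = 5000, seed = 1) {
  stopifnot(sizePx >= 32, nPores >= 1)
  res <- .with_seed(seed, {
    minf_nm <- stats::rlnorm(nPores, meanlogFeret, sdlogFeret)
    aspect <- stats::runif(nPores, 1, aspectMax)
    theta <- stats::runif(nPores, 0, pi)
    b_px <- minf_nm / 2 / nmPerPx           # semi-minor axis
    a_px <- b_px * aspect                    # semi-major axis
    ord <- order(a_px, decreasing = TRUE)    # place big pores first
    cx <- cy <- rep(NA_real_, nPores)
    for (i in ord) {
      r <- a_px[i] + marginPx
      if (1 + r >= sizePx - r)
        stop("placement error: pore density too high for the image size")
      placed <- FALSE
      for (k in seq_len(maxTries)) {
        x <- stats::runif(1, 1 + r, sizePx - r)
        y <- stats::runif(1, 1 + r, sizePx - r)
        ok <- TRUE
        done <- which(!is.na(cx))
        if (length(done)) {
          d <- sqrt((cx[done] - x)^2 + (cy[done] - y)^2)
          ok <- all(d > a_px[done] + a_px[i] + marginPx)
        }
        if (ok) { cx[i] <- x; cy[i] <- y; placed <- TRUE; break }
      }
      if (!placed)
        stop("placement error: pore density too high for the image size")
    }
    tex <- if (textureSd > 0)
      matrix(stats::rnorm(sizePx^2, 0, textureSd), sizePx, sizePx)
    else 0
    list(minf_nm = minf_nm, aspect = aspect, theta = theta, a_px = a_px,
         b_px = b_px, cx = cx, cy = cy, tex = tex)
  })
  px <- matrix(fiberIntensity, sizePx, sizePx) + res$tex
  rr <- matrix(seq_len(sizePx), sizePx, sizePx)        # row index (y)
  cc <- matrix(seq_len(sizePx), sizePx, sizePx, byrow = TRUE)
  for (i in seq_len(nPores)) {
    dx <- cc - res$cx[i]; dy <- rr - res$cy[i]
    u <- cos(res$theta[i]) * dx + sin(res$theta[i]) * dy
    v <- -sin(res$theta[i]) * dx + cos(res$theta[i]) * dy
    inside <- (u / res$a_px[i])^2 + (v / res$b_px[i])^2 <= 1
    px[inside] <- poreIntensity
  }
  img <- CalibratedImage(pmin(pmax(px, 0), 1), nmPerPx = nmPerPx,
                         label = sprintf("phantom seed %d", seed))
  if (blurSigma > 0) img <- gaussianSmooth(img, blurSigma)
  img@pixels <- round(img@pixels * 255) / 255   # 8-bit grid, lossless PNG
  truth <- data.frame(
    poreId = seq_len(nPores),
    centreRow = res$cy, centreCol = res$cx,
    semiMajor_px = res$a_px, semiMinor_px = res$b_px,
    theta = res$theta,
    minFeret_nm = 2 * res$b_px * nmPerPx,
    maxFeret_nm = 2 * res$a_px * nmPerPx,
    area_nm2 = pi * res$a_px * res$b_px * nmPerPx^2)
  list(image = img, truth = truth)
}

#' Write a generator's ground truth to JSON
#'
#' @param truth the \code{truth} element returned by a generator.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
  if (methods::is(truth, "data.frame")) truth <- as.list(truth)
  ser <- rapply(truth, function(x) {
    if (methods::is(x, "FKVMParams"))
      list(G = x@G, etaAlpha = x@etaAlpha, alpha = x@alpha)
    else x
  }, classes = "ANY", how = "replace")
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
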