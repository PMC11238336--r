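#' @include AllClasses.R
NULL

# Delimited-text readers and writers for rheometer exports. Vendor exports
# differ only in column names, frequency unit, separators and decimal mark,
# so a small column-mapping dialect is the single configuration mechanism.
# Internally every frequency is angular (rad/s); Hz is converted at the
# boundary via omega = 2 * pi * f.

#' Column-mapping dialect for rheometer text exports
#'
#' Describes how to interpret a delimited text export: which columns hold
#' which quantities, the frequency unit, and the separators. A dialect can
#' also be loaded from a YAML file with the same keys.
#'
#' @param frequency name of the frequency column.
#' @param gPrime name of the storage-modulus column (Pa).
#' @param gDoublePrime name of the loss-modulus column (Pa).
#' @param frequencyUnit \code{"Hz"} or \code{"rad/s"}.
#' @param strain optional strain-amplitude column (amplitude sweeps).
#' @param shearRate,viscosity optional columns for flow curves.
#' @param sep field separator (default comma).
#' @param dec decimal mark (default point).
#' @return A list of class \code{"sweepDialect"}.
#' @examples
#' d <- sweepDialect(frequency = "f_Hz", gPrime = "Gp", gDoublePrime = "Gpp")
#' @export
sweepDialect <- function(frequency = "frequency", gPrime = "g_prime",
                         gDoublePrime = "g_double_prime",
                         frequencyUnit = c("rad/s", "Hz"),
                         strain = "strain", shearRate = "shear_rate",
                         viscosity = "viscosity", sep = ",", dec = ".") {
  frequencyUnit <- match.arg(frequencyUnit)
  structure(list(frequency = frequency, gPrime = gPrime,
                 gDoublePrime = gDoublePrime, frequencyUnit = frequencyUnit,
                 strain = strain, shearRate = shearRate,
                 viscosity = viscosity, sep = sep, dec = dec),
            class = "sweepDialect")
}

#' Read a dialect definition from a YAML file
#'
#' @param path YAML file with any of the \code{\link{sweepDialect}} keys.
#' @return A \code{sweepDialect}.
#' @export
readDialect <- function(path) {
  if (!file.exists(path)) stop("dialect file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sweepDialect))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown dialect keys: ", paste(bad, collapse = ", "))
  do.call(sweepDialect, cfg)
}

.read_table <- function(path, dialect) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = dialect$sep,
                    dec = dialect$dec, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

.require_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop("format error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
}

#' Read an oscillatory frequency sweep from delimited text
#'
#' Loads a header-row CSV/TSV export, maps columns through the dialect,
#' converts Hz to rad/s (omega = 2 pi f) where declared, drops rows with
#' non-positive or non-finite moduli with a warning, and returns a
#' validated \code{\link{OscillatorySweep}}. The frequency grid is sorted
#' to match the declared direction.
#'
#' @param path file path.
#' @param dialect a \code{\link{sweepDialect}} (or path to a dialect YAML).
#' @param direction sweep direction recorded in the object.
#' @param strainAmplitude strain amplitude (fraction) recorded.
#' @param label sample label; defaults to the file name.
#' @return An \code{OscillatorySweep}.
#' @export
readSweep <- function(path, dialect = sweepDialect(),
                      direction = c("unspecified", "up", "down"),
                      strainAmplitude = 0.01, label = basename(path)) {
  direction <- match.arg(direction)
  if (is.character(dialect)) dialect <- readDialect(dialect)
  tab <- .read_table(path, dialect)
  .require_columns(tab, c(dialect$frequency, dialect$gPrime,
                          dialect$gDoublePrime), path)
  f <- as.numeric(tab[[dialect$frequency]])
  gp <- as.numeric(tab[[dialect$gPrime]])
  gpp <- as.numeric(tab[[dialect$gDoublePrime]])
  w <- if (dialect$frequencyUnit == "Hz") 2 * pi * f else f
  keep <- is.finite(w) & w > 0 & is.finite(gp) & gp > 0 &
    is.finite(gpp) & gpp > 0
  if (any(!keep))
    warning(sum(!keep), " row(s) with non-positive or non-finite values ",
            "dropped from ", path)
  if (sum(keep) < 3L)
    stop("data error: fewer than 3 valid rows in ", path)
  ord <- order(w[keep], decreasing = (direction == "down"))
  OscillatorySweep(omega = w[keep][ord], gPrime = gp[keep][ord],
                   gDoublePrime = gpp[keep][ord],
                   strainAmplitude = strainAmplitude,
                   direction = direction, label = label)
}

#' Write an oscillatory sweep to CSV
#'
#' The written file round-trips through \code{\link{readSweep}} with the
#' default dialect (rad/s), reproducing the arrays bit-identically: values
#' are serialised at full double precision.
#'
#' @param sweep an \code{OscillatorySweep}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSweep <- function(sweep, path) {
  stopifnot(methods::is(sweep, "OscillatorySweep"))
  methods::validObject(sweep)
  tab <- data.frame(
    frequency = sweep@omega,
    g_prime = sweep@gPrime,
    g_double_prime = sweep@gDoublePrime)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# label: ", sweep@label), con)
  writeLines(paste0("# strain_amplitude: ",
                    format(sweep@strainAmplitude, digits = 17)), con)
  writeLines(paste0("# direction: ", sweep@direction), con)
  writeLines("frequency,g_prime,g_double_prime", con)
  writeLines(paste(format(tab$frequency, digits = 17, trim = TRUE),
                   format(tab$g_prime, digits = 17, trim = TRUE),
                   format(tab$g_double_prime, digits = 17, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' Read back a sweep written by writeSweep
#'
#' Restores the label, strain amplitude and direction stored in the header
#' comments, then parses the table with the default dialect.
#'
#' @param path file written by \code{\link{writeSweep}}.
#' @return An \code{OscillatorySweep}.
#' @export
readSweepFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default) {
    hit <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[1]) else default
  }
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  writeLines(lines[!grepl("^#", lines)], tmp)
  readSweep(tmp, sweepDialect(frequency = "frequency"),
            direction = meta("direction", "unspecified"),
            strainAmplitude = as.numeric(meta("strain_amplitude", "0.01")),
            label = meta("label", basename(path)))
}

#' Combine up- and down-direction frequency sweeps
#'
#' The two sweeps of a bidirectional protocol are combined pointwise by the
#' geometric mean (moduli are analysed on log scales). The maximum relative
#' discrepancy between the two passes is reported and a hysteresis flag is
#' set when it exceeds \code{rtol}.
#'
#' @param up,down \code{OscillatorySweep}s on the same frequency grid
#'   (after sorting; grids must agree within \code{gridRtol} relative).
#' @param rtol relative discrepancy above which hysteresis is flagged.
#' @param gridRtol relative tolerance for frequency-grid agreement.
#' @return An \code{OscillatorySweep} (direction \code{"unspecified"}) with
#'   attributes \code{maxDiscrepancy} (max relative modulus discrepancy)
#'   and \code{hysteresis} (logical).
#' @export
mergeUpDown <- function(up, down, rtol = 0.1, gridRtol = 1e-6) {
  stopifnot(methods::is(up, "OscillatorySweep"),
            methods::is(down, "OscillatorySweep"))
  if (length(up@omega) != length(down@omega))
    stop("alignment error: sweeps have different lengths")
  ou <- order(up@omega); od <- order(down@omega)
  wu <- up@omega[ou]; wd <- down@omega[od]
  if (any(abs(wu - wd) / wu > gridRtol))
    stop("alignment error: frequency grids do not match")
  gp_u <- up@gPrime[ou]; gp_d <- down@gPrime[od]
  gpp_u <- up@gDoublePrime[ou]; gpp_d <- down@gDoublePrime[od]
  disc <- max(abs(gp_u - gp_d) / pmin(gp_u, gp_d),
              abs(gpp_u - gpp_d) / pmin(gpp_u, gpp_d))
  merged <- OscillatorySweep(
    omega = wu,
    gPrime = sqrt(gp_u * gp_d),
    gDoublePrime = sqrt(gpp_u * gpp_d),
    strainAmplitude = up@strainAmplitude,
    direction = "unspecified",
    label = up@label)
  attr(merged, "maxDiscrepancy") <- disc
  attr(merged, "hysteresis") <- disc > rtol
  merged
}

#' Read an amplitude sweep from delimited text
#'
#' @param path file path; needs strain, G' and G'' columns per the dialect.
#' @param dialect a \code{\link{sweepDialect}}; the \code{strain} entry
#'   names the strain-amplitude column (fraction).
#' @param frequency the constant oscillation frequency, Hz.
#' @param label sample label.
#' @return An \code{\link{AmplitudeSweep}}.
#' @export
readAmplitudeSweep <- function(path, dialect = sweepDialect(),
                               frequency = 1, label = basename(path)) {
  if (is.character(dialect)) dialect <- readDialect(dialect)
  tab <- .read_table(path, dialect)
  .require_columns(tab, c(dialect$strain, dialect$gPrime,
                          dialect$gDoublePrime), path)
  AmplitudeSweep(strain = as.numeric(tab[[dialect$strain]]),
                 gPrime = as.numeric(tab[[dialect$gPrime]]),
                 gDoublePrime = as.numeric(tab[[dialect$gDoublePrime]]),
                 frequency = frequency, label = label)
}

#' Read a steady-shear flow curve from delimited text
#'
#' @param path file path; needs shear-rate and viscosity columns per the
#'   dialect. Stress is derived as viscosity times shear rate.
#' @param dialect a \code{\link{sweepDialect}}.
#' @param direction sweep direction.
#' @param label sample label.
#' @return A \code{\link{FlowCurve}}.
#' @export
readFlowCurve <- function(path, dialect = sweepDialect(),
                          direction = c("unspecified", "up", "down"),
                          label = basename(path)) {
  direction <- match.arg(direction)
  if (is.character(dialect)) dialect <- readDialect(dialect)
  tab <- .read_table(path, dialect)
  .require_columns(tab, c(dialect$shearRate, dialect$viscosity), path)
  gd <- as.numeric(tab[[dialect$shearRate]])
  eta <- as.numeric(tab[[dialect$viscosity]])
  keep <- is.finite(gd) & gd > 0 & is.finite(eta) & eta > 0
  if (any(!keep))
    warning(sum(!keep), " invalid row(s) dropped from ", path)
  FlowCurve(shearRate = gd[keep], viscosity = eta[keep],
            direction = direction, label = label)
}

#' Write a flow curve to CSV
#'
#' @param curve a \code{FlowCurve}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFlowCurve <- function(curve, path) {
  stopifnot(methods::is(curve, "FlowCurve"))
  utils::write.csv(data.frame(shear_rate = curve@shearRate,
                              viscosity = curve@viscosity,
                              stress = curve@stress),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
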