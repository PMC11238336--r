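#' @include AllClasses.R
NULL

# Quantitative pore analysis of calibrated grayscale micrographs:
# Gaussian smoothing, Otsu binarisation (dark pixels = pores, bright =
# fiber network), edge-excluded connected-component labelling, Feret
# diameters from the convex hull of pixel corner points, and distribution
# summaries of the minimum Feret diameter.

#' Read a grayscale micrograph with physical calibration
#'
#' Reads a PNG or TIFF image; multi-channel images are converted to
#' grayscale by channel averaging. Intensities are returned in [0, 1].
#'
#' @param path image file (.png, .tif or .tiff).
#' @param nmPerPx physical pixel size, nm per pixel; must be supplied
#'   explicitly (magnification-to-scale mapping is instrument-specific).
#' @param label free-text label; defaults to the file name.
#' @return A \code{\link{CalibratedImage}}.
#' @export
readMicrograph <- function(path, nmPerPx, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  CalibratedImage(px, nmPerPx = nmPerPx, label = label)
}

#' Write a calibrated image to PNG or TIFF
#'
#' Intensities are clipped to [0, 1]. PNG output is 8-bit; TIFF output is
#' 8-bit as well so that the two formats hold identical data.
#'
#' @param img a \code{CalibratedImage}.
#' @param path output path (.png, .tif or .tiff).
#' @return \code{path}, invisibly.
#' @export
writeMicrograph <- function(img, path) {
  stopifnot(methods::is(img, "CalibratedImage"))
  px <- pmin(pmax(img@pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Gaussian smoothing of a calibrated image
#'
#' Convolution with a normalised, truncated sampled Gaussian kernel
#' (radius 4 sigma) under reflective boundary handling, which conserves
#' total intensity to well under 0.1 percent.
#'
#' @param img a \code{\link{CalibratedImage}}.
#' @param sigma kernel standard deviation in pixels (default 1).
#' @return A smoothed \code{CalibratedImage} of identical dimensions.
#' @export
gaussianSmooth <- function(img, sigma = 1) {
  stopifnot(methods::is(img, "CalibratedImage"))
  if (sigma <= 0) stop("sigma must be > 0")
  r <- ceiling(4 * sigma)
  g <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k <- k / sum(k)
  px <- img@pixels
  nr <- nrow(px); nc <- ncol(px)
  # reflective padding, then convolve and crop the interior
  ri <- c(rev(seq_len(min(r, nr))), seq_len(nr),
          nr + 1 - seq_len(min(r, nr)))
  ci <- c(rev(seq_len(min(r, nc))), seq_len(nc),
          nc + 1 - seq_len(min(r, nc)))
  pad <- px[ri, ci, drop = FALSE]
  sm <- EBImage::filter2(pad, k, boundary = "replicate")
  out <- sm[r + seq_len(nr), r + seq_len(nc), drop = FALSE]
  CalibratedImage(out, nmPerPx = img@nmPerPx, label = img@label)
}

#' Otsu threshold of a calibrated image
#'
#' Builds an \code{nBins}-bin equal-width histogram over the intensity
#' range and returns the bin-edge threshold maximising the between-class
#' variance. Pixels at or below the threshold form the pore (dark) class;
#' pixels above it the fiber (bright) class.
#'
#' @param img a \code{\link{CalibratedImage}} (or a numeric matrix).
#' @param nBins number of histogram bins (default 256).
#' @return The threshold intensity (a bin edge), with attribute
#'   \code{betweenClassVariance}.
#' @export
otsuThreshold <- function(img, nBins = 256) {
  px <- if (methods::is(img, "CalibratedImage")) img@pixels else img
  v <- as.numeric(px)
  rng <- range(v)
  if (diff(rng) == 0)
    stop("degenerate histogram: image has a single intensity")
  edges <- seq(rng[1], rng[2], length.out = nBins + 1)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                     nBins), nbins = nBins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(nBins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[nBins]
  # between-class variance for splitting after bin k (k = 1..nBins-1)
  k <- seq_len(nBins - 1)
  w0k <- w0[k]; w1k <- 1 - w0k
  valid <- w0k > 0 & w1k > 0
  sb <- rep(-Inf, nBins - 1)
  sb[valid] <- (muT * w0k[valid] - mu[k][valid])^2 /
    (w0k[valid] * w1k[valid])
  kstar <- which.max(sb)
  thr <- edges[kstar + 1]
  attr(thr, "betweenClassVariance") <- sb[kstar]
  thr
}

#' Binarise a micrograph into pore and fiber classes
#'
#' @param img a \code{CalibratedImage}.
#' @param threshold intensity threshold; defaults to
#'   \code{\link{otsuThreshold}}.
#' @param invert set \code{TRUE} when pores are bright rather than dark.
#' @return Logical matrix, \code{TRUE} for pore pixels.
#' @export
binarizePores <- function(img, threshold = otsuThreshold(img),
                          invert = FALSE) {
  stopifnot(methods::is(img, "CalibratedImage"))
  m <- img@pixels <= threshold
  if (invert) m <- !m
  m
}

# 8-connectivity labelling: EBImage::bwlabel gives 4-connected components;
# diagonal-touching label pairs are then merged with a small union-find
# over the label set (vectorised neighbour detection).
.label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  if (connectivity == 4 || max(lab) < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]    # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(max(lab))
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]  # path halving
        i <- parent[i]
      }
      i
    }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_along(parent), find, 1L)
    dense <- match(roots, sort(unique(roots)))
    lab[lab > 0L] <- dense[lab[lab > 0L]]
  }
  lab
}

#' Label pore components in a binary mask
#'
#' Connected-component labelling of the pore class (8-connectivity by
#' default), flagging components that touch the image border and
#' discarding components below a minimum pixel area.
#'
#' @param mask logical matrix, \code{TRUE} for pore pixels.
#' @param minAreaPx minimum component area in pixels (default 4); smaller
#'   components are discarded as noise (a size floor standing in for
#'   manual verification).
#' @param connectivity 8 (default) or 4.
#' @return A list: \code{labels} (integer matrix, 0 = background) and
#'   \code{components}, a data.frame with \code{poreId}, \code{area_px},
#'   \code{touchesEdge}, \code{centroidRow}, \code{centroidCol}.
#' @export
labelPores <- function(mask, minAreaPx = 4, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!is.logical(mask)) mask <- mask > 0
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- .label_components(mask, connectivity)
  nlab <- max(lab)
  if (nlab == 0L)
    return(list(labels = lab,
                components = data.frame(poreId = integer(0),
                  area_px = integer(0), touchesEdge = logical(0),
                  centroidRow = numeric(0), centroidCol = numeric(0))))
  idx <- which(lab > 0L)
  ids <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tabulate(ids, nbins = nlab)
  edge <- rows == 1L | rows == nrow(lab) | cols == 1L | cols == ncol(lab)
  touches <- as.logical(tabulate(ids[edge], nbins = nlab) > 0)
  cr <- tapply(rows, ids, mean)
  cc <- tapply(cols, ids, mean)
  keep <- which(area >= minAreaPx)
  # drop sub-floor components from the label image too
  if (length(keep) < nlab) {
    drop_mask <- !(lab %in% keep) & lab > 0L
    lab[drop_mask] <- 0L
  }
  relab <- match(lab, c(0L, keep)) - 1L
  lab <- matrix(as.integer(relab), nrow(mask), ncol(mask))
  list(labels = lab,
       components = data.frame(
         poreId = seq_along(keep),
         area_px = area[keep],
         touchesEdge = touches[keep],
         centroidRow = as.numeric(cr[as.character(keep)]),
         centroidCol = as.numeric(cc[as.character(keep)])))
}

# Feret diameters of one component. Pixels are treated as unit squares:
# the convex hull is taken over the four corner points of every pixel, so
# an axis-aligned s x s square has min Feret exactly s and max Feret
# exactly s * sqrt(2).
.feret_px <- function(rows, cols) {
  pts <- unique(cbind(
    x = c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5),
    y = c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh == 1L) return(c(0, 0))
  d2 <- as.matrix(stats::dist(hp))
  max_f <- max(d2)
  # rotating calipers: the minimum width is attained with one hull edge
  # flush against a supporting line
  min_f <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hp[j, 1] - hp[i, 1]; ey <- hp[j, 2] - hp[i, 2]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    # distance of all hull points from the line through edge (i, j)
    w <- max(abs((hp[, 1] - hp[i, 1]) * ey - (hp[, 2] - hp[i, 2]) * ex)) / len
    if (w < min_f) min_f <- w
  }
  if (!is.finite(min_f)) min_f <- 0
  c(min_f, max_f)
}

#' Feret diameters of a pixel component
#'
#' Minimum and maximum Feret diameter of a set of pixels, computed on the
#' convex hull of the pixel corner points (each pixel a unit square): the
#' maximum Feret is the hull diameter, the minimum Feret the smallest
#' width over all orientations (rotating calipers).
#'
#' @param rows,cols integer pixel coordinates of the component.
#' @param nmPerPx physical pixel size; both outputs are scaled by it.
#' @return Named numeric: \code{minFeret} and \code{maxFeret} (nm).
#' @export
feretDiameters <- function(rows, cols, nmPerPx = 1) {
  stopifnot(length(rows) == length(cols), length(rows) >= 1L)
  f <- unname(.feret_px(as.numeric(rows), as.numeric(cols))) * nmPerPx
  c(minFeret = f[1], maxFeret = f[2])
}

#' Summary statistics of a pore table
#'
#' Mean, sd, median and quartiles of the minimum Feret diameter over
#' non-edge pores only. The sd of a single pore is undefined and reported
#' as \code{NA}.
#'
#' @param table a \code{\link{PoreTable}}.
#' @return A \code{\link{PoreStats}}.
#' @export
poreStatistics <- function(table) {
  stopifnot(methods::is(table, "PoreTable"))
  p <- table@pores[!table@pores$touchesEdge, , drop = FALSE]
  if (nrow(p) == 0L)
    stop(structure(class = c("fracRheo_empty_stats", "error", "condition"),
                   list(message = "empty-stats error: no non-edge pores",
                        call = sys.call(-1))))
  mf <- p$minFeret_nm
  q <- stats::quantile(mf, c(0.25, 0.5, 0.75), names = FALSE)
  methods::new("PoreStats",
    nPores = nrow(p),
    mean = mean(mf),
    sd = if (nrow(p) > 1L) stats::sd(mf) else NA_real_,
    median = q[2], q25 = q[1], q75 = q[3],
    label = table@label)
}

#' Full pore-morphometry pipeline on one micrograph
#'
#' Composition smooth -> Otsu threshold -> label -> Feret -> statistics.
#' A run manifest recording every parameter is attached to the result.
#'
#' @param img a \code{\link{CalibratedImage}}.
#' @param sigma Gaussian smoothing sigma in pixels (default 1).
#' @param nBins histogram bins for the Otsu threshold (default 256).
#' @param minAreaPx minimum pore area in pixels (default 4).
#' @param connectivity 8 (default) or 4.
#' @param invert \code{TRUE} when pores are bright.
#' @return A list with elements \code{table} (a \code{PoreTable} including
#'   edge-touching pores, flagged), \code{stats} (a \code{PoreStats} over
#'   non-edge pores), \code{threshold} and \code{manifest}.
#' @export
analyzeMicrograph <- function(img, sigma = 1, nBins = 256, minAreaPx = 4,
                              connectivity = 8, invert = FALSE) {
  stopifnot(methods::is(img, "CalibratedImage"))
  sm <- gaussianSmooth(img, sigma = sigma)
  thr <- otsuThreshold(sm, nBins = nBins)
  mask <- binarizePores(sm, threshold = thr, invert = invert)
  lp <- labelPores(mask, minAreaPx = minAreaPx, connectivity = connectivity)
  comp <- lp$components
  nmpp <- img@nmPerPx
  if (nrow(comp)) {
    fer <- t(vapply(comp$poreId, function(id) {
      idx <- which(lp$labels == id)
      r <- (idx - 1L) %% nrow(lp$labels) + 1L
      cc <- (idx - 1L) %/% nrow(lp$labels) + 1L
      .feret_px(as.numeric(r), as.numeric(cc))
    }, numeric(2)))
    pores <- data.frame(
      poreId = comp$poreId,
      area_nm2 = comp$area_px * nmpp^2,
      minFeret_nm = fer[, 1] * nmpp,
      maxFeret_nm = fer[, 2] * nmpp,
      touchesEdge = comp$touchesEdge,
      centroidRow = comp$centroidRow,
      centroidCol = comp$centroidCol)
  } else {
    pores <- data.frame(poreId = integer(0), area_nm2 = numeric(0),
                        minFeret_nm = numeric(0), maxFeret_nm = numeric(0),
                        touchesEdge = logical(0), centroidRow = numeric(0),
                        centroidCol = numeric(0))
  }
  table <- methods::new("PoreTable", pores = pores, nmPerPx = nmpp,
                        label = img@label)
  stats <- poreStatistics(table)  # errors cleanly when no non-edge pores
  list(table = table, stats = stats, threshold = as.numeric(thr),
       manifest = list(sigma = sigma, nBins = nBins, minAreaPx = minAreaPx,
                       connectivity = connectivity, invert = invert,
                       nmPerPx = nmpp, label = img@label))
}

#' Write a pore table to CSV
#'
#' @param table a \code{PoreTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePoreTable <- function(table, path) {
  stopifnot(methods::is(table, "PoreTable"))
  utils::write.csv(table@pores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
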