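# Independent oracles used across the suite. Each one recomputes a
# quantity by a route disjoint from the package implementation (complex
# arithmetic, dense enumeration, direct convolution) on problem sizes
# small enough to be exact.

# FKVM moduli via complex arithmetic: G* = G + eta * (i w)^alpha with the
# principal branch of the complex power.
oracle_fkvm <- function(G, eta, alpha, w) {
  gstar <- G + eta * complex(modulus = w^alpha,
                             argument = alpha * pi / 2)
  list(gPrime = Re(gstar), gDoublePrime = Im(gstar))
}

# Feret diameters of a point cloud by dense projection: width and extent
# at every angle on a uniform grid (degrees). The width function of a
# convex set has kinks where the supporting vertex changes, and its
# minimum sits exactly at such a kink (flush-edge orientation), so a
# uniform grid alone converges only first-order there; the candidate set
# is therefore augmented with the flush-edge normal angles, computed here
# from base R's convex hull, independent of the package's calipers code.
oracle_feret <- function(pts, step_deg = 0.01) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  h <- grDevices::chull(pts)
  hp <- pts[c(h, h[1]), , drop = FALSE]
  edge_th <- atan2(diff(hp[, 2]), diff(hp[, 1])) + pi / 2  # edge normals
  th <- c(th, edge_th %% pi)
  u <- cbind(cos(th), sin(th))
  proj <- pts %*% t(u)                      # n x length(th)
  cols <- as.data.frame(t(proj))            # one column per point
  widths <- do.call(pmax, cols) - do.call(pmin, cols)
  c(min = min(widths), max = max(widths))
}

# corner-point cloud of a pixel set (the package's pixel-square convention)
corner_cloud <- function(rows, cols) {
  unique(cbind(x = c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5),
               y = c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)))
}

# Otsu by brute force: for every candidate bin edge, split the raw pixel
# values and compute the between-class variance directly.
oracle_otsu <- function(v, nBins = 256) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = nBins + 1)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), nBins)
  centers <- (edges[-1] + edges[-(nBins + 1)]) / 2
  vb <- centers[bin]                        # bin-centre representation
  best <- -Inf; best_thr <- NA_real_
  for (k in seq_len(nBins - 1)) {
    lo <- bin <= k; hi <- !lo
    if (!any(lo) || !any(hi)) next
    w0 <- mean(lo); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(vb[lo]) - mean(vb[hi]))^2
    if (sb > best) { best <- sb; best_thr <- edges[k + 1] }
  }
  best_thr
}

# dense 2-D convolution with reflective padding, direct quadruple loop
# (tiny images only)
oracle_convolve <- function(img, kernel) {
  r <- (nrow(kernel) - 1) / 2
  n <- nrow(img); m <- ncol(img)
  reflect <- function(i, n) {
    # reflect indices about the borders (no repeated edge sample beyond
    # one mirror; matches [rev(1:r), 1:n, n:(n-r+1)] padding)
    ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- reflect(i + di, n); jj <- reflect(j + dj, m)
      acc <- acc + img[ii, jj] * kernel[di + r + 1, dj + r + 1]
    }
    out[i, j] <- acc
  }
  out
}

# a noiseless sweep from known parameters on a log grid
make_sweep <- function(G = 2, eta = 1.5, alpha = 0.7, lo = 0.3, hi = 45,
                       n = 30, label = "fixture") {
  w <- exp(seq(log(lo), log(hi), length.out = n))
  m <- fkvmModuli(FKVMParams(G, eta, alpha), w)
  OscillatorySweep(w, m$gPrime, m$gDoublePrime, label = label)
}

# random convex-position point set: points on an ellipse boundary
random_convex_points <- function(n, rmax = 50) {
  a <- runif(1, 5, rmax); b <- runif(1, 2, a)
  phi <- runif(1, 0, pi)
  t <- sort(runif(n, 0, 2 * pi))
  x <- a * cos(t); y <- b * sin(t)
  cbind(x = cos(phi) * x - sin(phi) * y,
        y = sin(phi) * x + cos(phi) * y)
}
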