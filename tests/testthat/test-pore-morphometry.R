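# Smoothing, Otsu binarisation, labelling, Feret geometry, statistics.

make_img <- function(px, nmPerPx = 1, label = "test") {
  CalibratedImage(px, nmPerPx = nmPerPx, label = label)
}

test_that("Gaussian smoothing fixes constant images and conserves intensity", {
  const <- make_img(matrix(0.5, 32, 32))
  sm <- gaussianSmooth(const, sigma = 1)
  expect_equal(imagePixels(sm), imagePixels(const), tolerance = 1e-12)
  set.seed(51)
  noisy <- make_img(matrix(runif(48 * 40), 48, 40))
  sm2 <- gaussianSmooth(noisy, sigma = 1)
  expect_lt(abs(sum(imagePixels(sm2)) / sum(imagePixels(noisy)) - 1),
            0.001)
  expect_equal(dim(imagePixels(sm2)), c(48, 40))
})

test_that("a point source reproduces the sampled Gaussian kernel", {
  px <- matrix(0, 21, 21); px[11, 11] <- 1
  sm <- imagePixels(gaussianSmooth(make_img(px), sigma = 1))
  # centre-to-neighbour ratio = exp(0)/exp(-1/2)
  expect_equal(sm[11, 11] / sm[11, 12], exp(0.5), tolerance = 1e-10)
  expect_equal(sm[11, 11] / sm[10, 11], exp(0.5), tolerance = 1e-10)
  # direct dense-convolution oracle
  r <- ceiling(4)
  g <- dnorm(-r:r); k <- outer(g, g); k <- k / sum(k)
  expect_equal(sm, oracle_convolve(px, k), tolerance = 1e-10)
})

test_that("smoothing twice with sigma 1 approximates sigma sqrt(2) once", {
  set.seed(52)
  img <- make_img(matrix(runif(40 * 40), 40, 40))
  twice <- gaussianSmooth(gaussianSmooth(img, 1), 1)
  once <- gaussianSmooth(img, sqrt(2))
  rel <- abs(imagePixels(twice) - imagePixels(once)) /
    mean(imagePixels(once))
  expect_lt(max(rel), 0.01)
})

test_that("Otsu threshold separates a two-valued image", {
  px <- matrix(c(rep(50, 200), rep(200, 200)) / 255, 20, 20)
  thr <- otsuThreshold(make_img(px))
  expect_gte(thr, 50 / 255)
  expect_lt(thr, 200 / 255)
  expect_true(any(px <= thr) && any(px > thr))
  expect_error(otsuThreshold(make_img(matrix(0.5, 20, 20))),
               "degenerate")
})

test_that("Otsu equals the exhaustive between-class-variance argmax", {
  set.seed(53)
  for (i in 1:25) {
    n <- 400
    v <- c(rnorm(n, 60, 10), rnorm(n, 180, 10)) / 255
    px <- matrix(v, 40, 20)
    thr <- otsuThreshold(make_img(px))
    expect_equal(as.numeric(thr), oracle_otsu(as.numeric(px)),
                 tolerance = 1e-12)
  }
})

test_that("Otsu agrees with an independent library implementation", {
  # thresholds may differ inside an empty histogram gap (the argmax is
  # non-unique there), so compare the achieved between-class variance of
  # the induced partitions, which is the quantity Otsu maximises
  set.seed(54)
  bcv <- function(v, t) {
    lo <- v <= t
    mean(lo) * mean(!lo) * (mean(v[lo]) - mean(v[!lo]))^2
  }
  for (i in 1:10) {
    v <- c(rnorm(500, 60, 12), rnorm(500, 180, 12)) / 255
    v <- pmin(pmax(v, 0), 1)
    px <- matrix(v, 50, 20)
    thr <- otsuThreshold(make_img(px))
    ref <- EBImage::otsu(px, range = range(px), levels = 256)
    expect_equal(bcv(v, as.numeric(thr)), bcv(v, ref), tolerance = 1e-9)
  }
})

test_that("labelling counts interior pores and flags edge contact", {
  m <- matrix(FALSE, 20, 20)
  m[3:5, 3:5] <- TRUE
  m[10:12, 14:16] <- TRUE
  lp <- labelPores(m)
  expect_equal(nrow(lp$components), 2L)
  expect_false(any(lp$components$touchesEdge))
  # touch the left border
  m2 <- matrix(FALSE, 20, 20)
  m2[8:10, 1:3] <- TRUE
  lp2 <- labelPores(m2)
  expect_equal(nrow(lp2$components), 1L)
  expect_true(lp2$components$touchesEdge)
})

test_that("connectivity convention decides diagonal chains", {
  m <- matrix(FALSE, 12, 12)
  for (i in 3:8) m[i, i] <- TRUE          # diagonal chain of single px
  lp8 <- labelPores(m, minAreaPx = 1, connectivity = 8)
  lp4 <- labelPores(m, minAreaPx = 1, connectivity = 4)
  expect_equal(nrow(lp8$components), 1L)
  expect_equal(nrow(lp4$components), 6L)
})

test_that("the minimum-area floor removes speckle", {
  m <- matrix(FALSE, 16, 16)
  m[4, 4] <- TRUE                          # 1 px speckle
  m[8:11, 8:11] <- TRUE                    # 16 px pore
  lp <- labelPores(m, minAreaPx = 4)
  expect_equal(nrow(lp$components), 1L)
  expect_equal(lp$components$area_px, 16L)
  expect_equal(max(lp$labels), 1L)
  # empty mask is not an error
  expect_equal(nrow(labelPores(matrix(FALSE, 8, 8))$components), 0L)
})

test_that("Feret diameters of squares and disks follow closed forms", {
  # axis-aligned s x s pixel square, corner-point convention
  for (s in c(1, 3, 7)) {
    idx <- expand.grid(r = 1:s, c = 1:s)
    f <- feretDiameters(idx$r, idx$c)
    expect_equal(unname(f["minFeret"]), s, tolerance = 1e-12)
    expect_equal(unname(f["maxFeret"]), s * sqrt(2), tolerance = 1e-12)
  }
  # digital disk of radius r: both Ferets near 2r (corner convention can
  # add up to sqrt(2) px along the diagonals)
  r <- 9
  grid <- expand.grid(r = -15:15, c = -15:15)
  disk <- grid[grid$r^2 + grid$c^2 <= r^2, ]
  f <- feretDiameters(disk$r, disk$c)
  expect_gte(f[["minFeret"]], 2 * r)
  expect_lt(f[["minFeret"]], 2 * r + sqrt(2))
  expect_gte(f[["maxFeret"]], 2 * r)
  expect_lt(f[["maxFeret"]], 2 * r + sqrt(2))
  expect_lte(f[["minFeret"]], f[["maxFeret"]])
})

test_that("min Feret matches the dense-angle projection oracle", {
  set.seed(55)
  for (i in 1:40) {
    npx <- sample(5:40, 1)
    rows <- sample(1:30, npx, replace = TRUE)
    cols <- sample(1:30, npx, replace = TRUE)
    f <- feretDiameters(rows, cols)
    o <- oracle_feret(corner_cloud(rows, cols))
    expect_equal(unname(f["minFeret"]), unname(o["min"]),
                 tolerance = 1e-6)
    expect_equal(unname(f["maxFeret"]), unname(o["max"]),
                 tolerance = 1e-6)
  }
})

test_that("Feret diameters are invariant under translation and rotation", {
  set.seed(56)
  rows <- sample(2:12, 20, replace = TRUE)
  cols <- sample(2:12, 20, replace = TRUE)
  f0 <- feretDiameters(rows, cols)
  expect_equal(feretDiameters(rows + 7, cols + 3), f0, tolerance = 1e-12)
  # 90 degree rotation swaps rows and columns
  expect_equal(feretDiameters(cols, max(rows) + 1 - rows), f0,
               tolerance = 1e-12)
  # nm scaling is exact
  expect_equal(feretDiameters(rows, cols, nmPerPx = 2.5), f0 * 2.5,
               tolerance = 1e-12)
})

test_that("pore statistics use n-1 sd and refuse empty populations", {
  pores <- data.frame(poreId = 1:3, area_nm2 = c(100, 200, 300),
                      minFeret_nm = c(10, 20, 30),
                      maxFeret_nm = c(12, 25, 33),
                      touchesEdge = FALSE, centroidRow = 1:3,
                      centroidCol = 1:3)
  tab <- new("PoreTable", pores = pores, nmPerPx = 1, label = "x")
  s <- poreStatistics(tab)
  expect_equal(s@mean, 20)
  expect_equal(s@median, 20)
  expect_equal(s@sd, 10)
  # single pore: sd undefined, reported NA
  tab1 <- new("PoreTable", pores = pores[1, ], nmPerPx = 1, label = "x")
  expect_true(is.na(poreStatistics(tab1)@sd))
  # all-edge population is an error
  pores$touchesEdge <- TRUE
  tabe <- new("PoreTable", pores = pores, nmPerPx = 1, label = "x")
  expect_error(poreStatistics(tabe), class = "fracRheo_empty_stats")
})

test_that("edge pores are excluded from statistics", {
  m <- matrix(FALSE, 24, 24)
  m[1:4, 10:13] <- TRUE     # touches top edge
  m[10:13, 10:13] <- TRUE   # interior
  lp <- labelPores(m)
  expect_equal(sum(lp$components$touchesEdge), 1L)
  # a frame of pore pixels merges border-adjacent pores into one
  # edge-touching component, removing them all from the statistics
  framed <- matrix(FALSE, 24, 24)
  framed[2:5, 10:13] <- TRUE                 # adjacent to the frame
  framed[10:13, 2:5] <- TRUE                 # adjacent to the frame
  framed[c(1, 24), ] <- TRUE; framed[, c(1, 24)] <- TRUE
  lpf <- labelPores(framed)
  expect_true(all(lpf$components$touchesEdge))
  tabf <- new("PoreTable",
              pores = data.frame(poreId = lpf$components$poreId,
                                 area_nm2 = lpf$components$area_px,
                                 minFeret_nm = 1, maxFeret_nm = 2,
                                 touchesEdge = lpf$components$touchesEdge,
                                 centroidRow = lpf$components$centroidRow,
                                 centroidCol = lpf$components$centroidCol),
              nmPerPx = 1, label = "framed")
  expect_error(poreStatistics(tabf), class = "fracRheo_empty_stats")
})

test_that("the full pipeline recovers a phantom and scales with calibration", {
  ph <- generatePorePhantom(sizePx = 384, nPores = 25, seed = 57)
  res <- analyzeMicrograph(ph$image)
  expect_equal(nrow(poreData(res$table)), nrow(ph$truth))
  truth_mean <- mean(ph$truth$minFeret_nm)
  expect_lt(abs(res$stats@mean - truth_mean) / truth_mean, 0.10)
  # same pixels, halved calibration: all nm quantities halve exactly
  img2 <- CalibratedImage(imagePixels(ph$image),
                          nmPerPx = nmPerPx(ph$image) / 2)
  res2 <- analyzeMicrograph(img2)
  expect_equal(poreData(res2$table)$minFeret_nm,
               poreData(res$table)$minFeret_nm / 2, tolerance = 1e-12)
  expect_equal(poreData(res2$table)$area_nm2,
               poreData(res$table)$area_nm2 / 4, tolerance = 1e-12)
  expect_equal(res2$stats@mean, res$stats@mean / 2, tolerance = 1e-12)
  # manifest records the run parameters
  expect_equal(res$manifest$sigma, 1)
  expect_equal(res$manifest$minAreaPx, 4)
})

test_that("an all-bright image surfaces a clean empty-stats error", {
  img <- CalibratedImage(matrix(c(rep(0.9, 500), rep(0.91, 524)), 32, 32),
                         nmPerPx = 1)
  expect_error(analyzeMicrograph(img), class = "fracRheo_empty_stats")
})

test_that("PNG and TIFF round trips preserve the phantom exactly", {
  ph <- generatePorePhantom(sizePx = 128, nPores = 3, meanlogFeret = log(20), seed = 58)
  for (ext in c(".png", ".tif")) {
    path <- tempfile(fileext = ext)
    writeMicrograph(ph$image, path)
    back <- readMicrograph(path, nmPerPx = nmPerPx(ph$image))
    expect_equal(imagePixels(back), imagePixels(ph$image),
                 tolerance = 1e-9)
  }
})
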