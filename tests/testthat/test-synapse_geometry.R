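test_that("centrosome distance is Euclidean, scaled, and binned correctly", {
  a <- list(image_id = "c1", row = 10, col = 10)
  b <- list(image_id = "c1", row = 10, col = 14)
  m <- centrosomeDistance(a, b, 0.5)
  expect_equal(m$distance_um, 2)
  expect_equal(m$bin, "1-3")
  expect_equal(centrosomeDistance(a, a, 0.5)$bin, "<=1")
  expect_error(centrosomeDistance(a, list(image_id = "c2", row = 1, col = 1),
                                  0.5), "different images")
  expect_error(centrosomeDistance(a, b, -1), "pixelSizeUm")
})

test_that("centrosome distance is symmetric in its two points", {
  a <- list(image_id = "c1", row = 3, col = 19)
  b <- list(image_id = "c1", row = 14, col = 6)
  expect_equal(centrosomeDistance(a, b, 0.2)$distance_um,
               centrosomeDistance(b, a, 0.2)$distance_um)
})

test_that("bins partition [0, Inf) with the stated boundary rules", {
  d <- c(0, 0.8, 1.0, 2.0, 3.0, 4.0)
  expect_equal(distanceBin(d), c("<=1", "<=1", "<=1", "1-3", "1-3", ">3"))
  # every non-negative distance maps to exactly one bin
  set.seed(3)
  r <- c(runif(200, 0, 6), 1, 3, 1 + 1e-12, 3 + 1e-12)
  bins <- distanceBin(r)
  expect_true(all(bins %in% c("<=1", "1-3", ">3")))
  expect_equal(bins[r <= 1], rep("<=1", sum(r <= 1)))
  expect_equal(bins[r > 1 & r <= 3], rep("1-3", sum(r > 1 & r <= 3)))
  expect_equal(bins[r > 3], rep(">3", sum(r > 3)))
})

test_that("punctum detection finds the rendered centrosome", {
  conj <- makeConjugateImage(c(-4, -6), spec = syntheticCellSpec(
    noiseSigma = 0, seed = 21))
  cm <- segmentCell(conj$cd8)
  # a noise-free Gaussian punctum can tie symmetrically around its centre
  pk <- suppressWarnings(detectPunctum(conj$pericentrin, cm, "c1"))
  expect_lt(max(abs(c(pk$row, pk$col) - conj$centrosome)), 1.01)
  dm <- diskMask(20)
  expect_error(detectPunctum(ChannelImage(matrix(5, nrow(dm), ncol(dm)), 0.2),
                             cellMaskFromBinary(dm)),
               "constant channel")
})

test_that("tied maxima resolve to the smallest (row, col) with a warning", {
  px <- matrix(1, 64, 64)
  px[40, 40] <- 50
  px[20, 20] <- 50   # symmetric twin far from the first
  m <- matrix(TRUE, 64, 64); m[1, ] <- FALSE
  cm <- cellMaskFromBinary(m)
  expect_warning(pk <- detectPunctum(ChannelImage(px, 0.2), cm), "multiple")
  expect_true(pk$row <= 20.5)
})

test_that("line profiles through an annulus show two peaks at the ring", {
  conj <- makeConjugateImage(c(0, 0), spec = syntheticCellSpec(
    semiAxes = c(24, 24), noiseSigma = 0, seed = 12))
  cm <- segmentCell(conj$cd8)
  pf <- factinProfiles(conj$factin, cm, c(0, 45, 90, 135), "c1")
  expect_equal(length(unique(pf$angle_deg)), 4L)
  R_um <- 24 * 0.2
  for (a in c(0, 45, 90, 135)) {
    p <- pf[pf$angle_deg == a, ]
    expect_true(all(diff(p$position_um) > 0))
    neg <- p[p$position_um < 0, ]; pos <- p[p$position_um > 0, ]
    expect_equal(neg$position_um[which.max(neg$intensity)], -R_um,
                 tolerance = 0.15)
    expect_equal(pos$position_um[which.max(pos$intensity)], R_um,
                 tolerance = 0.15)
    # central clearance: ring peak well above the centre
    centre <- p$intensity[which.min(abs(p$position_um))]
    expect_gt(max(p$intensity) / centre, 2)
  }
})

test_that("peak-to-centre ratio is angle-invariant for a radially symmetric ring", {
  conj <- makeConjugateImage(c(0, 0), spec = syntheticCellSpec(
    semiAxes = c(24, 24), noiseSigma = 0, seed = 12))
  cm <- segmentCell(conj$cd8)
  pf <- factinProfiles(conj$factin, cm, c(0, 45, 90, 135), "c1")
  # ridge height estimated as the mean within +/- 0.5 um of the peak: the
  # stable estimator for a band-shaped maximum on a sampled profile
  ridge <- function(p) {
    at <- p$position_um[which.max(p$intensity)]
    mean(p$intensity[abs(p$position_um - at) <= 0.5])
  }
  ratios <- sapply(c(0, 45, 90, 135), function(a) {
    p <- pf[pf$angle_deg == a, ]
    ridge(p) / p$intensity[which.min(abs(p$position_um))]
  })
  expect_lt(diff(range(ratios)) / mean(ratios), 0.05)
})

test_that("profiles across a uniform disk are flat-topped", {
  img <- diskImage(25, fg = 100, bg = 10)
  cm <- segmentCell(img)
  pf <- factinProfiles(img, cm, 0)
  interior <- pf[abs(pf$position_um) < 0.7 * 25 * 0.2, ]
  expect_lt(max(interior$intensity) / min(interior$intensity), 1.05)
  expect_error(factinProfiles(img, cm, numeric(0)), "non-empty")
})

test_that("batch distances pair annotations per image", {
  ann <- data.frame(
    image_id = c("a", "a", "b", "b", "c"),
    role = c("centrosome", "synapse_center", "centrosome", "synapse_center",
             "centrosome"),
    row = c(10, 10, 5, 8, 1), col = c(10, 20, 5, 9, 1))
  out <- centrosomeDistances(ann, 0.2)
  expect_equal(nrow(out), 2L)   # image "c" lacks a synapse centre
  expect_equal(out$distance_um[out$cell_id == "a"], 2)
})
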