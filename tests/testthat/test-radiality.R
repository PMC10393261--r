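# Structure-tensor orientation -----------------------------------------------

test_that("stripe orientations are recovered within 0.05 rad", {
  n <- 96
  interior <- matrix(FALSE, n, n); interior[16:(n - 16), 16:(n - 16)] <- TRUE
  for (deg in c(0, 30, 60, 120)) {
    th <- deg * pi / 180
    of <- orientationField(stripeImage(n, th), frameMask(n), 1.5, 0)
    sel <- interior & validPixels(of)
    errs <- axialDiff(orientationAngle(of)[sel], th)
    expect_lt(max(errs), 0.05)
  }
})

test_that("a constant image has zero coherence and no valid pixels", {
  of <- orientationField(ChannelImage(matrix(7, 64, 64), 0.2),
                         frameMask(64), 1.5, 0)
  expect_equal(max(coherence(of)), 0)
  expect_equal(sum(validPixels(of)), 0L)
})

test_that("orientation is invariant to positive intensity scaling", {
  img <- stripeImage(64, pi / 5)
  cm <- frameMask(64)
  a1 <- orientationAngle(orientationField(img, cm, 1.5, 0.1))
  img2 <- ChannelImage(pixelData(img) * 12.5, 0.2)
  a2 <- orientationAngle(orientationField(img2, cm, 1.5, 0.1))
  expect_equal(a1, a2, tolerance = 1e-10)
})

# Elliptical Fourier descriptor ----------------------------------------------

test_that("EFD of a disk is circular with negligible higher harmonics", {
  cm <- cellMaskFromBinary(diskMask(50))
  efd <- fitHullEFD(cm, 10)
  ax <- SynapseMorph:::efdFirstHarmonicAxes(efd)
  expect_lt(abs(ax[1] / ax[2] - 1), 0.02)
  amps <- sqrt(rowSums(efd@coefficients^2))
  expect_lt(max(amps[-1]) / amps[1], 0.05)
})

test_that("EFD of a 2:1 ellipse matches the arc-length harmonic oracle", {
  cm <- cellMaskFromBinary(makeRoughMask(c(60, 30), 0, 0L))
  efd <- fitHullEFD(cm, 10)
  ax <- SynapseMorph:::efdFirstHarmonicAxes(efd)
  # frozen oracle: first Fourier harmonic of an arc-length-parameterized
  # 2:1 ellipse has axis ratio 1.70399 (computed by FFT of 1e5 uniform
  # arc-length samples of the continuous ellipse), not 2: constant-speed
  # traversal of an ellipse is not a pure first harmonic
  expect_equal(ax[1] / ax[2], 1.70399, tolerance = 0.02)
  # the full reconstruction nevertheless spans a 2:1 extent
  bnd <- efdEvaluate(efd, 1440)
  ratio <- diff(range(bnd[, "row"])) / diff(range(bnd[, "col"]))
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("EFD reconstruction tracks the hull boundary to sub-pixel error", {
  for (sa in list(c(50, 50), c(45, 28))) {
    cm <- cellMaskFromBinary(makeRoughMask(sa, 0, 0L))
    bnd <- efdEvaluate(fitHullEFD(cm, 10), 1440)
    poly <- SynapseMorph:::hullPolygon(hullMask(cm))
    dense <- SynapseMorph:::densifyPolygon(poly, 0.25)
    d <- sapply(seq_len(nrow(bnd)), function(i)
      min(sqrt((dense[, 1] - bnd[i, 1])^2 + (dense[, 2] - bnd[i, 2])^2)))
    expect_lt(mean(d), 1)
  }
})

test_that("degenerate masks are rejected", {
  m <- matrix(FALSE, 32, 32)
  m[10, 5:25] <- TRUE   # collinear
  expect_error(cellMaskFromBinary(m), "collinear")
})

# Radial sections -------------------------------------------------------------

test_that("disk sections have annulus areas in ratio 1:3:5:7", {
  cm <- cellMaskFromBinary(diskMask(50))
  sec <- radialSections(fitHullEFD(cm, 10), cm, 4)
  counts <- tabulate(sectionIndex(sec)[!is.na(sectionIndex(sec))], 4)
  # oracle: annulus ((k-1)R/4, kR/4] has area proportional to 2k-1
  expect_equal(counts / counts[1], c(1, 3, 5, 7), tolerance = 0.1)
})

test_that("sections partition the hull interior minus the centre disk", {
  for (seed in c(2, 5)) {
    sim <- makeFilamentCell(syntheticCellSpec(epsilon = 0.1, lobes = 5,
                                              seed = seed))
    cm <- segmentCell(sim$image)
    sec <- radialSections(fitHullEFD(cm, 10), cm, 4)
    si <- sectionIndex(sec)
    com <- centerOfMass(cm)
    hull <- hullMask(cm)
    inHull <- which(hull, arr.ind = TRUE)
    r <- sqrt((inHull[, 1] - com[1])^2 + (inHull[, 2] - com[2])^2)
    assigned <- !is.na(si[hull])
    expect_true(all(assigned[r > 1]))     # coverage
    expect_true(all(!assigned[r <= 1]))   # centre disk excluded
    expect_true(all(is.na(si[!hull])))    # nothing outside the hull
  }
})

test_that("section index is non-decreasing along rays from the centre", {
  cm <- cellMaskFromBinary(makeRoughMask(c(40, 30), 0, 0L))
  sec <- radialSections(fitHullEFD(cm, 10), cm, 5)
  si <- sectionIndex(sec)
  com <- centerOfMass(cm)
  for (th in seq(0, 2 * pi, length.out = 17)[-17]) {
    t <- seq(1.5, 60, by = 0.7)
    rows <- round(com[1] + t * sin(th)); cols <- round(com[2] + t * cos(th))
    ok <- rows >= 1 & rows <= nrow(si) & cols >= 1 & cols <= ncol(si)
    v <- si[cbind(rows[ok], cols[ok])]
    v <- v[!is.na(v)]
    expect_true(all(diff(v) >= 0))
  }
})

test_that("fewer than two sections is an error", {
  cm <- cellMaskFromBinary(diskMask(20))
  expect_error(radialSections(fitHullEFD(cm, 10), cm, 1), "K must be >= 2")
})

# Degree of Radiality ---------------------------------------------------------

test_that("DoR limit cases: radial, tangential, 45-degree, uniform fields", {
  cm <- cellMaskFromBinary(diskMask(50))
  flds <- radialCircularFields(cm)
  sec <- radialSections(fitHullEFD(cm, 10), cm, 4)
  angR <- radialAngles(flds)

  pureRadial <- degreeOfRadiality(fieldFromAngles(angR, flds), flds, sec)
  # numerator N, denominator capped at 1e-6 * N => DoR = 1e6, large, finite
  expect_true(all(pureRadial@dor > 1e5 & is.finite(pureRadial@dor)))

  angC <- wrapAxial(atan2(flds$circularRow, flds$circularCol))
  pureTan <- degreeOfRadiality(fieldFromAngles(angC, flds), flds, sec)
  expect_equal(max(pureTan@dor), 0, tolerance = 1e-10)

  at45 <- degreeOfRadiality(fieldFromAngles(angR + pi / 4, flds), flds, sec)
  expect_equal(at45@dor, rep(1, 4), tolerance = 1e-12)

  set.seed(31)
  u <- matrix(runif(length(angR), 0, pi), nrow(angR), ncol(angR))
  unif <- degreeOfRadiality(fieldFromAngles(u, flds), flds, sec)
  # E|cos theta| = E|sin theta| for axial-uniform angles => DoR -> 1
  big <- unif@nPixels > 2000
  expect_true(all(abs(unif@dor[big] - 1) < 0.05))
})

test_that("a section without valid pixels yields nPixels 0 and NA DoR", {
  cm <- cellMaskFromBinary(diskMask(30))
  flds <- radialCircularFields(cm)
  sec <- radialSections(fitHullEFD(cm, 10), cm, 4)
  ang <- radialAngles(flds)
  f <- fieldFromAngles(ang, flds)
  # invalidate the innermost section entirely
  v <- validPixels(f); v[sectionIndex(sec) %in% 1L] <- FALSE
  a <- orientationAngle(f); a[!v] <- NA_real_
  f2 <- new("OrientationField", angle = a, coherence = coherence(f), valid = v)
  prof <- degreeOfRadiality(f2, flds, sec)
  expect_equal(prof@nPixels[1], 0L)
  expect_true(is.na(prof@dor[1]))
})

test_that("dorAt returns the requested section and rejects absent distances", {
  cm <- cellMaskFromBinary(diskMask(30))
  flds <- radialCircularFields(cm)
  sec <- radialSections(fitHullEFD(cm, 10), cm, 4)
  prof <- degreeOfRadiality(fieldFromAngles(radialAngles(flds) + pi / 4, flds),
                            flds, sec)
  expect_equal(dorAt(prof, 2), prof@dor[2])
  expect_error(dorAt(prof, 0), "no section")
  expect_error(dorAt(prof, 5), "no section")
})

test_that("DoR is invariant to global intensity scaling of the image", {
  sim <- makeFilamentCell(syntheticCellSpec(seed = 77))
  p1 <- analyzeRadiality(sim$image)
  img2 <- ChannelImage(pixelData(sim$image) * 4.2, pixelSizeUm(sim$image))
  p2 <- analyzeRadiality(img2)
  expect_equal(p2@dor, p1@dor, tolerance = 1e-8)
})

test_that("rotating a synthetic cell by 90 degrees changes DoR by < 3%", {
  sim <- makeFilamentCell(syntheticCellSpec(seed = 13, noiseSigma = 0))
  p1 <- analyzeRadiality(sim$image)
  rot <- ChannelImage(t(pixelData(sim$image))[ncol(pixelData(sim$image)):1, ],
                      pixelSizeUm(sim$image))
  p2 <- analyzeRadiality(rot)
  rel <- abs(p2@dor - p1@dor) / p1@dor
  expect_true(all(rel < 0.03))
})

test_that("section-mean DoR orders with the radial mixing fraction", {
  run <- function(alpha, seed)
    analyzeRadiality(makeFilamentCell(
      syntheticCellSpec(radialityAlpha = alpha, noiseSigma = 0,
                        seed = seed))$image)@dor
  m1  <- rowMeans(sapply(1:12, function(j) run(1,   400 + j)))
  m05 <- rowMeans(sapply(1:12, function(j) run(0.5, 500 + j)))
  m0  <- rowMeans(sapply(1:12, function(j) run(0,   600 + j)))
  # interior sections (2, 3 of 4): the innermost sits on the organizing-
  # centre convergence dome and the outermost borders the edge shell
  expect_true(all(m1[2:3] > m05[2:3]))
  expect_true(all(m05[2:3] > 1))
  expect_true(all(m0[2:3] < 1))
})
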