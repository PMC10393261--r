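test_that("identical specs render bit-identical images", {
  s <- syntheticCellSpec(radialityAlpha = 0.6, seed = 11)
  a <- makeFilamentCell(s); b <- makeFilamentCell(s)
  expect_identical(pixelData(a$image), pixelData(b$image))
  expect_identical(orientationAngle(a$truth), orientationAngle(b$truth))
  # and the call leaves the global RNG untouched
  set.seed(99); before <- runif(3)
  makeFilamentCell(s)
  set.seed(99)
  expect_identical(runif(3), before)
})

test_that("pure radial ground truth matches the radial direction", {
  sim <- makeFilamentCell(syntheticCellSpec(radialityAlpha = 1,
                                            noiseSigma = 0,
                                            centerOffsetPx = c(0, 0),
                                            seed = 5))
  tr <- sim$truth
  dp <- which(validPixels(tr), arr.ind = TRUE)
  oc <- tr@centrosome
  r <- sqrt((dp[, 1] - oc[1])^2 + (dp[, 2] - oc[2])^2)
  radAng <- wrapAxial(atan2(dp[, 1] - oc[1], dp[, 2] - oc[2]))
  err <- axialDiff(orientationAngle(tr)[validPixels(tr)], radAng)
  # a drawn pixel can sit up to 1 px off its segment's axis: at radius r
  # that subtends atan(1/r), so compare away from the centre
  expect_lt(max(err[r > 6]), 0.25)
  expect_lt(median(err), 0.1)
})

test_that("pure tangential ground truth is perpendicular to the radius", {
  sim <- makeFilamentCell(syntheticCellSpec(radialityAlpha = 0,
                                            noiseSigma = 0,
                                            centerOffsetPx = c(0, 0),
                                            seed = 6))
  tr <- sim$truth
  dp <- which(validPixels(tr), arr.ind = TRUE)
  oc <- tr@centrosome
  r <- sqrt((dp[, 1] - oc[1])^2 + (dp[, 2] - oc[2])^2)
  radAng <- wrapAxial(atan2(dp[, 1] - oc[1], dp[, 2] - oc[2]))
  err <- axialDiff(orientationAngle(tr)[validPixels(tr)],
                   wrapAxial(radAng + pi / 2))
  # chords are straight, so the tangent direction drifts along the chord;
  # a half-chord of 4 px at radius r subtends atan(4/r)
  expect_lt(median(err[r > 10]), 0.3)
})

test_that("ground-truth invariants hold: drawn pixels inside the mask", {
  sim <- makeFilamentCell(syntheticCellSpec(radialityAlpha = 0.5, seed = 9))
  tr <- sim$truth
  expect_true(all(cellMask(tr)[validPixels(tr)]))
  expect_true(all(is.finite(orientationAngle(tr)[validPixels(tr)])))
  # background strictly below filament intensity at zero noise
  sim0 <- makeFilamentCell(syntheticCellSpec(noiseSigma = 0, seed = 9))
  px <- pixelData(sim0$image)
  expect_lt(max(px[!cellMask(sim0$truth)]), min(100, min(px[validPixels(sim0$truth)])))
})

test_that("degenerate footprints and invalid perturbations are rejected", {
  expect_error(syntheticCellSpec(semiAxes = c(3, 20)), "semiAxes")
  expect_error(makeRoughMask(c(30, 30), 1.2, 4L), "epsilon")
  expect_error(makeRoughMask(c(3, 3), 0, 0L), "degenerate")
})

test_that("rough masks behave as constructed", {
  disk <- makeRoughMask(c(40, 40), 0, 0L)
  # epsilon = 0 gives the exact digitized disk: area within 1% of pi r^2
  expect_equal(sum(disk), pi * 40^2, tolerance = 0.01)
  # lobes = 0 keeps the mask convex (roughness 1)
  conv <- cellMaskFromBinary(makeRoughMask(c(40, 30), 0.2, 0L))
  expect_equal(shapeMetrics(conv)$roughness, 1, tolerance = 0.02)
  # star-like perturbation exceeds the disk's roughness
  star <- cellMaskFromBinary(makeRoughMask(c(40, 40), 0.3, 8L))
  expect_gt(shapeMetrics(star)$roughness,
            shapeMetrics(cellMaskFromBinary(disk))$roughness)
})

test_that("ground-truth mask is recovered by segmentation at zero noise", {
  for (seed in c(4, 14)) {
    sim <- makeFilamentCell(syntheticCellSpec(noiseSigma = 0, seed = seed))
    got <- cellMask(segmentCell(sim$image))
    want <- cellMask(sim$truth)
    expect_gt(sum(got & want) / sum(got | want), 0.95)
  }
})

test_that("conjugate images put the punctum at the requested position", {
  conj <- makeConjugateImage(c(-3, -4), spec = syntheticCellSpec(
    noiseSigma = 0, seed = 2))
  peri <- pixelData(conj$pericentrin)
  brightest <- which(peri == max(peri), arr.ind = TRUE)
  expect_lt(max(abs(brightest[1, ] - conj$centrosome)), 1)
  # offset (0, 0) means centrosome == synapse centre
  c0 <- makeConjugateImage(c(0, 0), spec = syntheticCellSpec(seed = 2))
  expect_equal(c0$centrosome, c0$synapseCenter)
  # same geometry, different noise under different seeds
  a <- makeConjugateImage(c(-3, -4), spec = syntheticCellSpec(seed = 3))
  b <- makeConjugateImage(c(-3, -4), spec = syntheticCellSpec(seed = 4))
  expect_equal(a$centrosome, b$centrosome)
  expect_false(identical(pixelData(a$pericentrin), pixelData(b$pericentrin)))
  # points outside the footprint are rejected
  expect_error(makeConjugateImage(c(500, 0), spec = syntheticCellSpec(seed = 2)),
               "outside")
})
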