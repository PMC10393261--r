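# Shared fixtures, all generated in code.

# Digitized disk mask of given radius centred on a square raster.
diskMask <- function(radius, margin = 6L) {
  makeRoughMask(c(radius, radius), 0, 0L)
}

# Two-level cell image: disk foreground on dark background.
diskImage <- function(radius = 25, fg = 200, bg = 10, pixelSizeUm = 0.2) {
  m <- diskMask(radius)
  ChannelImage(bg + (fg - bg) * m, pixelSizeUm)
}

# Synthetic orientation field aligned with a given angle matrix over the
# domain of precomputed radial/circular fields.
fieldFromAngles <- function(angles, fields) {
  valid <- fields$domain
  a <- wrapAxial(angles)
  a[!valid] <- NA_real_
  new("OrientationField", angle = a,
      coherence = ifelse(valid, 1, 0), valid = valid)
}

# Angle matrices of the radial / circular directions themselves.
radialAngles <- function(fields) wrapAxial(atan2(fields$radialRow, fields$radialCol))

# Stripe-pattern image: intensity varies sinusoidally across direction theta.
stripeImage <- function(n = 96, theta = 0, period = 12, pixelSizeUm = 0.2) {
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  k <- 2 * pi / period
  ChannelImage(100 + 80 * sin(k * (row * cos(theta) - col * sin(theta))),
               pixelSizeUm)
}

# Full-frame CellMask for stripe tests (no real cell: hull = whole frame).
frameMask <- function(n) {
  m <- matrix(FALSE, n, n)
  m[2:(n - 1), 2:(n - 1)] <- TRUE
  cellMaskFromBinary(m)
}

wrapAxial <- SynapseMorph:::wrapAxial
axialDiff <- SynapseMorph:::axialDiff
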