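# programmatic fixtures shared across test files

make_mask <- function(m, px_per_cm = 100) {
  structure(list(mask = m, px_per_cm = px_per_cm), class = "binary_mask")
}

# 300 x 3 px vertical bar centred in a 320 x 40 frame
bar_mask <- function(px_per_cm = 100) {
  m <- matrix(FALSE, 320, 40)
  m[11:310, 19:21] <- TRUE
  make_mask(m, px_per_cm)
}

# vertical 300 px primary + one horizontal 100 px lateral at depth 50 px
t_root_mask <- function(px_per_cm = 100) {
  m <- matrix(FALSE, 320, 160)
  m[11:310, 30:32] <- TRUE
  m[60:62, 33:130] <- TRUE
  make_mask(m, px_per_cm)
}

# uniform flat image of a single hue (degrees), s = v = 1
hue_image <- function(hue_deg, h = 20, w = 20, px_per_cm = 100) {
  col <- grDevices::hsv(hue_deg / 360, 1, 1)
  v <- grDevices::col2rgb(col) / 255
  rgb <- array(0, c(h, w, 3))
  for (ch in 1:3) rgb[, , ch] <- v[ch]
  root_image(rgb, px_per_cm)
}

# dense-resampling quadrature oracle for elliptic Fourier coefficients:
# integrates the chord-length-parameterized contour numerically
efd_oracle <- function(pts, n_harmonics, n_dense = 2e5) {
  pts <- rbind(pts, pts[1, ])
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  tt <- c(0, cumsum(len)); T <- sum(len)
  s <- seq(0, T, length.out = n_dense + 1)[-(n_dense + 1)]
  i <- findInterval(s, tt, rightmost.closed = TRUE)
  i[i > nrow(seg)] <- nrow(seg)
  frac <- (s - tt[i]) / len[i]
  x <- pts[i, 1] + frac * seg[i, 1]
  y <- pts[i, 2] + frac * seg[i, 2]
  H <- matrix(0, n_harmonics, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(n_harmonics)) {
    cs <- cos(2 * pi * n * s / T); sn <- sin(2 * pi * n * s / T)
    H[n, ] <- 2 * c(mean(x * cs), mean(x * sn), mean(y * cs), mean(y * sn))
  }
  list(harmonics = H, offset = c(mean(x), mean(y)))
}

# brute-force segment-intersection test for polygon simplicity
polygon_is_simple <- function(pts) {
  n <- nrow(pts)
  p2 <- pts[c(2:n, 1), , drop = FALSE]
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- (b2[1] - b1[1]) * (a1[2] - b1[2]) - (b2[2] - b1[2]) * (a1[1] - b1[1])
    d2 <- (b2[1] - b1[1]) * (a2[2] - b1[2]) - (b2[2] - b1[2]) * (a2[1] - b1[1])
    d3 <- (a2[1] - a1[1]) * (b1[2] - a1[2]) - (a2[2] - a1[2]) * (b1[1] - a1[1])
    d4 <- (a2[1] - a1[1]) * (b2[2] - a1[2]) - (a2[2] - a1[2]) * (b2[1] - a1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(pts[i, ], p2[i, ], pts[j, ], p2[j, ])) return(FALSE)
    }
  }
  TRUE
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# RMS reconstruction error of a truncated Fourier series, evaluated at the
# contour's own chord-length parameters (the L2 error the truncation
# controls, so it is non-increasing in the harmonic count)
efd_recon_rms <- function(efd, pts, n_harm, n_dense = 4000) {
  pts2 <- rbind(pts, pts[1, ])
  seg <- diff(pts2); len <- sqrt(rowSums(seg^2))
  tt <- c(0, cumsum(len)); T <- sum(len)
  s <- seq(0, T, length.out = n_dense + 1)[-(n_dense + 1)]
  i <- findInterval(s, tt, rightmost.closed = TRUE)
  i[i > nrow(seg)] <- nrow(seg)
  fr <- (s - tt[i]) / len[i]
  X <- pts2[i, 1] + fr * seg[i, 1]
  Y <- pts2[i, 2] + fr * seg[i, 2]
  x <- rep(efd$offset[1], n_dense); y <- rep(efd$offset[2], n_dense)
  for (n in seq_len(n_harm)) {
    cs <- cos(2 * pi * n * s / T); sn <- sin(2 * pi * n * s / T)
    x <- x + efd$harmonics[n, "a"] * cs + efd$harmonics[n, "b"] * sn
    y <- y + efd$harmonics[n, "c"] * cs + efd$harmonics[n, "d"] * sn
  }
  sqrt(mean((x - X)^2 + (y - Y)^2))
}

# small helper: outline of an axis-aligned ellipse sampled at uniform angle
ellipse_outline <- function(a, b, n = 400) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  shape_outline(cbind(a * cos(th), b * sin(th)))
}
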