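#' Elliptic Fourier transform of a closed outline
#'
#' Kuhl--Giardina elliptic Fourier coefficients of a closed polygonal
#' contour parameterized by cumulative chord length (the polygon's arc
#' length). For each harmonic n the coefficients are
#' \deqn{a_n = \frac{T}{2\pi^2 n^2} \sum_p \frac{\Delta x_p}{\Delta t_p}
#'   (\cos\phi_p - \cos\phi_{p-1})}
#' and analogously b (sin, x), c (cos, y), d (sin, y), with
#' \eqn{\phi_p = 2\pi n t_p / T}. These sums are the exact Fourier
#' integrals of the piecewise-linear contour. The offset (A0, C0) is the
#' arc-length-weighted mean of the contour.
#'
#' Harmonic content depends on the parameterization: a contour traced at
#' uniform speed (e.g. a circle) concentrates on one harmonic, whereas the
#' same geometric ellipse parameterized by arc length spreads small
#' amounts of energy into odd higher harmonics.
#'
#' @param outline a `shape_outline` (or n x 2 matrix of points).
#' @param n_harmonics number of harmonics N (>= 1).
#' @return an `efd_set`: list(harmonics = N x 4 matrix (a, b, c, d),
#'   offset = c(A0, C0), T = contour length, n_points).
#' @export
efd_transform <- function(outline, n_harmonics = 20) {
  pts <- if (inherits(outline, "shape_outline")) outline$points else as.matrix(outline)
  if (nrow(pts) < 3) stop_param("outline needs >= 3 points")
  x <- c(pts[, 1], pts[1, 1]); y <- c(pts[, 2], pts[1, 2])
  dx <- diff(x); dy <- diff(y)
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  if (!length(dt)) stop_param("degenerate contour of zero length")
  t1 <- cumsum(dt); t0 <- c(0, t1[-length(t1)])
  T <- t1[length(t1)]
  H <- matrix(0, n_harmonics, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(n_harmonics)) {
    w <- 2 * pi * n / T
    dc <- cos(w * t1) - cos(w * t0)
    dsn <- sin(w * t1) - sin(w * t0)
    k <- T / (2 * pi^2 * n^2)
    H[n, ] <- k * c(sum(dx / dt * dc), sum(dx / dt * dsn),
                    sum(dy / dt * dc), sum(dy / dt * dsn))
  }
  xm <- x[-length(x)][keep]; ym <- y[-length(y)][keep]
  A0 <- unname(sum(dt * (xm + xm + dx) / 2) / T)
  C0 <- unname(sum(dt * (ym + ym + dy) / 2) / T)
  structure(list(harmonics = H, offset = c(A0 = A0, C0 = C0), T = T,
                 n_points = nrow(pts)),
            class = "efd_set")
}

#' Mean of elliptic Fourier descriptor sets
#'
#' Coefficient-wise arithmetic mean of harmonics and offsets; the inputs
#' must share the same harmonic count.
#'
#' @param sets nonempty list of `efd_set` objects.
#' @return an `efd_set`.
#' @export
mean_efd <- function(sets) {
  if (!length(sets)) stop_param("empty list of descriptor sets")
  Ns <- vapply(sets, function(s) nrow(s$harmonics), integer(1))
  if (length(unique(Ns)) != 1) stop_param("mixed harmonic counts")
  H <- Reduce(`+`, lapply(sets, `[[`, "harmonics")) / length(sets)
  off <- Reduce(`+`, lapply(sets, `[[`, "offset")) / length(sets)
  structure(list(harmonics = H, offset = off,
                 T = mean(vapply(sets, `[[`, numeric(1), "T")),
                 n_points = sets[[1]]$n_points),
            class = "efd_set")
}

#' Reconstruct an outline from truncated Fourier descriptors
#'
#' Synthesizes the contour from the first `n_harmonics` harmonics at
#' `n_points` uniformly spaced parameter values, then aligns the result
#' for cross-genotype comparison: the topmost point is placed at vertical
#' coordinate 0 and the outline is horizontally centred at 0.
#'
#' @param efd an `efd_set`.
#' @param n_harmonics harmonics used (default 5, the low-pass "basic
#'   shape" setting); must not exceed the stored count.
#' @param n_points points to synthesize (default 256).
#' @param align apply the top/centre alignment (default TRUE; when FALSE
#'   the stored offset is used).
#' @return a `shape_outline`.
#' @export
reconstruct_outline <- function(efd, n_harmonics = 5, n_points = 256,
                                align = TRUE) {
  N <- nrow(efd$harmonics)
  if (n_harmonics > N)
    stop_param("n_harmonics = %d exceeds the %d stored harmonics",
               n_harmonics, N)
  t <- seq(0, 1, length.out = n_points + 1)[-(n_points + 1)]
  x <- rep(efd$offset[1], n_points)
  y <- rep(efd$offset[2], n_points)
  for (n in seq_len(n_harmonics)) {
    cs <- cos(2 * pi * n * t); sn <- sin(2 * pi * n * t)
    x <- x + efd$harmonics[n, "a"] * cs + efd$harmonics[n, "b"] * sn
    y <- y + efd$harmonics[n, "c"] * cs + efd$harmonics[n, "d"] * sn
  }
  if (align) {
    y <- y - min(y)
    x <- x - mean(x)
  }
  shape_outline(cbind(x = x, y = y))
}

#' Per-genotype mean shape profile
#'
#' The mean-shape steps applied to one genotype's replicate masks:
#' dilate each mask (square kernel, default 50 px) so the outline captures
#' the whole root extent, extract the outline, take its elliptic Fourier
#' transform, average the descriptors over replicates, and reconstruct the
#' mean outline at a small number of harmonics (default 5) to keep only
#' the basic shape.
#'
#' @param masks list of `binary_mask` objects (replicates of one
#'   genotype).
#' @param kernel_px dilation kernel side (default 50).
#' @param n_harmonics harmonics stored per replicate (default 20).
#' @param reconstruct_harmonics harmonics used for the profile (default 5).
#' @param n_points points in the reconstructed profile.
#' @return list with `profile` (a `shape_outline`), `efd` (the mean
#'   `efd_set`) and `n_used`.
#' @export
mean_shape_pipeline <- function(masks, kernel_px = 50, n_harmonics = 20,
                                reconstruct_harmonics = 5, n_points = 256) {
  sets <- list()
  for (m in masks) {
    ok <- tryCatch({
      dm <- dilate_mask(m, kernel_px)
      sets[[length(sets) + 1L]] <- efd_transform(extract_outline(dm),
                                                 n_harmonics)
      TRUE
    }, error = function(e) {
      warning("replicate skipped: ", conditionMessage(e))
      FALSE
    })
  }
  if (!length(sets)) stop_param("no usable masks")
  me <- mean_efd(sets)
  list(profile = reconstruct_outline(me, reconstruct_harmonics, n_points),
       efd = me, n_used = length(sets))
}

#' Rasterize a closed outline into a filled square silhouette
#'
#' Scales the outline so its height spans the image, fills the polygon by
#' even-odd scanline crossing, and pads symmetrically along the width
#' direction to produce a square side_px x side_px binary image.
#'
#' @param outline a `shape_outline`.
#' @param side_px output side (default 64).
#' @return numeric side_px x side_px matrix in {0, 1}.
#' @export
rasterize_shape <- function(outline, side_px = 64) {
  pts <- outline$points
  x <- pts[, 1]; y <- pts[, 2]
  hgt <- max(y) - min(y); wdt <- max(x) - min(x)
  if (hgt <= 0 || wdt <= 0) stop_param("degenerate outline")
  s <- (side_px - 2) / hgt
  if (wdt * s > side_px)
    s <- (side_px - 2) / wdt  # wider than tall: fit the width instead
  xs <- (x - min(x)) * s; ys <- (y - min(y)) * s
  xs <- xs + (side_px - max(xs)) / 2   # pad along the width direction
  ys <- ys + 1
  img <- matrix(0, side_px, side_px)
  # even-odd scanline fill at pixel-centre rows
  n <- length(xs); j <- c(2:n, 1)
  for (r in seq_len(side_px)) {
    yc <- r - 0.5
    crosses <- ((ys < yc) & (ys[j] >= yc)) | ((ys[j] < yc) & (ys >= yc))
    if (!any(crosses)) next
    xi <- xs[crosses] + (yc - ys[crosses]) /
      (ys[j][crosses] - ys[crosses]) * (xs[j][crosses] - xs[crosses])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      c0 <- ceiling(xi[k] + 0.5); c1 <- floor(xi[k + 1] + 0.5)
      if (c1 >= c0) img[r, max(1, c0):min(side_px, c1)] <- 1
    }
  }
  img
}
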