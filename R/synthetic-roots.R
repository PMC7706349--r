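#' Render a synthetic seedling root image with known geometry
#'
#' Draws a primary root as a downward random walk of recorded arc length
#' (elongation rate x day), emits lateral roots as a Poisson process along
#' it with sampled emergence angles, and rasterizes the strokes onto a
#' blue-paper background (hue ~220 degrees) with a root-coloured
#' foreground (hue < 60 degrees), so the hue-threshold segmentation rule
#' applies on both sides. The canvas is sized to the drawn geometry plus a
#' margin.
#'
#' @param genotype_params list with elongation_rate (cm/day),
#'   branch_intensity (branches/cm), branch_angle_mean / branch_angle_sd
#'   (degrees from vertical), tortuosity (sd of the per-step heading
#'   change, radians), diameter_cm (stroke width).
#' @param day days after germination (> 0).
#' @param px_per_cm raster scale.
#' @param seed RNG seed.
#' @param max_px hard canvas limit; a render that would exceed it errors.
#' @return list with `image` (a [root_image()]) and `truth` (PRL, DEP, WID
#'   in cm, lateral count and per-lateral emergence angles in degrees, and
#'   total arc length TRL).
#' @export
simulate_root_system <- function(genotype_params, day, px_per_cm, seed = 1,
                                 max_px = 4000) {
  p <- genotype_params
  if (p$elongation_rate <= 0 || day <= 0)
    stop_param("elongation rate and day must be positive")
  with_seed(derive_seed(seed, "root_system"), {
    step_cm <- 0.05
    L <- p$elongation_rate * day
    n_step <- max(2L, ceiling(L / step_cm))
    # primary root: heading random walk pulled back toward vertical
    theta <- numeric(n_step); theta[1] <- stats::rnorm(1, 0, p$tortuosity)
    for (i in 2:n_step)
      theta[i] <- 0.97 * theta[i - 1] + stats::rnorm(1, 0, p$tortuosity)
    ds <- rep(L / n_step, n_step)
    xy <- cbind(x = cumsum(ds * sin(theta)), y = cumsum(ds * cos(theta)))
    xy <- rbind(c(0, 0), xy)
    arc <- c(0, cumsum(ds))

    # laterals: Poisson along the primary, shorter than the taproot
    n_lat <- stats::rpois(1, p$branch_intensity * L)
    lat <- list(); lat_angle <- numeric(0)
    if (n_lat > 0) {
      at <- sort(stats::runif(n_lat, 0.05 * L, 0.95 * L))
      for (j in seq_len(n_lat)) {
        base <- xy[which.min(abs(arc - at[j])), ]
        ang <- stats::rnorm(1, p$branch_angle_mean, p$branch_angle_sd)
        ang <- min(max(ang, 5), 90)
        side <- sample(c(-1, 1), 1)
        len <- stats::runif(1, 0.1, 0.35) * L * (1 - at[j] / L)
        len <- max(len, 0.2)
        m <- max(2L, ceiling(len / step_cm))
        phi <- ang * pi / 180
        dd <- seq(0, len, length.out = m)
        lat[[j]] <- cbind(base[1] + side * dd * sin(phi),
                          base[2] + dd * cos(phi))
        lat_angle <- c(lat_angle, ang)
      }
    }

    all_pts <- rbind(xy, do.call(rbind, lat))
    rad_px <- max(1, round(p$diameter_cm * px_per_cm / 2))
    margin <- rad_px + 5
    x0 <- min(all_pts[, 1]); x1 <- max(all_pts[, 1])
    w <- ceiling((x1 - x0) * px_per_cm) + 2 * margin
    h <- ceiling(max(all_pts[, 2]) * px_per_cm) + 2 * margin
    if (w > max_px || h > max_px)
      stop_param("canvas %dx%d exceeds max_px = %d", h, w, max_px)

    mask <- matrix(FALSE, h, w)
    to_px <- function(pts) cbind(r = pts[, 2] * px_per_cm + margin,
                                 c = (pts[, 1] - x0) * px_per_cm + margin)
    mask <- stamp_polyline(mask, to_px(xy), rad_px)
    for (l in lat) mask <- stamp_polyline(mask, to_px(l), rad_px)

    rgb <- array(0, c(h, w, 3))
    bg <- c(0.16, 0.35, 0.78)   # blue paper, hue ~ 220
    fgc <- c(0.88, 0.80, 0.62)  # root, hue ~ 42
    for (ch in 1:3) rgb[, , ch] <- ifelse(mask, fgc[ch], bg[ch])

    truth <- list(PRL = L,
                  TRL = L + if (n_lat > 0) sum(vapply(lat, function(l)
                    sum(sqrt(rowSums(diff(l)^2))), numeric(1))) else 0,
                  DEP = max(all_pts[, 2]) - min(0, min(all_pts[, 2])),
                  WID = x1 - x0,
                  LRB = n_lat, lateral_angles = lat_angle)
    list(image = root_image(rgb, px_per_cm,
                            meta = list(seed = seed, day = day)),
         mask = structure(list(mask = mask, px_per_cm = px_per_cm),
                          class = "binary_mask"),
         truth = truth)
  })
}

# stamp discs of radius rad_px along a polyline given in (row, col) px
stamp_polyline <- function(mask, rc, rad_px) {
  offs <- disc_offsets(rad_px)
  h <- nrow(mask); w <- ncol(mask)
  seg_len <- sqrt(rowSums(diff(rc)^2))
  for (i in seq_len(nrow(rc) - 1)) {
    n <- max(2L, ceiling(seg_len[i] / 0.5))
    rr <- seq(rc[i, 1], rc[i + 1, 1], length.out = n)
    cc <- seq(rc[i, 2], rc[i + 1, 2], length.out = n)
    pr <- round(rep(rr, each = nrow(offs)) + offs[, 1])
    pc <- round(rep(cc, each = nrow(offs)) + offs[, 2])
    ok <- pr >= 1 & pr <= h & pc >= 1 & pc <= w
    mask[cbind(pr[ok], pc[ok])] <- TRUE
  }
  mask
}

disc_offsets <- function(rad_px) {
  g <- expand.grid(dr = -rad_px:rad_px, dc = -rad_px:rad_px)
  as.matrix(g[g$dr^2 + g$dc^2 <= rad_px^2, ])
}

#' Write a root image (or mask) to PNG
#'
#' @param image a [root_image()] or `binary_mask`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_root_png <- function(image, path) {
  a <- if (inherits(image, "root_image")) image$rgb else (image$mask + 0)
  png::writePNG(a, path)
  invisible(path)
}

#' Generate a family of synthetic root silhouettes
#'
#' Produces closed, simple, counter-clockwise outlines from a catalogue of
#' root-shape archetypes, used as ground-truth fixtures for the shape
#' pipeline:
#' \itemize{
#'   \item "umbrella": wide at the top, tapering quickly with depth.
#'   \item "beard": moderately wide, near-uniform width, blunt.
#'   \item "drought": narrow and deep.
#' }
#' Within-family variation is controlled by `jitter`, which perturbs the
#' width profile with smooth low-order harmonics and the overall scale.
#'
#' @param family_id one of "umbrella", "beard", "drought".
#' @param n number of outlines.
#' @param jitter non-negative jitter amplitude (0 = identical outlines).
#' @param seed RNG seed.
#' @param height_px nominal silhouette height in pixels (default 300).
#' @return list of `shape_outline` objects.
#' @export
generate_shape_family <- function(family_id, n, jitter = 0.1, seed = 1,
                                  height_px = 300) {
  prof <- switch(family_id,
    umbrella = list(w = function(y) 0.90 * (1 - y)^0.8 + 0.06, depth = 1.0),
    beard = list(w = function(y) 0.45 * (1 - 0.25 * y) + 0.05, depth = 1.1),
    drought = list(w = function(y) 0.22 * (1 - y)^0.35 + 0.04, depth = 1.45),
    stop_param("unknown shape family '%s'", family_id))
  if (n < 1) stop_param("n must be >= 1")
  with_seed(derive_seed(seed, paste0("shape_family/", family_id)), {
    lapply(seq_len(n), function(i) {
      y <- seq(0, 1, length.out = 80)
      wob <- if (jitter > 0) {
        a <- stats::rnorm(3, 0, jitter)
        1 + a[1] * sin(pi * y) + a[2] * sin(2 * pi * y) + a[3] * sin(3 * pi * y)
      } else 1
      scl <- if (jitter > 0) exp(stats::rnorm(1, 0, jitter / 2)) else 1
      wdt <- pmax(prof$w(y) * wob, 0.02) * height_px * scl
      dep <- prof$depth * height_px * scl
      xr <- wdt / 2; yy <- y * dep
      pts <- rbind(cbind(xr, yy), cbind(-rev(xr), rev(yy)))
      shape_outline(pts)
    })
  })
}
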