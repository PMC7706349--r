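#' Root image container
#'
#' @param rgb H x W x 3 array with channel values in [0, 1].
#' @param px_per_cm raster scale.
#' @param meta optional list (genotype, replicate, day).
#' @return object of class `root_image`.
#' @export
root_image <- function(rgb, px_per_cm, meta = list()) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3, px_per_cm > 0)
  structure(list(rgb = rgb, px_per_cm = px_per_cm, meta = meta),
            class = "root_image")
}

#' Read a root image from PNG
#'
#' @param path PNG file.
#' @param px_per_cm raster scale.
#' @param meta optional metadata list.
#' @return a [root_image()].
#' @export
read_root_image <- function(path, px_per_cm, meta = list()) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  root_image(a[, , 1:3, drop = FALSE], px_per_cm, meta)
}

#' Segment root foreground from blue germination paper
#'
#' Converts the image to HSV (hue in degrees, [0, 360)) and labels pixels
#' with hue above `hue_bg` (default 175) as blue background, everything
#' else as root foreground; reds near 0 degrees stay foreground under this
#' single-threshold rule. If the resulting foreground covers more than
#' `fallback_frac` of the frame the background is assumed oversaturated
#' and the rule falls back to thresholding the L channel of Lab space with
#' Otsu's method (bright root on darker paper). Components smaller than
#' `min_px` are removed as paper-texture specks and the largest connected
#' foreground component is retained.
#'
#' @param image a [root_image()].
#' @param hue_bg background hue threshold in degrees (default 175).
#' @param fallback_frac foreground fraction triggering the Lab fallback.
#' @param min_px minimum component size kept before largest-component
#'   selection (default 20).
#' @return a `binary_mask`: list(mask = logical H x W matrix, px_per_cm).
#' @export
segment_root <- function(image, hue_bg = 175, fallback_frac = 0.5,
                         min_px = 20) {
  rgb <- image$rgb
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  hsv <- grDevices::rgb2hsv(r = as.vector(rgb[, , 1]),
                            g = as.vector(rgb[, , 2]),
                            b = as.vector(rgb[, , 3]), maxColorValue = 1)
  hue <- hsv[1, ] * 360
  fg <- matrix(hue <= hue_bg, h, w)
  if (mean(fg) > fallback_frac) {
    L <- lab_lightness(rgb)
    thr <- otsu_threshold(L)
    fg <- matrix(L > thr, h, w)
  }
  fg <- keep_largest_component(fg, min_px)
  if (!any(fg))
    stop_param("segmentation failed: no foreground under hue rule (hue range %.0f-%.0f) or Lab fallback",
               min(hue), max(hue))
  structure(list(mask = fg, px_per_cm = image$px_per_cm),
            class = "binary_mask")
}

# L channel of CIE Lab from sRGB in [0,1] (D65)
lab_lightness <- function(rgb) {
  lin <- function(u) ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  R <- lin(as.vector(rgb[, , 1])); G <- lin(as.vector(rgb[, , 2]))
  B <- lin(as.vector(rgb[, , 3]))
  Y <- 0.2126 * R + 0.7152 * G + 0.0722 * B
  f <- ifelse(Y > (6 / 29)^3, Y^(1 / 3), Y / (3 * (6 / 29)^2) + 4 / 29)
  116 * f - 16
}

otsu_threshold <- function(x, n_breaks = 256) {
  h <- hist(x, breaks = n_breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p); mu <- cumsum(p * mids); mu_t <- mu[length(mu)]
  sb <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

keep_largest_component <- function(mask, min_px = 0) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask + 0))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0])
  if (min_px > 0) {
    small <- which(sizes < min_px)
    if (length(small)) { mask[lab %in% small] <- FALSE; sizes[small] <- 0L }
  }
  if (!any(sizes > 0)) return(mask & FALSE)
  mask & (lab == which.max(sizes))
}

#' Skeletonize a binary mask
#'
#' Zhang--Suen thinning to a 1-pixel-wide, topology-preserving skeleton.
#' Thinning is idempotent: re-skeletonizing a skeleton changes nothing.
#'
#' @param mask a `binary_mask` (or logical matrix).
#' @return a `skeleton`: list(mask = logical matrix, pixels = (row, col)
#'   matrix, px_per_cm).
#' @export
skeletonize_mask <- function(mask) {
  px_per_cm <- if (is.list(mask)) mask$px_per_cm else NA_real_
  m <- if (is.list(mask)) mask$mask else mask
  if (!any(m)) stop_param("cannot skeletonize an empty mask")
  sk <- zhang_suen(m)
  structure(list(mask = sk, pixels = which(sk, arr.ind = TRUE),
                 px_per_cm = px_per_cm),
            class = "skeleton")
}

# vectorized Zhang-Suen thinning on a padded logical matrix
zhang_suen <- function(m) {
  h <- nrow(m); w <- ncol(m)
  M <- matrix(FALSE, h + 2, w + 2)
  M[2:(h + 1), 2:(w + 1)] <- m
  shift <- function(M, dr, dc) {
    out <- matrix(FALSE, nrow(M), ncol(M))
    rs <- (1 + max(0, dr)):(nrow(M) + min(0, dr))
    cs <- (1 + max(0, dc)):(ncol(M) + min(0, dc))
    out[rs, cs] <- M[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours P2..P9 clockwise from north
      P2 <- shift(M, 1, 0);  P3 <- shift(M, 1, -1); P4 <- shift(M, 0, -1)
      P5 <- shift(M, -1, -1); P6 <- shift(M, -1, 0); P7 <- shift(M, -1, 1)
      P8 <- shift(M, 0, 1);  P9 <- shift(M, 1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (pass == 1) {
        cond <- M & B >= 2 & B <= 6 & A == 1 & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- M & B >= 2 & B <= 6 & A == 1 & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) { M[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  M[2:(h + 1), 2:(w + 1)]
}

#' Dilate a binary mask with a square structuring element
#'
#' @param mask a `binary_mask` (or logical matrix).
#' @param kernel_px side of the square kernel (default 50; 1 is the
#'   identity). For even sizes the element's origin sits at pixel
#'   floor((k-1)/2) so dilation covers offsets -floor((k-1)/2) ...
#'   k-1-floor((k-1)/2).
#' @return dilated mask of the same type.
#' @export
dilate_mask <- function(mask, kernel_px = 50) {
  if (kernel_px < 1) stop_param("kernel_px must be >= 1")
  m <- if (is.list(mask)) mask$mask else mask
  left <- floor((kernel_px - 1) / 2); right <- kernel_px - 1 - left
  out <- dilate_1d(m, -left:right, rows = TRUE)
  out <- dilate_1d(out, -left:right, rows = FALSE)
  if (is.list(mask)) { mask$mask <- out; mask } else out
}

dilate_1d <- function(m, offsets, rows = TRUE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (d in offsets) {
    if (rows) {
      rs_to <- max(1, 1 + d):min(h, h + d)
      out[rs_to, ] <- out[rs_to, ] | m[rs_to - d, ]
    } else {
      cs_to <- max(1, 1 + d):min(w, w + d)
      out[, cs_to] <- out[, cs_to] | m[, cs_to - d]
    }
  }
  out
}

#' Extract the outline of the largest mask component
#'
#' Traces the boundary of the largest connected foreground component as an
#' ordered closed contour and orients it counter-clockwise (positive
#' shoelace area in the x-right / y-up sense).
#'
#' @param mask a `binary_mask` (or logical matrix).
#' @return a `shape_outline`: list(points = n x 2 matrix of (x, y) pixel
#'   coordinates, closed implicitly).
#' @export
extract_outline <- function(mask) {
  m <- if (is.list(mask)) mask$mask else mask
  if (!any(m)) stop_param("cannot extract an outline from an empty mask")
  m <- keep_largest_component(m)
  # EBImage images are indexed [x, y]; transpose so x = column, y = row
  img <- EBImage::Image(t(m + 0))
  oc <- EBImage::ocontour(EBImage::bwlabel(img))[[1]]
  pts <- cbind(x = oc[, 1] + 1, y = oc[, 2] + 1)
  shape_outline(pts)
}

#' Shape outline container
#'
#' @param points n x 2 matrix of (x, y) coordinates; the contour is closed
#'   implicitly (first point follows the last). Orientation is normalized
#'   to counter-clockwise (positive shoelace area with y up).
#' @return object of class `shape_outline`.
#' @export
shape_outline <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (nrow(points) >= 2 && all(points[1, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) < 3) stop_param("an outline needs >= 3 distinct points")
  if (polygon_area_signed(points[, 1], -points[, 2]) < 0)
    points <- points[nrow(points):1, , drop = FALSE]
  colnames(points) <- c("x", "y")
  structure(list(points = points), class = "shape_outline")
}
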