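test_that("EFD coefficients match a dense quadrature oracle", {
  sq <- shape_outline(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  e <- efd_transform(sq, 6)
  orc <- efd_oracle(sq$points, 6)
  expect_equal(e$harmonics, orc$harmonics, tolerance = 1e-6)
  expect_equal(unname(e$offset), orc$offset, tolerance = 1e-6)

  # an irregular simple polygon, same agreement
  set.seed(2)
  th <- sort(runif(9, 0, 2 * pi))
  poly <- cbind(cos(th) * runif(9, 1, 2), sin(th) * runif(9, 1, 2))
  e2 <- efd_transform(shape_outline(poly), 8)
  orc2 <- efd_oracle(shape_outline(poly)$points, 8)
  expect_equal(e2$harmonics, orc2$harmonics, tolerance = 1e-5)

  expect_error(efd_transform(cbind(c(0, 0, 0), c(1, 1, 1))), "degenerate|points")
})

test_that("a single-harmonic descriptor synthesizes an exact ellipse", {
  H <- matrix(0, 1, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  H[1, ] <- c(2, 0, 0, 1)
  efd <- structure(list(harmonics = H, offset = c(A0 = 0, C0 = 0),
                        T = 2 * pi, n_points = 0), class = "efd_set")
  o <- reconstruct_outline(efd, 1, n_points = 720, align = FALSE)
  # every synthesized point satisfies (x/2)^2 + y^2 = 1
  resid <- (o$points[, 1] / 2)^2 + o$points[, 2]^2 - 1
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("mean descriptors average coefficient-wise", {
  e1 <- efd_transform(ellipse_outline(2, 1), 5)
  e2 <- efd_transform(ellipse_outline(4, 3), 5)
  m <- mean_efd(list(e1, e2))
  expect_equal(m$harmonics, (e1$harmonics + e2$harmonics) / 2)
  expect_equal(mean_efd(list(e1, e1))$harmonics, e1$harmonics)
  # mean of two concentric ellipses reconstructs the intermediate one:
  # the first-harmonic magnitudes are the midpoints
  expect_equal(m$harmonics[1, "a"], (e1$harmonics[1, "a"] +
                                     e2$harmonics[1, "a"]) / 2)
  expect_error(mean_efd(list()), "empty")
  expect_error(mean_efd(list(e1, efd_transform(ellipse_outline(2, 1), 3))),
               "mixed")
})

test_that("reconstruction error decreases with harmonic count and aligns", {
  o <- generate_shape_family("umbrella", 1, jitter = 0.15, seed = 3)[[1]]
  e <- efd_transform(o, 12)
  errs <- vapply(1:12, function(n) efd_recon_rms(e, o$points, n),
                 numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[12], errs[1])

  r5 <- reconstruct_outline(e, 5)
  expect_equal(min(r5$points[, 2]), 0, tolerance = 1e-9)
  expect_equal(mean(r5$points[, 1]), 0, tolerance = 1e-9)
  expect_error(reconstruct_outline(e, 20), "exceeds")
})

test_that("EFD analysis/synthesis round trip is stable", {
  # a circle is traced at uniform speed, so analysis inverts synthesis
  circ <- ellipse_outline(3, 3, n = 1024)
  e <- efd_transform(circ, 5)
  r <- reconstruct_outline(e, 5, n_points = 1024, align = FALSE)
  e2 <- efd_transform(r, 5)
  expect_equal(e2$harmonics, e$harmonics, tolerance = 1e-5)
  expect_equal(e2$offset, e$offset, tolerance = 1e-5)
  # general band-limited shapes re-analyse to nearby coefficients: the
  # chord-length reparameterization perturbs them only slightly
  o <- generate_shape_family("beard", 1, jitter = 0.1, seed = 5)[[1]]
  eb <- efd_transform(o, 5)
  rb <- reconstruct_outline(eb, 5, n_points = 1024, align = FALSE)
  eb2 <- efd_transform(rb, 5)
  scale <- max(abs(eb$harmonics))
  expect_lt(max(abs(eb2$harmonics - eb$harmonics)) / scale, 0.05)
})

test_that("mean shapes commute with uniform scaling and ignore translation", {
  os <- generate_shape_family("drought", 3, jitter = 0.1, seed = 7)
  sets <- lapply(os, efd_transform, n_harmonics = 6)
  m1 <- mean_efd(sets)
  sets2 <- lapply(os, function(o)
    efd_transform(shape_outline(o$points * 2.5), 6))
  m2 <- mean_efd(sets2)
  expect_equal(m2$harmonics, m1$harmonics * 2.5, tolerance = 1e-9)
  # translation shifts only the offset, not the harmonics
  shifted <- efd_transform(shape_outline(sweep(os[[1]]$points, 2,
                                               c(40, -13), `+`)), 6)
  expect_equal(shifted$harmonics, sets[[1]]$harmonics, tolerance = 1e-9)
  expect_equal(unname(shifted$offset - sets[[1]]$offset), c(40, -13),
               tolerance = 1e-9)
})

test_that("the genotype mean-shape pipeline behaves on replicate masks", {
  base <- t_root_mask()
  out1 <- mean_shape_pipeline(list(base), kernel_px = 20)
  outN <- mean_shape_pipeline(rep(list(base), 5), kernel_px = 20)
  # identical replicates: the profile equals the single-mask profile
  expect_equal(outN$profile$points, out1$profile$points)
  expect_equal(outN$n_used, 5)

  # profiles of distinct families differ in descriptor space
  fu <- rasterize_shape(generate_shape_family("umbrella", 1, 0, 1)[[1]], 64)
  fd <- rasterize_shape(generate_shape_family("drought", 1, 0, 1)[[1]], 64)
  mu <- mean_shape_pipeline(list(make_mask(fu > 0)), kernel_px = 3)
  md <- mean_shape_pipeline(list(make_mask(fd > 0)), kernel_px = 3)
  dif <- mu$efd$harmonics - md$efd$harmonics
  expect_gt(sqrt(sum(dif^2)), 0)
  expect_error(mean_shape_pipeline(list()), "no usable")
})

test_that("rasterization fills the outline into a padded square", {
  o <- generate_shape_family("umbrella", 1, jitter = 0, seed = 1)[[1]]
  img <- rasterize_shape(o, 64)
  expect_equal(dim(img), c(64L, 64L))
  # filled area tracks the polygon area after the same scaling
  pts <- o$points
  s <- 62 / (max(pts[, 2]) - min(pts[, 2]))
  target <- abs(rootarch:::polygon_area_signed(pts[, 1], pts[, 2])) * s^2
  expect_lt(abs(sum(img) - target) / target, 0.02)
  # padding is width-only: the shape spans the full height
  rows <- which(rowSums(img) > 0)
  expect_lte(min(rows), 2); expect_gte(max(rows), 63)
  cols <- which(colSums(img) > 0)
  expect_gt(min(cols), 1)
})
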