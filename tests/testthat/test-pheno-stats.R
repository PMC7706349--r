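test_that("Tukey fences drop extreme observations per stratum", {
  tab <- data.frame(genotype = letters[1:5], replicate = 1, day = 9,
                    trait = "TRL", value = c(1, 2, 3, 4, 100))
  out <- remove_outliers(tab)
  expect_equal(out$value, c(1, 2, 3, 4))
  expect_equal(unname(attr(out, "n_removed")["TRL.9"]), 1L)

  # equal values: zero IQR, fences on the value, nothing removed
  tab2 <- transform(tab, value = 7)
  expect_equal(nrow(remove_outliers(tab2)), 5)

  # undersized stratum is skipped with a warning
  tab3 <- tab[1:2, ]
  expect_warning(out3 <- remove_outliers(tab3), "skipped")
  expect_equal(nrow(out3), 2)
})

test_that("REML fit recovers the balanced-design shrinkage form", {
  # no genetic signal: BLUPs collapse onto the grand mean
  cfg0 <- study_config(n_genotypes = 30, n_replicates = 8, sigma_g2 = 0,
                       sigma_b2 = 0, sigma_e2 = 1, mu = 2, seed = 3)
  f0 <- fit_mixed_model(simulate_phenotypes(cfg0)$table)
  expect_lt(max(abs(f0$blup - f0$vc$mu)), 0.15)

  # balanced one-way: blup deviation = shrinkage * (genotype mean - mean)
  cfg <- study_config(n_genotypes = 60, n_replicates = 14, sigma_g2 = 1,
                      sigma_b2 = 0, sigma_e2 = 2, n_blocks = 1, seed = 7)
  sim <- simulate_phenotypes(cfg)
  f <- fit_mixed_model(sim$table)
  gm <- tapply(sim$table$value, sim$table$genotype, mean)
  shrink <- f$vc$sigma_g2 / (f$vc$sigma_g2 + f$vc$sigma_e2 / 14)
  expect_equal(as.numeric((f$blup - f$vc$mu)[names(gm)]),
               as.numeric(shrink * (gm - mean(sim$table$value))),
               tolerance = 1e-6)

  # variance components are recovered across seeds
  est <- vapply(1:10, function(s) {
    cfg <- study_config(n_genotypes = 292, n_replicates = 14, sigma_g2 = 1,
                        sigma_b2 = 0.25, sigma_e2 = 2, seed = s)
    f <- fit_mixed_model(simulate_phenotypes(cfg)$table)
    c(f$vc$sigma_g2, f$vc$sigma_e2)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 1), 0.15)
  expect_lt(abs(mean(est[2, ]) - 2), 0.15 * 2)
})

test_that("entry-mean heritability follows its closed form", {
  expect_equal(heritability(list(sigma_g2 = 1, sigma_e2 = 0), 5), 1)
  expect_equal(heritability(list(sigma_g2 = 1, sigma_e2 = 14), 14), 0.5)
  h <- vapply(1:20, function(r)
    heritability(list(sigma_g2 = 1, sigma_e2 = 2), r), numeric(1))
  expect_true(all(diff(h) > 0))
  expect_true(is.na(heritability(list(sigma_g2 = 0, sigma_e2 = 0), 3)))
})

test_that("Tukey HSD flags separated groups and spares identical ones", {
  expect_equal(hsd_threshold(4, 9, 8, 8), 4 * sqrt(1.125))
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_false(any(tukey_hsd(g)$pairs$significant))
  set.seed(2)
  g2 <- list(a = rnorm(10, 0, 1), b = rnorm(10, 100, 1))
  out <- tukey_hsd(g2)
  expect_true(all(out$pairs$significant))
  # q agrees with the studentized-range distribution
  expect_equal(out$q, qtukey(0.95, 2, 18))
  expect_error(tukey_hsd(list(1:3)), "groups")
})

test_that("variance inflation factors match their definition", {
  # centred orthogonal predictors: all VIF = 1
  X <- unclass(stats::poly(1:20, 5))
  v <- vif(X)
  expect_equal(v$vif, rep(1, 5), tolerance = 1e-8)
  expect_false(any(v$flagged))

  # constructed R^2 = 0.8 gives VIF = 5
  set.seed(4)
  z <- rnorm(200); e <- rnorm(200)
  x1 <- z - mean(z)
  # noise orthogonalized against x1 (and the intercept) so R^2 is exact
  e_o <- residuals(lm(e ~ x1)); e_o <- e_o / sqrt(sum(e_o^2))
  x2 <- x1 * sqrt(0.8) + e_o * sqrt(0.2) * sqrt(sum(x1^2))
  v2 <- vif(cbind(x1, x2))
  expect_equal(v2$vif, c(5, 5), tolerance = 1e-6)

  # exact collinearity reports infinity and flags it
  v3 <- vif(cbind(a = 1:10, b = 1:10, c = rnorm(10)))
  expect_true(all(is.infinite(v3$vif[1:2])))
  expect_true(all(v3$flagged[1:2]))
})

test_that("trait correlation clustering groups duplicated traits first", {
  set.seed(6)
  B <- matrix(rnorm(292 * 5), 292, 5,
              dimnames = list(NULL, paste0("t", 1:5)))
  B <- cbind(B, t1_copy = B[, 1])
  out <- trait_correlation_cluster(B)
  expect_equal(out$cor["t1", "t1_copy"], 1)
  expect_true(all(diag(out$cor) == 1))
  expect_equal(out$cor, t(out$cor))
  # the duplicate pair is merged at height ~0
  expect_lt(out$hclust$height[1], 1e-9)
  # independent simulated traits stay near zero correlation
  r_off <- out$cor[upper.tri(out$cor)]
  expect_lt(mean(abs(r_off[r_off < 1 - 1e-12])), 0.15)

  Bz <- cbind(B, flat = 1)
  expect_warning(trait_correlation_cluster(Bz), "zero-variance")
})

test_that("phenotype clusters order labels by performance and are scale-free", {
  set.seed(8)
  hi <- matrix(rnorm(20 * 13, 5), 20, 13)
  lo <- matrix(rnorm(20 * 13, -5), 20, 13)
  B <- rbind(hi, lo)
  dimnames(B) <- list(sprintf("G%02d", 1:40), paste0("tr", 1:13))
  a <- phenotype_clusters(B, k = 2)
  expect_true(all(a[1:20] == "A"))
  expect_true(all(a[21:40] == "B"))
  # exhaustive partition
  expect_false(any(is.na(a)))
  # mean z decreases A -> B -> ...
  a8 <- phenotype_clusters(B, k = 8)
  mz <- attr(a8, "cluster_mean_z")
  expect_true(all(diff(mz) <= 1e-12))
  # multiplying a raw trait by 10 leaves the assignment unchanged
  B10 <- B; B10[, 3] <- B10[, 3] * 10
  expect_identical(as.character(phenotype_clusters(B10, k = 8)),
                   as.character(a8))
  expect_error(phenotype_clusters(B, k = 100), "exceeds")
})
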