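test_that("MAF filter removes monomorphic and rare markers at the boundary", {
  # 25 genotypes = 50 alleles, so allele counts map directly onto MAFs
  dos <- cbind(
    m_mono = rep(0L, 25),
    m_low = c(rep(1L, 2), rep(0L, 23)),    # MAF = 2/50 = 0.04
    m_edge = c(rep(1L, 3), rep(0L, 22)),   # MAF = 3/50 = 0.06
    m_common = c(rep(2L, 10), rep(0L, 15)))
  s <- snp_matrix(dos)
  kept <- filter_snps(s, maf_min = 0.05)
  expect_false("m_mono" %in% colnames(kept))
  expect_false("m_low" %in% colnames(kept))
  expect_true(all(c("m_edge", "m_common") %in% colnames(kept)))
  # exact boundary: MAF = 0.05 is retained ("below 0.05" removed)
  dos2 <- cbind(m_at = c(rep(1L, 2), rep(0L, 18)),  # 2/40 = 0.05
                m_ok = rep(c(0L, 2L), 10))
  expect_true("m_at" %in% colnames(filter_snps(snp_matrix(dos2))))

  # brute-force enumeration oracle on a toy matrix
  set.seed(1)
  toy <- matrix(sample(0:2, 5 * 30, TRUE, prob = c(0.7, 0.2, 0.1)), 5, 30)
  s3 <- snp_matrix(toy)
  maf_bf <- apply(toy, 2, function(col) min(mean(col) / 2, 1 - mean(col) / 2))
  keep_bf <- maf_bf >= 0.05 & maf_bf > 0
  expect_equal(ncol(filter_snps(s3)), sum(keep_bf))
})

test_that("allele-sharing distance matches hand counts", {
  s <- snp_matrix(rbind(a = c(0L, 1L, 2L), b = c(0L, 2L, 2L),
                        c = c(2L, 1L, 0L)))
  d <- nei_distance(s)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d, t(d))
  # shared fractions (1, 0.5, 1) -> distance 1 - 2.5/3
  expect_equal(d["a", "b"], 1 - 2.5 / 3, tolerance = 1e-12)
  # identical genotypes at distance 0, opposite homozygotes at 1
  s2 <- snp_matrix(rbind(x = c(0L, 2L, 0L), y = c(0L, 2L, 0L),
                         z = c(2L, 0L, 2L)))
  d2 <- nei_distance(s2)
  expect_equal(d2["x", "y"], 0)
  expect_equal(d2["x", "z"], 1)
})

test_that("Ward clustering on allele sharing recovers simulated structure", {
  g <- simulate_snp_matrix(list(n_markers = 800, n_subpops = 8, fst = 0.3,
                                maf_range = c(0.1, 0.5)), 36, seed = 5)
  snps <- filter_snps(g$snps)
  d <- nei_distance(snps)
  a <- genotype_clusters(d, k = 8)
  expect_gte(adjusted_rand(as.integer(a), g$truth$subpop), 0.9)
  expect_equal(length(a), 288L)
  expect_equal(levels(a), LETTERS[1:8])

  # k = n gives singletons; k > n errors
  small <- d[1:6, 1:6]
  expect_equal(length(unique(genotype_clusters(small, k = 6))), 6)
  expect_error(genotype_clusters(small, k = 7), "exceeds")

  # newick export round-trips through ape
  tf <- tempfile(fileext = ".nwk")
  genotype_clusters(small, k = 2, newick = tf)
  expect_equal(length(ape::read.tree(tf)$tip.label), 6)
})

test_that("BIC curve selection finds strong structure and flags weak", {
  hits <- vapply(1:10, function(s) {
    g <- simulate_snp_matrix(list(n_markers = 500, n_subpops = 8, fst = 0.3,
                                  maf_range = c(0.1, 0.5)), 12, seed = s)
    sc <- snp_pca(g$snps, n_pc = 10)$scores
    select_k_bic(sc, 12) == 8L
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  k <- select_k_bic(matrix(rnorm(100 * 4), 100), 8)
  expect_equal(length(attr(k, "bic")), 8)
  # a single Gaussian blob has no supported structure
  set.seed(9)
  k0 <- select_k_bic(matrix(rnorm(150 * 10), 150), 10)
  expect_lte(as.integer(k0), 2L)
  expect_true(attr(k0, "flat"))
  # degenerate input returns one cluster
  expect_equal(as.integer(select_k_bic(matrix(1, 20, 3), 5)), 1L)
})

test_that("dosage PCA matches an independent eigendecomposition", {
  set.seed(3)
  G <- matrix(sample(0:2, 20 * 50, TRUE), 20, 50)
  p <- snp_pca(snp_matrix(G))
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-12)
  # oracle: eigenvalues of the covariance of centred dosages
  ev <- eigen(stats::cov(G), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-10]
  expect_equal(p$var_frac[seq_along(ev)], ev / sum(ev), tolerance = 1e-8)
  # two distinct genotypes: one axis carries everything
  p2 <- snp_pca(snp_matrix(rbind(c(0L, 0L, 2L), c(2L, 2L, 0L))))
  expect_equal(p2$var_frac[1], 1, tolerance = 1e-12)
})

test_that("Hudson FST reproduces exact formula values and the simulation", {
  expect_equal(hudson_fst_freq(1, 0, 100, 100), 1)
  expect_equal(hudson_fst_freq(0.5, 0.5, 2, 2), -1)
  expect_error(hudson_fst_freq(0.5, 0.5, 1, 2), ">= 2")

  g <- simulate_snp_matrix(list(n_markers = 5000, n_subpops = 2, fst = 0.2,
                                maf_range = c(0.1, 0.5)), 50, seed = 3)
  f <- hudson_fst(g$snps, which(g$truth$subpop == 1),
                  which(g$truth$subpop == 2))
  expect_lt(abs(f$mean_fst - 0.2), 0.02)

  # a homogeneous group split at random centres on zero
  h <- simulate_snp_matrix(list(n_markers = 5000, n_subpops = 1, fst = 0.1,
                                maf_range = c(0.1, 0.5)), 60, seed = 4)
  set.seed(10)
  null_f <- vapply(1:20, function(i) {
    idx <- sample(60, 30)
    hudson_fst(h$snps, idx, setdiff(1:60, idx))$mean_fst
  }, numeric(1))
  expect_lt(abs(mean(null_f)), 0.01)
})

test_that("between-cluster FST matrix is symmetric with zero diagonal", {
  g <- simulate_snp_matrix(list(n_markers = 500, n_subpops = 3, fst = 0.25,
                                maf_range = c(0.1, 0.5)), 20, seed = 6)
  a <- factor(LETTERS[g$truth$subpop])
  names(a) <- rownames(g$snps)
  M <- fst_between_clusters(g$snps, a)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), c(0, 0, 0))
  expect_true(all(M[lower.tri(M)] > 0.1))
})
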