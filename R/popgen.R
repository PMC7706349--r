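#' Filter a SNP matrix on minor allele frequency
#'
#' Removes monomorphic markers and markers whose minor allele frequency
#' (computed from non-missing dosages) falls below `maf_min`. Markers at
#' exactly the threshold are retained.
#'
#' @param snps a [snp_matrix()].
#' @param maf_min minimum retained MAF (default 0.05).
#' @return the filtered [snp_matrix()], with attribute `n_removed`.
#' @export
filter_snps <- function(snps, maf_min = 0.05) {
  maf <- snp_maf(snps)
  keep <- !is.na(maf) & maf >= maf_min & maf > 0
  if (!any(keep)) stop_param("all markers removed by the MAF filter")
  out <- snp_matrix(unclass(snps)[, keep, drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Allele-sharing genetic distance between genotypes
#'
#' For each pair of genotypes the similarity is the fraction of alleles
#' shared across markers where both calls are present:
#' s(i, j) = 1 - mean(|d_i - d_j|) / 2 on the 0/1/2 dosage scale. The
#' distance is 1 - s. Identical genotypes have distance 0; opposite
#' homozygotes at every marker have distance 1. The measure is not
#' guaranteed to satisfy the triangle inequality.
#'
#' @param snps a [snp_matrix()].
#' @return a symmetric distance matrix with zero diagonal.
#' @export
nei_distance <- function(snps) {
  G <- unclass(snps)
  n <- nrow(G)
  if (n < 2) stop_param("need at least two genotypes")
  if (!anyNA(G)) {
    # sum |di - dj| via indicator cross-products: |a - b| over {0,1,2}
    I0 <- (G == 0L) + 0; I1 <- (G == 1L) + 0; I2 <- (G == 2L) + 0
    cross01 <- I0 %*% t(I1); cross12 <- I1 %*% t(I2); cross02 <- I0 %*% t(I2)
    sumabs <- cross01 + t(cross01) + cross12 + t(cross12) +
      2 * (cross02 + t(cross02))
    d <- sumabs / (2 * ncol(G))
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ok <- !is.na(G[i, ]) & !is.na(G[j, ])
      if (!any(ok)) stop_param("genotypes %d and %d share no markers", i, j)
      d[i, j] <- d[j, i] <- mean(abs(G[i, ok] - G[j, ok])) / 2
    }
  }
  dimnames(d) <- list(rownames(G), rownames(G))
  diag(d) <- 0
  d
}

#' Genotype-based clusters from a genetic distance matrix
#'
#' Ward minimum-variance hierarchical clustering of the distance matrix,
#' cut into `k` groups. Cluster labels "A", "B", ... are assigned in
#' dendrogram left-to-right order, so relabelling is deterministic and the
#' cross-tabulations downstream are label-invariant.
#'
#' @param dist symmetric distance matrix (or `dist`).
#' @param k number of clusters (default 8).
#' @param newick optional path; when given, the dendrogram is exported as a
#'   newick tree.
#' @return a `cluster_assignment`: named factor of labels with attributes
#'   `method` ("GBC") and `hclust` (the tree).
#' @export
genotype_clusters <- function(dist, k = 8, newick = NULL) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  if (k > n) stop_param("k = %d exceeds the %d genotypes", k, n)
  hc <- stats::hclust(d, method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  assign <- relabel_by_dendrogram(grp, hc, k)
  names(assign) <- names(grp)
  if (!is.null(newick)) {
    ape::write.tree(ape::as.phylo(hc), file = newick)
  }
  structure(assign, method = "GBC", hclust = hc,
            class = c("cluster_assignment", "factor"))
}

relabel_by_dendrogram <- function(grp, hc, k) {
  ord_first <- vapply(seq_len(k), function(g) min(match(which(grp == g), hc$order)),
                      numeric(1))
  new_lab <- LETTERS[rank(ord_first, ties.method = "first")]
  factor(new_lab[grp], levels = LETTERS[seq_len(k)])
}

#' Principal component analysis of SNP dosages
#'
#' Missing dosages are mean-imputed per marker, columns are centred (not
#' scaled), and the eigendecomposition is taken via [stats::prcomp()].
#'
#' @param snps a [snp_matrix()] (or plain numeric matrix).
#' @param n_pc number of score columns to return (default all).
#' @return list with `scores`, `var_frac` (per-PC fraction of total
#'   variance, summing to 1) and the `prcomp` fit.
#' @export
snp_pca <- function(snps, n_pc = NULL) {
  G <- unclass(snps)
  if (nrow(G) < 2 || ncol(G) < 2) stop_param("need >= 2 genotypes and markers")
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  p <- stats::prcomp(G, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  if (tot <= 0) stop_param("zero total variance")
  vf <- p$sdev^2 / tot
  k <- if (is.null(n_pc)) ncol(p$x) else min(n_pc, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE], var_frac = vf, fit = p)
}

#' Select the number of clusters by the BIC inflection point
#'
#' Runs k-means for k = 1..k_max on the leading principal-component scores
#' and scores each solution with a spherical-Gaussian BIC,
#' BIC(k) = n d log(RSS / (n d)) + k (d + 1) log(n) (lower is better).
#' Following the iterative k-means procedure, the returned k is the
#' inflection point of the BIC curve: the k maximising the second central
#' difference BIC(k-1) - 2 BIC(k) + BIC(k+1). If the curve is minimised at
#' k = 1 (no clustering supported) 1 is returned and the curve is flagged
#' flat.
#'
#' @param scores numeric matrix of observations (e.g. PCA scores) or a
#'   [snp_matrix()] (then the top 10 PCs are used).
#' @param k_max largest k to try (>= 2).
#' @param nstart k-means restarts per k.
#' @return integer k, with attributes `bic` (the curve, length k_max) and
#'   `flat` (logical).
#' @export
select_k_bic <- function(scores, k_max = 12, nstart = 10) {
  if (k_max < 2) stop_param("k_max must be >= 2")
  if (inherits(scores, "snp_matrix")) scores <- snp_pca(scores, n_pc = 10)$scores
  X <- as.matrix(scores)
  n <- nrow(X); d <- ncol(X)
  if (all(apply(X, 2, stats::var) == 0)) {
    return(structure(1L, bic = rep(NA_real_, k_max), flat = TRUE))
  }
  rss <- numeric(k_max)
  rss[1] <- sum(scale(X, scale = FALSE)^2)
  for (k in 2:k_max) {
    km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 50)
    rss[k] <- km$tot.withinss
  }
  rss <- pmax(rss, 1e-12)
  bic <- n * d * log(rss / (n * d)) + seq_len(k_max) * (d + 1) * log(n)
  # flat curve: no k even halves the within-cluster variance, so the
  # elbow is noise-driven rather than structure-driven
  flat <- rss[k_max] / rss[1] > 0.5
  if (which.min(bic) == 1L) return(structure(1L, bic = bic, flat = flat))
  ks <- 2:(k_max - 1)
  d2 <- bic[ks - 1] - 2 * bic[ks] + bic[ks + 1]
  structure(as.integer(ks[which.max(d2)]), bic = bic, flat = flat)
}

#' Hudson FST between two groups of genotypes
#'
#' Per-marker Hudson estimator with finite-sample bias correction,
#' \deqn{F_{ST} = \frac{(\tilde p_1 - \tilde p_2)^2
#'   - \tilde p_1 (1 - \tilde p_1)/(n_1 - 1)
#'   - \tilde p_2 (1 - \tilde p_2)/(n_2 - 1)}
#'   {\tilde p_1 (1 - \tilde p_2) + \tilde p_2 (1 - \tilde p_1)}}
#' where \eqn{\tilde p_i} is the sample allele frequency and \eqn{n_i} the
#' number of sampled alleles (2 x individuals for diploid dosages) in
#' group i. The headline mean is the ratio of the mean numerator to the
#' mean denominator across markers, which is robust to near-zero
#' denominators; the simple average of per-marker ratios is also reported.
#' Markers with zero denominator are excluded.
#'
#' @param snps a [snp_matrix()].
#' @param groupA,groupB row names or indices of the two groups (each >= 2
#'   genotypes).
#' @return list with `fst_per_marker`, `mean_fst` (ratio of averages) and
#'   `mean_fst_avg` (average of ratios).
#' @export
hudson_fst <- function(snps, groupA, groupB) {
  G <- unclass(snps)
  A <- G[groupA, , drop = FALSE]; B <- G[groupB, , drop = FALSE]
  if (nrow(A) < 2 || nrow(B) < 2) stop_param("both groups need >= 2 genotypes")
  nA <- 2 * colSums(!is.na(A)); nB <- 2 * colSums(!is.na(B))
  p1 <- colSums(A, na.rm = TRUE) / nA
  p2 <- colSums(B, na.rm = TRUE) / nB
  comp <- hudson_fst_components(p1, p2, nA, nB)
  ok <- is.finite(comp$num) & is.finite(comp$den) & comp$den > 0
  fst <- comp$num[ok] / comp$den[ok]
  list(fst_per_marker = fst,
       mean_fst = mean(comp$num[ok]) / mean(comp$den[ok]),
       mean_fst_avg = mean(fst))
}

#' Hudson FST from allele frequencies
#'
#' The bare estimator for one marker (or a vector of markers) given sample
#' allele frequencies and allele sample sizes; see [hudson_fst()].
#'
#' @param p1,p2 sample allele frequencies.
#' @param n1,n2 allele sample sizes (>= 2).
#' @return numeric FST value(s).
#' @export
hudson_fst_freq <- function(p1, p2, n1, n2) {
  if (any(c(n1, n2) < 2)) stop_param("allele sample sizes must be >= 2")
  comp <- hudson_fst_components(p1, p2, n1, n2)
  comp$num / comp$den
}

hudson_fst_components <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Pairwise mean FST between clusters
#'
#' Computes the Hudson mean FST for every pair of clusters in an
#' assignment, giving the lower-triangle matrix used to summarise genetic
#' differentiation between genotype-based clusters.
#'
#' @param snps a [snp_matrix()].
#' @param assignment factor of cluster labels named by genotype.
#' @return symmetric matrix of mean FST values (NA where a cluster has
#'   fewer than 2 members).
#' @export
fst_between_clusters <- function(snps, assignment) {
  labs <- levels(factor(assignment))
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_len(i - 1)) {
    gi <- names(assignment)[assignment == labs[i]]
    gj <- names(assignment)[assignment == labs[j]]
    if (length(gi) >= 2 && length(gj) >= 2)
      out[i, j] <- out[j, i] <- hudson_fst(snps, gi, gj)$mean_fst
  }
  diag(out) <- 0
  out
}
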