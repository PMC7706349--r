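#' Remove outliers by Tukey's boxplot rule
#'
#' Within each (trait, day) stratum, observations outside
#' [Q1 - 1.5 IQR, Q3 + 1.5 IQR] are dropped. Fences are computed across
#' all genotypes jointly: per-genotype strata of a dozen replicates make
#' quartiles too unstable to fence on.
#'
#' @param table long TraitTable with columns trait, day, value.
#' @param k fence multiplier (default 1.5).
#' @return the filtered table; attribute `n_removed` gives the per-stratum
#'   removal counts.
#' @export
remove_outliers <- function(table, k = 1.5) {
  strata <- interaction(table$trait, table$day, drop = TRUE)
  keep <- rep(TRUE, nrow(table))
  removed <- integer(0)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    v <- table$value[idx]
    if (sum(!is.na(v)) < 4) {
      warning("stratum ", s, " too small for fences; skipped")
      next
    }
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    bad <- !is.na(v) & (v < q[1] - k * iqr | v > q[2] + k * iqr)
    keep[idx[bad]] <- FALSE
    removed[s] <- sum(bad)
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "n_removed") <- removed
  out
}

#' Fit the replicated random-effects model for one trait and day
#'
#' REML fit of y = mu + genotype + block + residual with all factors
#' random, via lme4. The block term is included only when the data contain
#' at least two blocks. In a balanced design the genotype BLUPs equal the
#' classical shrinkage form
#' \deqn{\hat g_i = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2 / r}
#'   (\bar y_i - \bar y)}
#'
#' @param table long TraitTable (columns genotype, value and optionally
#'   block, trait, day).
#' @param trait,day optional filters applied to the table first.
#' @return list with `vc` (mu, sigma_g2, sigma_b2, sigma_e2), `blup`
#'   (named vector of conditional genotype means mu + g_hat), `fit` (the
#'   merMod object) and `n_rep` (mean replicates per genotype).
#' @export
fit_mixed_model <- function(table, trait = NULL, day = NULL) {
  if (!is.null(trait)) table <- table[table$trait == trait, , drop = FALSE]
  if (!is.null(day)) table <- table[table$day == day, , drop = FALSE]
  table <- table[!is.na(table$value), , drop = FALSE]
  if (length(unique(table$genotype)) < 2)
    stop_param("need >= 2 genotypes")
  has_block <- !is.null(table$block) && length(unique(table$block)) >= 2
  form <- if (has_block) value ~ (1 | genotype) + (1 | block)
          else value ~ (1 | genotype)
  fit <- lme4::lmer(form, data = table, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g) { v <- vc$vcov[vc$grp == g]; if (length(v)) v else 0 }
  mu <- unname(lme4::fixef(fit)[1])
  g_hat <- lme4::ranef(fit)$genotype[, 1]
  names(g_hat) <- rownames(lme4::ranef(fit)$genotype)
  list(vc = list(mu = mu,
                 sigma_g2 = get_vc("genotype"),
                 sigma_b2 = get_vc("block"),
                 sigma_e2 = get_vc("Residual")),
       blup = mu + g_hat,
       fit = fit,
       n_rep = nrow(table) / length(unique(table$genotype)))
}

#' Entry-mean broad-sense heritability
#'
#' \deqn{H^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2 / r}}
#' with r the number of replications.
#'
#' @param vc list with sigma_g2 and sigma_e2 (as from [fit_mixed_model()]).
#' @param r number of replications (>= 1).
#' @return H-squared in [0, 1], or NA when the denominator is zero.
#' @export
heritability <- function(vc, r) {
  stopifnot(r >= 1)
  den <- vc$sigma_g2 + vc$sigma_e2 / r
  if (den <= 0) return(NA_real_)
  vc$sigma_g2 / den
}

#' Tukey's honestly significant difference test
#'
#' For groups a and a' the threshold is
#' \deqn{HSD = q \sqrt{\frac{MSE}{2}\left(\frac{1}{S_a} +
#'   \frac{1}{S_{a'}}\right)}}
#' with q the studentized-range quantile at `alpha` for k groups and
#' N - k error degrees of freedom and MSE the one-way ANOVA mean squared
#' error. Pairs whose absolute mean difference exceeds their HSD are
#' flagged significant.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @param alpha familywise error rate (default 0.05).
#' @return list with `q`, `mse`, `df`, and `pairs` (data.frame of group
#'   pair, mean difference, hsd threshold, significance flag).
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2 || any(lengths(groups) < 2))
    stop_param("need >= 2 groups with >= 2 observations each")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  sizes <- lengths(groups)
  N <- sum(sizes)
  means <- vapply(groups, mean, numeric(1))
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    (N - k)
  q <- stats::qtukey(1 - alpha, nmeans = k, df = N - k)
  pairs <- t(utils::combn(k, 2))
  hsd <- q * sqrt(mse / 2 * (1 / sizes[pairs[, 1]] + 1 / sizes[pairs[, 2]]))
  diffs <- means[pairs[, 1]] - means[pairs[, 2]]
  list(q = q, mse = mse, df = N - k,
       pairs = data.frame(a = names(groups)[pairs[, 1]],
                          b = names(groups)[pairs[, 2]],
                          diff = unname(diffs), hsd = unname(hsd),
                          significant = unname(abs(diffs) > hsd)))
}

#' Tukey HSD threshold from summary statistics
#'
#' @param q studentized-range statistic.
#' @param mse mean squared error.
#' @param s_a,s_b the two group sizes.
#' @return the HSD threshold.
#' @export
hsd_threshold <- function(q, mse, s_a, s_b) {
  q * sqrt(mse / 2 * (1 / s_a + 1 / s_b))
}

#' Variance inflation factors
#'
#' For each predictor j, R_j^2 is the coefficient of determination of the
#' regression of predictor j on all others and VIF_j = 1 / (1 - R_j^2).
#' Predictors with VIF above `threshold` (default 5) are flagged; exact
#' collinearity yields VIF = Inf.
#'
#' @param predictors numeric matrix/data.frame, more rows than columns.
#' @param threshold flag level (default 5).
#' @return data.frame with columns predictor, r2, vif, flagged.
#' @export
vif <- function(predictors, threshold = 5) {
  X <- as.matrix(predictors)
  if (ncol(X) < 2) stop_param("need >= 2 predictors")
  if (nrow(X) <= ncol(X)) stop_param("need more rows than predictors")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  r2 <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    if (sst == 0) return(NA_real_)
    1 - ssr / sst
  }, numeric(1))
  v <- ifelse(r2 >= 1 - 1e-12, Inf, 1 / (1 - r2))
  data.frame(predictor = colnames(X), r2 = r2, vif = v,
             flagged = !is.na(v) & v > threshold)
}

#' Correlation structure of traits across genotypes
#'
#' Pairwise Pearson correlations of trait BLUPs over genotypes
#' (pairwise-complete), followed by complete-linkage hierarchical
#' clustering of traits on the distance 1 - r. Also reports the cumulative
#' correlation intensity, the sum of |r| over distinct trait pairs, used to
#' compare how tightly traits co-vary across imaging days.
#'
#' @param blups genotype x trait matrix of BLUP values.
#' @param min_pairs minimum genotypes per pair; sparser pairs give NA.
#' @return list with `cor` (trait correlation matrix), `hclust` (trait
#'   dendrogram) and `intensity`.
#' @export
trait_correlation_cluster <- function(blups, min_pairs = 10) {
  B <- as.matrix(blups)
  sds <- apply(B, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    warning("dropping zero-variance traits: ",
            paste(colnames(B)[which(sds == 0)], collapse = ", "))
    B <- B[, sds > 0, drop = FALSE]
  }
  if (ncol(B) < 3) stop_param("need >= 3 traits with variance")
  r <- stats::cor(B, use = "pairwise.complete.obs")
  n_pair <- crossprod(!is.na(B))
  r[n_pair < min_pairs] <- NA
  diag(r) <- 1
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "complete")
  list(cor = r, hclust = hc,
       intensity = sum(abs(r[upper.tri(r)]), na.rm = TRUE))
}

#' Phenotype-based clusters (PBC)
#'
#' Genotypes are clustered on their z-scored BLUPs for the 13 ideotype
#' traits using complete-linkage hierarchical clustering of Euclidean
#' distances, cut at k groups. Clusters are relabelled "A"..."H" by
#' decreasing mean z-score across all traits, so cluster A holds the
#' high-performing genotypes. No trait is sign-flipped before averaging.
#'
#' @param blups genotype x trait matrix (rownames = genotypes) holding the
#'   13 ideotype traits.
#' @param traits columns to use (default all columns).
#' @param k number of clusters (default 8).
#' @return a `cluster_assignment` factor named by genotype, with attributes
#'   `method` ("PBC"), `hclust`, and `cluster_mean_z`.
#' @export
phenotype_clusters <- function(blups, traits = colnames(blups), k = 8) {
  B <- as.matrix(blups)[, traits, drop = FALSE]
  if (k > nrow(B)) stop_param("k exceeds the number of genotypes")
  Z <- scale(B)
  hc <- stats::hclust(stats::dist(Z), method = "complete")
  grp <- stats::cutree(hc, k = k)
  assign <- relabel_by_meanz(grp, Z, k)
  names(assign) <- rownames(B)
  structure(assign, method = "PBC", hclust = hc,
            cluster_mean_z = attr(assign, "cluster_mean_z"),
            class = c("cluster_assignment", "factor"))
}

relabel_by_meanz <- function(grp, Z, k, sizes_break_ties = FALSE) {
  mz <- vapply(seq_len(k), function(g) mean(Z[grp == g, , drop = FALSE]),
               numeric(1))
  ord <- order(-mz)
  if (sizes_break_ties) {
    sz <- tabulate(grp, k)
    ord <- order(-mz, -sz)
  }
  new_lab <- character(k)
  new_lab[ord] <- LETTERS[seq_len(k)]
  out <- factor(new_lab[grp], levels = LETTERS[seq_len(k)])
  attr(out, "cluster_mean_z") <- stats::setNames(mz[ord], LETTERS[seq_len(k)])
  out
}

#' BLUP table for a multi-trait panel
#'
#' Fits [fit_mixed_model()] per trait at one day and assembles the genotype
#' x trait matrix of BLUPs, plus variance components and heritability per
#' trait.
#'
#' @param table long TraitTable.
#' @param day imaging day to analyse.
#' @param r replications for the heritability denominator (default: mean
#'   replicates observed).
#' @return list with `blups` (matrix), `vc` (per-trait list) and `h2`
#'   (named vector).
#' @export
blup_table <- function(table, day, r = NULL) {
  traits <- unique(table$trait)
  fits <- lapply(traits, function(tr) fit_mixed_model(table, trait = tr, day = day))
  names(fits) <- traits
  genos <- sort(unique(table$genotype))
  B <- matrix(NA_real_, length(genos), length(traits),
              dimnames = list(genos, traits))
  for (tr in traits) B[names(fits[[tr]]$blup), tr] <- fits[[tr]]$blup
  h2 <- vapply(traits, function(tr) {
    heritability(fits[[tr]]$vc, if (is.null(r)) fits[[tr]]$n_rep else r)
  }, numeric(1))
  list(blups = B, vc = lapply(fits, `[[`, "vc"), h2 = h2)
}
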