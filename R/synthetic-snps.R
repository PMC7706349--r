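#' Simulate a structured SNP dosage matrix
#'
#' Draws a genotype-by-marker dosage matrix under the Balding--Nichols
#' model of population differentiation. For each marker an ancestral
#' frequency p is drawn uniformly from `maf_range`; each of K
#' subpopulations then receives its own frequency from
#' Beta(p (1 - F) / F, (1 - p)(1 - F) / F), whose mean is p and whose
#' variance is F p (1 - p). Individual dosages are Binomial(2, p_subpop).
#'
#' @param snp_params list with `n_markers`, `n_subpops` (K), `fst`
#'   (differentiation F in [0, 1)) and `maf_range`.
#' @param n_per_subpop individuals per subpopulation (scalar or length-K).
#' @param seed RNG seed.
#' @return list with `snps` (a `snp_matrix`: integer matrix genotypes x
#'   markers, dimnames set) and `truth` (subpopulation labels and the
#'   per-subpopulation frequency matrix).
#' @export
simulate_snp_matrix <- function(snp_params, n_per_subpop, seed = 1) {
  K <- snp_params$n_subpops; Fv <- snp_params$fst; m <- snp_params$n_markers
  if (K < 1 || m < 1) stop_param("need n_subpops >= 1 and n_markers >= 1")
  if (Fv < 0 || Fv >= 1) stop_param("fst must lie in [0, 1)")
  n_per <- rep_len(n_per_subpop, K)
  n <- sum(n_per)
  with_seed(derive_seed(seed, "snp_matrix"), {
    p_anc <- stats::runif(m, snp_params$maf_range[1], snp_params$maf_range[2])
    # subpop frequencies; at F ~ 0 the Beta collapses onto the ancestral p
    p_sub <- if (Fv < 1e-12) {
      matrix(rep(p_anc, each = K), nrow = K)
    } else {
      matrix(stats::rbeta(K * m,
                          rep(p_anc, each = K) * (1 - Fv) / Fv,
                          rep(1 - p_anc, each = K) * (1 - Fv) / Fv),
             nrow = K)
    }
    pop <- rep(seq_len(K), times = n_per)
    dos <- matrix(stats::rbinom(n * m, 2L, p_sub[pop, , drop = FALSE]),
                  nrow = n, ncol = m)
    dimnames(dos) <- list(sprintf("G%03d", seq_len(n)),
                          sprintf("M%05d", seq_len(m)))
    list(snps = snp_matrix(dos),
         truth = list(subpop = stats::setNames(pop, rownames(dos)),
                      p_ancestral = p_anc, p_subpop = p_sub))
  })
}

#' SNP dosage matrix container
#'
#' Validates and wraps a genotype-by-marker matrix of biallelic dosages
#' coded 0/1/2 (heterozygote = 1), NA for missing calls.
#'
#' @param dosages numeric/integer matrix, genotypes in rows.
#' @return the matrix with class `snp_matrix`.
#' @export
snp_matrix <- function(dosages) {
  dosages <- as.matrix(dosages)
  ok <- dosages %in% c(0L, 1L, 2L) | is.na(dosages)
  if (!all(ok)) stop_param("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("G%03d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("M%05d", seq_len(ncol(dosages)))
  storage.mode(dosages) <- "integer"
  class(dosages) <- c("snp_matrix", class(matrix()))
  dosages
}

#' Per-marker minor allele frequency
#'
#' @param snps a [snp_matrix()].
#' @return numeric vector of MAFs in [0, 0.5], computed from non-missing
#'   dosages.
#' @export
snp_maf <- function(snps) {
  p <- colMeans(unclass(snps), na.rm = TRUE) / 2
  pmin(p, 1 - p)
}
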