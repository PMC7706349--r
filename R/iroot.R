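#' Informative-root (iRoot) ideotype definitions
#'
#' The five literature-derived ideotype categories and their constituent
#' traits with favorability directions (`+` higher favorable, `-` lower
#' favorable):
#' \itemize{
#'   \item nutrient_foraging: WID+, TRL_GR+, TRLUpper+ -- wide, fast-growing
#'     systems concentrating length in the topsoil.
#'   \item drought_tolerant: PRL+, LRA-, SOL2-, TRL_GR+ -- the "steep, deep
#'     and cheap" paradigm: long primary root, steep laterals, low spatial
#'     density.
#'   \item umbrella: PRL+, WID+, CVA+, LRA+, LED+ -- deep taproot plus
#'     shallow, wide laterals.
#'   \item beard: TRL+, WID-, LRB+, LRA-, SOL2-, LED- -- dense, narrow,
#'     uniformly distributed fibrous systems.
#'   \item maximum: TRL+, PRL+, WID+, CVA+, LRB+, VOL+, RHZO+,
#'     Root_weight+ -- maximal overall growth.
#' }
#' Directions follow the published direction markers; they can be
#' overridden by editing the returned list before scoring.
#'
#' @return named list of data.frames with columns `trait`, `direction`
#'   (one of "higher_favorable"/"lower_favorable").
#' @export
iroot_categories <- function() {
  def <- function(...) {
    x <- c(...)
    data.frame(trait = names(x),
               direction = ifelse(x == "+", "higher_favorable",
                                  "lower_favorable"),
               stringsAsFactors = FALSE)
  }
  list(
    nutrient_foraging = def(WID = "+", TRL_GR = "+", TRLUpper = "+"),
    drought_tolerant = def(PRL = "+", LRA = "-", SOL2 = "-", TRL_GR = "+"),
    umbrella = def(PRL = "+", WID = "+", CVA = "+", LRA = "+", LED = "+"),
    beard = def(TRL = "+", WID = "-", LRB = "+", LRA = "-", SOL2 = "-",
                LED = "-"),
    maximum = def(TRL = "+", PRL = "+", WID = "+", CVA = "+", LRB = "+",
                  VOL = "+", RHZO = "+", Root_weight = "+"))
}

#' Direction-aware genotype ranking for one trait
#'
#' Under `higher_favorable` the largest value receives rank 1; under
#' `lower_favorable` the smallest does. Ties receive the average of the
#' tied positions. Missing values are ranked last (worst), keeping the
#' panel intact.
#'
#' @param values named numeric vector (one value per genotype).
#' @param direction "higher_favorable" or "lower_favorable".
#' @return numeric ranks, same names as `values`.
#' @export
rank_trait <- function(values, direction = "higher_favorable") {
  direction <- match.arg(direction, c("higher_favorable", "lower_favorable"))
  if (all(is.na(values))) stop_param("all values missing")
  x <- if (direction == "higher_favorable") -values else values
  r <- rank(x, ties.method = "average", na.last = "keep")
  n_ok <- sum(!is.na(r))
  r[is.na(r)] <- n_ok + (length(r) - n_ok + 1) / 2
  r
}

#' Score genotypes against the iRoot categories
#'
#' Each category's score for a genotype is the sum of its direction-aware
#' trait ranks; genotypes are then ranked by ascending score (lowest sum =
#' best = rank 1, ties averaged). Scoring is conventionally done on BLUPs
#' at 9 days after germination, when lateral roots are developed but the
#' fastest genotypes have not yet outgrown the growth pouch.
#'
#' @param blups genotype x trait matrix of BLUPs (rownames = genotypes).
#' @param categories category definitions (default [iroot_categories()]).
#' @return list with `trait_ranks` (genotype x trait), `scores` (genotype x
#'   category rank-sum), `ranks` (genotype x category rank) and `top`
#'   (function(category, n) returning the best genotypes).
#' @export
score_categories <- function(blups, categories = iroot_categories()) {
  B <- as.matrix(blups)
  needed <- unique(unlist(lapply(categories, `[[`, "trait")))
  missing <- setdiff(needed, colnames(B))
  if (length(missing))
    stop_param("missing trait column(s): %s", paste(missing, collapse = ", "))
  # a trait may appear with both directions across categories; rank per use
  scores <- sapply(categories, function(cat) {
    rowSums(sapply(seq_len(nrow(cat)), function(i) {
      rank_trait(B[, cat$trait[i]], cat$direction[i])
    }))
  })
  rownames(scores) <- rownames(B)
  ranks <- apply(scores, 2, rank, ties.method = "average")
  trait_ranks <- sapply(needed, function(tr) rank_trait(B[, tr]))
  rownames(trait_ranks) <- rownames(B)
  list(trait_ranks = trait_ranks, scores = scores, ranks = ranks,
       top = function(category, n = 10) {
         ord <- order(ranks[, category])
         rownames(ranks)[ord][seq_len(n)]
       })
}

#' Cross-tabulate clusters against metadata, traits, and iRoot ranks
#'
#' Builds the summary bundle comparing genotype-, phenotype- and
#' shape-based cluster assignments: per-cluster counts of each metadata
#' level, per-cluster mean trait BLUPs, per-cluster mean iRoot category
#' rank, the mean PBC value per cluster (PBC "A" = 1 ... "H" = 8), and the
#' per-country mean PBC.
#'
#' @param assignments named list of `cluster_assignment` factors (each
#'   named by genotype), e.g. list(GBC = ..., PBC = ..., SBC = ...).
#' @param ranks genotype x category iRoot rank matrix (from
#'   [score_categories()]), or NULL.
#' @param metadata data.frame with rownames = genotypes and columns such as
#'   country, maturity_group, growth_habit, diversity; or NULL.
#' @param blups genotype x trait BLUP matrix for per-cluster trait means,
#'   or NULL.
#' @return nested list: one entry per assignment with `counts`,
#'   `trait_means`, `iroot_mean_rank`, `pbc_mean`; plus `country_pbc_mean`
#'   when both metadata and a PBC assignment are present.
#' @export
cross_tabulate <- function(assignments, ranks = NULL, metadata = NULL,
                           blups = NULL) {
  stopifnot(is.list(assignments), length(assignments) >= 1)
  genos <- names(assignments[[1]])
  for (a in assignments) {
    if (!setequal(names(a), genos))
      stop_param("assignments disagree on genotype keys: missing %s",
                 paste(utils::head(setdiff(genos, names(a))), collapse = ", "))
  }
  if (!is.null(metadata) && !all(genos %in% rownames(metadata)))
    stop_param("metadata missing genotypes: %s",
               paste(utils::head(setdiff(genos, rownames(metadata))), collapse = ", "))
  pbc <- assignments[["PBC"]]
  out <- lapply(assignments, function(a) {
    a <- a[genos]
    res <- list()
    if (!is.null(metadata)) {
      res$counts <- lapply(colnames(metadata), function(col) {
        table(metadata[genos, col], a)
      })
      names(res$counts) <- colnames(metadata)
    }
    if (!is.null(blups)) {
      res$trait_means <- t(sapply(levels(a), function(l) {
        colMeans(blups[genos[a == l], , drop = FALSE], na.rm = TRUE)
      }))
    }
    if (!is.null(ranks)) {
      res$iroot_mean_rank <- t(sapply(levels(a), function(l) {
        colMeans(ranks[genos[a == l], , drop = FALSE])
      }))
    }
    if (!is.null(pbc)) {
      pbc_num <- as.integer(pbc[genos])
      res$pbc_mean <- vapply(levels(a), function(l) mean(pbc_num[a == l]),
                             numeric(1))
    }
    res
  })
  if (!is.null(pbc) && !is.null(metadata) && "country" %in% colnames(metadata)) {
    pbc_num <- as.integer(pbc[genos])
    out$country_pbc_mean <- tapply(pbc_num, metadata[genos, "country"], mean)
  }
  out
}
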