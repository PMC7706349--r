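#' Construct a synthetic study configuration
#'
#' Bundles every generative parameter of the synthetic study: the
#' random-effects structure of the replicated phenotyping experiment
#' (grand mean, genotypic / block / residual variances), the per-genotype
#' root growth parameters used by the image renderer, the population
#' structure of the SNP generator, and the raster scale.
#'
#' The defaults mirror a growth-chamber seedling study: 14 replicates per
#' genotype imaged at 6, 9 and 12 days after germination, with replicates
#' assigned round-robin to blocks (growth chambers).
#'
#' @param n_genotypes number of genotypes in the panel.
#' @param n_replicates replicates per genotype (default 14).
#' @param days imaging days, strictly increasing (default c(6, 9, 12)).
#' @param mu grand mean of the simulated trait.
#' @param sigma_g2,sigma_b2,sigma_e2 genotypic, block and residual variance
#'   components (trait units squared); all must be non-negative.
#' @param n_blocks number of blocks (growth chambers).
#' @param root_params list of per-genotype growth parameters: elongation
#'   rate (cm/day), branch intensity (branches/cm), branch angle mean/sd
#'   (degrees from vertical), tortuosity (radians sd per step), and stroke
#'   diameter (cm).
#' @param snp_params list with n_markers, n_subpops, fst (differentiation F)
#'   and maf_range (ancestral allele-frequency window).
#' @param px_per_cm raster scale of rendered images.
#' @param seed master RNG seed.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_genotypes = 292, n_replicates = 14,
                         days = c(6, 9, 12), mu = 0,
                         sigma_g2 = 1, sigma_b2 = 0.25, sigma_e2 = 2,
                         n_blocks = 4,
                         root_params = list(elongation_rate = 4.0,
                                            branch_intensity = 2.0,
                                            branch_angle_mean = 70,
                                            branch_angle_sd = 10,
                                            tortuosity = 0.03,
                                            diameter_cm = 0.1),
                         snp_params = list(n_markers = 1000, n_subpops = 8,
                                           fst = 0.3,
                                           maf_range = c(0.1, 0.5)),
                         px_per_cm = 50, seed = 1) {
  if (any(c(sigma_g2, sigma_b2, sigma_e2) < 0))
    stop_param("variance components must be non-negative")
  if (n_replicates < 2) stop_param("n_replicates must be >= 2")
  if (px_per_cm <= 0) stop_param("px_per_cm must be positive")
  if (is.unsorted(days, strictly = TRUE)) stop_param("days must be strictly increasing")
  structure(list(n_genotypes = n_genotypes, n_replicates = n_replicates,
                 days = days, mu = mu, sigma_g2 = sigma_g2,
                 sigma_b2 = sigma_b2, sigma_e2 = sigma_e2,
                 n_blocks = n_blocks, root_params = root_params,
                 snp_params = snp_params, px_per_cm = px_per_cm,
                 seed = seed),
            class = "study_config")
}

#' Simulate a replicated single-trait phenotype table
#'
#' Draws observations from the random-effects model
#' \deqn{y_{ik} = \mu + g_i + b_k + e_{ik}}
#' with independent zero-mean normal genotype effects
#' \eqn{g_i \sim N(0, \sigma_g^2)}, block effects
#' \eqn{b_k \sim N(0, \sigma_b^2)} and residuals
#' \eqn{e_{ik} \sim N(0, \sigma_e^2)}. Replicates are assigned to blocks
#' round-robin so the design is balanced.
#'
#' @param config a [study_config()].
#' @param trait trait name stored in the output (default "TRL").
#' @param day imaging day stored in the output.
#' @return a list with `table` (long data.frame: genotype, replicate, block,
#'   day, trait, value) and `truth` (genotype effects `g`, block effects
#'   `b`, grand mean `mu`).
#' @export
simulate_phenotypes <- function(config, trait = "TRL", day = 9) {
  stopifnot(inherits(config, "study_config"))
  n <- config$n_genotypes; r <- config$n_replicates
  if (n * r < 4) stop_param("need n_genotypes * n_replicates >= 4")
  with_seed(derive_seed(config$seed, paste0("phenotypes/", trait, "/", day)), {
    g <- rnorm(n, 0, sqrt(config$sigma_g2))
    b <- rnorm(config$n_blocks, 0, sqrt(config$sigma_b2))
    block <- rep_len(seq_len(config$n_blocks), r)
    e <- rnorm(n * r, 0, sqrt(config$sigma_e2))
    tab <- data.frame(
      genotype = rep(sprintf("G%03d", seq_len(n)), each = r),
      replicate = rep(seq_len(r), times = n),
      block = rep(block, times = n),
      day = day, trait = trait,
      value = config$mu + rep(g, each = r) + b[rep(block, times = n)] + e,
      stringsAsFactors = FALSE)
    list(table = tab,
         truth = list(g = stats::setNames(g, sprintf("G%03d", seq_len(n))),
                      b = b, mu = config$mu))
  })
}

# Study conditions for the 13 ideotype traits: day-9 panel means, plot-level
# SDs and entry-mean heritabilities typical of a 292-genotype, 14-replicate
# seedling experiment. Variance components are recovered from (SD, H2, r):
# sigma_e2 = SD^2 / (1 + H2 / (r (1 - H2))), sigma_g2 = SD^2 - sigma_e2.
iroot_trait_conditions <- function() {
  data.frame(
    trait = c("TRL", "PRL", "WID", "CVA", "LRB", "VOL", "LRA", "SOL2",
              "LED", "RHZO", "TRL_GR", "TRLUpper", "Root_weight"),
    mean = c(215.1, 35.0, 16.1, 287.4, 70.8, 152.3, 86.1, 130,
             2.6, 3696, 150, 141.8, 0.09),
    sd = c(90.7, 7.3, 5.7, 142.8, 24.7, 76.7, 10.8, 15,
           1.4, 1562, 60, 68.0, 0.03),
    h2 = c(0.92, 0.86, 0.90, 0.90, 0.85, 0.92, 0.45, 0.30,
           0.84, 0.92, 0.90, 0.90, 0.95),
    stringsAsFactors = FALSE)
}

#' Simulate the full 13-trait ideotype panel
#'
#' Generates one long trait table covering the 13 traits used for ideotype
#' scoring and phenotype-based clustering, at one or more imaging days.
#' Per-trait variance components are derived from panel-scale means,
#' standard deviations and entry-mean heritabilities; genotype effects are
#' drawn independently per trait.
#'
#' @param config a [study_config()]; its `mu`/`sigma_*` fields are ignored
#'   in favour of the per-trait conditions.
#' @param days subset of `config$days` to simulate (default all).
#' @param conditions data.frame with columns trait, mean, sd, h2 overriding
#'   the built-in panel conditions.
#' @return list with `table` (long TraitTable) and `truth` (named list of
#'   per-trait genotype effect vectors).
#' @export
simulate_trait_panel <- function(config, days = config$days,
                                 conditions = iroot_trait_conditions()) {
  r <- config$n_replicates
  tabs <- list(); truth <- list()
  for (d in days) for (i in seq_len(nrow(conditions))) {
    tr <- conditions$trait[i]
    h2 <- conditions$h2[i]
    s2 <- conditions$sd[i]^2
    se2 <- s2 / (1 + h2 / (r * (1 - h2)))
    sg2 <- s2 - se2
    cfg <- config
    cfg$mu <- conditions$mean[i]; cfg$sigma_g2 <- sg2; cfg$sigma_e2 <- se2
    cfg$sigma_b2 <- 0.01 * s2
    sim <- simulate_phenotypes(cfg, trait = tr, day = d)
    tabs[[length(tabs) + 1L]] <- sim$table
    truth[[paste(tr, d, sep = "@")]] <- sim$truth$g
  }
  list(table = do.call(rbind, tabs), truth = truth)
}
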