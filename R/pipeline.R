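#' Table of descriptive statistics, heritability and genotype significance
#'
#' Per (trait, day): mean, median, min, max, SD of the plot-level values,
#' entry-mean broad-sense heritability from the fitted variance
#' components, and the significance of the genotype effect from a
#' likelihood-ratio test of sigma_g^2 = 0 (REML fits with and without the
#' genotype term; the p-value is halved to account for the boundary null).
#'
#' @param table long TraitTable (columns genotype, replicate, day, trait,
#'   value, optionally block).
#' @param r replications for heritability (default: observed mean).
#' @return data.frame, one row per trait x day.
#' @export
make_descriptive_table <- function(table, r = NULL) {
  combos <- unique(table[, c("trait", "day")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    tr <- combos$trait[i]; d <- combos$day[i]
    v <- table$value[table$trait == tr & table$day == d]
    v <- v[!is.na(v)]
    base <- data.frame(trait = tr, day = d, mean = mean(v),
                       median = stats::median(v), min = min(v),
                       max = max(v), sd = stats::sd(v))
    if (base$sd == 0) {
      base$h2 <- NA_real_; base$p_genotype <- NA_real_
    } else {
      fit <- fit_mixed_model(table, trait = tr, day = d)
      base$h2 <- heritability(fit$vc, if (is.null(r)) fit$n_rep else r)
      base$p_genotype <- lrt_genotype(table, tr, d)
    }
    base
  })
  do.call(rbind, rows)
}

lrt_genotype <- function(table, tr, d) {
  dat <- table[table$trait == tr & table$day == d & !is.na(table$value), ]
  has_block <- !is.null(dat$block) && length(unique(dat$block)) >= 2
  f1 <- if (has_block) value ~ (1 | genotype) + (1 | block)
        else value ~ (1 | genotype)
  m1 <- lme4::lmer(f1, data = dat, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))
  m0 <- if (has_block) {
    lme4::lmer(value ~ (1 | block), data = dat, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))
  } else stats::lm(value ~ 1, data = dat)
  ll0 <- as.numeric(stats::logLik(m0)); ll1 <- as.numeric(stats::logLik(m1))
  stat <- max(0, 2 * (ll1 - ll0))
  stats::pchisq(stat, df = 1, lower.tail = FALSE) / 2
}

#' Run the full synthetic study
#'
#' Orchestrates every stage of the pipeline on simulated inputs with known
#' ground truth: phenotype simulation for the 13 ideotype traits, Tukey
#' outlier removal, per-trait mixed models (BLUPs, variance components,
#' heritability), phenotype-based clusters, iRoot category scores,
#' SNP simulation, MAF filtering, allele-sharing distances, genotype-based
#' clusters with the between-cluster FST matrix, PCA, BIC-based k
#' selection, shape-family generation with the mean-shape and
#' autoencoder/k-means shape clusters, and the cross-tabulation bundle.
#' Deterministic given (config, seed).
#'
#' @param config a [study_config()] or the path of a YAML file whose
#'   fields are passed to [study_config()].
#' @param out_dir optional directory; when given, stage outputs are
#'   written (CSVs, JSON report, newick tree) and a MANIFEST.json with
#'   checksums is produced.
#' @param day focal imaging day for scoring and clustering (default 9).
#' @param quick logical; trims the shape stage (fewer epochs) for smoke
#'   runs.
#' @return a `study_report` list with all stage outputs.
#' @export
run_study <- function(config, out_dir = NULL, day = 9, quick = FALSE) {
  if (is.character(config)) config <- do.call(study_config, read_study_yaml(config))
  stopifnot(inherits(config, "study_config"))

  sim <- simulate_trait_panel(config, days = day)
  clean <- remove_outliers(sim$table)
  bl <- blup_table(clean, day = day, r = config$n_replicates)
  descr <- make_descriptive_table(clean, r = config$n_replicates)

  pbc <- phenotype_clusters(bl$blups, k = min(8, config$n_genotypes))
  scores <- score_categories(bl$blups)

  gsim <- simulate_snp_matrix(config$snp_params,
                              n_per_subpop = ceiling(config$n_genotypes /
                                                     config$snp_params$n_subpops),
                              seed = config$seed)
  snps <- gsim$snps[seq_len(config$n_genotypes), , drop = FALSE]
  snps <- filter_snps(snp_matrix(snps))
  rownames(snps) <- rownames(bl$blups)
  dist <- nei_distance(snps)
  gbc <- genotype_clusters(dist, k = min(8, config$n_genotypes))
  fst <- fst_between_clusters(snps, gbc)
  pca <- snp_pca(snps, n_pc = 10)
  k_hat <- select_k_bic(pca$scores, k_max = min(12, config$n_genotypes - 1))

  fams <- c("umbrella", "beard", "drought")
  geno_fam <- rep_len(fams, config$n_genotypes)
  outlines <- lapply(seq_len(config$n_genotypes), function(i) {
    generate_shape_family(geno_fam[i], 1, jitter = 0.08,
                          seed = config$seed + i)[[1]]
  })
  efds <- lapply(outlines, efd_transform, n_harmonics = 20)
  profiles <- lapply(efds, reconstruct_outline, n_harmonics = 5)
  imgs <- lapply(profiles, rasterize_shape, side_px = 64)
  ae <- train_autoencoder(imgs, latent_dim = 8,
                          epochs = if (quick) 5 else 40,
                          seed = config$seed)
  lat <- ae$encode(imgs)
  rownames(lat) <- rownames(bl$blups)
  sbc <- shape_clusters(lat, k = min(8, config$n_genotypes),
                        trait_z = scale(bl$blups), seed = config$seed)

  xtab <- cross_tabulate(list(GBC = gbc, PBC = pbc, SBC = sbc),
                         ranks = scores$ranks, blups = bl$blups)

  report <- list(config = unclass(config), day = day,
                 descriptives = descr, h2 = bl$h2,
                 blups = bl$blups, pbc = pbc, iroot = scores,
                 gbc = gbc, fst_between_gbc = fst,
                 pca_var_frac = pca$var_frac[1:2], k_bic = k_hat,
                 sbc = sbc, shape_truth = geno_fam,
                 ae_history = ae$history, cross_tabs = xtab)
  class(report) <- "study_report"
  if (!is.null(out_dir)) write_study_report(report, out_dir, dist)
  report
}

read_study_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(study_config))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop_param("unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg
}

write_study_report <- function(report, out_dir, dist = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, name, writer) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    paths[[name]] <<- p
  }
  wr(report$descriptives, "descriptives.csv",
     function(o, p) utils::write.csv(o, p, row.names = FALSE))
  wr(report$blups, "blups.csv",
     function(o, p) utils::write.csv(o, p, row.names = TRUE))
  wr(report$iroot$ranks, "iroot_ranks.csv",
     function(o, p) utils::write.csv(o, p, row.names = TRUE))
  wr(data.frame(genotype = names(report$gbc), GBC = report$gbc,
                PBC = report$pbc[names(report$gbc)],
                SBC = report$sbc[names(report$gbc)]),
     "clusters.csv", function(o, p) utils::write.csv(o, p, row.names = FALSE))
  wr(report$fst_between_gbc, "fst_between_gbc.csv",
     function(o, p) utils::write.csv(o, p, row.names = TRUE))
  if (!is.null(dist))
    wr(dist, "nei_distance.csv",
       function(o, p) utils::write.csv(o, p, row.names = TRUE))
  summary <- list(day = report$day, h2 = as.list(report$h2),
                  pca_var_frac = report$pca_var_frac,
                  k_bic = as.integer(report$k_bic),
                  seed = report$config$seed)
  wr(summary, "report.json",
     function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE))
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = report$config$seed,
    files = lapply(paths, function(p) list(
      path = basename(p),
      md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
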