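test_that("direction-aware ranking handles both directions and ties", {
  expect_equal(unname(rank_trait(c(3, 1, 2), "higher_favorable")), c(1, 3, 2))
  expect_equal(unname(rank_trait(c(3, 1, 2), "lower_favorable")), c(3, 1, 2))
  expect_equal(unname(rank_trait(c(5, 5, 1), "higher_favorable")),
               c(1.5, 1.5, 3))
  # missing values rank last, keeping the panel intact
  r <- rank_trait(c(3, NA, 2, NA))
  expect_equal(unname(r), c(1, 3.5, 2, 3.5))
  expect_error(rank_trait(c(NA_real_, NA_real_)), "missing")
})

test_that("category definitions carry the published trait directions", {
  cats <- iroot_categories()
  expect_named(cats, c("nutrient_foraging", "drought_tolerant", "umbrella",
                       "beard", "maximum"))
  expect_setequal(cats$nutrient_foraging$trait, c("WID", "TRL_GR", "TRLUpper"))
  dt <- cats$drought_tolerant
  expect_equal(dt$direction[dt$trait == "LRA"], "lower_favorable")
  expect_equal(dt$direction[dt$trait == "SOL2"], "lower_favorable")
  bd <- cats$beard
  expect_equal(bd$direction[bd$trait == "LED"], "lower_favorable")
  expect_equal(bd$direction[bd$trait == "WID"], "lower_favorable")
  expect_equal(nrow(cats$maximum), 8)
})

test_that("category scores agree with a brute-force rank-sum oracle", {
  cats <- iroot_categories()
  needed <- unique(unlist(lapply(cats, `[[`, "trait")))
  brute <- function(B) {
    sapply(cats, function(cat) {
      rowSums(sapply(seq_len(nrow(cat)), function(i) {
        v <- B[, cat$trait[i]]
        if (cat$direction[i] == "higher_favorable") v <- -v
        rank(v, ties.method = "average")
      }))
    })
  }
  set.seed(20)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    B <- matrix(stats::rnorm(n * length(needed)), n,
                dimnames = list(sprintf("g%02d", 1:n), needed))
    if (rep %% 3 == 0) {
      # inject ties
      B[, "TRL"] <- round(B[, "TRL"])
      B[1:2, "WID"] <- 1
    }
    sc <- score_categories(B)
    expect_equal(unname(sc$scores), unname(brute(B)))
  }
})

test_that("scoring honours its invariances and degenerate cases", {
  cats <- iroot_categories()
  needed <- unique(unlist(lapply(cats, `[[`, "trait")))
  set.seed(21)
  B <- matrix(rnorm(8 * length(needed)), 8,
              dimnames = list(paste0("g", 1:8), needed))
  sc <- score_categories(B)
  # permutation invariance of genotype order
  perm <- sample(8)
  sc2 <- score_categories(B[perm, ])
  expect_equal(sc2$scores[rownames(sc$scores), ], sc$scores)
  # invariance under strictly monotone trait transforms
  B3 <- B; B3[, "TRL"] <- exp(B3[, "TRL"]); B3[, "LRA"] <- B3[, "LRA"]^3
  expect_equal(score_categories(B3)$scores, sc$scores)
  # mean category rank is (n+1)/2 without ties
  expect_equal(unname(colMeans(sc$ranks)), rep(4.5, 5))
  # identical genotypes tie everywhere
  B4 <- matrix(1, 5, length(needed), dimnames = list(paste0("g", 1:5), needed))
  sc4 <- score_categories(B4)
  expect_true(all(apply(sc4$scores, 2, function(x) length(unique(x)) == 1)))
  # a genotype dominating every trait in its favourable direction tops
  # the maximum category with the minimal possible score
  B5 <- B
  B5["g1", cats$maximum$trait] <- apply(B[, cats$maximum$trait], 2, max) + 1
  sc5 <- score_categories(B5)
  expect_equal(unname(sc5$scores["g1", "maximum"]), nrow(cats$maximum))
  expect_equal(unname(sc5$ranks["g1", "maximum"]), 1)
  # a missing trait column is reported by name
  expect_error(score_categories(B[, setdiff(needed, "CVA")]), "CVA")
})

test_that("cross-tabulation aggregates clusters, metadata and ranks", {
  genos <- paste0("g", 1:6)
  gbc <- factor(c("A", "A", "B", "B", "B", "A")); names(gbc) <- genos
  pbc <- factor(c("A", "B", "A", "B", "B", "A")); names(pbc) <- genos
  meta <- data.frame(country = c("China", "USA", "China", "Japan", "USA",
                                 "China"),
                     row.names = genos)
  ranks <- cbind(maximum = c(1, 2, 3, 4, 5, 6),
                 beard = c(6, 5, 4, 3, 2, 1))
  rownames(ranks) <- genos
  blups <- matrix(1:12, 6, 2, dimnames = list(genos, c("TRL", "WID")))
  out <- cross_tabulate(list(GBC = gbc, PBC = pbc), ranks = ranks,
                        metadata = meta, blups = blups)
  # counts partition the panel
  expect_equal(sum(out$GBC$counts$country), 6)
  # hand-computed means: GBC A = {g1,g2,g6}
  expect_equal(unname(out$GBC$iroot_mean_rank["A", "maximum"]), 3)
  expect_equal(unname(out$GBC$iroot_mean_rank["A", "beard"]), 4)
  expect_equal(unname(out$GBC$trait_means["A", "TRL"]), mean(c(1, 2, 6)))
  # PBC mean per GBC: A -> (1 + 2 + 1)/3
  expect_equal(unname(out$GBC$pbc_mean["A"]), mean(c(1, 2, 1)))
  expect_equal(unname(out$country_pbc_mean["China"]), mean(c(1, 1, 1)))

  # single-cluster assignment reproduces global means
  one <- factor(rep("A", 6)); names(one) <- genos
  out1 <- cross_tabulate(list(GBC = one, PBC = pbc), ranks = ranks,
                         blups = blups)
  expect_equal(unname(out1$GBC$trait_means["A", ]), unname(colMeans(blups)))
  # key mismatches are reported
  bad <- gbc[1:5]
  expect_error(cross_tabulate(list(GBC = bad, PBC = pbc)), "disagree")
})
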