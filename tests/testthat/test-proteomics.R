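sim_small <- simulate_proteome(proteome_sim_config(n_proteins = 400, seed = 101))

test_that("quant tables validate their design and round trip through TSV", {
  qt <- sim_small$quant
  f <- tempfile(fileext = ".tsv")
  write_quant_table(qt, f)
  back <- read_quant_table(f, qt$design)
  expect_equal(back$proteins, qt$proteins)
  expect_equal(unname(back$intensities), unname(qt$intensities),
               tolerance = 1e-12)

  toy <- data.frame(accession = c("P1", "P2", "P3"), symbol = c("A", "B", "C"),
                    unique_peptides = c(1, 2, 3), ctrl_1 = 1:3, mut_1 = 4:6,
                    ctrl_2 = 1:3, mut_2 = 4:6)
  design <- data.frame(channel = c("ctrl_1", "mut_1", "ctrl_2", "mut_2"),
                       pair = c(1, 1, 2, 2),
                       condition = c("control", "mutant", "control", "mutant"))
  tf <- tempfile(fileext = ".tsv")
  write.table(toy, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(nrow(read_quant_table(tf, design)$proteins), 3)

  dup <- toy; dup$accession <- c("P1", "P1", "P3")
  write.table(dup, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_quant_table(tf, design), "duplicate")

  neg <- toy; neg$ctrl_1[2] <- -5
  write.table(neg, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_quant_table(tf, design), ">= 0")

  corrupt <- toy; corrupt$mut_2 <- c("4", "x", "6")
  write.table(corrupt, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_quant_table(tf, design), "row 2")

  incomplete <- design[-2, ]
  expect_error(quant_table(toy[, 1:3], as.matrix(toy[, c(4, 6, 7)]),
                           incomplete),
               "exactly one control and one mutant")
})

test_that("unique-peptide filtering keeps order and applies the threshold", {
  qt <- sim_small$quant
  qt$proteins$unique_peptides <- rep(c(1, 2, 3, 5), length.out = 400)
  f2 <- filter_min_unique_peptides(qt, k = 2)
  expect_equal(nrow(f2$proteins), 300)
  expect_equal(f2$proteins$accession,
               qt$proteins$accession[qt$proteins$unique_peptides >= 2])
  expect_identical(filter_min_unique_peptides(qt, k = 1)$proteins, qt$proteins)
  expect_error(filter_min_unique_peptides(qt, k = 0), ">= 1")

  # retained fraction matches the tail mass of the peptide-count distribution
  big <- simulate_proteome(proteome_sim_config(n_proteins = 20000, seed = 7))
  kept <- nrow(filter_min_unique_peptides(big$quant, 2)$proteins) / 20000
  p_keep <- 1 - dpois(0, 2)  # counts are 1 + Poisson(2); >= 2 iff Poisson >= 1
  expect_lt(abs(kept - p_keep), 4 * sqrt(p_keep * (1 - p_keep) / 20000))
})

test_that("channel median normalization equalizes medians and preserves ranks", {
  qt <- sim_small$quant
  nm <- normalize_channels(qt)
  med <- apply(nm$intensities, 2, median)
  expect_lt(max(med) - min(med), 1e-9)
  for (j in seq_len(ncol(qt$intensities)))
    expect_equal(rank(nm$intensities[, j]), rank(qt$intensities[, j]))

  # already equal-median table is unchanged
  expect_equal(normalize_channels(nm)$intensities, nm$intensities,
               tolerance = 1e-12)

  # doubling one channel is undone up to a single global scale factor
  doubled <- qt
  doubled$intensities[, 3] <- doubled$intensities[, 3] * 2
  renorm <- normalize_channels(doubled)
  ref <- normalize_channels(qt)
  ratio <- renorm$intensities / ref$intensities
  expect_lt(diff(range(ratio)), 1e-9)

  zero_chan <- qt
  zero_chan$intensities[, 1] <- 0
  expect_error(normalize_channels(zero_chan), "all-zero")
})

test_that("paired log ratios are exact on constructed tables", {
  qt <- sim_small$quant
  same <- qt
  for (p in unique(qt$design$pair)) {
    mutch <- qt$design$channel[qt$design$pair == p &
                                 qt$design$condition == "mutant"]
    ctlch <- qt$design$channel[qt$design$pair == p &
                                 qt$design$condition == "control"]
    same$intensities[, mutch] <- same$intensities[, ctlch]
  }
  expect_true(all(paired_log_ratios(same) == 0))
  twice <- same
  for (p in unique(qt$design$pair)) {
    mutch <- qt$design$channel[qt$design$pair == p &
                                 qt$design$condition == "mutant"]
    twice$intensities[, mutch] <- twice$intensities[, mutch] * 2
  }
  expect_equal(unname(paired_log_ratios(twice)),
               matrix(1, 400, 4), tolerance = 1e-12)
})

test_that("the moderated paired test reproduces the reference EB fit exactly", {
  ratios <- paired_log_ratios(normalize_channels(sim_small$quant))
  fit <- moderated_paired_test(ratios)
  lf <- limma::lmFit(ratios, design = matrix(1, ncol(ratios), 1))
  lf <- limma::eBayes(lf)
  expect_equal(fit$params$prior_df, lf$df.prior, tolerance = 1e-8)
  expect_equal(fit$params$prior_var, lf$s2.prior, tolerance = 1e-8)
  expect_equal(fit$table$moderated_t, unname(lf$t[, 1]), tolerance = 1e-10)
  expect_equal(fit$table$p_value, unname(lf$p.value[, 1]), tolerance = 1e-10)
})

test_that("forcing a zero prior reproduces the ordinary paired t test", {
  all_ratios <- paired_log_ratios(normalize_channels(sim_small$quant))
  ratios <- all_ratios[1:25, ]
  fit <- moderated_paired_test(all_ratios, prior_df = 0)
  for (i in 1:25) {
    tt <- t.test(ratios[i, ])
    expect_equal(fit$table$moderated_t[i], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(fit$table$p_value[i], tt$p.value, tolerance = 1e-10)
    expect_equal(fit$table$df_total[1], ncol(ratios) - 1)
  }
})

test_that("shrinkage keeps posterior variances between sample and prior", {
  ratios <- paired_log_ratios(normalize_channels(sim_small$quant))
  fit <- moderated_paired_test(ratios)
  s2 <- apply(ratios, 1, var)
  s02 <- fit$params$prior_var
  st2 <- fit$params$posterior_var
  expect_true(all(st2 >= pmin(s2, s02) - 1e-12))
  expect_true(all(st2 <= pmax(s2, s02) + 1e-12))
  # a protein whose sample variance equals the prior stays at the prior
  ratios2 <- ratios
  v <- ratios2[1, ] - mean(ratios2[1, ])
  ratios2[1, ] <- v * sqrt(s02 / var(v))
  fit2 <- moderated_paired_test(ratios2, prior_df = fit$params$prior_df)
  expect_equal(unname(fit2$params$posterior_var[1]), fit2$params$prior_var,
               tolerance = 1e-3)
})

test_that("the test is scale invariant and antisymmetric under label swap", {
  qt <- normalize_channels(sim_small$quant)
  d1 <- differential_abundance(qt)
  scaled <- qt
  scaled$intensities <- scaled$intensities * 7.3
  d2 <- differential_abundance(scaled)
  expect_equal(d1$table$moderated_t, d2$table$moderated_t, tolerance = 1e-9)
  expect_equal(d1$table$p_value, d2$table$p_value, tolerance = 1e-9)
  expect_equal(d1$table$q_value, d2$table$q_value, tolerance = 1e-9)

  swapped <- qt
  swapped$design$condition <- c(control = "mutant",
                                mutant = "control")[qt$design$condition]
  d3 <- differential_abundance(swapped)
  expect_equal(d3$table$mean_log2fc, -d1$table$mean_log2fc, tolerance = 1e-9)
  expect_equal(d3$table$p_value, d1$table$p_value, tolerance = 1e-9)
})

test_that("a degenerate variance ensemble is rejected with advice", {
  ratios <- matrix(rep(c(-1, 0, 1, 0), each = 20), nrow = 20)
  expect_error(moderated_paired_test(ratios), "ordinary paired t")
  expect_error(moderated_paired_test(matrix(rnorm(8), 2, 4)), ">= 10 proteins")
  expect_error(moderated_paired_test(matrix(rnorm(20), 20, 1)), ">= 2 pairs")
})

test_that("BH step-up matches hand computation and the reference implementation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(1)
  for (i in 1:10) {
    p <- runif(sample(3:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone in rank
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("the candidate cascade equals an independent brute-force filter", {
  sim <- simulate_proteome(proteome_sim_config(n_proteins = 1500, seed = 55))
  qt <- normalize_channels(sim$quant)
  # plant the seven catalog proteins with strong effects so some reach the top tier
  catalog <- c("VAPA", "VAPB", "REEP1", "EZRIN", "PRNP", "KIF5C", "DYNC1I1")
  qt$proteins$symbol[1:7] <- catalog
  for (p in unique(qt$design$pair)) {
    mutch <- qt$design$channel[qt$design$pair == p &
                                 qt$design$condition == "mutant"]
    qt$intensities[1:5, mutch] <- qt$intensities[1:5, mutch] * 4
  }
  diff <- differential_abundance(qt)
  casc <- candidate_cascade(diff, map_catalog())
  orc <- oracle_cascade_counts(diff$table, diff$alpha, diff$fdr,
                               c(catalog, "EZR"))
  expect_equal(casc$tiers, orc)
  expect_gte(casc$tiers[["map_catalog_hits"]], 5)
  expect_true(all(c("VAPA", "EZRIN") %in% casc$members$map_catalog_hits))

  empty_cat <- map_catalog("NOT_A_GENE")
  casc2 <- candidate_cascade(diff, empty_cat)
  expect_equal(casc2$tiers[["map_catalog_hits"]], 0)
  expect_error(candidate_cascade(diff, structure(character(0),
                                                 class = "map_catalog")),
               "non-empty")
})

test_that("FDR-subset scoping is available as a flag", {
  qt <- normalize_channels(sim_small$quant)
  d_all <- differential_abundance(qt, fdr_scope = "all")
  d_sub <- differential_abundance(qt, fdr_scope = "alpha_subset")
  expect_true(all(is.na(d_sub$table$q_value[!d_sub$table$sig_p01])))
  sub <- d_sub$table$sig_p01
  expect_equal(d_sub$table$q_value[sub],
               bh_adjust(d_all$table$p_value[sub]))
})

test_that("hypergeometric enrichment matches combinatorial hand calculations", {
  bg <- paste0("G", 1:20)
  sets <- list(S = bg[1:5])
  res <- enrichment(bg[1:5], bg, sets)
  expect_equal(res$p_value, 1 / choose(20, 5))
  # foreground = background = the whole set forces the overlap: p = 1
  res2 <- enrichment(bg[1:5], bg[1:5], sets)
  expect_equal(res2$p_value, 1)
  expect_error(enrichment(c(bg[1], "MISSING"), bg, sets), "MISSING")
  expect_error(enrichment(bg[1], bg, list(S = character(0))), "non-empty")
})

test_that("enrichment p-values are well calibrated under random foregrounds", {
  set.seed(33)
  bg <- paste0("G", 1:200)
  sets <- list(S = bg[1:40])
  ps <- replicate(400, enrichment(sample(bg, 30), bg, sets)$p_value)
  # discrete-uniform null: P(p <= 0.05) cannot exceed 0.05 and the bulk is flat
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  expect_gt(mean(ps > 0.5), 0.4)
})

test_that("GMT files round trip", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG9"), f)
  sets <- read_gmt(f)
  expect_equal(sets, list(setA = c("G1", "G2", "G3"), setB = "G9"))
  writeLines("empty\tdesc", f)
  expect_error(read_gmt(f), "empty")
})

test_that("volcano export has one flagged row per protein", {
  qt <- normalize_channels(sim_small$quant)
  d <- differential_abundance(qt)
  v <- volcano_table(d)
  expect_equal(nrow(v), nrow(d$table))
  expect_equal(v$sig_p01, d$table$p_value < 0.01)
  expect_true(all(v$neg_log10_p >= 0))
  # anything in the FDR tier that also clears raw significance carries both flags
  both <- v$sig_fdr05 & v$sig_p01
  expect_true(all(d$table$q_value[both] <= 0.05 & d$table$p_value[both] < 0.01))
})
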