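#' Configuration for the paired TMT proteome simulator
#'
#' Emulates a single TMT 10-plex co-sedimentation experiment with a paired
#' littermate design: `n_pairs` control/mutant channel pairs, a minority of
#' proteins carrying a true log2 effect, litter-level random effects, per
#' channel loading biases and log-normal reporter noise.
#'
#' True effect magnitudes are drawn as `location + |N(0, scale)|` with a
#' random sign, so every perturbed protein has |log2 fold change| >= the
#' location parameter.
#'
#' @param n_proteins number of quantified proteins.
#' @param n_pairs littermate pairs (2 channels each; > 5 pairs exceeds one
#'   10-plex unless `multi_plex = TRUE`).
#' @param frac_perturbed fraction of proteins with a true effect.
#' @param effect_log2_dist `c(location, scale)` of the effect magnitude.
#' @param pair_effect_sd litter random-effect sd on the per-pair log2 ratio.
#' @param channel_bias per-channel multiplicative loading offsets (length
#'   2 * n_pairs), or a single sd from which log2 biases are drawn.
#' @param reporter_noise_sd log2-space reporter noise sd (typical scale).
#' @param noise_df spread of per-protein noise variances: variances follow a
#'   scaled inverse chi-square with this many degrees of freedom around
#'   `reporter_noise_sd^2` (smaller = more heterogeneous); `Inf` gives every
#'   protein the same variance.
#' @param baseline_log2_mean,baseline_log2_sd protein abundance baseline.
#' @param unique_peptide_lambda unique peptide counts are 1 + Poisson(lambda).
#' @param multi_plex allow more than 10 channels.
#' @param seed integer seed.
#' @return an object of class `proteome_sim_config`.
#' @export
proteome_sim_config <- function(n_proteins = 5283, n_pairs = 4,
                                frac_perturbed = 0.05,
                                effect_log2_dist = c(location = 1, scale = 0.5),
                                pair_effect_sd = 0.2,
                                channel_bias = 0.25,
                                reporter_noise_sd = 0.25,
                                noise_df = 10,
                                baseline_log2_mean = 10,
                                baseline_log2_sd = 2,
                                unique_peptide_lambda = 2,
                                multi_plex = FALSE,
                                seed = 1L) {
  n_proteins <- assert_count(n_proteins, "n_proteins")
  n_pairs <- assert_count(n_pairs, "n_pairs", min = 2L)
  if (2 * n_pairs > 10 && !multi_plex)
    config_error("n_pairs",
                 "2 x n_pairs exceeds the 10 channels of one TMT 10-plex; set multi_plex = TRUE to allow")
  assert_scalar_number(frac_perturbed, "frac_perturbed", 0, 1)
  assert_scalar_number(pair_effect_sd, "pair_effect_sd", 0)
  assert_scalar_number(reporter_noise_sd, "reporter_noise_sd", 0)
  if (!(is.numeric(noise_df) && length(noise_df) == 1L && noise_df > 0))
    config_error("noise_df", "must be a positive number (Inf allowed)")
  if (!(length(channel_bias) %in% c(1L, 2L * n_pairs)))
    config_error("channel_bias",
                 "must be a single sd or one multiplicative offset per channel")
  if (length(channel_bias) > 1 && any(channel_bias <= 0))
    config_error("channel_bias", "offsets must be positive")
  structure(list(n_proteins = n_proteins, n_pairs = n_pairs,
                 frac_perturbed = frac_perturbed,
                 effect_log2_dist = effect_log2_dist,
                 pair_effect_sd = pair_effect_sd, channel_bias = channel_bias,
                 reporter_noise_sd = reporter_noise_sd,
                 noise_df = noise_df,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 unique_peptide_lambda = unique_peptide_lambda,
                 multi_plex = multi_plex, seed = seed),
            class = "proteome_sim_config")
}

#' Simulate a paired TMT quant table with known ground truth
#'
#' @param config a [proteome_sim_config()].
#' @return list with `quant` (a [quant_table()]) and `truth` (data frame:
#'   accession, symbol, perturbed, true_log2fc).
#' @export
simulate_proteome <- function(config) {
  if (!inherits(config, "proteome_sim_config"))
    config_error("config", "must be a proteome_sim_config")
  np <- config$n_proteins; nk <- config$n_pairs
  with_seed(config$seed, {
    acc <- sprintf("P%05d", seq_len(np))
    sym <- sprintf("GENE%05d", seq_len(np))
    upep <- 1L + rpois(np, config$unique_peptide_lambda)
    perturbed <- runif(np) < config$frac_perturbed
    mag <- config$effect_log2_dist[["location"]] +
      abs(rnorm(np, 0, config$effect_log2_dist[["scale"]]))
    eff <- ifelse(perturbed, mag * sample(c(-1, 1), np, replace = TRUE), 0)
    base <- rnorm(np, config$baseline_log2_mean, config$baseline_log2_sd)
    noise_sd <- if (is.finite(config$noise_df))
      config$reporter_noise_sd * sqrt(config$noise_df /
                                        stats::rchisq(np, config$noise_df))
    else rep(config$reporter_noise_sd, np)
    bias <- if (length(config$channel_bias) == 1L)
      2^rnorm(2 * nk, 0, config$channel_bias) else config$channel_bias
    ints <- matrix(0, np, 2 * nk)
    design <- data.frame(channel = character(2 * nk), pair = integer(2 * nk),
                         condition = character(2 * nk), stringsAsFactors = FALSE)
    for (j in seq_len(nk)) {
      litter <- rnorm(np, 0, config$pair_effect_sd)
      ctl <- base + rnorm(np, 0, noise_sd)
      mut <- base + eff + litter + rnorm(np, 0, noise_sd)
      jc <- 2 * j - 1; jm <- 2 * j
      ints[, jc] <- 2^ctl * bias[jc]
      ints[, jm] <- 2^mut * bias[jm]
      design$channel[jc] <- sprintf("ctrl_%d", j)
      design$channel[jm] <- sprintf("mut_%d", j)
      design$pair[c(jc, jm)] <- j
      design$condition[c(jc, jm)] <- c("control", "mutant")
    }
    proteins <- data.frame(accession = acc, symbol = sym,
                           unique_peptides = upep, stringsAsFactors = FALSE)
    list(quant = quant_table(proteins, ints, design),
         truth = data.frame(accession = acc, symbol = sym,
                            perturbed = perturbed, true_log2fc = eff,
                            stringsAsFactors = FALSE))
  })
}
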