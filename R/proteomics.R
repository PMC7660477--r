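#' Construct a TMT protein quantification table
#'
#' Holds protein records, a proteins x channels reporter signal/noise matrix
#' and the paired design (each pair id has exactly one control and one mutant
#' channel).
#'
#' @param proteins data frame with columns `accession`, `symbol`,
#'   `unique_peptides`; accessions must be unique.
#' @param intensities numeric matrix (proteins x channels) of reporter
#'   signal/noise values, all >= 0.
#' @param design data frame with columns `channel`, `pair`, `condition`
#'   (`control` or `mutant`), one row per channel in column order of
#'   `intensities`.
#' @return an object of class `quant_table`.
#' @export
quant_table <- function(proteins, intensities, design) {
  req <- c("accession", "symbol", "unique_peptides")
  if (!all(req %in% names(proteins)))
    abort("proteins needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(proteins$accession))
    abort("duplicate protein accessions are not allowed")
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(proteins))
    abort("intensities rows must match protein records")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    abort("reporter intensities must be finite and >= 0")
  if (!all(c("channel", "pair", "condition") %in% names(design)))
    abort("design needs columns channel, pair, condition")
  if (nrow(design) != ncol(intensities))
    abort("design rows must match intensity channels")
  if (!all(design$condition %in% c("control", "mutant")))
    abort("design conditions must be 'control' or 'mutant'")
  for (p in unique(design$pair)) {
    cond <- design$condition[design$pair == p]
    if (!(sum(cond == "control") == 1L && sum(cond == "mutant") == 1L))
      abort("pair '", p, "' must have exactly one control and one mutant channel")
  }
  rownames(intensities) <- proteins$accession
  colnames(intensities) <- design$channel
  structure(list(proteins = proteins, intensities = intensities,
                 design = design), class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("<quant_table> %d proteins x %d channels (%d pairs)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$design$pair))))
  invisible(x)
}

#' Read / write a quant table as TSV
#'
#' The TSV has columns accession, symbol, unique_peptides and one column per
#' channel; the design maps channels to pairs and conditions.
#'
#' @param file path to a tab-separated table.
#' @param design data frame (channel, pair, condition) or path to a design
#'   TSV.
#' @return a [quant_table()].
#' @export
read_quant_table <- function(file, design) {
  if (is.character(design)) design <- read.delim(design, stringsAsFactors = FALSE)
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("accession", "symbol", "unique_peptides")
  missing_cols <- setdiff(c(req, design$channel), names(df))
  if (length(missing_cols))
    abort("quant table is missing column(s): ", paste(missing_cols, collapse = ", "))
  ints <- as.matrix(df[, design$channel, drop = FALSE])
  if (!is.numeric(ints)) {
    bad <- which(is.na(suppressWarnings(apply(df[, design$channel, drop = FALSE],
                                              2, as.numeric))), arr.ind = TRUE)
    abort("non-numeric intensity at table row ",
          paste(unique(bad[, 1]), collapse = ", "))
  }
  if (any(is.na(ints)))
    abort("missing intensity at table row ",
          paste(unique(which(rowSums(is.na(ints)) > 0)), collapse = ", "))
  quant_table(df[, req], ints, design)
}

#' @rdname read_quant_table
#' @param x a [quant_table()].
#' @export
write_quant_table <- function(x, file) {
  out <- cbind(x$proteins, as.data.frame(x$intensities, check.names = FALSE))
  write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Keep proteins with at least k unique peptides
#'
#' @param x a [quant_table()].
#' @param k minimum unique-peptide count (default 2).
#' @return filtered [quant_table()], row order preserved.
#' @export
filter_min_unique_peptides <- function(x, k = 2) {
  if (k < 1) abort("k must be >= 1")
  keep <- x$proteins$unique_peptides >= k
  quant_table(x$proteins[keep, , drop = FALSE],
              x$intensities[keep, , drop = FALSE], x$design)
}

# half-minimum imputation of exact zeros, per channel
impute_zero_intensities <- function(ints) {
  for (j in seq_len(ncol(ints))) {
    v <- ints[, j]
    if (all(v == 0)) abort("channel ", colnames(ints)[j], " is all-zero")
    if (any(v == 0)) ints[v == 0, j] <- 0.5 * min(v[v > 0])
  }
  ints
}

#' Median-normalize TMT channels
#'
#' Rescales every channel multiplicatively so all channel medians equal the
#' grand median, the computational analogue of correcting channel loading to
#' 1:1:...:1. Exact zeros are first imputed at half the channel's smallest
#' positive value so no protein is dropped silently.
#'
#' @param x a [quant_table()].
#' @param impute_zeros replace exact zeros before scaling (default TRUE).
#' @return normalized [quant_table()].
#' @export
normalize_channels <- function(x, impute_zeros = TRUE) {
  ints <- x$intensities
  if (impute_zeros) ints <- impute_zero_intensities(ints) else {
    if (any(apply(ints, 2, function(v) all(v == 0))))
      abort("a channel is all-zero")
  }
  med <- apply(ints, 2, median)
  if (any(med == 0)) abort("a channel median is zero; cannot normalize")
  target <- median(ints)
  ints <- sweep(ints, 2, target / med, `*`)
  quant_table(x$proteins, ints, x$design)
}

#' Per-pair log2 mutant/control ratios
#'
#' @param x a [quant_table()] (normalized; exact zeros are imputed as in
#'   [normalize_channels()]).
#' @return numeric matrix proteins x pairs of log2(mutant/control).
#' @export
paired_log_ratios <- function(x) {
  ints <- impute_zero_intensities(x$intensities)
  pairs <- unique(x$design$pair)
  out <- matrix(NA_real_, nrow(ints), length(pairs),
                dimnames = list(rownames(ints), as.character(pairs)))
  for (i in seq_along(pairs)) {
    mut <- x$design$channel[x$design$pair == pairs[i] &
                              x$design$condition == "mutant"]
    ctl <- x$design$channel[x$design$pair == pairs[i] &
                              x$design$condition == "control"]
    out[, i] <- log2(ints[, mut]) - log2(ints[, ctl])
  }
  out
}

# Newton solve of trigamma(y) = x
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated paired t test
#'
#' One-sample moderated t on per-pair log ratios. Per-protein sample variances
#' s^2 (d = n_pairs - 1 df each) are shrunk toward a prior variance s0^2 with
#' prior df d0, both estimated from the ensemble of log sample variances by
#' moment matching on the scaled-F (log-variance) distribution:
#' `var(log s^2)` in excess of `trigamma(d/2)` determines d0 via the inverse
#' trigamma, and the mean determines s0^2. The posterior variance is
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`, the statistic
#' `t = mean(ratio) / sqrt(s~^2 / n)` and p is two-sided from the t
#' distribution with d0 + d degrees of freedom.
#'
#' @param ratios proteins x pairs matrix from [paired_log_ratios()]
#'   (>= 2 pairs, >= 10 proteins so the variance ensemble is estimable).
#' @param prior_df optional fixed prior df; `0` reproduces the ordinary paired
#'   t test exactly.
#' @return list with `table` (data frame: accession, mean_log2fc, moderated_t,
#'   df_total, p_value) and `params` (prior_df d0, prior_var s0^2, posterior
#'   variances).
#' @export
moderated_paired_test <- function(ratios, prior_df = NULL) {
  ratios <- as.matrix(ratios)
  if (is.null(rownames(ratios)))
    rownames(ratios) <- sprintf("feature_%d", seq_len(nrow(ratios)))
  n <- ncol(ratios)
  if (n < 2L) abort("moderated test needs >= 2 pairs")
  if (nrow(ratios) < 10L)
    abort("moderated test needs >= 10 proteins to estimate the variance prior")
  d <- n - 1
  m <- rowMeans(ratios)
  s2 <- apply(ratios, 1, var)
  if (all(s2 == s2[1]))
    abort("all proteins have identical ratio variance; the variance ensemble ",
          "is degenerate - use an ordinary paired t test instead")
  if (is.null(prior_df)) {
    z <- log(s2)
    if (any(!is.finite(z)))
      z[!is.finite(z)] <- log(min(s2[s2 > 0])) # guard exact-zero variances
    evar <- var(z)
    rhs <- evar - trigamma(d / 2)
    if (rhs > 0) {
      d0 <- 2 * trigamma_inverse(rhs)
      s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
    }
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) exp(mean(log(s2)) - digamma(d / 2) + log(d / 2)) else
      mean(s2)
  }
  st2 <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  tstat <- m / sqrt(st2 / n)
  df_total <- d0 + d
  p <- 2 * pt(-abs(tstat), df = df_total)
  list(table = data.frame(accession = rownames(ratios), mean_log2fc = m,
                          moderated_t = tstat, df_total = df_total,
                          p_value = p, row.names = NULL,
                          stringsAsFactors = FALSE),
       params = list(prior_df = d0, prior_var = s02, posterior_var = st2,
                     residual_df = d))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' q_i = min over j with p_(j) >= p_(i) of m p_(j) / j, capped at 1.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, monotone in the p-value ranks.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Full differential-abundance result
#'
#' Runs the moderated paired test on the log ratios of a (normalized) quant
#' table, adjusts p-values by Benjamini-Hochberg, and flags the two
#' significance tiers (raw p < `alpha`; q <= `fdr`).
#'
#' @param x a normalized [quant_table()].
#' @param alpha raw p-value tier threshold (default 0.01).
#' @param fdr FDR tier threshold (default 0.05).
#' @param fdr_scope adjust over `"all"` p-values (default) or only within the
#'   raw-significant subset (`"alpha_subset"`).
#' @param prior_df passed to [moderated_paired_test()].
#' @return list of class `diff_result` with `table` (accession, symbol,
#'   unique_peptides, mean_log2fc, moderated_t, df_total, p_value, q_value,
#'   sig_p01, sig_fdr05) and `params`.
#' @export
differential_abundance <- function(x, alpha = 0.01, fdr = 0.05,
                                   fdr_scope = c("all", "alpha_subset"),
                                   prior_df = NULL) {
  fdr_scope <- match.arg(fdr_scope)
  ratios <- paired_log_ratios(x)
  fit <- moderated_paired_test(ratios, prior_df = prior_df)
  tab <- fit$table
  tab$symbol <- x$proteins$symbol[match(tab$accession, x$proteins$accession)]
  tab$unique_peptides <- x$proteins$unique_peptides[
    match(tab$accession, x$proteins$accession)]
  if (fdr_scope == "all") {
    tab$q_value <- bh_adjust(tab$p_value)
  } else {
    tab$q_value <- NA_real_
    sub <- tab$p_value < alpha
    tab$q_value[sub] <- bh_adjust(tab$p_value[sub])
  }
  tab$sig_p01 <- tab$p_value < alpha
  tab$sig_fdr05 <- !is.na(tab$q_value) & tab$q_value <= fdr
  structure(list(table = tab, params = fit$params, alpha = alpha, fdr = fdr,
                 fdr_scope = fdr_scope), class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf("<diff_result> %d proteins; %d at p < %g; %d at FDR <= %g (d0 = %.2f)\n",
              nrow(x$table), sum(x$table$sig_p01), x$alpha,
              sum(x$table$sig_fdr05), x$fdr, x$params$prior_df))
  invisible(x)
}

# symbol harmonization: common aliases of the catalog proteins
symbol_aliases <- c(EZRIN = "EZR", DYNC1L1 = "DYNC1I1", DYNC1L2 = "DYNC1I2")

canonical_symbol <- function(sym) {
  s <- toupper(trimws(sym))
  hit <- symbol_aliases[s]
  ifelse(is.na(hit), s, hit)
}

#' Catalog of direct microtubule binders
#'
#' Default catalog: the seven proteins with documented direct microtubule
#' binding used as the final filter tier (VAPA, VAPB, REEP1, EZR(EZRIN),
#' PRNP, KIF5C, DYNC1I1). Matching is case-insensitive and alias-aware
#' (EZRIN = EZR; DYNC1l1/DYNC1l2 map to DYNC1I1/DYNC1I2).
#'
#' @param symbols character vector of gene symbols.
#' @return upper-cased, alias-canonicalized symbol set of class `map_catalog`.
#' @export
map_catalog <- function(symbols = c("VAPA", "VAPB", "REEP1", "EZR", "PRNP",
                                    "KIF5C", "DYNC1I1")) {
  if (!length(symbols)) abort("the MAP catalog must not be empty")
  structure(unique(canonical_symbol(symbols)), class = "map_catalog")
}

#' Candidate MAP filter cascade
#'
#' Tier counts and member lists for the study's filter pyramid: all quantified
#' proteins, the raw-significance tier (p < alpha), the FDR tier (q <= fdr),
#' and the intersection of the FDR tier with a catalog of known direct
#' microtubule binders.
#'
#' @param diff a [differential_abundance()] result.
#' @param catalog a [map_catalog()].
#' @return list of class `cascade_report` with `tiers` (named counts) and
#'   `members` (symbols of the FDR and catalog tiers).
#' @export
candidate_cascade <- function(diff, catalog = map_catalog()) {
  if (!inherits(catalog, "map_catalog") || !length(catalog))
    abort("candidate_cascade needs a non-empty map_catalog")
  tab <- diff$table
  sym <- canonical_symbol(tab$symbol)
  fdr_members <- tab$symbol[tab$sig_fdr05]
  hits <- tab$symbol[tab$sig_fdr05 & sym %in% unclass(catalog)]
  structure(list(
    tiers = c(quantified = nrow(tab),
              raw_significant = sum(tab$sig_p01),
              fdr_significant = sum(tab$sig_fdr05),
              map_catalog_hits = length(hits)),
    alpha = diff$alpha, fdr = diff$fdr,
    members = list(fdr_significant = fdr_members, map_catalog_hits = hits)),
    class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Candidate filter cascade:\n")
  cat(sprintf("  quantified proteins      : %d\n", x$tiers["quantified"]))
  cat(sprintf("  p < %-4g                 : %d\n", x$alpha,
              x$tiers["raw_significant"]))
  cat(sprintf("  FDR <= %-4g              : %d\n", x$fdr,
              x$tiers["fdr_significant"]))
  cat(sprintf("  known microtubule binders: %d (%s)\n",
              x$tiers["map_catalog_hits"],
              paste(x$members$map_catalog_hits, collapse = ", ")))
  invisible(x)
}

#' Read GMT gene sets
#'
#' @param file GMT path (set name, description, member symbols per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  if (any(lengths(sets) == 0)) abort("GMT contains an empty gene set")
  sets
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric p-value of the foreground/set overlap given the
#' background, BH-adjusted across sets.
#'
#' @param foreground character vector of hit symbols (subset of background).
#' @param background character vector defining the tested universe.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @return data frame: set, set_size (in background), overlap, p_value,
#'   q_value, members.
#' @export
enrichment <- function(foreground, background, sets) {
  fg <- unique(canonical_symbol(foreground))
  bg <- unique(canonical_symbol(background))
  out_of_bg <- setdiff(fg, bg)
  if (length(out_of_bg))
    abort("foreground symbols missing from background: ",
          paste(out_of_bg, collapse = ", "))
  if (any(lengths(sets) == 0)) abort("gene sets must be non-empty")
  N <- length(bg); n <- length(fg)
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    K <- length(intersect(canonical_symbol(sets[[nm]]), bg))
    k <- length(intersect(canonical_symbol(sets[[nm]]), fg))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  }))
  res$q_value <- bh_adjust(res$p_value)
  res[order(res$p_value), ]
}

#' Volcano-plot export table
#'
#' @param diff a [differential_abundance()] result.
#' @return data frame: accession, symbol, log2fc, neg_log10_p, sig_p01,
#'   sig_fdr05.
#' @export
volcano_table <- function(diff) {
  tab <- diff$table
  data.frame(accession = tab$accession, symbol = tab$symbol,
             log2fc = tab$mean_log2fc, neg_log10_p = -log10(tab$p_value),
             sig_p01 = tab$sig_p01, sig_fdr05 = tab$sig_fdr05,
             stringsAsFactors = FALSE)
}
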