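#' Construct a Ct table
#'
#' Long-format quantification-cycle table: one row per well replicate, with
#' gene roles split into targets and reference (control) genes.
#'
#' @param df data frame with columns `sample_id`, `group`, `gene`,
#'   `replicate`, `ct` (finite cycles).
#' @param reference_genes character vector (>= 1) of reference gene names.
#' @return data frame of class `ct_table` with a `reference_genes` attribute.
#' @export
ct_table <- function(df, reference_genes) {
  req <- c("sample_id", "group", "gene", "replicate", "ct")
  if (!all(req %in% names(df)))
    abort("Ct table needs columns: ", paste(req, collapse = ", "))
  if (any(!is.finite(df$ct))) abort("replicate Ct values must be finite")
  if (!length(reference_genes)) abort("at least one reference gene is required")
  missing_ref <- setdiff(reference_genes, unique(df$gene))
  if (length(missing_ref))
    abort("reference gene(s) not measured: ", paste(missing_ref, collapse = ", "))
  structure(as.data.frame(df), class = c("ct_table", "data.frame"),
            reference_genes = reference_genes)
}

#' Read a wide Ct TSV (sample, group, gene, ct_1..ct_k)
#'
#' @param file path.
#' @param reference_genes reference gene names.
#' @return a [ct_table()].
#' @export
read_ct_table <- function(file, reference_genes) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  ct_cols <- grep("^ct_", names(df), value = TRUE)
  if (!length(ct_cols)) abort("no ct_1..ct_k columns found")
  long <- do.call(rbind, lapply(seq_along(ct_cols), function(i) {
    data.frame(sample_id = df$sample, group = df$group, gene = df$gene,
               replicate = i, ct = df[[ct_cols[i]]], stringsAsFactors = FALSE)
  }))
  long <- long[is.finite(long$ct), ]
  ct_table(long, reference_genes)
}

#' Amplification factor from percent efficiency
#'
#' @param pct percent efficiency in (0, 100].
#' @return amplification factor `E = 1 + pct / 100`.
#' @export
efficiency_from_percent <- function(pct) {
  E <- 1 + pct / 100
  check_efficiency(E)
  E
}

check_efficiency <- function(E) {
  if (any(!is.finite(E)) || any(E <= 1) || any(E > 2))
    abort("amplification factors must lie in (1, 2] (2 = perfect doubling)")
  invisible(E)
}

# replicate-averaged Ct of one gene in one sample
mean_ct <- function(ct, sample, gene) {
  v <- ct$ct[ct$sample_id == sample & ct$gene == gene]
  if (!length(v)) abort("gene '", gene, "' not measured for sample '", sample, "'")
  mean(v)
}

#' Geometric mean of the reference-gene Ct values for a sample
#'
#' Technical replicates of each reference gene are averaged first; the
#' geometric mean is then taken across reference genes, in cycle space (the
#' study's literal procedure). `space = "quantity"` instead geometric-means
#' the per-gene relative quantities `E^-Ct` and returns the equivalent cycle
#' value at efficiency 2.
#'
#' @param ct a [ct_table()].
#' @param sample sample id.
#' @param space `"ct"` (default, literal) or `"quantity"`.
#' @param efficiencies named amplification factors (needed for
#'   `space = "quantity"`).
#' @return reference value in cycles.
#' @export
reference_geomean <- function(ct, sample, space = c("ct", "quantity"),
                              efficiencies = NULL) {
  space <- match.arg(space)
  refs <- attr(ct, "reference_genes")
  cts <- vapply(refs, function(g) mean_ct(ct, sample, g), numeric(1))
  if (space == "ct") return(geometric_mean(cts))
  if (is.null(efficiencies)) abort("quantity-space reference needs efficiencies")
  check_efficiency(efficiencies[refs])
  q <- efficiencies[refs]^(-cts)
  -log2(geometric_mean(q))
}

#' Efficiency-corrected relative expression of a target in one sample
#'
#' Relative level = `E_target^(-dCt)` with `dCt` = replicate-averaged target
#' Ct minus the reference geometric mean from [reference_geomean()].
#'
#' @param ct a [ct_table()].
#' @param efficiencies named per-gene amplification factors in (1, 2].
#' @param target target gene.
#' @param sample sample id.
#' @param ref_space passed to [reference_geomean()].
#' @return relative expression level (dimensionless).
#' @export
relative_level <- function(ct, efficiencies, target, sample,
                           ref_space = "ct") {
  if (is.na(efficiencies[target])) abort("no efficiency for gene '", target, "'")
  check_efficiency(efficiencies[target])
  dct <- mean_ct(ct, sample, target) -
    reference_geomean(ct, sample, space = ref_space,
                      efficiencies = efficiencies)
  unname(efficiencies[target]^(-dct))
}

#' Group-level relative expression report
#'
#' Computes per-sample relative levels for every target gene, normalizes to
#' the control-group mean, and compares groups per target (t test with a
#' Shapiro-Wilk gate switching to Mann-Whitney). With `method = "pfaffl"` the
#' group ratio is computed as the Pfaffl ratio
#' `E_target^dCt_target / E_ref^dCt_ref` using group-mean Cts (reference
#' efficiency = geometric mean of the reference genes' efficiencies).
#'
#' @param ct a [ct_table()].
#' @param efficiencies named per-gene amplification factors.
#' @param control_group label of the reference group.
#' @param method `"e_dct"` (default) or `"pfaffl"`.
#' @param ref_space passed to [reference_geomean()].
#' @return list of class `qpcr_report`: `levels` (per sample x target),
#'   `group_ratios` (target, ratio), `tests` (per target `test_result`).
#' @export
qpcr_relative_expression <- function(ct, efficiencies, control_group,
                                     method = c("e_dct", "pfaffl"),
                                     ref_space = "ct") {
  method <- match.arg(method)
  refs <- attr(ct, "reference_genes")
  targets <- setdiff(unique(ct$gene), refs)
  samples <- unique(ct[, c("sample_id", "group")])
  if (!control_group %in% samples$group)
    abort("control group '", control_group, "' not present")
  levels_df <- do.call(rbind, lapply(targets, function(tg) {
    lv <- vapply(samples$sample_id, function(s)
      relative_level(ct, efficiencies, tg, s, ref_space = ref_space),
      numeric(1))
    data.frame(sample_id = samples$sample_id, group = samples$group,
               gene = tg, level = lv, stringsAsFactors = FALSE)
  }))
  # normalize to control mean so controls average 1
  for (tg in targets) {
    sel <- levels_df$gene == tg
    ctl_mean <- mean(levels_df$level[sel & levels_df$group == control_group])
    levels_df$level_rel_control[sel] <- levels_df$level[sel] / ctl_mean
  }
  other <- setdiff(unique(samples$group), control_group)
  ratios <- do.call(rbind, lapply(targets, function(tg) {
    do.call(rbind, lapply(other, function(g) {
      r <- if (method == "e_dct") {
        sel <- levels_df$gene == tg
        mean(levels_df$level[sel & levels_df$group == g]) /
          mean(levels_df$level[sel & levels_df$group == control_group])
      } else {
        e_ref <- geometric_mean(efficiencies[refs])
        grp_mean_ct <- function(gene, grp) {
          ids <- samples$sample_id[samples$group == grp]
          mean(vapply(ids, function(s) mean_ct(ct, s, gene), numeric(1)))
        }
        ref_ct <- function(grp) {
          ids <- samples$sample_id[samples$group == grp]
          mean(vapply(ids, function(s) reference_geomean(ct, s), numeric(1)))
        }
        dct_t <- grp_mean_ct(tg, control_group) - grp_mean_ct(tg, g)
        dct_r <- ref_ct(control_group) - ref_ct(g)
        unname(efficiencies[tg]^dct_t / e_ref^dct_r)
      }
      data.frame(gene = tg, group = g, ratio_vs_control = r,
                 stringsAsFactors = FALSE)
    }))
  }))
  tests <- lapply(setNames(targets, targets), function(tg) {
    sel <- levels_df$gene == tg
    if (length(other) != 1L) return(NULL)
    welch_or_student_t(
      levels_df$level_rel_control[sel & levels_df$group == other],
      levels_df$level_rel_control[sel & levels_df$group == control_group],
      auto_switch = TRUE)
  })
  structure(list(levels = levels_df, group_ratios = ratios, tests = tests,
                 method = method, control_group = control_group),
            class = "qpcr_report")
}

#' @export
print.qpcr_report <- function(x, ...) {
  cat("qPCR relative expression (", x$method, "), control = ",
      x$control_group, "\n", sep = "")
  for (i in seq_len(nrow(x$group_ratios))) {
    r <- x$group_ratios[i, ]
    p <- x$tests[[r$gene]]$p_value
    cat(sprintf("  %s %s/%s: fold change %.3f%s\n", r$gene, r$group,
                x$control_group, r$ratio_vs_control,
                if (!is.null(p)) sprintf(", p = %.3g", p) else ""))
  }
  invisible(x)
}

#' Configuration for the qPCR simulator
#'
#' Ct values are generated as `baseline - log_E(quantity x loading) + noise`;
#' reference genes share quantity 1 in both groups, target quantities carry
#' the configured fold changes in the mutant group, and a per-sample loading
#' factor affects all genes of a sample alike (removed by dCt).
#'
#' @param true_fold_changes named per-target fold changes (mutant/control).
#' @param reference_genes names of the stable reference genes.
#' @param efficiencies named per-gene amplification factors in (1, 2].
#' @param baselines named per-gene baseline Ct at quantity 1 (defaults: 24 for
#'   targets, 20 for references).
#' @param ct_noise_sd well-to-well Ct noise sd (cycles).
#' @param loading_log2_sd per-sample loading spread (log2).
#' @param n_samples_per_group biological replicates per group.
#' @param replicates technical replicates per well (default 3).
#' @param groups group labels, control first.
#' @param seed integer seed.
#' @return an object of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(true_fold_changes = c(Vapb = 1, Reep1 = 1,
                                                  Ezr = 1, Prnp = 1),
                            reference_genes = c("Hprt", "Tfrc", "Pgk1"),
                            efficiencies = NULL, baselines = NULL,
                            ct_noise_sd = 0.1, loading_log2_sd = 0.3,
                            n_samples_per_group = 5, replicates = 3,
                            groups = c("control", "mutant"), seed = 1L) {
  targets <- names(true_fold_changes)
  genes <- c(targets, reference_genes)
  if (is.null(efficiencies))
    efficiencies <- setNames(rep(1.9, length(genes)), genes)
  check_efficiency(efficiencies[genes])
  if (is.null(baselines))
    baselines <- setNames(c(rep(24, length(targets)),
                            rep(20, length(reference_genes))), genes)
  assert_scalar_number(ct_noise_sd, "ct_noise_sd", 0)
  replicates <- assert_count(replicates, "replicates")
  n_samples_per_group <- assert_count(n_samples_per_group, "n_samples_per_group")
  structure(list(true_fold_changes = true_fold_changes,
                 reference_genes = reference_genes, efficiencies = efficiencies,
                 baselines = baselines, ct_noise_sd = ct_noise_sd,
                 loading_log2_sd = loading_log2_sd,
                 n_samples_per_group = n_samples_per_group,
                 replicates = replicates, groups = groups, seed = seed),
            class = "qpcr_sim_config")
}

#' Simulate a Ct table with known fold changes
#'
#' @param config a [qpcr_sim_config()].
#' @return a [ct_table()].
#' @export
simulate_qpcr <- function(config) {
  if (!inherits(config, "qpcr_sim_config"))
    config_error("config", "must be a qpcr_sim_config")
  with_seed(config$seed, {
    targets <- names(config$true_fold_changes)
    genes <- c(targets, config$reference_genes)
    rows <- list()
    for (g in config$groups) {
      for (s in seq_len(config$n_samples_per_group)) {
        sid <- sprintf("%s_%02d", g, s)
        load <- 2^rnorm(1, 0, config$loading_log2_sd)
        for (gene in genes) {
          q <- if (gene %in% targets && g != config$groups[1])
            config$true_fold_changes[[gene]] else 1
          E <- config$efficiencies[[gene]]
          ct0 <- config$baselines[[gene]] - log(q * load) / log(E)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, group = g, gene = gene,
            replicate = seq_len(config$replicates),
            ct = ct0 + rnorm(config$replicates, 0, config$ct_noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    ct_table(do.call(rbind, rows), config$reference_genes)
  })
}
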