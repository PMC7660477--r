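#' Ordered region schemes for binned cell counting
#'
#' Built-in schemes: `"cortex10"` (ten equally spaced depth bins, bin 1
#' deepest/ventricular side), `"hippocampus"` (OL, PCL, RL, LM, MDG, DG, H),
#' `"cerebellum"` (IGL, PCL, ML, EGL) and `"electroporation"` (VZ, SVZ, iIZ,
#' mIZ, oIZ, iCP, mCP, oCP).
#'
#' @param name built-in scheme name, or `"custom"` with `labels`.
#' @param labels ordered unique region labels for a custom scheme.
#' @return ordered character vector of class `region_scheme`.
#' @export
region_scheme <- function(name = c("cortex10", "hippocampus", "cerebellum",
                                   "electroporation", "custom"),
                          labels = NULL) {
  name <- match.arg(name)
  labels <- switch(name,
    cortex10 = paste0("bin_", 1:10),
    hippocampus = c("OL", "PCL", "RL", "LM", "MDG", "DG", "H"),
    cerebellum = c("IGL", "PCL", "ML", "EGL"),
    electroporation = c("VZ", "SVZ", "iIZ", "mIZ", "oIZ", "iCP", "mCP", "oCP"),
    custom = labels)
  if (is.null(labels) || !length(labels) || anyDuplicated(labels))
    abort("a region scheme needs unique, ordered labels")
  structure(as.character(labels), class = "region_scheme", name = name)
}

#' Bin normalized depth positions into equal-width regions
#'
#' Bin i (1-based, deep to superficial) receives positions in the half-open
#' interval [(i-1)/n, i/n); a position exactly at 1.0 falls in the last bin.
#'
#' @param positions depth fractions in `[0, 1]`.
#' @param n_bins number of equal bins (default 10).
#' @return named integer vector of counts summing to `length(positions)`.
#' @export
bin_positions <- function(positions, n_bins = 10) {
  if (any(!is.finite(positions)) || any(positions < 0 | positions > 1))
    abort("positions must be depth fractions in [0, 1]")
  idx <- pmin(floor(positions * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  names(counts) <- paste0("bin_", seq_len(n_bins))
  counts
}

#' Construct a per-animal cell count table
#'
#' @param df data frame with columns `animal_id`, `group`, `region`, `count`;
#'   every animal must have one count per region of the scheme.
#' @param scheme a [region_scheme()].
#' @return data frame of class `cell_count_table` (scheme attached).
#' @export
cell_count_table <- function(df, scheme) {
  req <- c("animal_id", "group", "region", "count")
  if (!all(req %in% names(df)))
    abort("count table needs columns: ", paste(req, collapse = ", "))
  if (any(df$count < 0) || any(df$count != round(df$count)))
    abort("counts must be non-negative integers")
  bad_region <- setdiff(unique(df$region), scheme)
  if (length(bad_region))
    abort("regions not in scheme: ", paste(bad_region, collapse = ", "))
  for (a in unique(df$animal_id)) {
    have <- df$region[df$animal_id == a]
    if (!setequal(have, scheme) || length(have) != length(scheme))
      abort("animal '", a, "' must have exactly one count per region")
  }
  structure(as.data.frame(df), class = c("cell_count_table", "data.frame"),
            scheme = scheme)
}

#' Simulation configuration for binned cell distributions
#'
#' Each animal's cells are distributed over the scheme's regions by an
#' independent multinomial draw with group-specific probabilities.
#'
#' @param n_animals_per_group animals per group.
#' @param n_cells_per_animal cells counted per animal.
#' @param bin_probs named list (one per group) of probability vectors over the
#'   scheme's regions, each summing to 1.
#' @param scheme a [region_scheme()].
#' @param seed integer seed.
#' @return an object of class `bin_sim_config`.
#' @export
bin_sim_config <- function(n_animals_per_group = 5, n_cells_per_animal = 300,
                           bin_probs, scheme = region_scheme("cortex10"),
                           seed = 1L) {
  n_animals_per_group <- assert_count(n_animals_per_group, "n_animals_per_group")
  n_cells_per_animal <- assert_count(n_cells_per_animal, "n_cells_per_animal")
  for (g in names(bin_probs)) {
    p <- bin_probs[[g]]
    if (length(p) != length(scheme))
      config_error("bin_probs",
                   paste0("group '", g, "' length must match the scheme (",
                          length(scheme), " regions)"))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      config_error("bin_probs",
                   paste0("group '", g, "' must be a probability vector summing to 1"))
  }
  structure(list(n_animals_per_group = n_animals_per_group,
                 n_cells_per_animal = n_cells_per_animal,
                 bin_probs = bin_probs, scheme = scheme, seed = seed),
            class = "bin_sim_config")
}

#' Default laminar bin probabilities
#'
#' A control profile peaked in the superficial bins (destination of the
#' labelled cohort) and a migration-defect profile with mass shifted to the
#' deep bins, emulating an arrest of neuronal migration.
#'
#' @return named list of two 10-bin probability vectors.
#' @export
default_bin_probs <- function() {
  list(control = c(0.02, 0.02, 0.03, 0.04, 0.05, 0.08, 0.12, 0.20, 0.30, 0.14),
       mutant  = c(0.10, 0.10, 0.05, 0.05, 0.05, 0.08, 0.10, 0.15, 0.22, 0.10))
}

#' Simulate a per-animal cell count table
#'
#' @param config a [bin_sim_config()].
#' @return a [cell_count_table()].
#' @export
simulate_bins <- function(config) {
  if (!inherits(config, "bin_sim_config"))
    config_error("config", "must be a bin_sim_config")
  with_seed(config$seed, {
    rows <- list()
    for (g in names(config$bin_probs)) {
      draws <- rmultinom(config$n_animals_per_group, config$n_cells_per_animal,
                         config$bin_probs[[g]])
      for (a in seq_len(config$n_animals_per_group)) {
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("%s_%02d", g, a), group = g,
          region = as.character(config$scheme), count = draws[, a],
          stringsAsFactors = FALSE)
      }
    }
    cell_count_table(do.call(rbind, rows), config$scheme)
  })
}

#' Per-animal region proportions with group summaries
#'
#' @param table a [cell_count_table()].
#' @return list with `proportions` (animal_id, group, region, proportion) and
#'   `summary` (group, region, mean, sem, n).
#' @export
relative_distribution <- function(table) {
  scheme <- attr(table, "scheme")
  totals <- tapply(table$count, table$animal_id, sum)
  if (any(totals == 0))
    abort("animal with zero total count: ",
          paste(names(totals)[totals == 0], collapse = ", "))
  prop <- table
  prop$proportion <- as.numeric(prop$count / totals[prop$animal_id])
  prop$region <- factor(prop$region, levels = scheme)
  agg <- aggregate(proportion ~ group + region, prop, function(v)
    c(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v)))
  summary <- data.frame(group = agg$group, region = agg$region,
                        mean = agg$proportion[, "mean"],
                        sem = agg$proportion[, "sem"],
                        n = agg$proportion[, "n"])
  list(proportions = prop[, c("animal_id", "group", "region", "proportion")],
       summary = summary[order(summary$group, summary$region), ])
}

#' Compare binned distributions between groups
#'
#' Two-way mixed (split-plot) ANOVA on per-animal region proportions (or raw
#' counts): group as the between-animal factor, region as the repeated
#' within-animal factor, with the group effect tested against the
#' between-animal stratum. Per-region group contrasts use the per-region data
#' with Sidak (default) or Tukey correction across regions x group pairs, and
#' total counts are compared by a t test or Mann-Whitney according to a
#' Shapiro-Wilk normality gate.
#'
#' @param table a [cell_count_table()].
#' @param posthoc `"sidak"` or `"tukey"`.
#' @param use analyse `"proportions"` (default) or `"counts"`.
#' @param gg_correction apply the Greenhouse-Geisser sphericity correction to
#'   the within-animal (region and interaction) tests; off by default.
#' @return list of class `distribution_result`: `anova` (effect, df1, df2, F,
#'   p), `posthoc` (per region x pair), `totals` (a `test_result`),
#'   `distribution` from [relative_distribution()].
#' @export
compare_distributions <- function(table, posthoc = c("sidak", "tukey"),
                                  use = c("proportions", "counts"),
                                  gg_correction = FALSE) {
  posthoc <- match.arg(posthoc); use <- match.arg(use)
  scheme <- attr(table, "scheme")
  groups <- unique(table$group)
  if (length(groups) < 2L) abort("need at least two groups")
  n_per_group <- tapply(table$animal_id, table$group,
                        function(a) length(unique(a)))
  if (any(n_per_group < 2L)) abort("need >= 2 animals per group")
  rel <- relative_distribution(table)
  dat <- rel$proportions
  dat$count <- table$count[match(paste(dat$animal_id, dat$region),
                                 paste(table$animal_id, table$region))]
  dat$y <- if (use == "proportions") dat$proportion else dat$count
  dat$group <- factor(dat$group)
  dat$region <- factor(dat$region, levels = scheme)
  dat$animal_id <- factor(dat$animal_id)

  fit <- aov(y ~ group * region + Error(animal_id), data = dat)
  s <- summary(fit)
  between <- s[["Error: animal_id"]][[1]]
  within <- s[["Error: Within"]][[1]]
  pick <- function(stratum, label) {
    i <- grep(paste0("^", label, "\\s*$"), trimws(rownames(stratum)))
    resid <- grep("Residuals", rownames(stratum))
    data.frame(effect = label, df1 = stratum$Df[i], df2 = stratum$Df[resid],
               F = stratum$`F value`[i], p = stratum$`Pr(>F)`[i],
               stringsAsFactors = FALSE)
  }
  anova_tab <- rbind(pick(between, "group"),
                     pick(within, "region"),
                     pick(within, "group:region"))
  if (gg_correction) {
    # Greenhouse-Geisser epsilon from the pooled within-group covariance of
    # the animal x region response matrix
    wide <- tapply(dat$y, list(dat$animal_id, dat$region), mean)
    grp_of <- tapply(as.character(dat$group), dat$animal_id, `[`, 1)
    centered <- wide
    for (g in unique(grp_of))
      centered[grp_of == g, ] <- scale(wide[grp_of == g, , drop = FALSE],
                                       scale = FALSE)
    S <- crossprod(centered) / (nrow(wide) - length(unique(grp_of)))
    k <- ncol(S)
    Cm <- diag(k) - 1 / k
    CS <- Cm %*% S %*% Cm
    eps <- sum(diag(CS))^2 / ((k - 1) * sum(CS * CS))
    eps <- min(1, max(eps, 1 / (k - 1)))
    within_rows <- anova_tab$effect != "group"
    anova_tab$df1[within_rows] <- anova_tab$df1[within_rows] * eps
    anova_tab$df2[within_rows] <- anova_tab$df2[within_rows] * eps
    anova_tab$p[within_rows] <- stats::pf(anova_tab$F[within_rows],
                                          anova_tab$df1[within_rows],
                                          anova_tab$df2[within_rows],
                                          lower.tail = FALSE)
    attr(anova_tab, "gg_epsilon") <- eps
  }

  # per-region pairwise group contrasts
  pairs <- combn(levels(dat$group), 2)
  m <- length(scheme) * ncol(pairs)
  ph <- do.call(rbind, lapply(scheme, function(rg) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- dat$y[dat$region == rg & dat$group == pairs[1, i]]
      b <- dat$y[dat$region == rg & dat$group == pairs[2, i]]
      if (posthoc == "sidak") {
        tt <- tryCatch(t.test(a, b), error = function(e) NULL)
        p_raw <- if (is.null(tt)) 1 else tt$p.value
        p_adj <- adjust_pvalues(p_raw, "sidak", m = m)
        stat <- if (is.null(tt)) 0 else unname(tt$statistic)
      } else {
        # Tukey-style studentized range on the per-region cell means
        cell <- split(dat$y[dat$region == rg], dat$group[dat$region == rg])
        k <- length(cell)
        nn <- lengths(cell)
        mse <- sum(vapply(cell, function(v) sum((v - mean(v))^2), numeric(1))) /
          sum(nn - 1)
        se <- sqrt(mse / 2 * (1 / length(a) + 1 / length(b)))
        stat <- (mean(a) - mean(b)) / se
        p_raw <- ptukey(abs(stat), k, sum(nn - 1), lower.tail = FALSE)
        p_adj <- adjust_pvalues(p_raw, "sidak", m = length(scheme))
      }
      data.frame(region = rg, group1 = pairs[1, i], group2 = pairs[2, i],
                 statistic = stat, p_raw = p_raw, p_adj = p_adj,
                 stringsAsFactors = FALSE)
    }))
  }))

  totals_by_animal <- tapply(table$count, table$animal_id, sum)
  grp_of_animal <- tapply(as.character(table$group), table$animal_id, `[`, 1)
  totals_test <- if (length(groups) == 2L) {
    welch_or_student_t(totals_by_animal[grp_of_animal == groups[1]],
                       totals_by_animal[grp_of_animal == groups[2]],
                       auto_switch = TRUE)
  } else NULL

  structure(list(anova = anova_tab, posthoc = ph, posthoc_method = posthoc,
                 response = use, gg_correction = gg_correction,
                 totals = totals_test,
                 distribution = rel), class = "distribution_result")
}

#' @export
print.distribution_result <- function(x, ...) {
  cat("Binned distribution comparison (", x$response, ")\n", sep = "")
  print(x$anova, row.names = FALSE)
  sig <- x$posthoc[x$posthoc$p_adj < 0.05, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant per-region contrasts (", x$posthoc_method, "):\n", sep = "")
    print(sig, row.names = FALSE)
  } else cat("no significant per-region contrasts\n")
  invisible(x)
}
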