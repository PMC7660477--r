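#' Upper-tail chi-square p-value
#'
#' @param statistic chi-square statistic.
#' @param df degrees of freedom.
#' @return p-value.
#' @export
chisq_pvalue <- function(statistic, df) pchisq(statistic, df, lower.tail = FALSE)

new_test_result <- function(test, statistic, df = NA_real_, p_value, n,
                            effect = NULL, correction = "none", options = list()) {
  structure(list(test = test, statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), n = n, effect = effect,
                 correction = correction, options = options),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (n: %s)\n", x$test,
              x$statistic,
              if (is.finite(x$df)) sprintf(", df = %g", x$df) else "",
              x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Serialize a test result to JSON
#'
#' @param x a `test_result` (or trafficking/distribution report).
#' @param file optional path; when given the JSON is written there.
#' @return JSON string, invisibly when written to file.
#' @export
test_result_json <- function(x, file = NULL) {
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                         na = "null", force = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' Pearson chi-square test of independence
#'
#' No continuity correction (the study's contingency comparisons use 2 x 4
#' tables with large n).
#'
#' @param tab r x c matrix of counts (>= 2 rows and columns, no zero
#'   marginal).
#' @return a `test_result`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    abort("chi-square needs at least a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    abort("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("a zero marginal makes the chi-square test undefined")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  new_test_result("chi-square test of independence",
                  statistic = ct$statistic, df = ct$parameter,
                  p_value = ct$p.value, n = sum(tab),
                  effect = list(row_proportions = prop.table(tab, 1)))
}

#' Mann-Whitney U test
#'
#' U is computed from midranks. In `"auto"` mode the p-value is exact (by
#' enumeration of the U null distribution) when n_x + n_y <= 12 and there are
#' no ties, otherwise a normal approximation with tie correction (and
#' continuity correction) is used. Two-sided throughout.
#'
#' @param x,y numeric samples (>= 1 observation each).
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @param continuity apply the continuity correction in the asymptotic branch.
#' @return a `test_result`; `statistic` is U for the first sample.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "asymptotic"),
                         continuity = TRUE) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) abort("both groups need at least 1 observation")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = !ties && length(x) + length(y) <= 12,
                  exact = TRUE,
                  asymptotic = FALSE)
  if (exact && ties)
    abort("exact Mann-Whitney p-values are undefined with ties; use asymptotic mode")
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = continuity))
  new_test_result("Mann-Whitney U test", statistic = wt$statistic,
                  p_value = wt$p.value, n = c(length(x), length(y)),
                  effect = list(median_x = median(x), median_y = median(y)),
                  options = list(mode = mode,
                                 branch = if (exact) "exact" else "asymptotic",
                                 continuity = continuity, ties = ties))
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc contrasts
#'
#' The omnibus H uses the tie-corrected Kruskal-Wallis statistic; pairwise
#' Dunn z contrasts compare mean ranks with a tie-corrected standard error and
#' a Bonferroni-family correction.
#'
#' @param groups named list of numeric vectors (>= 3 groups).
#' @param correction `"bonferroni"` (default) or `"sidak"`.
#' @return list with `omnibus` (a `test_result`) and `pairwise` (data frame of
#'   Dunn contrasts).
#' @export
kruskal_dunn <- function(groups, correction = c("bonferroni", "sidak")) {
  correction <- match.arg(correction)
  if (length(groups) < 3L)
    abort("kruskal_dunn needs >= 3 groups; use mann_whitney for two")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kt <- kruskal.test(x, g)
  omnibus <- new_test_result("Kruskal-Wallis rank sum test",
                             statistic = kt$statistic, df = kt$parameter,
                             p_value = kt$p.value, n = lengths(groups),
                             effect = list(medians = vapply(groups, median,
                                                            numeric(1))))
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  tie_tab <- table(x)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- combn(names(groups), 2)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / length(groups[[a]]) + 1 / length(groups[[b]])))
    z <- (rbar[[a]] - rbar[[b]]) / se
    data.frame(group1 = a, group2 = b, z = z, p_raw = 2 * pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))
  pw$p_adj <- adjust_pvalues(pw$p_raw, method = correction)
  list(omnibus = omnibus, pairwise = pw, correction = correction)
}

#' Multiple-comparison p-value adjustment
#'
#' Bonferroni (`min(1, m p)`), Sidak (`1 - (1 - p)^m`) or Benjamini-Hochberg
#' step-up (delegating to [bh_adjust()]).
#'
#' @param p p-values in `[0, 1]`.
#' @param method `"bonferroni"`, `"sidak"` or `"bh"`.
#' @param m number of comparisons (defaults to `length(p)`).
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "sidak", "bh"),
                           m = length(p)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  switch(method,
         bonferroni = pmin(1, m * p),
         sidak = 1 - (1 - p)^m,
         bh = bh_adjust(p))
}

#' Two-sample t test with a normality gate
#'
#' Welch by default (Student with `var_equal = TRUE`), two-sided. A
#' Shapiro-Wilk normality gate on each group (or on the pair differences) is
#' reported alongside; with `auto_switch = TRUE` a failed gate switches to the
#' Mann-Whitney test. The degenerate case of zero variance in both groups with
#' equal means yields p = 1 rather than an error.
#'
#' @param x,y numeric samples (n >= 2 per group; paired requires equal n).
#' @param paired paired test on differences.
#' @param var_equal pool variances (Student's t).
#' @param auto_switch switch to the nonparametric test when the gate rejects.
#' @param gate_alpha significance level of the normality gate.
#' @return a `test_result` (with `options$normality_gate` recorded).
#' @export
welch_or_student_t <- function(x, y, paired = FALSE, var_equal = FALSE,
                               auto_switch = FALSE, gate_alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) abort("need n >= 2 per group")
  if (paired && length(x) != length(y)) abort("paired test needs equal n")
  gate_data <- if (paired) list(differences = x - y) else list(x = x, y = y)
  gate <- lapply(gate_data, function(v) {
    if (length(unique(v)) < 3L) return(NA_real_)  # W undefined for constants
    shapiro.test(v)$p.value
  })
  gate_pass <- all(vapply(gate, function(p) is.na(p) || p >= gate_alpha,
                          logical(1)))
  if (auto_switch && !gate_pass) {
    res <- if (paired) {
      d <- x - y
      wt <- suppressWarnings(wilcox.test(d))
      new_test_result("Wilcoxon signed-rank test", statistic = wt$statistic,
                      p_value = wt$p.value, n = length(d))
    } else mann_whitney(x, y)
    res$options$normality_gate <- list(p = gate, passed = gate_pass,
                                       switched = TRUE)
    return(res)
  }
  degenerate <- if (paired) sd(x - y) == 0 else sd(x) == 0 && sd(y) == 0
  if (degenerate) {
    same <- if (paired) all(x == y) else mean(x) == mean(y)
    res <- new_test_result(
      if (paired) "paired t test" else "t test",
      statistic = if (same) 0 else Inf, df = NA_real_,
      p_value = if (same) 1 else 0,
      n = c(length(x), length(y)),
      effect = list(mean_x = mean(x), mean_y = mean(y)))
    res$options$normality_gate <- list(p = gate, passed = gate_pass,
                                       switched = FALSE)
    return(res)
  }
  tt <- t.test(x, y, paired = paired, var.equal = var_equal)
  res <- new_test_result(tt$method, statistic = tt$statistic,
                         df = tt$parameter, p_value = tt$p.value,
                         n = c(length(x), length(y)),
                         effect = list(mean_x = mean(x), mean_y = mean(y)))
  res$options$normality_gate <- list(p = gate, passed = gate_pass,
                                     switched = FALSE)
  res
}
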