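#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate aov chisq.test dnorm kruskal.test median pchisq
#'   pnorm pt ptukey qnorm quantile rexp rlnorm rmultinom rnorm rpois runif sd
#'   setNames shapiro.test t.test uniroot var wilcox.test
#' @importFrom utils read.delim write.table head combn read.csv write.csv
NULL

abort <- function(..., class = "maptrace_error") {
  stop(errorCondition(paste0(...), class = c(class, "maptrace_error")))
}

config_error <- function(field, msg) {
  abort("invalid configuration field '", field, "': ", msg,
        class = "maptrace_config_error")
}

assert_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error(field, "must be a single finite number")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    config_error(field, sprintf("must be in %s%s, %s]",
                                if (strict_lower) "(" else "[", lower, upper))
  invisible(x)
}

assert_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    config_error(field, paste0("must be an integer >= ", min))
  invisible(as.integer(x))
}

#' Evaluate an expression with a local RNG seed
#'
#' Saves and restores the global `.Random.seed` so generators are pure
#' functions of their `(config, seed)` arguments and never leak random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    config_error("seed", "must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

geometric_mean <- function(x) exp(mean(log(x)))
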