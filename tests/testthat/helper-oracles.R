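# Independent oracles used across the suite. These are deliberately written
# as naive loops / enumerations, separate from the package's implementations.

# brute-force scan of step-sign sequences: maximal same-sign blocks of at
# least `min_steps` consecutive steps
oracle_blocks <- function(signs, min_steps = 2L) {
  out <- list()
  n <- length(signs)
  i <- 1L
  while (i <= n) {
    if (signs[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && signs[j + 1L] == signs[i]) j <- j + 1L
    if (j - i + 1L >= min_steps)
      out[[length(out) + 1L]] <- c(start_step = i, end_step = j, sign = signs[i])
    i <- j + 1L
  }
  if (length(out)) do.call(rbind, out) else
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("start_step", "end_step", "sign")))
}

# positions with unit steps from a sign sequence
positions_from_signs <- function(signs, x0 = 50) x0 + cumsum(c(0, signs))

# truth table for track classification
oracle_classify <- function(directions) {
  a <- sum(directions == "anterograde"); r <- sum(directions == "retrograde")
  if (a == 0 && r == 0) "immobile"
  else if (a > 0 && r > 0) "bidirectional"
  else if (a > 0) "anterograde"
  else "retrograde"
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact <- function(x, y) {
  nx <- length(x)
  v <- c(x, y)
  rk <- rank(v)
  u_of <- function(idx) sum(rk[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  all_u <- apply(combn(length(v), nx), 2, u_of)
  p <- 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs))
  min(1, p)
}

# construct a tie-free sample pair with a prescribed U statistic
sample_with_U <- function(nx, ny, u) {
  stopifnot(u >= 0, u <= nx * ny)
  a <- integer(nx) # a[i] = how many y values lie below x_(i)
  rem <- u
  for (i in nx:1) {
    take <- min(ny, rem)
    a[i] <- take
    rem <- rem - take
  }
  pos <- seq_len(nx) + a           # positions of x in the sorted pool 1..nx+ny
  x <- sort(pos)
  y <- setdiff(seq_len(nx + ny), x)
  list(x = as.numeric(x), y = as.numeric(y))
}

# split-plot (two-way mixed) ANOVA from scratch via sums of squares;
# balanced regions, possibly unbalanced group sizes
oracle_mixed_anova <- function(y, group, animal, region) {
  group <- as.character(group); animal <- as.character(animal)
  region <- as.character(region)
  r <- length(unique(region))
  grand <- mean(y)
  animals <- unique(animal)
  grp_of <- vapply(animals, function(a) group[animal == a][1], character(1))
  ybar_an <- vapply(animals, function(a) mean(y[animal == a]), numeric(1))
  ybar_g <- tapply(y, group, mean)
  ybar_r <- tapply(y, region, mean)
  n_g <- table(grp_of)

  ss_total <- sum((y - grand)^2)
  ss_between <- r * sum((ybar_an - grand)^2)
  ss_group <- r * sum(n_g * (ybar_g[names(n_g)] - grand)^2)
  ss_animal <- ss_between - ss_group
  n_animals <- length(animals)
  ss_region <- n_animals * sum((ybar_r - grand)^2)
  ss_int <- 0
  for (g in names(ybar_g)) for (rg in names(ybar_r)) {
    sel <- group == g & region == rg
    ss_int <- ss_int + sum(sel) * (mean(y[sel]) - ybar_g[[g]] - ybar_r[[rg]] + grand)^2
  }
  ss_err <- ss_total - ss_between - ss_region - ss_int

  g_n <- length(unique(group))
  df_group <- g_n - 1
  df_animal <- sum(n_g - 1)
  df_region <- r - 1
  df_int <- df_group * df_region
  df_err <- df_region * df_animal

  F_group <- (ss_group / df_group) / (ss_animal / df_animal)
  F_region <- (ss_region / df_region) / (ss_err / df_err)
  F_int <- (ss_int / df_int) / (ss_err / df_err)
  data.frame(
    effect = c("group", "region", "group:region"),
    df1 = c(df_group, df_region, df_int),
    df2 = c(df_animal, df_err, df_err),
    F = c(F_group, F_region, F_int),
    p = c(pf(F_group, df_group, df_animal, lower.tail = FALSE),
          pf(F_region, df_region, df_err, lower.tail = FALSE),
          pf(F_int, df_int, df_err, lower.tail = FALSE)),
    stringsAsFactors = FALSE)
}

# independent filter cascade used to check candidate_cascade
oracle_cascade_counts <- function(tab, alpha, fdr, catalog_symbols) {
  p01 <- 0L; f05 <- 0L; hits <- character(0)
  q <- p.adjust(tab$p_value, method = "BH")
  for (i in seq_len(nrow(tab))) {
    if (tab$p_value[i] < alpha) p01 <- p01 + 1L
    if (q[i] <= fdr) {
      f05 <- f05 + 1L
      if (toupper(tab$symbol[i]) %in% toupper(catalog_symbols))
        hits <- c(hits, tab$symbol[i])
    }
  }
  c(quantified = nrow(tab), raw_significant = p01, fdr_significant = f05,
    map_catalog_hits = length(hits))
}

# small helper: a hand-built track with given positions
make_track <- function(pos, id = "t1", group = "g", dt = 0.5, px = 0.1) {
  maptrace::track(id, group, pos, frame_interval_s = dt, pixel_size_um = px)
}
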