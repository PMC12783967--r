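# Group statistics matching the study's reporting: two-way ANOVA
# (genotype x age, type-II sums of squares) with Bonferroni-adjusted
# pairwise genotype contrasts within age, tie-corrected Kruskal-Wallis for
# the PSD comparisons, unpaired two-tailed t tests recomputable from
# printed summaries, a Z-score outlier filter, and mean +/- SD (n) summary
# tables with significance stars.

#' Two-way ANOVA with Bonferroni-adjusted genotype contrasts
#'
#' Fits `value ~ genotype * age`, reports type-II sums of squares per effect
#' (each main effect measured after the other, the interaction after both;
#' robust for mildly unbalanced designs) and, within each age level, an
#' unpaired two-tailed genotype contrast with Bonferroni adjustment over the
#' number of contrasts.
#'
#' @param data Data frame of per-observation values.
#' @param value,genotype,age Column names.
#' @param var_equal Pooled-variance contrasts if `TRUE`.
#' @return A list of class `anova_report`: `anova` (data frame: effect, SS,
#'   df, F, p), `pairwise` (data frame: age, t, df, p, p_adj).
#' @export
two_way_anova_bonferroni <- function(data, value = "value",
                                     genotype = "genotype", age = "age",
                                     var_equal = TRUE) {
  df <- data.frame(value = data[[value]],
                   genotype = factor(data[[genotype]]),
                   age = factor(data[[age]]))
  if (nlevels(df$genotype) < 2 || nlevels(df$age) < 2)
    stop("need >= 2 levels per factor")
  counts <- table(df$genotype, df$age)
  if (any(counts < 2)) {
    bad <- which(counts < 2, arr.ind = TRUE)[1, ]
    stop(sprintf("cell %s x %s has fewer than 2 observations",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  # type-II sums of squares by nested model comparison: each main effect is
  # measured after the other main effect, the interaction after both
  rss <- function(form) sum(stats::resid(stats::lm(form, data = df))^2)
  r_full <- rss(value ~ genotype * age)
  r_add <- rss(value ~ genotype + age)
  ss <- c(genotype = rss(value ~ age) - r_add,
          age = rss(value ~ genotype) - r_add,
          `genotype:age` = r_add - r_full)
  dfs <- c(nlevels(df$genotype) - 1L, nlevels(df$age) - 1L,
           (nlevels(df$genotype) - 1L) * (nlevels(df$age) - 1L))
  df_res <- nrow(df) - nlevels(df$genotype) * nlevels(df$age)
  ms_res <- r_full / df_res
  Fv <- (ss / dfs) / ms_res
  atab <- data.frame(effect = names(ss), sum_sq = unname(ss), df = dfs,
                     F = unname(Fv),
                     p = unname(stats::pf(Fv, dfs, df_res, lower.tail = FALSE)),
                     row.names = NULL)
  ages <- levels(df$age)
  pw <- do.call(rbind, lapply(ages, function(a) {
    sub <- df[df$age == a, ]
    g <- split(sub$value, droplevels(sub$genotype))
    tt <- t_test_from_summary(mean(g[[1]]), stats::sd(g[[1]]), length(g[[1]]),
                              mean(g[[2]]), stats::sd(g[[2]]), length(g[[2]]),
                              variant = if (var_equal) "pooled" else "welch")
    data.frame(age = a, t = tt$t, df = tt$df, p = tt$p)
  }))
  pw$p_adj <- pmin(1, pw$p * nrow(pw))  # Bonferroni over contrasts
  structure(list(anova = atab, pairwise = pw), class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat("<anova_report>\n")
  print(format(x$anova, digits = 4))
  cat("pairwise genotype contrasts (Bonferroni):\n")
  print(format(x$pairwise, digits = 4))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with its chi-square p-value (the
#' non-parametric comparison used for band-power distributions). Groups of
#' identical values across the board return `H = 0`, `p = 1`.
#'
#' @param groups A list of numeric vectors (>= 2 groups, each non-empty).
#' @return A list with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 1))
  values <- unlist(groups)
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Unpaired two-tailed t test from summary statistics
#'
#' Recomputes the two-sample t statistic from group means, SDs and sizes,
#' as needed to check printed comparisons when only summaries are published.
#' With zero variance in both groups and equal means, returns `t = 0`,
#' `p = 1`.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries (n >= 2 each).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A list with `t`, `df` and two-tailed `p`.
#' @examples
#' t_test_from_summary(0.312, 0.094, 8, 0.145, 0.05, 8, variant = "pooled")
#' @export
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b) return(list(t = 0, df = n_a + n_b - 2, p = 1))
    return(list(t = Inf * sign(mean_a - mean_b), df = n_a + n_b - 2, p = 0))
  }
  if (variant == "pooled") {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Z-score outlier filter
#'
#' Single-pass removal of values whose standardised score (from the sample
#' mean and SD of all values) exceeds the threshold in magnitude. With zero
#' SD nothing is removed. Note that for n observations the attainable |z|
#' is bounded by (n-1)/sqrt(n), so small samples can never trigger large
#' thresholds.
#'
#' @param values Numeric vector, n >= 3.
#' @param threshold |z| cutoff (default 2).
#' @return A list with `retained`, `removed` and `z`.
#' @examples
#' z_outlier_filter(c(rep(1, 8), 10))$removed  # 10
#' @export
z_outlier_filter <- function(values, threshold = 2) {
  stopifnot(length(values) >= 3)
  s <- stats::sd(values)
  if (s == 0) return(list(retained = values, removed = numeric(0),
                          z = rep(0, length(values))))
  z <- (values - mean(values)) / s
  keep <- abs(z) <= threshold
  list(retained = values[keep], removed = values[!keep], z = z)
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `""` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of stars.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) "" else if (pp < 0.001) "***" else if (pp < 0.01) "**"
    else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' Render a mean +/- SD (n) summary table
#'
#' Summarises per-observation results as `mean +/- SD (n)` strings, one row
#' per metric and one column per genotype x age group, with optional
#' significance stars appended per group. Missing groups render as `""`.
#'
#' @param rows Data frame with columns `metric`, `genotype`, `age`, `value`.
#' @param p_values Optional data frame with `metric`, `genotype`, `age`,
#'   `p`; stars are appended to the matching cells.
#' @param digits Significant digits for mean and SD.
#' @return A data frame, first column `metric`, then one column per group.
#' @export
render_summary_table <- function(rows, p_values = NULL, digits = 3) {
  stopifnot(nrow(rows) >= 1,
            all(c("metric", "genotype", "age", "value") %in% names(rows)))
  groups <- unique(rows[, c("genotype", "age")])
  groups <- groups[order(groups$genotype, groups$age), ]
  metrics <- unique(rows$metric)
  fmt <- function(v, star) {
    if (length(v) == 0) return("")
    s <- if (length(v) < 2) 0 else stats::sd(v)
    sprintf("%s ± %s (%d)%s", signif(mean(v), digits), signif(s, digits),
            length(v), star)
  }
  out <- data.frame(metric = metrics)
  for (i in seq_len(nrow(groups))) {
    col <- vapply(metrics, function(m) {
      sel <- rows$metric == m & rows$genotype == groups$genotype[i] &
        rows$age == groups$age[i]
      star <- ""
      if (!is.null(p_values)) {
        ps <- p_values[p_values$metric == m &
                         p_values$genotype == groups$genotype[i] &
                         p_values$age == groups$age[i], "p"]
        if (length(ps) == 1) star <- paste0(" ", p_stars(ps))
      }
      fmt(rows$value[sel], sub(" $", "", star))
    }, character(1))
    out[[paste(groups$genotype[i], groups$age[i], sep = "_")]] <- col
  }
  out
}
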