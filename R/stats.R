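#' Normality gate for choosing parametric vs nonparametric tests
#'
#' Applies the Shapiro-Wilk test to every group: the comparison is run
#' parametrically only if all groups are compatible with normality
#' (p >= `alpha` in each). Groups with fewer than 3 observations or zero
#' variance cannot be tested and route to the nonparametric branch with a
#' warning.
#'
#' @param groups a list of numeric vectors (or a single vector).
#' @param alpha gate level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`, with the per-group
#'   Shapiro-Wilk p values in `attr(, "shapiro_p")`.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  if (!is.list(groups)) groups <- list(groups)
  ps <- rep(NA_real_, length(groups))
  degenerate <- FALSE
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (length(g) < 3) {
      warning("group with n < 3: defaulting to nonparametric", call. = FALSE)
      degenerate <- TRUE
    } else if (stats::sd(g) == 0) {
      warning("group with zero variance: defaulting to nonparametric",
              call. = FALSE)
      degenerate <- TRUE
    } else {
      ps[i] <- stats::shapiro.test(g)$p.value
    }
  }
  branch <- if (degenerate || any(ps < alpha, na.rm = TRUE)) {
    "nonparametric"
  } else {
    "parametric"
  }
  structure(branch, shapiro_p = ps)
}

#' Two-group comparison with normality gating
#'
#' Unpaired two-sided t test (classic, equal variances) when the gate is
#' parametric, Wilcoxon rank-sum otherwise. The gate defaults to
#' [normality_gate()] on the two groups.
#'
#' @param a,b numeric vectors (non-empty).
#' @param gate `"parametric"`, `"nonparametric"`, or `NULL` to decide via
#'   the Shapiro-Wilk gate.
#' @param comparison optional label copied into the result.
#' @return one-row data frame: `comparison`, `test`, `statistic`, `df`,
#'   `p_value`, `branch`.
#' @export
two_group_test <- function(a, b, gate = NULL, comparison = NA_character_) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (is.null(gate)) gate <- as.character(normality_gate(list(a, b)))
  gate <- match.arg(gate, c("parametric", "nonparametric"))
  if (gate == "parametric") {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(comparison = comparison, test = "unpaired t",
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, branch = gate)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(comparison = comparison, test = "Wilcoxon rank-sum",
               statistic = unname(wt$statistic), df = NA_real_,
               p_value = wt$p.value, branch = gate)
  }
}

#' One-sample t test of fold changes against unity
#'
#' Two-sided one-sample t test of the mean fold change against the
#' hypothetical value mu = 1 (no change relative to the untreated
#' reference).
#'
#' @param fold_changes numeric vector, n >= 2, non-degenerate.
#' @return one-row data frame: `test`, `mean_fold_change`, `statistic`,
#'   `df`, `p_value`.
#' @export
one_sample_vs_unity <- function(fold_changes) {
  if (length(fold_changes) < 2) stop("need n >= 2", call. = FALSE)
  if (stats::sd(fold_changes) == 0) {
    stop("degenerate input: fold changes have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(fold_changes, mu = 1)
  data.frame(test = "one-sample t vs 1",
             mean_fold_change = mean(fold_changes),
             statistic = unname(tt$statistic),
             df = unname(tt$parameter),
             p_value = tt$p.value)
}

#' Two-way ANOVA with multiple comparisons
#'
#' Fits `value ~ genotype * treatment` by ANOVA and reports the effects
#' table plus corrected pairwise comparisons of the cell means (Sidak by
#' default, the standard companion to a two-way ANOVA in mainstream
#' biostatistics software; selectable).
#'
#' @param values numeric response.
#' @param factor_genotype,factor_treatment factors (>= 2 levels each, every
#'   crossed cell non-empty).
#' @param correction multiple-comparisons adjustment passed to
#'   `emmeans::contrast` (e.g. `"sidak"`, `"bonferroni"`, `"tukey"`).
#' @return list with `anova_table` (term, df, sum_sq, F, p), `pairwise`
#'   (corrected cell-mean comparisons), and `correction`.
#' @export
two_way_anova_mc <- function(values, factor_genotype, factor_treatment,
                             correction = "sidak") {
  g <- factor(factor_genotype)
  tr <- factor(factor_treatment)
  if (nlevels(g) < 2 || nlevels(tr) < 2) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  cells <- table(g, tr)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop(sprintf("empty design cell: genotype '%s' x treatment '%s'",
                 rownames(cells)[bad[1, 1]], colnames(cells)[bad[1, 2]]),
         call. = FALSE)
  }
  df <- data.frame(value = values, genotype = g, treatment = tr)
  fit <- stats::aov(value ~ genotype * treatment, data = df)
  an <- summary(fit)[[1]]
  anova_table <- data.frame(
    term = trimws(rownames(an)),
    df = an[["Df"]],
    sum_sq = an[["Sum Sq"]],
    statistic = an[["F value"]],
    p_value = an[["Pr(>F)"]]
  )
  emm <- emmeans::emmeans(fit, ~ genotype * treatment)
  pw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = correction))
  list(anova_table = anova_table, pairwise = pw, correction = correction)
}

#' Compare two histograms by Gaussian fits and the extra-sum-of-squares F test
#'
#' Fits an unweighted least-squares Gaussian `A * exp(-(x - m)^2 / (2 s^2))`
#' to each histogram separately and a single shared Gaussian to both
#' jointly, and compares the shared (null) against the separate
#' (alternative) model with the extra-sum-of-squares F test:
#' `F = ((RSS_shared - RSS_separate) / d_df) / (RSS_separate / df_separate)`.
#' Initial guesses are the max bin (amplitude) and the count-weighted mean
#' and sd of the bin centers. Non-convergent fits propagate as an error
#' with the optimizer's diagnostics; there is no silent fallback.
#'
#' @param histogram_a,histogram_b data frames with columns `mid` (common bin
#'   centers, identical in both) and `count`; at least 4 bins with mass each.
#' @return object of class `fit_comparison`: `rss_shared`, `rss_separate`,
#'   `df_extra`, `df_separate`, `f_statistic`, `p_value`, and per-histogram
#'   and shared fit parameters.
#' @export
gaussian_fit_compare <- function(histogram_a, histogram_b) {
  check_hist <- function(h, nm) {
    if (!all(c("mid", "count") %in% names(h))) {
      stop(nm, " must have columns `mid` and `count`", call. = FALSE)
    }
    if (sum(h$count > 0) < 4) {
      stop(nm, " needs at least 4 bins with mass", call. = FALSE)
    }
  }
  check_hist(histogram_a, "histogram_a")
  check_hist(histogram_b, "histogram_b")
  if (!isTRUE(all.equal(histogram_a$mid, histogram_b$mid))) {
    stop("histograms must share common bins", call. = FALSE)
  }

  gfit <- function(x, y) {
    start <- list(A = max(y),
                  m = stats::weighted.mean(x, y),
                  s = sqrt(stats::weighted.mean((x - stats::weighted.mean(x, y))^2, y)))
    if (!is.finite(start$s) || start$s <= 0) start$s <- diff(range(x)) / 4
    fit <- minpack.lm::nlsLM(
      y ~ A * exp(-(x - m)^2 / (2 * s^2)),
      data = data.frame(x = x, y = y), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    list(pars = stats::coef(fit), rss = sum(stats::resid(fit)^2))
  }
  fa <- gfit(histogram_a$mid, histogram_a$count)
  fb <- gfit(histogram_b$mid, histogram_b$count)
  pooled_x <- c(histogram_a$mid, histogram_b$mid)
  pooled_y <- c(histogram_a$count, histogram_b$count)
  fs <- gfit(pooled_x, pooled_y)

  rss_sep <- fa$rss + fb$rss
  rss_sh <- fs$rss
  df_extra <- 3L
  df_sep <- length(pooled_y) - 6L
  if (df_sep <= 0) stop("too few bins for the F test", call. = FALSE)
  num <- max(rss_sh - rss_sep, 0)
  if (num < 1e-12 && rss_sep < 1e-12) {
    f_stat <- 0; p <- 1
  } else if (rss_sep < 1e-12) {
    f_stat <- Inf; p <- 0
  } else {
    f_stat <- (num / df_extra) / (rss_sep / df_sep)
    p <- stats::pf(f_stat, df_extra, df_sep, lower.tail = FALSE)
  }
  structure(
    list(rss_shared = rss_sh, rss_separate = rss_sep,
         df_extra = df_extra, df_separate = df_sep,
         f_statistic = f_stat, p_value = p,
         fit_a = fa$pars, fit_b = fb$pars, fit_shared = fs$pars),
    class = "fit_comparison"
  )
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat(sprintf(
    "<fit_comparison> F(%d, %d) = %.4g, p = %.4g | RSS shared %.4g vs separate %.4g\n",
    x$df_extra, x$df_separate, x$f_statistic, x$p_value,
    x$rss_shared, x$rss_separate))
  invisible(x)
}

#' Aggregate replicate measurements to one value per animal
#'
#' Comparisons are made between animals, not fields of view: replicate
#' measurements belonging to the same animal are first collapsed to a single
#' summary (mean by default, median for nonparametric branches).
#'
#' @param df data frame of measurements.
#' @param value_col name of the value column.
#' @param animal_col name of the animal identifier column.
#' @param group_col optional grouping column carried through.
#' @param fun summary function (default `mean`).
#' @return data frame with one row per animal.
#' @export
aggregate_per_animal <- function(df, value_col, animal_col,
                                 group_col = NULL, fun = mean) {
  by <- df[, c(animal_col, group_col), drop = FALSE]
  agg <- stats::aggregate(df[[value_col]], by = by, FUN = fun)
  names(agg)[ncol(agg)] <- value_col
  agg
}
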