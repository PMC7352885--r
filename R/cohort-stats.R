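# Scalar cohort statistics implemented from their textbook formulas:
# Pearson product-moment correlation with t-based p, Student's t tests
# (paired / pooled two-sample, Welch by flag), one-way ANOVA with
# Holm-Sidak-adjusted pairwise comparisons.

new_test_result <- function(statistic, df, p_value, n, method,
                            adjusted_p = NULL, ...) {
  structure(c(list(statistic = statistic, degrees_of_freedom = df,
                   p_value = p_value, adjusted_p = adjusted_p, n = n,
                   method = method), list(...)),
            class = "loc_test")
}

#' @export
print.loc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.4g%s (n = %s)\n",
              x$method, x$statistic,
              paste(signif(x$degrees_of_freedom, 6), collapse = ", "),
              x$p_value,
              if (!is.null(x$adjusted_p))
                sprintf(", adjusted p = %.4g", x$adjusted_p) else "",
              paste(x$n, collapse = ", ")))
  invisible(x)
}

check_finite <- function(x, what) {
  blx_assert(is.numeric(x) && all(is.finite(x)), "invalid_input",
             paste(what, "must be finite numeric values"))
}

#' Pearson correlation with t-distribution p-value
#'
#' Product-moment correlation `r`; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' `n - 2` degrees of freedom. Localization data are correlated on the log10
#' scale (see [score_localization()]), matching the double-log10 axes the
#' statistic is used on.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return a `loc_test` with `r` as the statistic.
#' @export
pearson_correlation <- function(x, y) {
  check_finite(x, "x"); check_finite(y, "y")
  n <- length(x)
  blx_assert(length(y) == n, "invalid_input", "x and y must have equal length")
  blx_assert(n >= 3, "invalid_input", "correlation needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    blx_error("degenerate_input", "zero variance in x or y")
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(-1, min(1, r))
  df <- n - 2
  p <- if (abs(r) == 1) 0 else {
    t_stat <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(t_stat), df)
  }
  new_test_result(r, df, p, n, "Pearson correlation")
}

#' Student's t test
#'
#' Paired (mean of differences) or two-sample test; the two-sample form uses
#' the pooled-variance Student statistic by default, with Welch's unequal-
#' variance form available via `var_equal = FALSE`. Two-sided p-values.
#'
#' @param a,b numeric samples; equal length required when `paired`.
#' @param paired paired test on `a - b`.
#' @param var_equal pooled-variance Student form (default) vs Welch.
#' @return a `loc_test` with the t statistic.
#' @export
t_test <- function(a, b, paired = FALSE, var_equal = TRUE) {
  check_finite(a, "a"); check_finite(b, "b")
  blx_assert(length(a) >= 2 && length(b) >= 2, "invalid_input",
             "each sample needs n >= 2")
  if (paired) {
    blx_assert(length(a) == length(b), "invalid_input",
               "paired test needs equal lengths")
    d <- a - b
    if (sd(d) == 0 && mean(d) != 0)
      blx_error("degenerate_input",
                "differences are constant and non-zero: t is unbounded")
    if (sd(d) == 0) return(new_test_result(0, length(d) - 1, 1, length(d),
                                           "paired t test"))
    t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
    df <- length(d) - 1
    return(new_test_result(t_stat, df, 2 * pt(-abs(t_stat), df), length(d),
                           "paired t test"))
  }
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a); v2 <- var(b)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 == 0) {
      if (mean(a) != mean(b))
        blx_error("degenerate_input",
                  "zero pooled variance with unequal means: t is unbounded")
      return(new_test_result(0, n1 + n2 - 2, 1, c(n1, n2),
                             "two-sample t test (pooled)"))
    }
    t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "two-sample t test (pooled)"
  } else {
    if (v1 == 0 && v2 == 0)
      blx_error("degenerate_input", "zero variance in both samples")
    se2 <- v1 / n1 + v2 / n2
    t_stat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    method <- "two-sample t test (Welch)"
  }
  new_test_result(t_stat, df, 2 * pt(-abs(t_stat), df), c(n1, n2), method)
}

#' Holm-Sidak step-down adjustment
#'
#' For raw p-values p(1) <= ... <= p(m), the adjusted value is
#' `1 - (1 - p(i))^(m - i + 1)`, enforced monotone nondecreasing along the
#' ordering. Adjusted values are never smaller than the raw ones.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  blx_assert(is.numeric(p) && all(is.finite(p)) && all(p >= 0 & p <= 1),
             "invalid_input", "p must be probabilities")
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

#' One-way ANOVA with Holm-Sidak pairwise comparisons
#'
#' Classical one-way F test (between/within sum-of-squares decomposition)
#' followed by all pairwise pooled-variance Student t tests whose p-values
#' are adjusted by the Holm-Sidak step-down method — the procedure used to
#' compare localization-shift categories.
#'
#' @param groups list of numeric vectors, >= 2 groups of n >= 2 each.
#' @return list of class `anova_hs`: `anova` (a `loc_test` with the F
#'   statistic, df = c(between, within)) and `pairwise` (data frame with
#'   group pair, t, df, raw and Holm-Sidak-adjusted p).
#' @export
anova_holm_sidak <- function(groups) {
  blx_assert(is.list(groups) && length(groups) >= 2, "invalid_input",
             "groups must be a list of >= 2 numeric vectors")
  for (g in groups) check_finite(g, "each group")
  blx_assert(all(vapply(groups, length, 1L) >= 2), "invalid_input",
             "each group needs n >= 2")
  if (all(vapply(groups, sd, 0) == 0))
    blx_error("degenerate_input", "all groups are constant")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))

  k <- length(groups)
  n_i <- vapply(groups, length, 1L)
  n <- sum(n_i)
  grand <- mean(unlist(groups))
  means <- vapply(groups, mean, 0)
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1
  df2 <- n - k
  if (ss_within == 0)
    blx_error("degenerate_input", "zero within-group variance")
  f_stat <- (ss_between / df1) / (ss_within / df2)
  omnibus <- new_test_result(f_stat, c(df1, df2),
                             pf(f_stat, df1, df2, lower.tail = FALSE),
                             n_i, "one-way ANOVA")

  pairs <- utils::combn(names(groups), 2)
  pw <- do.call(rbind, apply(pairs, 2, function(pr) {
    res <- t_test(groups[[pr[1]]], groups[[pr[2]]])
    data.frame(group1 = pr[1], group2 = pr[2], t = res$statistic,
               df = res$degrees_of_freedom, p = res$p_value,
               stringsAsFactors = FALSE)
  }))
  pw$adjusted_p <- holm_sidak_adjust(pw$p)
  structure(list(anova = omnibus, pairwise = pw), class = "anova_hs")
}

#' @export
print.anova_hs <- function(x, ...) {
  print(x$anova)
  cat("pairwise comparisons (Holm-Sidak adjusted):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
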