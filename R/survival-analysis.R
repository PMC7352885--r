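# Kaplan-Meier estimation, log-rank (Mantel-Cox) testing, and the
# signature-projection workflow (cluster a cohort on signature genes, compare
# the clusters' survival). Estimation and testing delegate to the survival
# package (survfit / survdiff), exposed here as tidy tables.

check_surv_records <- function(records) {
  blx_assert(is.data.frame(records) &&
               all(c("time_days", "event") %in% names(records)),
             "invalid_record", "records need time_days and event columns")
  if (!all(is.finite(records$time_days)) || any(records$time_days <= 0))
    blx_error("invalid_record", "times must be finite and > 0")
  blx_assert(all(records$event %in% c(0, 1)), "invalid_record",
             "event must be 0 (censored) or 1 (death observed)")
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival probability over the distinct event times; subjects censored at
#' an event time are counted at risk for that time (the standard
#' product-limit convention, with tied events pooled in one risk-set row).
#'
#' @param records data frame with `time_days`, `event` (1 = death observed,
#'   0 = censored) and optionally `stratum`; one curve is returned per
#'   stratum.
#' @return data frame of class `km_curve`: `stratum`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(records) {
  records <- check_surv_records(records)
  if (is.null(records$stratum)) records$stratum <- "all"
  out <- list()
  for (s in unique(records$stratum)) {
    r <- records[records$stratum == s, ]
    fit <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = r)
    out[[s]] <- data.frame(stratum = s, time = fit$time, n_risk = fit$n.risk,
                           n_event = fit$n.event, n_censor = fit$n.censor,
                           survival = fit$surv, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("km_curve", "data.frame")
  res
}

#' @export
plot.km_curve <- function(x, ...) {
  strata <- unique(x$stratum)
  graphics::plot(NA, xlim = c(0, max(x$time)), ylim = c(0, 1),
                 xlab = "time (days)", ylab = "survival", ...)
  for (i in seq_along(strata)) {
    d <- x[x$stratum == strata[i], ]
    graphics::lines(stats::stepfun(d$time, c(1, d$survival)), col = i,
                    do.points = FALSE)
  }
  graphics::legend("topright", legend = strata, col = seq_along(strata),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Log-rank (Mantel-Cox) test between two strata
#'
#' Chi-square statistic from observed-minus-expected event counts summed
#' over the event times, with the hypergeometric variance; df = 1, upper-
#' tail p from the chi-square reference distribution.
#'
#' @param records data frame with `time_days`, `event` and `stratum`
#'   (exactly two strata, each with at least one observed event).
#' @return a `loc_test` with the chi-square statistic.
#' @export
logrank_test <- function(records) {
  records <- check_surv_records(records)
  blx_assert("stratum" %in% names(records), "invalid_record",
             "records need a stratum column")
  strata <- unique(records$stratum)
  blx_assert(length(strata) == 2, "invalid_record",
             "log-rank test compares exactly two strata")
  ev <- tapply(records$event, records$stratum, sum)
  if (any(ev == 0))
    blx_error("undefined_test",
              paste("stratum with zero observed events:",
                    paste(names(ev)[ev == 0], collapse = ", ")))
  sd_fit <- survival::survdiff(survival::Surv(time_days, event) ~ stratum,
                               data = records)
  new_test_result(sd_fit$chisq, 1,
                  pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
                  as.integer(table(records$stratum)),
                  "log-rank (Mantel-Cox) test")
}

#' Signature projection: cluster on signature genes, compare survival
#'
#' Restricts the expression matrix to the signature genes, fills masked
#' entries by [knn_impute()], clusters the samples by Euclidean distance and
#' complete linkage, cuts the tree at `k` (default two clusters, matching
#' two-curve Kaplan-Meier comparisons), and tests the clusters' survival by
#' log-rank.
#'
#' @param expr genes x samples matrix (`NA` = masked) or `expression_sim`.
#' @param signature character vector of signature gene ids.
#' @param records survival data frame with `sample_id`, `time_days`,
#'   `event` covering the expression samples.
#' @param k number of clusters to cut at.
#' @param impute_k neighbours for imputation.
#' @return list of class `signature_projection`: `labels` (cluster per
#'   sample), `test` (log-rank `loc_test`; overall k-stratum test when
#'   k > 2), `curves` ([km_estimate()] per cluster), `clustering`.
#' @export
signature_projection <- function(expr, signature, records, k = 2,
                                 impute_k = 10) {
  m <- as_expr_matrix(expr)
  missing_genes <- setdiff(signature, rownames(m))
  if (length(missing_genes))
    blx_error("missing_signature",
              paste("signature genes absent from the matrix:",
                    paste(missing_genes, collapse = ", ")))
  check_surv_records(records)
  blx_assert(all(colnames(m) %in% records$sample_id), "invalid_record",
             "every expression sample needs a survival record")
  sig <- m[signature, , drop = FALSE]
  sig <- knn_impute(sig, k = min(impute_k, nrow(sig) - 1))
  clust <- hierarchical_cluster(sig, distance = "euclidean", k = k)
  labels <- clust$labels
  if (length(unique(labels)) < 2)
    blx_error("degenerate_partition", "fewer than 2 non-empty clusters")
  rec <- records[match(names(labels), records$sample_id), ]
  rec$stratum <- paste0("cluster", labels)
  test <- if (k == 2) logrank_test(rec) else {
    sd_fit <- survival::survdiff(survival::Surv(time_days, event) ~ stratum,
                                 data = rec)
    df <- length(unique(rec$stratum)) - 1
    new_test_result(sd_fit$chisq, df,
                    pchisq(sd_fit$chisq, df = df, lower.tail = FALSE),
                    as.integer(table(rec$stratum)), "log-rank (Mantel-Cox) test")
  }
  structure(list(labels = labels, test = test, curves = km_estimate(rec),
                 clustering = clust), class = "signature_projection")
}
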