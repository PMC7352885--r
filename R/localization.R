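# Relative localization scoring, tumor-minus-non-tumor shifts, rank
# categorization by non-tumor mitochondrial BAX, protection classification,
# and carbonate-extraction membrane distribution.

#' Relative protein localization
#'
#' The relative localization of an analyte is the quotient of its relative
#' mitochondrial protein (per COX IV) and relative cytosolic protein (per
#' beta-ACTIN). High values indicate a shift towards the mitochondria,
#' independent of the cellular protein concentration. All downstream
#' statistics use the log10 scale.
#'
#' @param rel_mito relative mitochondrial protein (vectorized, > 0).
#' @param rel_cyto relative cytosolic protein (vectorized, > 0).
#' @return data frame with `rel_mito`, `rel_cyto`, `rel_loc`,
#'   `log10_rel_loc`.
#' @examples
#' relative_localization(2, 0.5) # rel_loc 4, log10 ~ 0.602
#' @export
relative_localization <- function(rel_mito, rel_cyto) {
  blx_assert(is.numeric(rel_mito) && is.numeric(rel_cyto) &&
               length(rel_mito) == length(rel_cyto),
             "invalid_quantification", "inputs must be numeric, equal length")
  if (!all(is.finite(rel_mito)) || !all(is.finite(rel_cyto)) ||
      any(rel_mito <= 0) || any(rel_cyto <= 0))
    blx_error("invalid_quantification",
              "relative amounts must be finite and > 0")
  rel_loc <- rel_mito / rel_cyto
  data.frame(rel_mito = rel_mito, rel_cyto = rel_cyto, rel_loc = rel_loc,
             log10_rel_loc = log10(rel_loc))
}

#' Score a marker-normalized cohort table
#'
#' Attaches the relative localization quotient and its log10 to every
#' sample x analyte row of a [marker_normalize()] result and recovers the
#' patient id / tissue from the rendered sample ids (`<patient>_T` /
#' `<patient>_N`) when absent.
#'
#' @param normalized data frame with `sample_id`, `tissue`, `analyte`,
#'   `rel_mito`, `rel_cyto`.
#' @return localization table: `patient_id`, `tissue` (`tumor`/`non_tumor`),
#'   `analyte`, `rel_mito`, `rel_cyto`, `rel_loc`, `log10_rel_loc`.
#' @export
score_localization <- function(normalized) {
  blx_assert(all(c("sample_id", "analyte", "rel_mito", "rel_cyto") %in%
                   names(normalized)), "invalid_input",
             "need sample_id, analyte, rel_mito, rel_cyto columns")
  loc <- relative_localization(normalized$rel_mito, normalized$rel_cyto)
  patient_id <- if ("patient_id" %in% names(normalized)) normalized$patient_id
    else sub("_[TN]$", "", normalized$sample_id)
  tissue <- normalized$tissue
  tissue <- ifelse(tissue %in% c("T", "tumor"), "tumor",
                   ifelse(tissue %in% c("N", "non_tumor"), "non_tumor", tissue))
  cbind(data.frame(patient_id = patient_id, tissue = tissue,
                   analyte = normalized$analyte, stringsAsFactors = FALSE),
        loc)
}

#' Tumor-minus-non-tumor localization shift
#'
#' For each patient, the difference of tumor and non-tumor log10 relative
#' localization for one analyte. Negative values are shifts to the cytosol;
#' BAX-protected tumors show shifts of about -2 log10 units.
#'
#' @param loc localization table from [score_localization()] (both tissues
#'   per patient), or a single tumor record when `nontumor` is given.
#' @param nontumor optional non-tumor record paired with a tumor record in
#'   `loc` (both one-row data frames with `patient_id`, `analyte`,
#'   `log10_rel_loc`).
#' @param analyte which analyte to difference (cohort form).
#' @return data frame `patient_id`, `delta_log10`.
#' @export
delta_localization <- function(loc, nontumor = NULL, analyte = "BAX") {
  if (!is.null(nontumor)) {
    blx_assert(loc$patient_id == nontumor$patient_id &&
                 loc$analyte == nontumor$analyte, "pairing",
               "records are not a tumor/non-tumor pair for one patient and analyte")
    return(data.frame(patient_id = loc$patient_id,
                      delta_log10 = loc$log10_rel_loc - nontumor$log10_rel_loc))
  }
  d <- loc[loc$analyte == analyte, , drop = FALSE]
  tum <- d[d$tissue == "tumor", c("patient_id", "log10_rel_loc")]
  nt <- d[d$tissue == "non_tumor", c("patient_id", "log10_rel_loc")]
  merged <- merge(tum, nt, by = "patient_id", suffixes = c("_t", "_n"),
                  all = TRUE)
  if (anyNA(merged$log10_rel_loc_t) || anyNA(merged$log10_rel_loc_n)) {
    bad <- merged$patient_id[!complete.cases(merged)]
    blx_error("pairing", paste("unpaired patients:", paste(bad, collapse = ", ")))
  }
  out <- data.frame(patient_id = merged$patient_id,
                    delta_log10 = merged$log10_rel_loc_t - merged$log10_rel_loc_n,
                    stringsAsFactors = FALSE)
  out[order(out$patient_id), , drop = FALSE]
}

# balanced 4-way rank partition: base floor(n/4) per category, remainder
# given out in category order 2, 3, 4, 1 (middles first)
category_sizes <- function(n) {
  base <- rep(n %/% 4, 4)
  extra_order <- c(2L, 3L, 4L, 1L)
  r <- n %% 4
  if (r > 0) base[extra_order[seq_len(r)]] <- base[extra_order[seq_len(r)]] + 1L
  base
}

#' Categorize patients by non-tumor mitochondrial BAX
#'
#' Rank-orders patients by their non-tumor relative mitochondrial BAX and
#' partitions them into four ordered categories (`low_extreme`,
#' `low_moderate`, `high_moderate`, `high_extreme`) of balanced size:
#' `floor(n/4)` per category with the remainder assigned to the middle
#' categories first. A 34-patient cohort therefore always splits 8/9/9/8.
#' Ties are broken by the stable (value, patient_id) order.
#'
#' @param x either a localization table from [score_localization()] (the
#'   non-tumor BAX `rel_mito` values are extracted) or a named numeric vector
#'   of non-tumor relative mitochondrial BAX per patient.
#' @return data frame `patient_id`, `rel_mito_bax_nontumor`, `category`
#'   (ordered factor).
#' @export
categorize_by_nontumor_mito_bax <- function(x) {
  if (is.data.frame(x)) {
    d <- x[x$analyte == "BAX" & x$tissue == "non_tumor", , drop = FALSE]
    blx_assert(!anyDuplicated(d$patient_id), "invalid_input",
               "one non-tumor BAX record per patient required")
    vals <- setNames(d$rel_mito, d$patient_id)
  } else {
    blx_assert(is.numeric(x), "invalid_input",
               "x must be a localization table or a numeric vector")
    vals <- x
    if (is.null(names(vals))) names(vals) <- sprintf("P%02d", seq_along(vals))
  }
  n <- length(vals)
  if (n < 4) blx_error("insufficient_cohort",
                       "categorization needs at least 4 patients")
  ord <- order(vals, names(vals))  # stable (value, patient_id)
  sizes <- category_sizes(n)
  levels <- c("low_extreme", "low_moderate", "high_moderate", "high_extreme")
  category <- rep(levels, times = sizes)
  out <- data.frame(patient_id = names(vals)[ord],
                    rel_mito_bax_nontumor = unname(vals[ord]),
                    category = factor(category, levels = levels, ordered = TRUE),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# exact 1-D 2-means on sorted values: scan all split points, minimize
# within-cluster sum of squares; returns the midpoint between cluster means
two_means_threshold <- function(x) {
  x <- sort(x)
  n <- length(x)
  blx_assert(n >= 2 && diff(range(x)) > 0, "degenerate_input",
             "automatic threshold needs >= 2 distinct shift values")
  best <- NULL
  best_ss <- Inf
  for (k in seq_len(n - 1)) {
    lo <- x[seq_len(k)]
    hi <- x[(k + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- (mean(lo) + mean(hi)) / 2
    }
  }
  best
}

#' Classify BAX-protected tumors from paired localization shifts
#'
#' A patient is called `protected` when the tumor-minus-non-tumor log10
#' relative BAX localization shift is at or below the threshold (default
#' -1.0: the midpoint between no shift and the typical ~2-log protected
#' shift; inclusive). With `threshold = "auto"` the threshold is fitted as a
#' two-component split (exact 1-D 2-means) of the observed shifts, for
#' threshold-free use.
#'
#' @param loc localization table from [score_localization()] with paired BAX
#'   records for every patient.
#' @param threshold_log10 numeric threshold in log10 units, or `"auto"`.
#' @param categories optional result of [categorize_by_nontumor_mito_bax()];
#'   when given, per-category protected counts are attached as the
#'   `category_counts` attribute and a `category` column is added.
#' @return data frame of protection calls: `patient_id`, `delta_log10`,
#'   `label` (`protected`/`non_protected`), optional `category`; attribute
#'   `threshold_log10` records the threshold used.
#' @export
classify_protection <- function(loc, threshold_log10 = -1.0,
                                categories = NULL) {
  delta <- delta_localization(loc, analyte = "BAX")
  if (identical(threshold_log10, "auto"))
    threshold_log10 <- two_means_threshold(delta$delta_log10)
  blx_assert(is.numeric(threshold_log10) && length(threshold_log10) == 1,
             "invalid_config", "threshold_log10 must be a number or \"auto\"")
  calls <- data.frame(
    patient_id = delta$patient_id,
    delta_log10 = delta$delta_log10,
    label = ifelse(delta$delta_log10 <= threshold_log10,
                   "protected", "non_protected"),
    stringsAsFactors = FALSE)
  if (is.null(categories) && is.data.frame(loc) &&
      all(c("tissue", "rel_mito") %in% names(loc)))
    categories <- tryCatch(categorize_by_nontumor_mito_bax(loc),
                           baxloc_error = function(e) NULL)
  if (!is.null(categories)) {
    calls$category <- categories$category[match(calls$patient_id,
                                                categories$patient_id)]
    attr(calls, "category_counts") <-
      table(category = calls$category, label = calls$label)
  }
  attr(calls, "threshold_log10") <- threshold_log10
  calls
}

#' Carbonate-extraction membrane distribution
#'
#' Alkaline carbonate extraction (pH 11.5) splits outer-mitochondrial-
#' membrane protein into a membrane-integral pool (pellet) and a
#' membrane-associated pool (supernatant). The distribution statistic is the
#' integral/associated quotient, reported on the log10 scale; values below 1
#' indicate an associated-shifted pool.
#'
#' @param integral amount in the carbonate pellet (OMM-integral), > 0.
#' @param associated amount in the supernatant (OMM-associated), > 0.
#' @param sample_id optional sample identifiers.
#' @return data frame `sample_id`, `integral_amount`, `associated_amount`,
#'   `distribution`, `log10_distribution`.
#' @export
carbonate_distribution <- function(integral, associated, sample_id = NULL) {
  blx_assert(is.numeric(integral) && is.numeric(associated) &&
               length(integral) == length(associated),
             "invalid_quantification", "inputs must be numeric, equal length")
  if (!all(is.finite(integral)) || !all(is.finite(associated)) ||
      any(integral <= 0) || any(associated <= 0))
    blx_error("invalid_quantification", "amounts must be finite and > 0")
  if (is.null(sample_id)) sample_id <- sprintf("S%02d", seq_along(integral))
  distribution <- integral / associated
  data.frame(sample_id = sample_id, integral_amount = integral,
             associated_amount = associated, distribution = distribution,
             log10_distribution = log10(distribution),
             stringsAsFactors = FALSE)
}
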