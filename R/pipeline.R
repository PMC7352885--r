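# End-to-end orchestration: simulate -> render -> calibrate -> score ->
# classify -> differential expression -> clustering -> survival, from one
# config, with deterministic per-stage seeds and a run manifest.

# stable per-stage seed below 2^31, derived from the global seed
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(stage)) * 131L) %% 2147483647L
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a paired tumor/non-tumor cohort from shuttling kinetics,
#' renders and calibrates the blots, scores relative BAX/BAK localization,
#' classifies BAX-protected tumors, then carries the *predicted* subgroup
#' labels into differential expression (quantile normalization, presence
#' filter, per-gene t test), clusters the differential-gene submatrix, and
#' runs the signature-projection survival comparison. The simulator's hidden
#' truth is used only to plant effects and, separately, by
#' [evaluate_calls()]; no analysis stage reads it.
#'
#' @param config a [cohort_config()]; its seed derives every stage seed.
#' @param out_dir optional directory: stage outputs are written as TSV plus
#'   a JSON `manifest`.
#' @param through_origin calibrate with a through-origin standard curve
#'   (default). Rendered blots are background-free by construction, and an
#'   affine intercept estimated from a five-point titration is too uncertain
#'   to back-calculate bands lying orders of magnitude below the titration
#'   range — its use would exclude precisely the weak mitochondrial BAX
#'   bands of protected tumors. Set `FALSE` for data with a genuine
#'   background offset.
#' @param threshold_log10 protection threshold, see [classify_protection()].
#' @param alpha,min_presence,impute_k downstream thresholds.
#' @param n_genes,n_de,effect_log2,missing_rate expression-simulation knobs.
#' @param hazard_ratio,baseline_rate,censor_rate survival-simulation knobs.
#' @return list with `truth`, `lanes`, `localization`, `calls`,
#'   `expression`, `de`, `clustering`, `survival`, `projection`, `manifest`.
#' @export
run_all <- function(config = cohort_config(), out_dir = NULL,
                    through_origin = TRUE,
                    threshold_log10 = -1.0, alpha = 0.05,
                    min_presence = 0.8, impute_k = 10,
                    n_genes = 1000, n_de = 50, effect_log2 = 2,
                    missing_rate = 0.05, hazard_ratio = 3,
                    baseline_rate = 1 / 1000, censor_rate = 1 / 2000) {
  blx_assert(inherits(config, "cohort_config"), "invalid_config",
             "config must be a cohort_config object")
  truth <- simulate_cohort(config)
  lanes <- render_blots(truth, config, seed = stage_seed(config$seed, "render"))
  calibrated <- calibrate_lanes(lanes, through_origin = through_origin)
  loc <- score_localization(marker_normalize(calibrated))
  calls <- classify_protection(loc, threshold_log10 = threshold_log10)

  # expression/survival are generated from the planted biology (hidden
  # truth); analyses below them only ever see the blot-derived calls
  truth_flag <- unique(truth[, c("patient_id", "protected")])
  planted <- ifelse(truth_flag$protected, "protected", "non_protected")
  names(planted) <- truth_flag$patient_id
  expr <- simulate_expression(planted, n_genes = n_genes, n_de = n_de,
                              effect_log2 = effect_log2,
                              missing_rate = missing_rate,
                              seed = stage_seed(config$seed, "expression"))
  surv <- simulate_survival(planted, hazard_ratio = hazard_ratio,
                            baseline_rate = baseline_rate,
                            censor_rate = censor_rate,
                            seed = stage_seed(config$seed, "survival"))

  pred_labels <- setNames(calls$label, calls$patient_id)[colnames(expr$values)]
  norm <- quantile_normalize(expr$values)
  filtered <- presence_filter(norm, min_presence = min_presence)
  de <- de_genes(filtered, pred_labels, alpha = alpha)
  clustering <- if (nrow(de) >= 2)
    hierarchical_cluster(filtered[de$gene, , drop = FALSE],
                         distance = "pearson", k = 2) else NULL
  projection <- if (nrow(de) >= 2)
    signature_projection(filtered, de$gene, surv, k = 2,
                         impute_k = impute_k) else NULL

  manifest <- list(
    n_patients = config$n_patients,
    n_samples = length(unique(lanes$sample_id[!is.na(lanes$sample_id)])),
    n_blots = length(unique(lanes$blot_id)),
    n_lanes = nrow(lanes),
    n_excluded_lanes = nrow(attr(calibrated, "excluded")),
    n_protected_calls = sum(calls$label == "protected"),
    n_genes_filtered = nrow(filtered),
    n_de_genes = nrow(de),
    threshold_log10 = attr(calls, "threshold_log10"),
    seeds = list(global = config$seed,
                 render = stage_seed(config$seed, "render"),
                 expression = stage_seed(config$seed, "expression"),
                 survival = stage_seed(config$seed, "survival")))

  res <- list(truth = truth, lanes = lanes, localization = loc, calls = calls,
              expression = expr, de = de, clustering = clustering,
              survival = surv, projection = projection, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(lanes, file.path(out_dir, "lanes.tsv"))
    write_tsv_table(loc, file.path(out_dir, "localization.tsv"))
    write_tsv_table(as.data.frame(calls), file.path(out_dir, "calls.tsv"))
    write_tsv_table(de, file.path(out_dir, "de_genes.tsv"))
    write_tsv_table(surv, file.path(out_dir, "survival.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' Evaluate protection calls against simulator ground truth
#'
#' The one stage allowed to read the hidden `protected` flag: compares the
#' classifier's labels with the planted ones and reports accuracy and the
#' confusion counts.
#'
#' @param calls result of [classify_protection()] (or the `calls` element of
#'   [run_all()]).
#' @param truth a `tissue_truth` from [simulate_cohort()].
#' @return list with `accuracy`, `confusion` (2x2 table), `n`.
#' @export
evaluate_calls <- function(calls, truth) {
  truth_flag <- unique(truth[, c("patient_id", "protected")])
  idx <- match(calls$patient_id, truth_flag$patient_id)
  blx_assert(!anyNA(idx), "pairing", "calls contain unknown patients")
  planted <- ifelse(truth_flag$protected[idx], "protected", "non_protected")
  confusion <- table(planted = planted, called = calls$label)
  list(accuracy = mean(planted == calls$label), confusion = confusion,
       n = nrow(calls))
}
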