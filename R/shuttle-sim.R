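# Synthetic cohort generator: two-compartment shuttling kinetics at steady
# state, rendered as noisy western-blot lane tables with per-blot HeLa
# titration standards, plus matched expression and survival data.

ANALYTES <- c("BAX", "BAK", "COXIV", "ACTIN")

#' Shuttling-kinetics parameters for one analyte
#'
#' BAX and BAK constantly translocate to the mitochondria (rate `k_trans`)
#' and are retrotranslocated back into the cytosol (rate `k_retro`); the
#' balance of the two rates sets the steady-state mitochondrial pool.
#'
#' @param k_trans translocation rate, cytosol to mitochondria (per hour).
#' @param k_retro retrotranslocation rate, mitochondria to cytosol (per hour).
#' @param total_protein total abundance in HeLa-equivalent units.
#' @return an object of class `shuttle_params`.
#' @examples
#' steady_state_fraction(shuttle_params(1, 3))
#' @export
shuttle_params <- function(k_trans, k_retro, total_protein = 1) {
  blx_assert(is.numeric(k_trans) && length(k_trans) == 1 && is.finite(k_trans) &&
               k_trans > 0, "invalid_parameter", "k_trans must be a positive number")
  blx_assert(is.numeric(k_retro) && length(k_retro) == 1 && is.finite(k_retro) &&
               k_retro > 0, "invalid_parameter", "k_retro must be a positive number")
  blx_assert(is.numeric(total_protein) && length(total_protein) == 1 &&
               is.finite(total_protein) && total_protein > 0,
             "invalid_parameter", "total_protein must be a positive number")
  structure(list(k_trans = k_trans, k_retro = k_retro,
                 total_protein = total_protein), class = "shuttle_params")
}

#' Steady-state mitochondrial fraction of a shuttling protein
#'
#' For memoryless exchange between cytosol and mitochondria the equilibrium
#' mitochondrial fraction is `k_trans / (k_trans + k_retro)`; multiplied by
#' the total abundance it gives the mitochondrial amount. The fraction is
#' increasing in `k_trans` and decreasing in `k_retro`: faster
#' retrotranslocation means less mitochondrial BAX/BAK.
#'
#' @param params a [shuttle_params()] object, or the `k_trans` rate(s).
#' @param k_retro retrotranslocation rate(s); ignored when `params` is a
#'   `shuttle_params` object. Both rate arguments are vectorized.
#' @return mitochondrial fraction in (0, 1).
#' @export
steady_state_fraction <- function(params, k_retro = NULL) {
  if (inherits(params, "shuttle_params")) {
    k_trans <- params$k_trans
    k_retro <- params$k_retro
  } else {
    k_trans <- params
  }
  blx_assert(is.numeric(k_trans) && all(is.finite(k_trans)) && all(k_trans > 0),
             "invalid_parameter", "k_trans must be positive and finite")
  blx_assert(is.numeric(k_retro) && all(is.finite(k_retro)) && all(k_retro > 0),
             "invalid_parameter", "k_retro must be positive and finite")
  k_trans / (k_trans + k_retro)
}

#' Configuration for a simulated tumor/non-tumor cohort
#'
#' The defaults define the reference study condition: 34 patients with
#' paired tumor and non-tumor samples, 11 of whom carry a planted
#' BAX-protected tumor whose retrotranslocation rate is increased 100-fold
#' (a 2-log10 cytosolic shift of the mitochondrial/cytosolic ratio), blots
#' with a five-point HeLa titration per analyte, 0.15 log10 multiplicative
#' band noise and 0.3 log10 blot-to-blot gain spread.
#'
#' @param n_patients number of patients (each contributes a tumor and a
#'   non-tumor sample).
#' @param fraction_protected fraction of patients planted as BAX-protected;
#'   `round(fraction_protected * n_patients)` patients are flagged.
#' @param protected_retro_fold multiplier applied to the tumor BAX
#'   retrotranslocation rate of protected patients (>= 1).
#' @param lanes_per_blot blot capacity in lanes (one band per lane).
#' @param noise_sd_log10 standard deviation of the multiplicative lognormal
#'   band noise, log10 units.
#' @param gain_sd_log10 standard deviation of the per-blot, per-analyte
#'   detection gain, log10 units.
#' @param rate_jitter_sd_log10 tumor-vs-non-tumor lognormal jitter applied to
#'   every kinetic rate, log10 units.
#' @param standard_amounts HeLa-equivalent amounts of the titration series;
#'   strictly increasing, at least 3 points.
#' @param seed integer seed making every downstream simulation deterministic.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 34,
                          fraction_protected = 11 / 34,
                          protected_retro_fold = 100,
                          lanes_per_blot = 50,
                          noise_sd_log10 = 0.15,
                          gain_sd_log10 = 0.3,
                          rate_jitter_sd_log10 = 0.05,
                          standard_amounts = c(0.25, 0.5, 1, 2, 4),
                          seed = 1L) {
  blx_assert(is.numeric(n_patients) && n_patients >= 1 &&
               n_patients == round(n_patients),
             "invalid_config", "n_patients must be a positive integer")
  blx_assert(fraction_protected >= 0 && fraction_protected <= 1,
             "invalid_config", "fraction_protected must lie in [0, 1]")
  blx_assert(protected_retro_fold >= 1,
             "invalid_config", "protected_retro_fold must be >= 1")
  blx_assert(noise_sd_log10 >= 0 && gain_sd_log10 >= 0 &&
               rate_jitter_sd_log10 >= 0,
             "invalid_config", "noise/gain/jitter sds must be >= 0")
  blx_assert(length(standard_amounts) >= 3 &&
               all(diff(standard_amounts) > 0) && all(standard_amounts > 0),
             "invalid_config",
             "standard_amounts must be >= 3 strictly increasing positive values")
  blx_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "invalid_config", "seed must be a single integer")
  structure(list(n_patients = as.integer(n_patients),
                 fraction_protected = fraction_protected,
                 protected_retro_fold = protected_retro_fold,
                 lanes_per_blot = as.integer(lanes_per_blot),
                 noise_sd_log10 = noise_sd_log10,
                 gain_sd_log10 = gain_sd_log10,
                 rate_jitter_sd_log10 = rate_jitter_sd_log10,
                 standard_amounts = as.numeric(standard_amounts),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# lognormal draw on the log10 scale
rlnorm10 <- function(n, meanlog10 = 0, sdlog10 = 0) {
  10^rnorm(n, meanlog10, sdlog10)
}

#' Simulate ground-truth localizations for a paired cohort
#'
#' Draws per-patient shuttling rates for BAX (predominantly cytosolic:
#' retrotranslocation faster than translocation) and BAK (predominantly
#' mitochondrial), derives steady-state mitochondrial and cytosolic amounts,
#' and plants a BAX-protected subgroup whose tumor BAX retrotranslocation
#' rate is multiplied by `protected_retro_fold`. Protected flags are assigned
#' to the patients with the highest non-tumor mitochondrial BAX fraction,
#' mirroring the observation that the pronounced-shift subgroup arises from
#' tissues with high mitochondrial BAX. BAK rates and all other quantities
#' differ between tissues only by the configured jitter.
#'
#' The `protected` column is hidden ground truth for evaluation only; the
#' classifier never sees it.
#'
#' @param config a [cohort_config()].
#' @return data frame of class `tissue_truth` with one row per
#'   patient x tissue x analyte (BAX, BAK): kinetic rates, `total_protein`,
#'   `mito_amount`, `cyto_amount`, marker abundances `coxiv_amount`,
#'   `actin_amount`, and the hidden `protected` flag.
#' @export
simulate_cohort <- function(config) {
  blx_assert(inherits(config, "cohort_config"), "invalid_config",
             "config must be a cohort_config object")
  set.seed(config$seed)
  n <- config$n_patients
  jit <- config$rate_jitter_sd_log10
  patient_id <- sprintf("P%02d", seq_len(n))

  base <- list(
    BAX = list(kt = rlnorm10(n, 0, 0.15), kr = rlnorm10(n, 0.7, 0.4)),
    BAK = list(kt = rlnorm10(n, 0, 0.15), kr = rlnorm10(n, -0.5, 0.3))
  )
  n_prot <- as.integer(round(config$fraction_protected * n))
  mito_frac_nt <- steady_state_fraction(base$BAX$kt, base$BAX$kr)
  protected <- rank(-mito_frac_nt, ties.method = "first") <= n_prot

  rows <- list()
  for (tissue in c("non_tumor", "tumor")) {
    total <- rlnorm10(n, 0, 0.2)
    coxiv <- rlnorm10(n, 0, 0.15)
    actin <- rlnorm10(n, 0, 0.15)
    for (analyte in c("BAX", "BAK")) {
      kt <- base[[analyte]]$kt
      kr <- base[[analyte]]$kr
      if (tissue == "tumor") {
        kt <- kt * rlnorm10(n, 0, jit)
        kr <- kr * rlnorm10(n, 0, jit)
        if (analyte == "BAX")
          kr[protected] <- kr[protected] * config$protected_retro_fold
      }
      frac <- steady_state_fraction(kt, kr)
      rows[[paste(tissue, analyte)]] <- data.frame(
        patient_id = patient_id, tissue = tissue, protected = protected,
        analyte = analyte, k_trans = kt, k_retro = kr, total_protein = total,
        mito_amount = total * frac, cyto_amount = total * (1 - frac),
        coxiv_amount = coxiv, actin_amount = actin,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  class(truth) <- c("tissue_truth", "data.frame")
  truth
}

# lanes contributed by one tissue sample: analyte bands plus fraction markers
sample_band_layout <- function() {
  data.frame(
    analyte = c("BAX", "BAX", "BAK", "BAK", "COXIV", "ACTIN"),
    fraction = c("mito", "cyto", "mito", "cyto", "mito", "cyto"),
    stringsAsFactors = FALSE)
}

#' Render ground-truth cohorts as noisy blot lane tables
#'
#' Packs tissue samples onto blots, each blot carrying its own HeLa
#' whole-cell-lysate titration series for every analyte (the standard the
#' calibration stage fits per blot), the sample bands for BAX and BAK in the
#' mitochondrial and cytosolic fractions, and the loading-control bands
#' (COX IV in the mitochondrial, beta-ACTIN in the cytosolic fraction).
#' Band intensity is `gain * amount * 10^N(0, noise_sd_log10)` with an
#' independent lognormal gain per blot and analyte (antibody/exposure
#' variation), so raw intensities are not comparable across blots until
#' standard-curve calibration.
#'
#' @param truths a `tissue_truth` data frame from [simulate_cohort()].
#' @param config the [cohort_config()] used to generate `truths`.
#' @param seed seed for gains and band noise; defaults to `config$seed + 1`.
#' @return data frame of lane records: `blot_id`, `lane_index`, `analyte`,
#'   `fraction` (`mito`, `cyto` or `std`), `sample_id`, `tissue` (`T`, `N` or
#'   `NA`), `std_amount` (standards only) and `intensity`.
#' @export
render_blots <- function(truths, config, seed = NULL) {
  blx_assert(inherits(config, "cohort_config"), "invalid_config",
             "config must be a cohort_config object")
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)

  std_amounts <- config$standard_amounts
  n_std <- length(std_amounts) * length(ANALYTES)
  layout <- sample_band_layout()
  n_per_sample <- nrow(layout)
  blx_assert(config$lanes_per_blot >= n_std + n_per_sample, "invalid_config",
             sprintf(paste("blot capacity (%d lanes) is smaller than one",
                           "titration series plus one sample with markers (%d lanes)"),
                     config$lanes_per_blot, n_std + n_per_sample))
  samples_per_blot <- (config$lanes_per_blot - n_std) %/% n_per_sample

  samples <- unique(truths[, c("patient_id", "tissue")])
  samples <- samples[order(samples$patient_id, samples$tissue), ]
  samples$sample_id <- paste0(samples$patient_id, "_",
                              ifelse(samples$tissue == "tumor", "T", "N"))
  samples$blot_id <- sprintf("B%02d",
                             (seq_len(nrow(samples)) - 1) %/% samples_per_blot + 1)

  amount_of <- function(sid, tis, analyte, fraction) {
    row <- truths[truths$patient_id == sid & truths$tissue == tis &
                    truths$analyte == ifelse(analyte %in% c("BAX", "BAK"),
                                             analyte, "BAX"), , drop = FALSE][1, ]
    switch(analyte,
           BAX = , BAK = if (fraction == "mito") row$mito_amount else row$cyto_amount,
           COXIV = row$coxiv_amount,
           ACTIN = row$actin_amount)
  }

  blots <- unique(samples$blot_id)
  gains <- matrix(rlnorm10(length(blots) * length(ANALYTES), 0,
                           config$gain_sd_log10),
                  nrow = length(blots), dimnames = list(blots, ANALYTES))

  out <- list()
  for (b in blots) {
    lanes <- data.frame(
      analyte = rep(ANALYTES, each = length(std_amounts)),
      fraction = "std", sample_id = NA_character_, tissue = NA_character_,
      std_amount = rep(std_amounts, times = length(ANALYTES)),
      amount = rep(std_amounts, times = length(ANALYTES)),
      stringsAsFactors = FALSE)
    for (i in which(samples$blot_id == b)) {
      s <- samples[i, ]
      amt <- mapply(amount_of, s$patient_id, s$tissue,
                    layout$analyte, layout$fraction)
      lanes <- rbind(lanes, data.frame(
        analyte = layout$analyte, fraction = layout$fraction,
        sample_id = s$sample_id,
        tissue = ifelse(s$tissue == "tumor", "T", "N"),
        std_amount = NA_real_, amount = amt, stringsAsFactors = FALSE))
    }
    noise <- rlnorm10(nrow(lanes), 0, config$noise_sd_log10)
    lanes$intensity <- gains[b, lanes$analyte] * lanes$amount * noise
    lanes$blot_id <- b
    lanes$lane_index <- seq_len(nrow(lanes))
    out[[b]] <- lanes[, c("blot_id", "lane_index", "analyte", "fraction",
                          "sample_id", "tissue", "std_amount", "intensity")]
  }
  lanes <- do.call(rbind, out)
  rownames(lanes) <- NULL
  lanes
}

#' Simulate a log2 expression matrix with planted differential genes
#'
#' Emulates a quantile-normalizable microarray-style matrix: per-gene
#' baseline means, Gaussian noise on the log2 scale, `n_de` genes whose mean
#' differs by `effect_log2` between the two label classes, and
#' detection-failure missingness injected completely at random at
#' `missing_rate` (the analogue of masking signals with detection p > 0.05).
#'
#' @param labels character/factor of sample class labels (two classes for a
#'   differential-expression scenario); names or length give the samples.
#' @param n_genes total number of genes.
#' @param n_de number of planted differential genes (first class shifted up).
#' @param effect_log2 mean difference planted in the differential genes.
#' @param sd_log2 per-observation noise standard deviation.
#' @param missing_rate probability that any entry is detection-failed.
#' @param seed integer seed.
#' @return list of class `expression_sim` with `values` (genes x samples
#'   matrix, `NA` at masked entries), `mask` (logical matrix, `TRUE` =
#'   detection failed) and `de_genes` (planted gene ids).
#' @export
simulate_expression <- function(labels, n_genes = 2000, n_de = 50,
                                effect_log2 = 2, sd_log2 = 0.5,
                                missing_rate = 0.05, seed = 1L) {
  blx_assert(length(labels) >= 2, "labeling", "need at least two samples")
  blx_assert(missing_rate >= 0 && missing_rate < 1, "invalid_config",
             "missing_rate must lie in [0, 1)")
  blx_assert(n_de <= n_genes, "invalid_config", "n_de cannot exceed n_genes")
  set.seed(seed)
  sample_ids <- if (!is.null(names(labels))) names(labels) else
    sprintf("S%03d", seq_along(labels))
  labels <- as.character(labels)
  n_s <- length(labels)
  genes <- sprintf("G%05d", seq_len(n_genes))

  base_mean <- rnorm(n_genes, 8, 1.5)
  values <- matrix(rnorm(n_genes * n_s, 0, sd_log2), n_genes, n_s,
                   dimnames = list(genes, sample_ids)) + base_mean
  de <- character(0)
  if (n_de > 0) {
    de <- genes[seq_len(n_de)]
    up_class <- sort(unique(labels))[1]
    values[de, labels == up_class] <-
      values[de, labels == up_class] + effect_log2
  }
  mask <- matrix(runif(n_genes * n_s) < missing_rate, n_genes, n_s,
                 dimnames = dimnames(values))
  values[mask] <- NA_real_
  structure(list(values = values, mask = mask, de_genes = de,
                 labels = setNames(labels, sample_ids)),
            class = "expression_sim")
}

#' Simulate survival records with group-dependent hazard
#'
#' Event times are exponential with the baseline rate in the reference group
#' (first level of `labels` after sorting) and `baseline_rate * hazard_ratio`
#' in the other group; censoring times are independent exponentials with rate
#' `censor_rate` (0 disables censoring).
#'
#' @param labels sample group labels (the stratum column of the output).
#' @param hazard_ratio hazard multiplier for the non-reference group.
#' @param baseline_rate event rate per day in the reference group.
#' @param censor_rate independent censoring rate per day.
#' @param seed integer seed.
#' @return data frame with `sample_id`, `time_days`, `event` (1 = death
#'   observed, 0 = censored) and `stratum`.
#' @export
simulate_survival <- function(labels, hazard_ratio = 3,
                              baseline_rate = 1 / 1000, censor_rate = 1 / 2000,
                              seed = 1L) {
  blx_assert(length(labels) >= 2, "labeling", "need at least two samples")
  blx_assert(hazard_ratio > 0 && baseline_rate > 0 && censor_rate >= 0,
             "invalid_config", "rates must be positive (censor_rate >= 0)")
  set.seed(seed)
  sample_ids <- if (!is.null(names(labels))) names(labels) else
    sprintf("S%03d", seq_along(labels))
  labels <- as.character(labels)
  n <- length(labels)
  ref <- sort(unique(labels))[1]
  rate <- ifelse(labels == ref, baseline_rate, baseline_rate * hazard_ratio)
  t_event <- rexp(n, rate)
  if (censor_rate > 0) {
    t_cens <- rexp(n, censor_rate)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  data.frame(sample_id = sample_ids, time_days = time, event = event,
             stratum = labels, stringsAsFactors = FALSE)
}
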