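test_that("steady-state mitochondrial fraction follows the kinetic closed form", {
  expect_equal(steady_state_fraction(1, 1), 0.5)
  expect_lte(steady_state_fraction(1, 1e9), 1e-8)
  expect_equal(steady_state_fraction(2, 8), 0.2)
  expect_equal(steady_state_fraction(shuttle_params(2, 8, 5)), 0.2)
  expect_error(steady_state_fraction(-1, 2), class = "baxloc_invalid_parameter")
  expect_error(shuttle_params(1, 0), class = "baxloc_invalid_parameter")
  expect_error(shuttle_params(1, 1, -2), class = "baxloc_invalid_parameter")
})

test_that("steady-state fraction is monotone in both rates", {
  kt_grid <- 10^seq(-2, 2, length.out = 25)
  kr_grid <- 10^seq(-2, 2, length.out = 25)
  for (kr in kr_grid)
    expect_true(all(diff(steady_state_fraction(kt_grid, kr)) > 0))
  for (kt in kt_grid)
    expect_true(all(diff(steady_state_fraction(kt, kr_grid)) < 0))
})

test_that("simulated cohorts are paired, conserved and correctly flagged", {
  cfg <- cohort_config(n_patients = 34, fraction_protected = 11 / 34, seed = 3L)
  truth <- simulate_cohort(cfg)
  expect_equal(length(unique(truth$patient_id)), 34)
  expect_equal(nrow(truth), 34 * 2 * 2)  # patient x tissue x analyte
  per_flag <- unique(truth[, c("patient_id", "protected")])
  expect_equal(sum(per_flag$protected), 11)
  # conservation: compartment amounts sum to total abundance
  expect_equal(truth$mito_amount + truth$cyto_amount, truth$total_protein,
               tolerance = 1e-12)
  # closed form links amounts to rates
  expect_equal(truth$mito_amount,
               truth$total_protein * truth$k_trans /
                 (truth$k_trans + truth$k_retro), tolerance = 1e-12)
  expect_identical(truth, simulate_cohort(cfg))
})

test_that("unprotected cohorts keep BAX rates tissue-invariant up to jitter", {
  cfg <- cohort_config(n_patients = 10, fraction_protected = 0,
                       rate_jitter_sd_log10 = 0, seed = 5L)
  truth <- simulate_cohort(cfg)
  bax <- truth[truth$analyte == "BAX", ]
  ratio <- bax$k_retro[bax$tissue == "tumor"] /
    bax$k_retro[bax$tissue == "non_tumor"]
  expect_equal(ratio, rep(1, 10))
})

test_that("planted protection shifts the true log10 mito/cyto ratio by -log10(fold)", {
  cfg <- cohort_config(n_patients = 8, fraction_protected = 0.5,
                       protected_retro_fold = 100,
                       rate_jitter_sd_log10 = 0, seed = 9L)
  truth <- simulate_cohort(cfg)
  bax <- truth[truth$analyte == "BAX", ]
  lr <- log10(bax$mito_amount / bax$cyto_amount)
  delta <- lr[bax$tissue == "tumor"] - lr[bax$tissue == "non_tumor"]
  expect_equal(unname(delta[bax$protected[bax$tissue == "tumor"]]),
               rep(-2, 4), tolerance = 1e-9)
  expect_equal(unname(delta[!bax$protected[bax$tissue == "tumor"]]),
               rep(0, 4), tolerance = 1e-9)
})

test_that("rendered blots carry full titrations and honor the noise model", {
  cfg <- noise_free_config(n_patients = 6)
  truth <- simulate_cohort(cfg)
  lanes <- render_blots(truth, cfg)
  expect_false(anyDuplicated(lanes[, c("blot_id", "lane_index")]) > 0)
  # every blot has the complete titration series for every analyte
  for (b in unique(lanes$blot_id)) {
    std <- lanes[lanes$blot_id == b & lanes$fraction == "std", ]
    counts <- table(std$analyte)
    expect_setequal(names(counts), c("BAX", "BAK", "COXIV", "ACTIN"))
    expect_true(all(counts == length(cfg$standard_amounts)))
    expect_equal(sort(std$std_amount[std$analyte == "BAX"]),
                 cfg$standard_amounts)
  }
  # noise = 0, gain = 1: standard intensity equals the loaded amount
  std <- lanes[lanes$fraction == "std", ]
  expect_equal(std$intensity, std$std_amount)
  # and sample bands equal the true amounts (slope-1 linear response)
  bax_mito <- lanes[lanes$analyte == "BAX" & lanes$fraction == "mito", ]
  key <- paste(sub("_[TN]$", "", bax_mito$sample_id),
               ifelse(bax_mito$tissue == "T", "tumor", "non_tumor"))
  tr <- truth[truth$analyte == "BAX", ]
  expect_equal(bax_mito$intensity,
               tr$mito_amount[match(key, paste(tr$patient_id, tr$tissue))])
  expect_identical(lanes, render_blots(truth, cfg))
})

test_that("blot capacity below one titration plus one sample is a config error", {
  cfg <- cohort_config(n_patients = 2, lanes_per_blot = 25, seed = 1L)
  truth <- simulate_cohort(cfg)
  expect_error(render_blots(truth, cfg), class = "baxloc_invalid_config")
})

test_that("expression simulation plants effects and records missingness", {
  labels <- rep(c("protected", "non_protected"), each = 17)
  sim <- simulate_expression(labels, n_genes = 400, n_de = 50,
                             effect_log2 = 2, sd_log2 = 0.5,
                             missing_rate = 0.1, seed = 21L)
  expect_equal(dim(sim$values), c(400, 34))
  expect_identical(is.na(sim$values), sim$mask)
  expect_equal(length(sim$de_genes), 50)
  obs_rate <- mean(sim$mask)
  expect_lt(abs(obs_rate - 0.1), 0.01)
  # planted genes separate by about the requested effect
  de_means <- rowMeans(sim$values[sim$de_genes, labels == "non_protected"],
                       na.rm = TRUE) -
    rowMeans(sim$values[sim$de_genes, labels == "protected"], na.rm = TRUE)
  expect_lt(abs(mean(de_means) - 2), 0.2)
  expect_identical(sim$values,
                   simulate_expression(labels, n_genes = 400, n_de = 50,
                                       effect_log2 = 2, sd_log2 = 0.5,
                                       missing_rate = 0.1, seed = 21L)$values)
})

test_that("survival simulation: censoring flagging and exponential medians", {
  labels <- rep(c("a", "b"), each = 200)
  no_cens <- simulate_survival(labels, hazard_ratio = 3, censor_rate = 0,
                               seed = 2L)
  expect_true(all(no_cens$event == 1))
  # hazard ratio 3 scales the exponential median by 1/3
  med_ratio <- median(no_cens$time_days[no_cens$stratum == "b"]) /
    median(no_cens$time_days[no_cens$stratum == "a"])
  expect_lt(abs(med_ratio - 1 / 3), 0.15 * (1 / 3))
  expect_identical(no_cens, simulate_survival(labels, hazard_ratio = 3,
                                              censor_rate = 0, seed = 2L))
})
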