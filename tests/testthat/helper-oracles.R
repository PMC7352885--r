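# Independent oracles used across the suite. Each recomputes the target
# quantity by a route the implementation does not share: closed-form normal
# equations, naive agglomeration, direct O-E/V sums, permutation nulls.

# ordinary least squares by the closed-form normal equations
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# naive complete-linkage agglomeration: exhaustive pairwise recomputation at
# every step; returns merge heights and the partition after each merge
brute_complete_linkage <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- max(dmat[clusters[[i]], clusters[[j]]])
      if (d < best_d - 1e-12) {
        best_d <- d
        best <- c(i, j)
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_d)
    partitions[[length(partitions) + 1]] <-
      lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition (set of sets) for comparison
canon_partition <- function(groups) {
  sets <- lapply(groups, function(g) paste(sort(g), collapse = ","))
  paste(sort(unlist(sets)), collapse = "|")
}

# partition of 1..n from cutree labels
cutree_partition <- function(labels) {
  canon_partition(split(seq_along(labels), labels))
}

# log-rank chi-square by direct observed-minus-expected / hypergeometric
# variance sums over event times
logrank_chisq_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# a small deterministic localization table for pairing tests
toy_localization <- function(deltas) {
  n <- length(deltas)
  ids <- sprintf("P%02d", seq_len(n))
  nt <- data.frame(patient_id = ids, tissue = "non_tumor", analyte = "BAX",
                   rel_mito = 1, rel_cyto = 1, rel_loc = 1, log10_rel_loc = 0,
                   stringsAsFactors = FALSE)
  tu <- nt
  tu$tissue <- "tumor"
  tu$rel_loc <- 10^deltas
  tu$rel_mito <- tu$rel_loc
  tu$log10_rel_loc <- deltas
  rbind(nt, tu)
}

# noise-free rendering config for round-trip checks
noise_free_config <- function(n_patients = 6, seed = 11L, ...) {
  cohort_config(n_patients = n_patients, noise_sd_log10 = 0,
                gain_sd_log10 = 0, rate_jitter_sd_log10 = 0, seed = seed, ...)
}
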