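# Standard-curve calibration of blot lane tables: per-blot per-analyte OLS
# fit of the HeLa titration, inverse prediction of sample band amounts, and
# loading-control normalization.

#' Fit a per-blot standard curve from HeLa titration lanes
#'
#' Each blot carries a titration of the same HeLa whole-cell lysate for every
#' analyte; amounts back-calculated against that curve are expressed in
#' HeLa-equivalent units and therefore comparable across blots regardless of
#' per-blot detection gain. The fit is ordinary least squares,
#' `intensity = slope * amount + intercept`; a through-origin variant is
#' available for background-free densitometry.
#'
#' @param std_lanes data frame of standard lanes from a single blot and
#'   analyte, with columns `std_amount` and `intensity` (and optionally
#'   `blot_id`, `analyte`, carried into the result).
#' @param through_origin force `intercept = 0`.
#' @return object of class `standard_curve`: `blot_id`, `analyte`, `points`,
#'   `slope`, `intercept`, `r_squared`.
#' @examples
#' fit_standard_curve(data.frame(std_amount = c(1, 2, 4),
#'                               intensity = c(10, 20, 40)))
#' @export
fit_standard_curve <- function(std_lanes, through_origin = FALSE) {
  blx_assert(all(c("std_amount", "intensity") %in% names(std_lanes)),
             "invalid_input", "std_lanes needs std_amount and intensity columns")
  std_lanes <- std_lanes[is.finite(std_lanes$std_amount) &
                           is.finite(std_lanes$intensity), , drop = FALSE]
  if (nrow(std_lanes) < 3)
    blx_error("insufficient_standards",
              "standard-curve fit needs at least 3 titration lanes")
  blx_assert(length(unique(std_lanes$blot_id)) <= 1 &&
               length(unique(std_lanes$analyte)) <= 1, "invalid_input",
             "standard lanes must come from one blot and one analyte")
  fit <- if (through_origin)
    lm(intensity ~ std_amount + 0, data = std_lanes)
  else
    lm(intensity ~ std_amount, data = std_lanes)
  cf <- coef(fit)
  slope <- unname(cf[["std_amount"]])
  intercept <- if (through_origin) 0 else unname(cf[["(Intercept)"]])
  if (!is.finite(slope) || slope <= 0)
    blx_error("non_monotone_standard",
              sprintf("fitted standard-curve slope is not positive (%.4g)", slope))
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((std_lanes$intensity - mean(std_lanes$intensity))^2)
  structure(list(
    blot_id = if ("blot_id" %in% names(std_lanes)) std_lanes$blot_id[1] else NA,
    analyte = if ("analyte" %in% names(std_lanes)) std_lanes$analyte[1] else NA,
    points = std_lanes[order(std_lanes$std_amount),
                       c("std_amount", "intensity")],
    slope = slope, intercept = intercept,
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve [blot %s, %s]: intensity = %.4g * amount + %.4g (R2 = %.4f, %d points)\n",
              x$blot_id, x$analyte, x$slope, x$intercept, x$r_squared,
              nrow(x$points)))
  invisible(x)
}

#' Back-calculate a band's standardized amount from a standard curve
#'
#' Inverse prediction `amount = (intensity - intercept) / slope`, in
#' HeLa-equivalent units. Amounts outside the titration range are kept but
#' flagged `extrapolated` (extreme localizations legitimately span log
#' scales); non-positive back-calculated amounts are an error — flooring
#' them would fabricate signal that biases log-ratios.
#'
#' @param lane a lane record (list/one-row data frame) with `intensity`, and
#'   `blot_id`/`analyte` checked against the curve when present.
#' @param curve a [fit_standard_curve()] result.
#' @return list with `amount` and `extrapolated`.
#' @export
quantify_band <- function(lane, curve) {
  blx_assert(inherits(curve, "standard_curve"), "invalid_input",
             "curve must be a standard_curve")
  if (!is.null(lane$blot_id) && !is.na(curve$blot_id))
    blx_assert(lane$blot_id == curve$blot_id, "invalid_input",
               "lane and curve come from different blots")
  if (!is.null(lane$analyte) && !is.na(curve$analyte))
    blx_assert(lane$analyte == curve$analyte, "invalid_input",
               "lane and curve measure different analytes")
  amount <- (lane$intensity - curve$intercept) / curve$slope
  if (!is.finite(amount) || amount <= 0)
    blx_error("nonpositive_amount",
              sprintf("back-calculated amount %.4g is not positive", amount))
  rng <- range(curve$points$std_amount)
  list(amount = amount, extrapolated = amount < rng[1] || amount > rng[2])
}

#' Calibrate all sample lanes of a lane table
#'
#' Fits one standard curve per blot x analyte from the `fraction == "std"`
#' lanes and back-calculates every sample band. Lanes whose back-calculated
#' amount is non-positive are excluded and reported in the `excluded`
#' attribute rather than floored.
#'
#' @param lanes lane table as produced by [render_blots()] or read with
#'   [read_tsv_table()].
#' @param through_origin passed to [fit_standard_curve()].
#' @return data frame of sample lanes with `amount` and `extrapolated`
#'   columns; attributes `curves` (list of fits) and `excluded` (dropped
#'   lanes with reason).
#' @export
calibrate_lanes <- function(lanes, through_origin = FALSE) {
  need <- c("blot_id", "lane_index", "analyte", "fraction", "sample_id",
            "intensity")
  blx_assert(all(need %in% names(lanes)), "invalid_input",
             paste("lane table must have columns:", paste(need, collapse = ", ")))
  blx_assert(!anyDuplicated(lanes[, c("blot_id", "lane_index")]),
             "invalid_input", "(blot_id, lane_index) must be unique")

  std <- lanes[lanes$fraction == "std", , drop = FALSE]
  smp <- lanes[lanes$fraction != "std", , drop = FALSE]
  curves <- list()
  for (b in unique(smp$blot_id)) {
    for (a in unique(smp$analyte[smp$blot_id == b])) {
      key <- paste(b, a, sep = ":")
      curves[[key]] <- fit_standard_curve(
        std[std$blot_id == b & std$analyte == a, , drop = FALSE],
        through_origin = through_origin)
    }
  }
  amount <- numeric(nrow(smp))
  extrapolated <- logical(nrow(smp))
  keep <- rep(TRUE, nrow(smp))
  reason <- character(nrow(smp))
  for (i in seq_len(nrow(smp))) {
    q <- tryCatch(quantify_band(smp[i, ], curves[[paste(smp$blot_id[i],
                                                        smp$analyte[i],
                                                        sep = ":")]]),
                  baxloc_nonpositive_amount = function(e) e)
    if (inherits(q, "condition")) {
      keep[i] <- FALSE
      reason[i] <- conditionMessage(q)
    } else {
      amount[i] <- q$amount
      extrapolated[i] <- q$extrapolated
    }
  }
  out <- smp[keep, , drop = FALSE]
  out$amount <- amount[keep]
  out$extrapolated <- extrapolated[keep]
  excluded <- smp[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!keep]
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  attr(out, "excluded") <- excluded
  out
}

#' Normalize calibrated amounts to the fractionation loading controls
#'
#' Mitochondrial amounts are expressed relative to COX IV and cytosolic
#' amounts relative to beta-ACTIN, measured in the same fraction of the same
#' sample. These ratios are invariant to how much of each fraction was
#' loaded, making samples run on different blots comparable.
#'
#' @param calibrated output of [calibrate_lanes()].
#' @return data frame with one row per sample x analyte (BAX, BAK):
#'   `sample_id`, `tissue`, `analyte`, `rel_mito`, `rel_cyto`, and QC flag
#'   `extrapolated` (any contributing band extrapolated).
#' @export
marker_normalize <- function(calibrated) {
  blx_assert(all(c("sample_id", "analyte", "fraction", "amount") %in%
                   names(calibrated)), "invalid_input",
             "calibrated lanes need sample_id, analyte, fraction, amount")
  smp <- calibrated[!is.na(calibrated$sample_id), , drop = FALSE]
  get_amount <- function(rows, analyte, fraction) {
    hit <- rows$analyte == analyte & rows$fraction == fraction
    if (!any(hit)) return(NULL)
    rows[which(hit)[1], c("amount", "extrapolated")]
  }
  out <- list()
  for (sid in unique(smp$sample_id)) {
    rows <- smp[smp$sample_id == sid, , drop = FALSE]
    coxiv <- get_amount(rows, "COXIV", "mito")
    actin <- get_amount(rows, "ACTIN", "cyto")
    for (analyte in intersect(c("BAX", "BAK"), rows$analyte)) {
      mito <- get_amount(rows, analyte, "mito")
      cyto <- get_amount(rows, analyte, "cyto")
      if (is.null(mito) || is.null(cyto)) next
      if (is.null(coxiv))
        blx_error("missing_marker",
                  sprintf("sample %s: no COX IV band in the mitochondrial fraction", sid))
      if (is.null(actin))
        blx_error("missing_marker",
                  sprintf("sample %s: no beta-ACTIN band in the cytosolic fraction", sid))
      out[[paste(sid, analyte)]] <- data.frame(
        sample_id = sid,
        tissue = if ("tissue" %in% names(rows)) rows$tissue[1] else NA_character_,
        analyte = analyte,
        rel_mito = mito$amount / coxiv$amount,
        rel_cyto = cyto$amount / actin$amount,
        extrapolated = any(mito$extrapolated, cyto$extrapolated,
                           coxiv$extrapolated, actin$extrapolated),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
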