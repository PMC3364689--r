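#' Reliability classification of QPPR-based dose-metric predictions
#'
#' Whether the clearance QPPR can be trusted inside the PBPK model is judged
#' on two axes: how *sensitive* the 24 h venous AUC is to metabolism (ratio
#' of the AUC with no metabolism to the AUC with maximum hepatic
#' extraction), and how *uncertain* the QPPR prediction is (fold difference
#' between predicted and experimental CL_intPL). Both axes use the same
#' three bins: low when within a factor of 2, medium when within an order of
#' magnitude, high beyond that (boundary values fall in the lower class).
#'
#' @name reliability
NULL

.reliability_bins <- c(low = 2, medium = 10)

.classify_fold <- function(x) {
  cls <- ifelse(x <= .reliability_bins["low"], "low",
                ifelse(x <= .reliability_bins["medium"], "medium", "high"))
  factor(cls, levels = c("low", "medium", "high"))
}

#' Sensitivity of the AUC dose metric to metabolism
#'
#' @param auc_emin 24 h AUC with essentially no metabolism (E = 0.001),
#'   mg h/L.
#' @param auc_emax 24 h AUC with maximum hepatic extraction (E = 0.999).
#' @return data.frame with `ratio` (= auc_emin/auc_emax, >= 1 in practice)
#'   and `class` (low/medium/high). Vectorized.
#' @export
sensitivity_class <- function(auc_emin, auc_emax) {
  if (any(auc_emin <= 0 | auc_emax <= 0)) stop("AUCs must be positive")
  ratio <- auc_emin / auc_emax
  data.frame(ratio = ratio, class = .classify_fold(ratio))
}

#' Uncertainty of the QPPR clearance prediction
#'
#' Fold difference `10^|pred - exp|` between predicted and experimental
#' log10 CL_intPL (symmetric, so over- and under-prediction score alike).
#' A missing experimental value (`NA`) represents the data-poor situation
#' of an untested chemical and is classified `high` by convention.
#'
#' @param pred_log_clint_pl predicted log10 CL_intPL.
#' @param exp_log_clint_pl experimental log10 CL_intPL, or `NA`.
#' @return data.frame with `fold` and `class`. Vectorized.
#' @export
uncertainty_class <- function(pred_log_clint_pl, exp_log_clint_pl) {
  stopifnot(all(is.finite(pred_log_clint_pl)))
  fold <- 10^abs(pred_log_clint_pl - exp_log_clint_pl)
  cls <- .classify_fold(fold)
  cls[is.na(exp_log_clint_pl)] <- "high"
  data.frame(fold = fold, class = cls)
}

#' Confidence in applying the QPPR within the PBPK model
#'
#' Lookup on the sensitivity-by-uncertainty grid: when sensitivity is low
#' the AUC barely depends on metabolism, so confidence is high regardless of
#' the prediction uncertainty; at medium sensitivity, confidence is high
#' when uncertainty is low and medium otherwise. High-sensitivity cells are
#' outside the populated grid: they return `"low"` with the `extrapolated`
#' flag set.
#'
#' @param sensitivity,uncertainty class labels (`"low"`, `"medium"`,
#'   `"high"`), vectorized.
#' @return data.frame with `confidence` and logical `extrapolated`.
#' @export
confidence_call <- function(sensitivity, uncertainty) {
  sensitivity <- as.character(sensitivity)
  uncertainty <- as.character(uncertainty)
  lv <- c("low", "medium", "high")
  stopifnot(all(sensitivity %in% lv), all(uncertainty %in% lv))
  grid <- matrix(c(
    # uncertainty: low     medium    high
    "high", "high", "high",   # sensitivity low
    "high", "medium", "medium", # sensitivity medium
    "low",  "low",  "low"     # sensitivity high (unpopulated, extrapolated)
  ), nrow = 3, byrow = TRUE, dimnames = list(lv, lv))
  conf <- grid[cbind(sensitivity, uncertainty)]
  data.frame(confidence = factor(conf, levels = lv),
             extrapolated = sensitivity == "high")
}

#' Reliability table for a chemical panel
#'
#' Runs the full pipeline for every chemical of the requested panel: the
#' E = 0.001 / E = 0.999 bounding PBPK simulations (1 ppm continuous 24 h
#' exposure) for the sensitivity axis, and the calibration-QPPR point
#' prediction against the experimental CL_intPL for the uncertainty axis.
#' For the evaluation panel the experimental values are withheld by default
#' (`assume_unknown = TRUE`), replicating the data-poor situation of new
#' chemicals, so uncertainty is uniformly high.
#'
#' @param dataset `"calibration"` or `"evaluation"`.
#' @param fit calibration `qppr_fit` (default [fit_qppr()]).
#' @param phys a [physiology_spec()].
#' @param assume_unknown withhold experimental clearances (default `TRUE`
#'   for the evaluation panel).
#' @param dt output grid step passed to [pbpk_simulate()].
#' @return data.frame with one row per chemical: ratios, per-axis classes
#'   and the overall confidence call.
#' @export
reliability_table <- function(dataset = c("calibration", "evaluation"),
                              fit = fit_qppr(), phys = physiology_spec(),
                              assume_unknown = dataset == "evaluation",
                              dt = 0.5) {
  dataset <- match.arg(dataset)
  panel <- .load_panel(dataset)
  ci <- predict_mean_ci(fit, panel)
  auc <- vapply(seq_len(nrow(panel)), function(i) {
    chem <- panel[i, ]
    exp_spec <- exposure_spec(1, chem$mw, t_end_exposure = 24, t_sim = 24)
    c(pbpk_simulate(chem, phys, exp_spec, clearance_spec(e_fixed = 0.001),
                    dt = dt)$auc24,
      pbpk_simulate(chem, phys, exp_spec, clearance_spec(e_fixed = 0.999),
                    dt = dt)$auc24)
  }, numeric(2))
  sens <- sensitivity_class(auc[1, ], auc[2, ])
  exp_val <- if (isTRUE(assume_unknown)) NA_real_ else panel$log_clint_pl_exp
  unc <- uncertainty_class(ci$point, exp_val)
  conf <- confidence_call(sens$class, unc$class)
  data.frame(
    name = panel$name, dataset = dataset,
    auc_emin = auc[1, ], auc_emax = auc[2, ],
    sensitivity_ratio = sens$ratio, sensitivity_class = sens$class,
    uncertainty_fold = unc$fold, uncertainty_class = unc$class,
    confidence = conf$confidence, extrapolated = conf$extrapolated
  )
}
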