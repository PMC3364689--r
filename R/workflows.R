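#' End-to-end reproduction of the packaged analysis
#'
#' Runs every stage on the packaged panels: the calibration QPPR (with its
#' phospholipid:water-descriptor variant and the blood-referenced
#' two-predictor refit), the 95% mean-CI widths for both panels, the
#' 4-scenario PBPK AUC table for all 37 chemicals (1 ppm continuous 24 h),
#' the end-of-exposure concentration ratios for the 8 h profile, and the
#' reliability tables. Deterministic: two runs produce identical reports.
#'
#' @param out_dir optional directory; when given, the report is written as
#'   `report.json` plus `auc_table.csv` and `reliability_<panel>.csv`.
#' @param level confidence level for the QPPR bounds.
#' @param dt output grid step for the PBPK runs, h.
#' @param quiet suppress per-stage progress messages.
#' @return the report, invisibly when `out_dir` is given: a list with
#'   elements `regression`, `ci_widths`, `auc_table`, `summary` and
#'   `reliability`.
#' @export
reproduce_all <- function(out_dir = NULL, level = 0.95, dt = 0.5,
                          quiet = FALSE) {
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  cal <- load_calibration_set()
  ev <- load_evaluation_set()
  all37 <- rbind(cal, ev)

  say("stage 1/4: regression")
  fit <- fit_qppr(cal)
  cal_v <- cal
  cal_v$log_pplw <- log10(cal$p_pl_blood) + cal$log_pbw
  fit_pplw <- fit_multilinear(cal_v, "log_clint_pl_exp",
                              c("log_pplw", "log_pbw", "ip"))
  cal_b <- cal
  cal_b$log_clint_blood <- cal$log_clint_pl_exp + log10(cal$p_pl_blood)
  fit_blood <- fit_multilinear(cal_b, "log_clint_blood", c("log_pow", "ip"))
  regression <- list(
    qppr = fit[c("coefficients", "coef_standard_errors", "coef_p_values",
                 "r2", "r2_adj", "q2", "s", "f_stat", "f_p_value", "vifs")],
    pplw_variant = fit_pplw[c("coefficients", "r2", "r2_adj", "q2")],
    blood_referenced = fit_blood[c("coefficients", "r2", "r2_adj")]
  )

  say("stage 2/4: confidence intervals")
  box <- applicability_domain()
  ci_cal <- cbind(name = cal$name, dataset = "calibration",
                  predict_mean_ci(fit, cal, level, box))
  ci_ev <- cbind(name = ev$name, dataset = "evaluation",
                 predict_mean_ci(fit, ev, level, box))
  ci_widths <- rbind(ci_cal, ci_ev)

  say("stage 3/4: PBPK scenarios (", nrow(all37), " chemicals x 4)")
  phys <- physiology_spec()
  rows <- lapply(seq_len(nrow(all37)), function(i) {
    chem <- all37[i, ]
    sc24 <- run_four_scenarios(chem, phys,
                               exposure_spec(1, chem$mw, t_end_exposure = 24,
                                             t_sim = 24),
                               fit = fit, level = level, dt = dt)
    sc8 <- run_four_scenarios(chem, phys,
                              exposure_spec(1, chem$mw, t_end_exposure = 8,
                                            t_sim = 24),
                              fit = fit, level = level, dt = dt)
    data.frame(
      name = chem$name, dataset = chem$dataset,
      auc24_emin = sc24$E_min$auc24, auc24_emax = sc24$E_max$auc24,
      auc24_lmci = sc24$LMCI$auc24, auc24_umci = sc24$UMCI$auc24,
      cend8_emin = sc8$E_min$c_end_exposure,
      cend8_emax = sc8$E_max$c_end_exposure,
      cend8_lmci = sc8$LMCI$c_end_exposure,
      cend8_umci = sc8$UMCI$c_end_exposure
    )
  })
  auc_table <- do.call(rbind, rows)

  msd <- function(x) c(mean = mean(x), sd = stats::sd(x))
  is_cal <- auc_table$dataset == "calibration"
  summary_ratios <- list(
    auc_ratio_bounds_calibration =
      msd(auc_table$auc24_emin[is_cal] / auc_table$auc24_emax[is_cal]),
    auc_ratio_bounds_evaluation =
      msd(auc_table$auc24_emin[!is_cal] / auc_table$auc24_emax[!is_cal]),
    auc_ratio_qppr_calibration =
      msd(auc_table$auc24_lmci[is_cal] / auc_table$auc24_umci[is_cal]),
    auc_ratio_qppr_evaluation =
      msd(auc_table$auc24_lmci[!is_cal] / auc_table$auc24_umci[!is_cal]),
    cend_ratio_bounds_calibration =
      msd(auc_table$cend8_emin[is_cal] / auc_table$cend8_emax[is_cal]),
    cend_ratio_qppr_calibration =
      msd(auc_table$cend8_lmci[is_cal] / auc_table$cend8_umci[is_cal]),
    ci_width_calibration = msd(ci_cal$width),
    ci_width_evaluation = msd(ci_ev$width)
  )

  say("stage 4/4: reliability classification")
  reliability <- list(
    calibration = reliability_table("calibration", fit, phys, dt = dt),
    evaluation = reliability_table("evaluation", fit, phys, dt = dt)
  )

  report <- list(regression = regression, ci_widths = ci_widths,
                 auc_table = auc_table, summary = summary_ratios,
                 reliability = reliability)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(regression = regression, summary = summary_ratios),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(auc_table, file.path(out_dir, "auc_table.csv"),
                     row.names = FALSE)
    utils::write.csv(ci_widths, file.path(out_dir, "ci_widths.csv"),
                     row.names = FALSE)
    for (panel in names(reliability)) {
      utils::write.csv(reliability[[panel]],
                       file.path(out_dir, paste0("reliability_", panel, ".csv")),
                       row.names = FALSE)
    }
    return(invisible(report))
  }
  report
}

#' Export the four-scenario venous-concentration envelope of one chemical
#'
#' Time courses of venous blood concentration for the two bounding
#' extraction scenarios and the two QPPR confidence-bound scenarios, on an
#' aligned grid (default: 8 h exposure, 24 h horizon, 0.1 h step — the
#' envelope-figure convention).
#'
#' @param chemical chemical name (resolved via [canonical_chemical_name()]).
#' @param out optional CSV path.
#' @param conc_ppm exposure concentration, ppm.
#' @param t_end_exposure,t_sim exposure window and horizon, h.
#' @param dt grid step, h.
#' @param fit calibration `qppr_fit`.
#' @param phys a [physiology_spec()].
#' @return data.frame with `time_h` and one venous-concentration column per
#'   scenario (`c_ven_emin`, `c_ven_lmci`, `c_ven_umci`, `c_ven_emax`,
#'   mg/L).
#' @export
export_envelopes <- function(chemical, out = NULL, conc_ppm = 1,
                             t_end_exposure = 8, t_sim = 24, dt = 0.1,
                             fit = fit_qppr(), phys = physiology_spec()) {
  chem <- chemical_record(chemical)
  sc <- run_four_scenarios(
    chem, phys,
    exposure_spec(conc_ppm, chem$mw, t_end_exposure = t_end_exposure,
                  t_sim = t_sim),
    fit = fit, dt = dt)
  env <- data.frame(time_h = sc$E_min$time,
                    c_ven_emin = sc$E_min$c_ven,
                    c_ven_lmci = sc$LMCI$c_ven,
                    c_ven_umci = sc$UMCI$c_ven,
                    c_ven_emax = sc$E_max$c_ven)
  if (!is.null(out)) {
    utils::write.csv(env, out, row.names = FALSE)
    return(invisible(env))
  }
  env
}
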