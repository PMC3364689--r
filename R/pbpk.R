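#' Human physiology for the inhalation PBPK model
#'
#' Reference adult parameterization: 70 kg body weight, cardiac output and
#' alveolar ventilation both 18 L/h/kg^0.74, and the four perfused
#' compartments (liver, richly perfused, poorly perfused, fat) as fractions
#' of body weight and cardiac output. The remaining body mass (bone, etc.)
#' holds no chemical.
#'
#' @param bw body weight, kg.
#' @param qc_coeff,qp_coeff allometric coefficients of cardiac output and
#'   alveolar ventilation, L/h/kg^0.74.
#' @param vol_frac named fractions of body weight for `liver`, `rich`,
#'   `poor`, `fat` (must sum to <= 1).
#' @param flow_frac named fractions of cardiac output for the same
#'   compartments (must sum to exactly 1).
#' @return object of class `physiology_spec` with the inputs plus derived
#'   absolute flows (`qc`, `qp`, `flows` in L/h) and volumes (`vols` in L).
#' @export
physiology_spec <- function(bw = 70, qc_coeff = 18, qp_coeff = 18,
                            vol_frac = c(liver = 0.026, rich = 0.05,
                                         poor = 0.62, fat = 0.19),
                            flow_frac = c(liver = 0.26, rich = 0.44,
                                          poor = 0.25, fat = 0.05)) {
  tissues <- c("liver", "rich", "poor", "fat")
  stopifnot(bw > 0, qc_coeff > 0, qp_coeff > 0,
            setequal(names(vol_frac), tissues),
            setequal(names(flow_frac), tissues),
            all(vol_frac > 0), all(flow_frac > 0))
  if (abs(sum(flow_frac) - 1) > 1e-12) {
    stop("flow fractions must sum to 1 (got ", sum(flow_frac), ")")
  }
  if (sum(vol_frac) > 1) stop("volume fractions must sum to <= 1")
  qc <- qc_coeff * bw^0.74
  structure(list(
    bw = bw, qc_coeff = qc_coeff, qp_coeff = qp_coeff,
    vol_frac = vol_frac[tissues], flow_frac = flow_frac[tissues],
    qc = qc, qp = qp_coeff * bw^0.74,
    vols = vol_frac[tissues] * bw, flows = flow_frac[tissues] * qc
  ), class = "physiology_spec")
}

#' Inhalation exposure profile
#'
#' Square-wave inhalation exposure: `conc_ppm` between `t_start` and
#' `t_end_exposure`, clean air afterwards, simulated to `t_sim`.
#'
#' @param conc_ppm exposure concentration, ppm (volume mixing ratio).
#' @param mw molecular weight, g/mol (for ppm to mg/L conversion).
#' @param t_start,t_end_exposure,t_sim exposure window and horizon, h.
#' @return object of class `exposure_spec`.
#' @export
exposure_spec <- function(conc_ppm = 1, mw, t_start = 0,
                          t_end_exposure = 24, t_sim = 24) {
  stopifnot(conc_ppm >= 0, mw > 0, t_start >= 0,
            t_start < t_end_exposure, t_end_exposure <= t_sim)
  structure(list(conc_ppm = conc_ppm, mw = mw, t_start = t_start,
                 t_end_exposure = t_end_exposure, t_sim = t_sim),
            class = "exposure_spec")
}

#' Hepatic clearance specification
#'
#' Either a fixed hepatic extraction ratio (`e_fixed`, the bounding
#' "no metabolism" / "maximum extraction" scenarios) or a QPPR-derived
#' log10 phospholipid-referenced intrinsic clearance (`clint_pl_log10`)
#' which is converted to a whole-liver blood clearance and then to an
#' extraction ratio via [hepatic_extraction()]. `kf` is the optional
#' first-order hepatic constant entering the extraction ratio as
#' `kf * V_liver`.
#'
#' @param e_fixed extraction ratio in (0, 1), or `NULL`.
#' @param clint_pl_log10 log10 CL_intPL (L PL/h/kg^0.75), or `NULL`.
#' @param kf first-order metabolic constant, 1/h (>= 0).
#' @return object of class `clearance_spec`.
#' @export
clearance_spec <- function(e_fixed = NULL, clint_pl_log10 = NULL, kf = 0) {
  if (is.null(e_fixed) == is.null(clint_pl_log10)) {
    stop("set exactly one of 'e_fixed' and 'clint_pl_log10'")
  }
  stopifnot(kf >= 0)
  if (!is.null(e_fixed) && (e_fixed <= 0 || e_fixed >= 1)) {
    stop("'e_fixed' must lie strictly between 0 and 1")
  }
  structure(list(
    mode = if (is.null(e_fixed)) "intrinsic_clearance" else "fixed_extraction",
    e_fixed = e_fixed, clint_pl_log10 = clint_pl_log10, kf = kf
  ), class = "clearance_spec")
}

#' Convert a gas-phase ppm concentration to mg/L
#'
#' `conc_ppm * mw / 24450`, with 24450 mL/mol the molar volume of an ideal
#' gas at 25 degrees C and 1 atm (the usual PBPK convention).
#'
#' @param conc_ppm concentration, ppm.
#' @param mw molecular weight, g/mol.
#' @param molar_volume molar volume, mL/mol.
#' @return concentration in mg/L.
#' @export
ppm_to_mg_per_l <- function(conc_ppm, mw, molar_volume = 24450) {
  stopifnot(conc_ppm >= 0, mw > 0, molar_volume > 0)
  conc_ppm * mw / molar_volume
}

#' Scale a phospholipid-referenced clearance to a human whole-body value
#'
#' `10^clint_pl_log10 * pplb * bw^0.75`: the phospholipid-referenced
#' intrinsic clearance is converted to blood reference with the
#' phospholipid:blood PC and scaled allometrically (per kg^0.75) to the
#' human body weight.
#'
#' @param clint_pl_log10 log10 CL_intPL, L PL/h/kg^0.75.
#' @param pplb phospholipid:blood PC.
#' @param bw body weight, kg.
#' @return intrinsic clearance, L blood/h.
#' @export
human_clint <- function(clint_pl_log10, pplb, bw) {
  stopifnot(is.finite(clint_pl_log10), pplb > 0, bw > 0)
  10^clint_pl_log10 * pplb * bw^0.75
}

#' Well-stirred-liver hepatic extraction ratio
#'
#' `E = (CLint + Kf * V_L) / (CLint + Kf * V_L + Q_L)`; the hepatic
#' clearance follows as `CL_h = Q_L * E`.
#'
#' @param clint intrinsic clearance, L blood/h (>= 0).
#' @param kf first-order metabolic constant, 1/h (>= 0).
#' @param v_liver liver volume, L.
#' @param q_liver liver blood flow, L/h (> 0).
#' @return extraction ratio in \[0, 1).
#' @export
hepatic_extraction <- function(clint, kf = 0, v_liver, q_liver) {
  stopifnot(clint >= 0, kf >= 0, v_liver >= 0, q_liver > 0)
  num <- clint + kf * v_liver
  num / (num + q_liver)
}

#' Simulate the four-compartment inhalation PBPK model
#'
#' Perfusion-limited mass balances for liver, richly perfused, poorly
#' perfused and fat compartments connected by blood flow, with a
#' steady-state gas-exchange lung:
#' `C_art = (Qp * C_inh + Qc * C_ven) / (Qc + Qp / Pba)`,
#' `dA_t/dt = Q_t * (C_art - A_t / V_t / P_tb)`, and hepatic metabolism
#' removing `CL_h * C_art` from the liver with `CL_h = Q_L * E`. Mixed
#' venous blood is the flow-weighted sum of tissue effluents. The venous
#' AUC and the cumulative inhaled, exhaled and metabolized amounts are
#' carried as extra integrated states, so the mass balance closes to solver
#' precision at every output time.
#'
#' @param chem one-row data.frame of a chemical record (needs `pba`, the
#'   four tissue:blood PCs, `p_pl_blood`, `mw`, `name`); see
#'   [chemical_record()].
#' @param phys a [physiology_spec()].
#' @param exposure an [exposure_spec()]; its `mw` defaults to the
#'   chemical's when built via the `conc_ppm`/`t_end_exposure` shortcut
#'   arguments of [run_four_scenarios()].
#' @param clearance a [clearance_spec()].
#' @param dt output grid step, h.
#' @param rtol,atol solver tolerances (stiff-capable lsoda).
#' @return object of class `pbpk_result`: list with `time` (h), `c_ven`,
#'   `c_art` (mg/L), `tissue_amounts` (mg, one column per compartment),
#'   `amount_inhaled`, `amount_exhaled`, `amount_metabolized` (mg),
#'   `auc_ven` (running mg h/L), scalars `auc24`, `c_end_exposure`,
#'   `extraction_ratio`, `mass_balance_error`, and the input specs.
#' @export
pbpk_simulate <- function(chem, phys = physiology_spec(), exposure,
                          clearance, dt = 0.1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(phys, "physiology_spec"),
            inherits(exposure, "exposure_spec"),
            inherits(clearance, "clearance_spec"),
            is.data.frame(chem), nrow(chem) == 1L)
  ptb <- c(liver = chem$p_liver_blood, rich = chem$p_rich_blood,
           poor = chem$p_poor_blood, fat = chem$p_fat_blood)
  if (any(!is.finite(ptb) | ptb <= 0) || !is.finite(chem$pba) || chem$pba <= 0) {
    stop("chemical '", chem$name, "' lacks positive partition coefficients")
  }
  vols <- phys$vols
  flows <- phys$flows
  qc <- phys$qc
  qp <- phys$qp
  pba <- chem$pba

  E <- if (clearance$mode == "fixed_extraction") {
    clearance$e_fixed
  } else {
    clint <- human_clint(clearance$clint_pl_log10, chem$p_pl_blood, phys$bw)
    hepatic_extraction(clint, clearance$kf, vols[["liver"]], flows[["liver"]])
  }
  clh <- flows[["liver"]] * E
  cinh_exposed <- ppm_to_mg_per_l(exposure$conc_ppm, exposure$mw)

  deriv <- function(t, y, cinh) {
    cvt <- y[1:4] / vols / ptb
    cven <- sum(flows * cvt) / qc
    cart <- (qp * cinh + qc * cven) / (qc + qp / pba)
    dA <- flows * (cart - cvt)
    dA[1] <- dA[1] - clh * cart
    list(c(dA, cven, qp * cinh, qp * cart / pba, clh * cart))
  }

  # integrate in legs so the square-wave inhalation stays smooth within a leg
  breaks <- unique(c(0, exposure$t_start, exposure$t_end_exposure, exposure$t_sim))
  breaks <- sort(breaks[breaks <= exposure$t_sim])
  grid <- sort(unique(c(seq(0, exposure$t_sim, by = dt), breaks)))
  y <- stats::setNames(rep(0, 8),
                       c("liver", "rich", "poor", "fat",
                         "auc_ven", "inhaled", "exhaled", "metabolized"))
  rows <- NULL
  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1L]
    cinh <- if (t0 >= exposure$t_start && t0 < exposure$t_end_exposure)
      cinh_exposed else 0
    times <- grid[grid >= t0 & grid <= t1]
    sol <- tryCatch(
      deSolve::ode(y, times, deriv, cinh, method = "lsoda",
                   rtol = rtol, atol = atol),
      warning = function(w) stop("PBPK solver failed for '", chem$name,
                                 "': ", conditionMessage(w), call. = FALSE),
      error = function(e) stop("PBPK solver failed for '", chem$name,
                               "': ", conditionMessage(e), call. = FALSE)
    )
    y <- sol[nrow(sol), -1L]
    rows <- rbind(rows, if (k == 1L) sol else sol[-1L, , drop = FALSE])
  }
  if (min(rows[, 2:5]) < -1e-7) {
    stop("negative compartment amount for '", chem$name, "'")
  }
  time <- rows[, "time"]
  A <- pmax(rows[, c("liver", "rich", "poor", "fat"), drop = FALSE], 0)
  cvt <- sweep(A, 2, vols * ptb, "/")
  cven <- drop(cvt %*% flows) / qc
  cinh_t <- ifelse(time >= exposure$t_start & time < exposure$t_end_exposure,
                   cinh_exposed, 0)
  cart <- (qp * cinh_t + qc * cven) / (qc + qp / pba)

  inhaled <- rows[, "inhaled"]
  accounted <- rowSums(A) + rows[, "exhaled"] + rows[, "metabolized"]
  mbe <- max(abs(inhaled - accounted) / pmax(inhaled, atol))

  auc_state <- rows[, "auc_ven"]
  t24 <- min(24, exposure$t_sim)
  structure(list(
    chemical = chem$name,
    time = time, c_ven = cven, c_art = cart,
    tissue_amounts = A,
    amount_inhaled = inhaled, amount_exhaled = rows[, "exhaled"],
    amount_metabolized = rows[, "metabolized"], auc_ven = auc_state,
    auc24 = stats::approx(time, auc_state, t24)$y,
    c_end_exposure = stats::approx(time, cven, exposure$t_end_exposure)$y,
    extraction_ratio = unname(E),
    mass_balance_error = mbe,
    physiology = phys, exposure = exposure, clearance = clearance
  ), class = "pbpk_result")
}

#' @export
print.pbpk_result <- function(x, ...) {
  cat(sprintf(
    "PBPK simulation: %s | %g ppm, %g-%g h exposure, %g h horizon\n",
    x$chemical, x$exposure$conc_ppm, x$exposure$t_start,
    x$exposure$t_end_exposure, x$exposure$t_sim))
  cat(sprintf("  E = %.4g   AUC24 = %.4g mg h/L   C(end exposure) = %.4g mg/L\n",
              x$extraction_ratio, x$auc24, x$c_end_exposure))
  cat(sprintf("  mass-balance error (rel) = %.2e\n", x$mass_balance_error))
  invisible(x)
}

#' Venous AUC up to a time point
#'
#' Reads the venous-blood AUC from the integrated AUC state carried by the
#' solver (not recomputed from the sampled concentration curve).
#'
#' @param result a [pbpk_simulate()] result.
#' @param t_end endpoint, h; must lie within the simulated horizon.
#' @return AUC from 0 to `t_end`, mg h/L.
#' @export
auc_at <- function(result, t_end) {
  stopifnot(inherits(result, "pbpk_result"))
  if (t_end < 0 || t_end > max(result$time)) {
    stop("t_end must lie within the simulated horizon [0, ",
         max(result$time), "] h")
  }
  stats::approx(result$time, result$auc_ven, t_end)$y
}

#' Run the four metabolism scenarios for one chemical
#'
#' The bounding scenarios fix the hepatic extraction ratio at `e_min`
#' (0.001, essentially no metabolism) and `e_max` (0.999, flow-limited
#' maximum extraction); the QPPR scenarios set the intrinsic clearance to
#' the lower (LMCI) and upper (UMCI) bound of the level-`level` mean
#' confidence interval of the predicted log CL_intPL at the chemical's
#' descriptors, converted through [human_clint()] and
#' [hepatic_extraction()] (including the chemical's `kf`).
#'
#' @param chem one-row chemical record.
#' @param phys a [physiology_spec()].
#' @param exposure an [exposure_spec()]; defaults to 1 ppm continuous 24 h
#'   at the chemical's molecular weight.
#' @param fit calibration `qppr_fit` (default [fit_qppr()]).
#' @param level confidence level (default 0.95).
#' @param e_min,e_max bounding extraction ratios.
#' @param ... passed to [pbpk_simulate()].
#' @return named list of `pbpk_result`s: `E_min`, `E_max`, `LMCI`, `UMCI`.
#' @export
run_four_scenarios <- function(chem, phys = physiology_spec(),
                               exposure = exposure_spec(1, chem$mw),
                               fit = fit_qppr(), level = 0.95,
                               e_min = 0.001, e_max = 0.999, ...) {
  ci <- predict_mean_ci(fit, chem, level = level)
  kf <- if ("kf" %in% names(chem)) chem$kf else 0
  list(
    E_min = pbpk_simulate(chem, phys, exposure, clearance_spec(e_fixed = e_min), ...),
    E_max = pbpk_simulate(chem, phys, exposure, clearance_spec(e_fixed = e_max), ...),
    LMCI = pbpk_simulate(chem, phys, exposure,
                         clearance_spec(clint_pl_log10 = ci$lmci, kf = kf), ...),
    UMCI = pbpk_simulate(chem, phys, exposure,
                         clearance_spec(clint_pl_log10 = ci$umci, kf = kf), ...)
  )
}
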