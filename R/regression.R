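#' Ordinary least-squares QPPR fit with full diagnostics
#'
#' Fits the multilinear QPPR `response ~ predictors` by OLS and collects the
#' statistics used to judge model adequacy: coefficient table with standard
#' errors and t-test p-values, R2, adjusted R2, standard error of the estimate
#' `s`, the F statistic with its p-value, per-predictor variance inflation
#' factors, the leave-one-out Q2 and the `(X'X)^-1` matrix needed for
#' mean-confidence-interval algebra.
#'
#' @param records data.frame holding the response and predictor columns.
#' @param response name of the response column (log10 clearance scale).
#' @param predictors character vector of predictor column names.
#' @return object of class `qppr_fit`: list with `predictor_names`,
#'   `coefficients`, `coef_standard_errors`, `coef_p_values`, `r2`, `r2_adj`,
#'   `q2`, `s`, `f_stat`, `f_p_value`, `vifs`, `xtx_inverse`, `n`,
#'   `residuals`, plus the underlying `lm` object and the training data.
#' @examples
#' fit <- fit_multilinear(load_calibration_set(), "log_clint_pl_exp",
#'                        c("log_pow", "log_pbw", "ip"))
#' fit$r2
#' @export
fit_multilinear <- function(records, response = "log_clint_pl_exp",
                            predictors = c("log_pow", "log_pbw", "ip")) {
  stopifnot(is.data.frame(records), length(predictors) >= 1L)
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  dat <- records[, cols, drop = FALSE]
  if (any(!vapply(dat, is.numeric, TRUE)) || any(!is.finite(as.matrix(dat)))) {
    stop("response and predictors must be finite numeric")
  }
  n <- nrow(dat)
  p <- length(predictors)
  if (n <= p + 1L) stop("need n > p + 1 observations (n = ", n, ", p = ", p, ")")

  fml <- stats::reformulate(predictors, response)
  X <- stats::model.matrix(fml, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  model <- stats::lm(fml, data = dat)
  sm <- summary(model)
  fs <- sm$fstatistic

  fit <- structure(list(
    predictor_names = predictors,
    response = response,
    coefficients = stats::coef(model),
    coef_standard_errors = sm$coefficients[, "Std. Error"],
    coef_p_values = sm$coefficients[, "Pr(>|t|)"],
    r2 = sm$r.squared,
    r2_adj = sm$adj.r.squared,
    q2 = NA_real_,
    s = sm$sigma,
    f_stat = if (is.null(fs)) NA_real_ else unname(fs["value"]),
    f_p_value = if (is.null(fs)) NA_real_ else
      unname(stats::pf(fs["value"], fs["numdf"], fs["dendf"], lower.tail = FALSE)),
    vifs = if (p >= 2L) vif(dat[, predictors, drop = FALSE]) else NULL,
    xtx_inverse = chol2inv(qr.R(qrX)),
    n = n,
    residuals = unname(stats::resid(model)),
    model = model,
    data = dat
  ), class = "qppr_fit")
  dimnames(fit$xtx_inverse) <- list(colnames(X), colnames(X))
  fit$q2 <- loo_q2(records, response, predictors)
  fit
}

#' @export
print.qppr_fit <- function(x, ...) {
  cat("QPPR multilinear fit:", x$response, "~",
      paste(x$predictor_names, collapse = " + "), "\n")
  ct <- cbind(estimate = x$coefficients, se = x$coef_standard_errors,
              p = x$coef_p_values)
  print(round(ct, 4))
  cat(sprintf("n = %d   R2 = %.3f   R2_adj = %.3f   Q2 = %.3f   s = %.3f\n",
              x$n, x$r2, x$r2_adj, x$q2, x$s))
  if (!is.null(x$vifs)) {
    cat("VIF:", paste(sprintf("%s = %.2f", names(x$vifs), x$vifs), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Leave-one-out cross-validated Q2
#'
#' For each record the model is refit without it and used to predict it;
#' Q2 = 1 - PRESS/SSY with PRESS the predicted residual sum of squares.
#' The total sum of squares SSY is centred on each leave-one-out training
#' fold's mean, `SSY = sum((y_i - mean(y[-i]))^2)`, i.e. both numerator and
#' denominator are deviations from quantities estimated without record i
#' (see the methods vignette for why this convention is used).
#'
#' @inheritParams fit_multilinear
#' @return Q2 (dimensionless, <= 1).
#' @export
loo_q2 <- function(records, response = "log_clint_pl_exp",
                   predictors = c("log_pow", "log_pbw", "ip")) {
  dat <- records[, c(response, predictors), drop = FALSE]
  n <- nrow(dat)
  if (n < length(predictors) + 3L) stop("too few records for leave-one-out Q2")
  fml <- stats::reformulate(predictors, response)
  y <- dat[[response]]
  press <- 0
  ssy <- 0
  for (i in seq_len(n)) {
    fit_i <- stats::lm(fml, data = dat[-i, , drop = FALSE])
    press <- press + (y[i] - stats::predict(fit_i, dat[i, , drop = FALSE]))^2
    ssy <- ssy + (y[i] - mean(y[-i]))^2
  }
  if (ssy <= 0) stop("degenerate response: zero total sum of squares")
  unname(1 - press / ssy)
}

#' Variance inflation factors
#'
#' VIF_i = 1 / (1 - R_i^2) where R_i^2 is the coefficient of determination of
#' the regression (with intercept) of predictor i on the other predictors.
#' Perfect collinearity yields `Inf`.
#'
#' @param design data.frame or matrix of predictor columns (>= 2 columns).
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(design) {
  design <- as.data.frame(design)
  if (ncol(design) < 2L) stop("VIF needs at least two predictors")
  vapply(names(design), function(v) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(names(design), v), v),
                            data = design))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Stepwise predictor selection on partial-F p-values
#'
#' Forward-entry / backward-removal stepwise regression: at each step the
#' candidate whose addition has the smallest partial-F p-value enters if that
#' p-value is below `p_enter`; after each entry, any included predictor whose
#' partial-F p-value exceeds `p_remove` is removed (largest first). Ties are
#' broken by the input order of `candidates`. Deterministic given the data
#' and thresholds.
#'
#' @inheritParams fit_multilinear
#' @param candidates character vector of candidate predictor columns.
#' @param p_enter entry threshold on the partial-F p-value (default 0.05).
#' @param p_remove removal threshold (default 0.10; must exceed `p_enter`).
#' @return `qppr_fit` for the selected model (intercept-only fits are
#'   returned with `predictor_names = character(0)` and an `empty` flag),
#'   with the selection trace in attribute `"trace"`.
#' @export
stepwise_select <- function(records, response = "log_clint_pl_exp",
                            candidates, p_enter = 0.05, p_remove = 0.10) {
  stopifnot(length(candidates) >= 1L, p_enter < p_remove)
  included <- character(0)
  trace <- character(0)
  partial_f_p <- function(base, extra) {
    # p-value of the F test for adding `extra` to the model with `base`
    small <- if (length(base) == 0L) {
      stats::lm(stats::reformulate("1", response), data = records)
    } else {
      stats::lm(stats::reformulate(base, response), data = records)
    }
    big <- stats::lm(stats::reformulate(c(base, extra), response), data = records)
    tab <- stats::anova(small, big)
    tab[["Pr(>F)"]][2L]
  }
  repeat {
    pool <- setdiff(candidates, included)
    if (length(pool) == 0L) break
    pvals <- vapply(pool, function(v) partial_f_p(included, v), numeric(1))
    best <- which.min(pvals)  # ties -> first in input order
    if (!is.finite(pvals[best]) || pvals[best] >= p_enter) break
    included <- c(included, pool[best])
    trace <- c(trace, paste0("+", pool[best], " (p=", signif(pvals[best], 3), ")"))
    repeat {
      if (length(included) < 2L) break
      drop_p <- vapply(included, function(v) {
        partial_f_p(setdiff(included, v), v)
      }, numeric(1))
      worst <- which.max(drop_p)
      if (drop_p[worst] <= p_remove) break
      trace <- c(trace, paste0("-", included[worst], " (p=", signif(drop_p[worst], 3), ")"))
      included <- included[-worst]
    }
  }
  if (length(included) == 0L) {
    fit <- structure(list(
      predictor_names = character(0), response = response,
      coefficients = c(`(Intercept)` = mean(records[[response]])),
      r2 = 0, q2 = NA_real_, n = nrow(records), empty = TRUE
    ), class = "qppr_fit")
  } else {
    fit <- fit_multilinear(records, response, included)
  }
  attr(fit, "trace") <- trace
  fit
}

#' Applicability-domain box of the calibration descriptors
#'
#' The closed per-descriptor ranges spanned by the calibration panel:
#' log Pow in \[1.09, 4.03\], log Pbw in \[0.160, 2.492\], ionization
#' potential in \[9.130, 11.276\] eV. The box is computed from the packaged
#' calibration descriptors at full precision. A custom box can be built with
#' `domain_box()`.
#'
#' @return object of class `domain_box`: named list of `c(min, max)` ranges.
#' @export
applicability_domain <- function() {
  cal <- load_calibration_set()
  domain_box(log_pow = range(cal$log_pow), log_pbw = range(cal$log_pbw),
             ip = range(cal$ip))
}

#' @rdname applicability_domain
#' @param ... named `c(min, max)` numeric ranges, one per descriptor.
#' @export
domain_box <- function(...) {
  box <- list(...)
  stopifnot(length(box) >= 1L, !is.null(names(box)), all(nzchar(names(box))))
  for (nm in names(box)) {
    r <- box[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2]) {
      stop("range for '", nm, "' must be c(min, max) with min <= max")
    }
  }
  structure(box, class = "domain_box")
}

#' Check descriptors against an applicability-domain box
#'
#' A point is inside iff every descriptor lies within its closed
#' \[min, max\] interval.
#'
#' @param x0 named numeric vector, one-row data.frame, or data.frame of
#'   descriptor values.
#' @param box a [domain_box()] (default: [applicability_domain()]).
#' @return data.frame with one logical column per descriptor plus `overall`.
#' @export
check_domain <- function(x0, box = applicability_domain()) {
  stopifnot(inherits(box, "domain_box"))
  if (is.numeric(x0)) x0 <- as.data.frame(as.list(x0))
  missing_cols <- setdiff(names(box), names(x0))
  if (length(missing_cols) > 0L) {
    stop("descriptor(s) absent from x0: ", paste(missing_cols, collapse = ", "))
  }
  flags <- lapply(names(box), function(nm) {
    x0[[nm]] >= box[[nm]][1] & x0[[nm]] <= box[[nm]][2]
  })
  names(flags) <- names(box)
  out <- as.data.frame(flags)
  out$overall <- Reduce(`&`, flags)
  out
}

#' 95% confidence interval of the mean predicted response
#'
#' For a descriptor vector x0 (with intercept prepended) the half-width of
#' the level-`level` confidence interval of the *mean* response is
#' `t(1-(1-level)/2, n-p-1) * s * sqrt(x0' (X'X)^-1 x0)`. This is the
#' uncertainty of the regression surface itself, not a prediction interval
#' for a new observation.
#'
#' @param fit a [fit_multilinear()] result.
#' @param newdata data.frame of descriptor values (one row per prediction).
#' @param level confidence level in (0, 1), default 0.95.
#' @param box optional [domain_box()]; when given, `in_domain` reports
#'   whether each row lies inside it.
#' @return data.frame with columns `point`, `lmci`, `umci`, `width`, `level`
#'   and (when `box` is given) `in_domain`; all on the log10 response scale.
#' @export
predict_mean_ci <- function(fit, newdata, level = 0.95, box = NULL) {
  stopifnot(inherits(fit, "qppr_fit"), level > 0, level < 1)
  if (is.numeric(newdata)) newdata <- as.data.frame(as.list(newdata))
  missing_cols <- setdiff(fit$predictor_names, names(newdata))
  if (length(missing_cols) > 0L) {
    stop("newdata lacks predictor(s): ", paste(missing_cols, collapse = ", "))
  }
  X0 <- cbind(1, as.matrix(newdata[, fit$predictor_names, drop = FALSE]))
  p <- length(fit$predictor_names)
  df <- fit$n - p - 1L
  tq <- stats::qt(1 - (1 - level) / 2, df)
  half <- tq * fit$s * sqrt(rowSums((X0 %*% fit$xtx_inverse) * X0))
  point <- drop(X0 %*% fit$coefficients)
  out <- data.frame(point = point, lmci = point - half, umci = point + half,
                    width = 2 * half, level = level)
  if (!is.null(box)) out$in_domain <- check_domain(newdata, box)$overall
  rownames(out) <- rownames(newdata)
  out
}

#' Normal-probability-plot coordinates for standardized residuals
#'
#' Residuals are internally studentized (`r_i / (s * sqrt(1 - h_ii))` when a
#' `qppr_fit` is supplied; scaled by their standard deviation otherwise),
#' ranked, and paired with expected normal cumulative probabilities at the
#' Blom plotting positions `(i - 3/8) / (n + 1/4)`.
#'
#' @param residuals numeric vector of residuals, or a `qppr_fit`.
#' @return data.frame with `standardized` (sorted), `observed` (normal CDF of
#'   the standardized residual) and `expected` (plotting position).
#' @export
normality_plot_data <- function(residuals) {
  if (inherits(residuals, "qppr_fit")) {
    z <- stats::rstandard(residuals$model)
  } else {
    if (length(residuals) < 3L) stop("need at least 3 residuals")
    s <- stats::sd(residuals)
    if (s == 0) stop("zero-variance residuals")
    z <- (residuals - mean(residuals)) / s
  }
  z <- sort(unname(z))
  n <- length(z)
  data.frame(standardized = z,
             observed = stats::pnorm(z),
             expected = (seq_len(n) - 3 / 8) / (n + 1 / 4))
}

#' Fit the reference clearance QPPR
#'
#' Convenience wrapper: OLS of experimental log CL_intPL on
#' `log_pow + log_pbw + ip` over the calibration panel (the packaged model
#' used by all downstream PBPK workflows).
#'
#' @param records calibration records; defaults to [load_calibration_set()].
#' @return `qppr_fit`.
#' @export
fit_qppr <- function(records = load_calibration_set()) {
  fit_multilinear(records, "log_clint_pl_exp", c("log_pow", "log_pbw", "ip"))
}
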