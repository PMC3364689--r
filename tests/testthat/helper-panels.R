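# Shared fixtures: load each panel once per test run.
cal_panel <- load_calibration_set()
eval_panel <- load_evaluation_set()
qppr_cal_fit <- fit_qppr(cal_panel)

read_reference <- function(file) {
  utils::read.csv(test_path(file), comment.char = "#",
                  stringsAsFactors = FALSE)
}

# Independent brute-force LOO Q2: one literal refit per left-out record,
# fold-centred total sum of squares. Kept free of package internals so it
# can serve as the oracle for loo_q2().
brute_force_q2 <- function(dat, response, predictors) {
  fml <- stats::reformulate(predictors, response)
  y <- dat[[response]]
  press <- numeric(0)
  devs <- numeric(0)
  for (i in seq_len(nrow(dat))) {
    train <- dat[-i, , drop = FALSE]
    beta <- stats::coef(stats::lm(fml, data = train))
    x0 <- c(1, as.numeric(dat[i, predictors]))
    press <- c(press, (y[i] - sum(beta * x0))^2)
    devs <- c(devs, (y[i] - mean(train[[response]]))^2)
  }
  1 - sum(press) / sum(devs)
}
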