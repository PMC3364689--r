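#' Generate synthetic VOC-like chemical records
#'
#' Draws reproducible chemical records for property-based testing.
#' Descriptors (`log_pow`, `log_pbw`, `ip`) are uniform in the supplied
#' applicability box; the water:air PC is sampled log-uniformly over the
#' range spanned by the packaged panel, and the remaining partition
#' coefficients are derived self-consistently: `pba = pwa * 10^log_pbw` and
#' `p_pl_blood` from [phospholipid_blood_pc()]. Tissue:blood PCs and the
#' molecular weight are drawn from ranges representative of lipophilic
#' low-molecular-weight VOCs; `kf` is 0.
#'
#' With `response = "qppr"` a `log_clint_pl_exp` column is added, generated
#' from the packaged calibration QPPR coefficients plus Gaussian noise, for
#' parameter-recovery experiments.
#'
#' @param n number of records (>= 1).
#' @param seed integer seed; the generator restores the caller's RNG state.
#' @param domain a [domain_box()] with `log_pow`, `log_pbw` and `ip` ranges
#'   (default: [applicability_domain()]).
#' @param response `"none"` (default) or `"qppr"`.
#' @param sigma residual standard deviation for `response = "qppr"`
#'   (log10 units, default 0.3).
#' @return data.frame of validated chemical records.
#' @examples
#' syn <- generate_synthetic_chemicals(5, seed = 1)
#' identical(syn, generate_synthetic_chemicals(5, seed = 1))
#' @export
generate_synthetic_chemicals <- function(n, seed,
                                         domain = applicability_domain(),
                                         response = c("none", "qppr"),
                                         sigma = 0.3) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  n <- as.integer(n)
  response <- match.arg(response)
  stopifnot(inherits(domain, "domain_box"),
            all(c("log_pow", "log_pbw", "ip") %in% names(domain)))

  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  runif_in <- function(r) stats::runif(n, r[1], r[2])
  log_pow <- runif_in(domain$log_pow)
  log_pbw <- runif_in(domain$log_pbw)
  ip <- runif_in(domain$ip)
  # water:air PC spans ~5e-3 (ethylene-like) to ~35 (very soluble VOCs)
  pwa <- 10^stats::runif(n, -2.3, 1.55)
  pba <- pwa * 10^log_pbw
  poa <- 10^log_pow * pwa
  rec <- data.frame(
    name = sprintf("synthetic-voc-%03d", seq_len(n)),
    dataset = "calibration",
    log_pow = log_pow, log_pbw = log_pbw, ip = ip,
    pba = pba,
    p_liver_blood = stats::runif(n, 0.9, 7.1),
    p_rich_blood = stats::runif(n, 0.9, 7.1),
    p_poor_blood = stats::runif(n, 0.4, 3.5),
    p_fat_blood = stats::runif(n, 5, 160),
    p_pl_blood = phospholipid_blood_pc(poa, pwa, pba),
    mw = stats::runif(n, 28, 253),
    kf = 0,
    stringsAsFactors = FALSE
  )
  if (response == "qppr") {
    beta <- fit_qppr()$coefficients
    rec$log_clint_pl_exp <-
      beta[1] + beta["log_pow"] * log_pow + beta["log_pbw"] * log_pbw +
      beta["ip"] * ip + stats::rnorm(n, 0, sigma)
  }
  validate_chemical_records(rec, require_response = response == "qppr")
  rec
}
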