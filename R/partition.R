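#' Phospholipid:blood partition coefficient
#'
#' Computes the phospholipid:blood partition coefficient as the ratio of the
#' phospholipid:air PC (approximated by its n-octanol and water fractions,
#' 30% octanol-like and 70% water-like) to the blood:air PC:
#' \deqn{P_{plb} = \frac{0.3\,P_{oa} + 0.7\,P_{wa}}{P_{ba}}}
#'
#' @param poa n-octanol:air partition coefficient (dimensionless, > 0).
#' @param pwa water:air partition coefficient (inverse Henry constant at
#'   body temperature; dimensionless, > 0).
#' @param pba blood:air partition coefficient (dimensionless, > 0).
#' @return phospholipid:blood PC (dimensionless). Vectorized.
#' @examples
#' phospholipid_blood_pc(1, 1, 1)       # weights sum to 1
#' phospholipid_blood_pc(121.1, 1.24, 8.19)  # benzene, ~4.55
#' @export
phospholipid_blood_pc <- function(poa, pwa, pba) {
  if (any(!is.finite(poa) | poa <= 0)) stop("'poa' must be finite and > 0")
  if (any(!is.finite(pwa) | pwa <= 0)) stop("'pwa' must be finite and > 0")
  if (any(!is.finite(pba) | pba <= 0)) stop("'pba' must be finite and > 0")
  (0.3 * poa + 0.7 * pwa) / pba
}

#' Derive the full partition-coefficient set of a VOC
#'
#' The water:air PC is recovered from the blood:air and blood:water PCs
#' (`pwa = pba / pbw`) rather than re-predicted, so that the derived set is
#' exactly consistent with the tabulated inputs; the octanol:air PC follows as
#' `poa = pow * pwa`, and the phospholipid-referenced PCs from
#' [phospholipid_blood_pc()]. All logs are base 10.
#'
#' @param log_pow log10 n-octanol:water PC.
#' @param log_pbw log10 blood:water PC.
#' @param pba blood:air PC (> 0).
#' @return object of class `partition_set`: list with elements `pow`, `pwa`,
#'   `poa`, `pba`, `pbw`, `pplb` (phospholipid:blood) and `pplw`
#'   (phospholipid:water).
#' @examples
#' ps <- derive_partition_set(1.99, 0.820, 8.19)  # benzene
#' ps$pplb
#' @export
derive_partition_set <- function(log_pow, log_pbw, pba) {
  if (any(!is.finite(pba) | pba <= 0)) stop("'pba' must be finite and > 0")
  stopifnot(is.finite(log_pow), is.finite(log_pbw))
  pow <- 10^log_pow
  pbw <- 10^log_pbw
  pwa <- pba / pbw
  poa <- pow * pwa
  pplb <- phospholipid_blood_pc(poa, pwa, pba)
  structure(
    list(pow = pow, pwa = pwa, poa = poa, pba = pba, pbw = pbw,
         pplb = pplb, pplw = pplb * pbw),
    class = "partition_set"
  )
}

#' @export
print.partition_set <- function(x, ...) {
  cat("Partition set (dimensionless PCs)\n")
  for (nm in names(x)) cat(sprintf("  %-5s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Convert intrinsic clearance between phospholipid and blood reference
#'
#' Intrinsic clearance is Vmax/Km; referencing Km to the phospholipid
#' concentration multiplies it by the phospholipid:blood PC, so the
#' blood-referenced clearance is the phospholipid-referenced clearance times
#' `pplb`, and conversely.
#'
#' @param clint_pl intrinsic clearance, L phospholipid/h/kg^0.75 (> 0).
#' @param clint_blood intrinsic clearance, L blood/h/kg^0.75 (> 0).
#' @param pplb phospholipid:blood PC (> 0).
#' @return the converted clearance. Vectorized.
#' @export
clint_pl_to_blood <- function(clint_pl, pplb) {
  if (any(!is.finite(clint_pl) | clint_pl <= 0)) stop("'clint_pl' must be > 0")
  if (any(!is.finite(pplb) | pplb <= 0)) stop("'pplb' must be > 0")
  clint_pl * pplb
}

#' @rdname clint_pl_to_blood
#' @export
clint_blood_to_pl <- function(clint_blood, pplb) {
  if (any(!is.finite(clint_blood) | clint_blood <= 0)) stop("'clint_blood' must be > 0")
  if (any(!is.finite(pplb) | pplb <= 0)) stop("'pplb' must be > 0")
  clint_blood / pplb
}
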