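#' Chemical panels: fixtures, validation and name handling
#'
#' The package ships two literature-compiled panels of volatile organic
#' chemicals (VOCs): a 26-chemical calibration set used to fit the clearance
#' QPPR and an 11-chemical evaluation set used to score it. Each record
#' carries the QPPR descriptors (log Pow, log Pbw, ionization potential), the
#' experimental phospholipid-referenced intrinsic clearance, the partition
#' coefficients needed by the inhalation PBPK model, the molecular weight and
#' the first-order hepatic constant Kf.
#'
#' @name chemical-panels
NULL

# Columns every chemical table must carry, with the domain constraint each
# value has to satisfy.
.chem_numeric_cols <- c(
  "log_pow", "log_pbw", "ip", "pba",
  "p_liver_blood", "p_rich_blood", "p_poor_blood", "p_fat_blood",
  "p_pl_blood", "mw", "kf"
)

.read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "qpprpbpk", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Normalize a chemical name to its canonical slug
#'
#' Canonical names are lowercase and locant-prefixed
#' (`"1,1,2,2-tetrachloroethane"`, `"cis-1,2-dichloroethylene"`). Literature
#' tables often print the inverted ordering `"Dichloroethane (1,1-)"` or
#' `"Xylene (m-)"`; both orderings resolve to the same slug.
#'
#' @param x character vector of chemical names in either ordering.
#' @return character vector of canonical names.
#' @examples
#' canonical_chemical_name("Dichloroethane (1,1-)")
#' canonical_chemical_name("Xylene (m-)")
#' @export
canonical_chemical_name <- function(x) {
  out <- tolower(trimws(x))
  # inverted "name (locant-)" form: move the parenthesised locant up front
  inv <- regmatches(out, regexec("^([a-z0-9-]+) \\(([a-z0-9,-]+?)-?\\)$", out))
  flip <- vapply(inv, length, 1L) == 3L
  out[flip] <- vapply(inv[flip], function(m) paste0(m[3], "-", m[2]), "")
  out
}

#' Validate a table of chemical records
#'
#' Checks the schema used throughout the package: all required fields present,
#' partition coefficients strictly positive, Kf non-negative, descriptors
#' finite. Errors name the offending field and record.
#'
#' @param records data.frame of chemical records.
#' @param require_response require a finite `log_clint_pl_exp` column.
#' @return `records`, invisibly, if valid.
#' @export
validate_chemical_records <- function(records, require_response = TRUE) {
  stopifnot(is.data.frame(records))
  needed <- c("name", .chem_numeric_cols)
  if (require_response) needed <- c(needed, "log_clint_pl_exp")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("chemical table is missing field(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(records$name)) {
    stop("duplicated chemical name(s): ",
         paste(unique(records$name[duplicated(records$name)]), collapse = ", "))
  }
  for (col in intersect(needed, .chem_numeric_cols)) {
    v <- records[[col]]
    bad <- !is.finite(v)
    if (col %in% c("pba", "p_liver_blood", "p_rich_blood", "p_poor_blood",
                   "p_fat_blood", "p_pl_blood", "mw")) {
      bad <- bad | v <= 0
    }
    if (col == "kf") bad <- bad | v < 0
    if (any(bad)) {
      stop("invalid value in field '", col, "' for record(s): ",
           paste(records$name[bad], collapse = ", "))
    }
  }
  if (require_response && any(!is.finite(records$log_clint_pl_exp))) {
    stop("invalid value in field 'log_clint_pl_exp' for record(s): ",
         paste(records$name[!is.finite(records$log_clint_pl_exp)], collapse = ", "))
  }
  invisible(records)
}

.load_panel <- function(dataset = c("calibration", "evaluation", "all")) {
  dataset <- match.arg(dataset)
  pcs <- .read_fixture("partition_coefficients.csv")
  dsc <- .read_fixture("clearance_descriptors.csv")
  cst <- .read_fixture("chemical_constants.csv")
  tab <- merge(dsc, pcs[, setdiff(names(pcs), "dataset")], by = "name")
  tab <- merge(tab, cst, by = "name")
  if (dataset != "all") tab <- tab[tab$dataset == dataset, , drop = FALSE]
  # keep the published row order (descriptor fixture order)
  tab <- tab[order(match(tab$name, dsc$name)), , drop = FALSE]
  rownames(tab) <- NULL
  validate_chemical_records(tab)
  tab
}

#' Load the 26-chemical QPPR calibration panel
#'
#' @return data.frame with one row per VOC: `name`, `dataset`, descriptors
#'   `log_pow`, `log_pbw`, `ip` (eV), experimental `log_clint_pl_exp`
#'   (log10 L phospholipid/h/kg^0.75), blood:air PC `pba`, tissue:blood PCs
#'   (`p_liver_blood`, `p_rich_blood`, `p_poor_blood`, `p_fat_blood`),
#'   phospholipid:blood PC `p_pl_blood`, molecular weight `mw` (g/mol) and
#'   first-order hepatic constant `kf` (1/h).
#' @examples
#' cal <- load_calibration_set()
#' nrow(cal)
#' @export
load_calibration_set <- function() .load_panel("calibration")

#' Load the 11-chemical QPPR evaluation panel
#'
#' @return data.frame with the same columns as [load_calibration_set()].
#' @export
load_evaluation_set <- function() .load_panel("evaluation")

#' Load both panels at once
#'
#' @return data.frame of all 37 VOCs, calibration rows first.
#' @export
load_chemical_table <- function() .load_panel("all")

#' Look up a single chemical record by name
#'
#' @param name chemical name (any ordering accepted, see
#'   [canonical_chemical_name()]).
#' @return one-row data.frame.
#' @export
chemical_record <- function(name) {
  tab <- load_chemical_table()
  slug <- canonical_chemical_name(name)
  hit <- tab[tab$name == slug, , drop = FALSE]
  if (nrow(hit) != 1L) {
    stop("unknown chemical '", name, "' (canonical form '", slug,
         "'); names are matched after canonical_chemical_name() normalization")
  }
  hit
}

#' Write a chemical table to CSV
#'
#' Plain comma-separated export that round-trips through
#' [utils::read.csv()] to full stored precision; used by the fixture
#' round-trip tests and the CLI `fixtures dump` subcommand.
#'
#' @param records data.frame of chemical records.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chemical_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
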