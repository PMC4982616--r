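# Bioaccumulation factor and the tabular formats for BAF / grain records.

.treatments <- c("CK", "low", "high")

# Case-insensitive mapping onto the canonical treatment labels.
canonical_treatment <- function(x) {
  idx <- match(tolower(x), tolower(.treatments))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "),
         " (expected CK, low or high)", call. = FALSE)
  }
  .treatments[idx]
}

#' Bioaccumulation factor
#'
#' `BAF = C_grain / C_soil`: the dimensionless ratio of the Pb concentration
#' in dehulled wheat grain to the total Pb concentration in the soil it grew
#' in. Vectorized over both arguments.
#'
#' @param grain_pb Pb in grain, mg/kg, `>= 0`.
#' @param soil_pb Total Pb in soil, mg/kg, strictly `> 0`.
#' @return Numeric vector of BAFs.
#' @examples
#' compute_baf(0.35, 350)  # 0.001
#' @export
compute_baf <- function(grain_pb, soil_pb) {
  if (any(!is.finite(soil_pb)) || any(soil_pb <= 0)) {
    stop("soil_pb must be finite and > 0 (it is a divisor)", call. = FALSE)
  }
  if (any(!is.finite(grain_pb)) || any(grain_pb < 0)) {
    stop("grain_pb must be finite and >= 0", call. = FALSE)
  }
  grain_pb / soil_pb
}

#' Read and write BAF record tables
#'
#' A BAF table holds one row per (soil, cultivar, treatment) observation with
#' columns `soil_id`, `cultivar`, `treatment` (one of `CK`, `low`, `high`,
#' matched case-insensitively on read) and `baf` (dimensionless, `> 0` since
#' its log10 is taken downstream).
#'
#' @param path CSV path.
#' @return A validated tibble of BAF records.
#' @export
read_baf_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, col_types = readr::cols(
    soil_id = readr::col_character(),
    cultivar = readr::col_character(),
    treatment = readr::col_character(),
    baf = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(c("soil_id", "cultivar", "treatment", "baf"), names(tbl))
  if (length(missing)) {
    stop("BAF table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl$treatment <- canonical_treatment(tbl$treatment)
  bad <- which(!is.finite(tbl$baf) | tbl$baf <= 0)
  if (length(bad)) .fail_field(bad[1], "baf", tbl$baf[bad[1]], "BAF must be finite and > 0")
  tibble::as_tibble(tbl)
}

#' @rdname read_baf_table
#' @param records A BAF record tibble.
#' @export
write_baf_table <- function(records, path) {
  out <- records[, c("soil_id", "cultivar", "treatment", "baf")]
  out$treatment <- canonical_treatment(out$treatment)
  readr::write_csv(out, path, progress = FALSE)
  invisible(records)
}

#' Read and write grain measurement tables
#'
#' A grain table holds the raw pot-experiment measurements: columns
#' `soil_id`, `cultivar`, `treatment`, `grain_pb_mg_per_kg` (`>= 0`) and
#' `soil_pb_total_mg_per_kg` (`> 0`). [compute_baf()] on the two
#' concentration columns gives the corresponding BAF records.
#'
#' @param path CSV path.
#' @return A validated tibble with internal column names `grain_pb` and
#'   `soil_pb_total`.
#' @export
read_grain_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, col_types = readr::cols(
    soil_id = readr::col_character(),
    cultivar = readr::col_character(),
    treatment = readr::col_character(),
    grain_pb_mg_per_kg = readr::col_double(),
    soil_pb_total_mg_per_kg = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(c("soil_id", "cultivar", "treatment",
                       "grain_pb_mg_per_kg", "soil_pb_total_mg_per_kg"),
                     names(tbl))
  if (length(missing)) {
    stop("grain table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  names(tbl)[names(tbl) == "grain_pb_mg_per_kg"] <- "grain_pb"
  names(tbl)[names(tbl) == "soil_pb_total_mg_per_kg"] <- "soil_pb_total"
  tbl$treatment <- canonical_treatment(tbl$treatment)
  bad <- which(!is.finite(tbl$soil_pb_total) | tbl$soil_pb_total <= 0)
  if (length(bad)) {
    .fail_field(bad[1], "soil_pb_total", tbl$soil_pb_total[bad[1]],
                "total soil Pb must be finite and > 0")
  }
  bad <- which(!is.finite(tbl$grain_pb) | tbl$grain_pb < 0)
  if (length(bad)) {
    .fail_field(bad[1], "grain_pb", tbl$grain_pb[bad[1]],
                "grain Pb must be finite and >= 0")
  }
  tibble::as_tibble(tbl)
}

#' @rdname read_grain_table
#' @param measurements A grain measurement tibble.
#' @export
write_grain_table <- function(measurements, path) {
  out <- measurements[, c("soil_id", "cultivar", "treatment",
                          "grain_pb", "soil_pb_total")]
  names(out)[names(out) == "grain_pb"] <- "grain_pb_mg_per_kg"
  names(out)[names(out) == "soil_pb_total"] <- "soil_pb_total_mg_per_kg"
  out$treatment <- canonical_treatment(out$treatment)
  readr::write_csv(out, path, progress = FALSE)
  invisible(measurements)
}

# Left-join BAF records onto soils; every soil_id must resolve.
join_soils <- function(records, soils, allow_missing = FALSE) {
  unresolved <- setdiff(unique(records$soil_id), soils$soil_id)
  if (length(unresolved) && !allow_missing) {
    stop("soil_id(s) not present in soil table: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  dplyr::inner_join(records, soils, by = "soil_id")
}
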