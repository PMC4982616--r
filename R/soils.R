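# Soil tables: reading, validation, packaged reference panel.

# canonical CSV headers -> internal column names
.soil_col_map <- c(
  soil_id = "soil_id",
  location = "location",
  ph = "ph",
  oc = "oc_g_per_kg",
  cec = "cec_cmol_per_kg",
  clay = "clay_pct",
  background_pb = "background_pb_mg_per_kg"
)

.fail_field <- function(row, field, value, why) {
  stop(sprintf("invalid value for '%s' in row %d (%s): %s",
               field, row, format(value), why), call. = FALSE)
}

# Range checks shared by the reader and any constructor path. `tbl` uses
# internal names. Errors name the offending row and field.
validate_soils <- function(tbl) {
  num_fields <- c("ph", "oc", "cec", "clay", "background_pb")
  for (f in num_fields) {
    v <- tbl[[f]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      .fail_field(if (is.na(bad)) 1L else bad, f, v[bad], "non-numeric or missing")
    }
  }
  check <- function(field, ok, why) {
    bad <- which(!ok)
    if (length(bad)) .fail_field(bad[1], field, tbl[[field]][bad[1]], why)
  }
  check("ph", tbl$ph >= 0 & tbl$ph <= 14, "pH must lie in [0, 14]")
  check("oc", tbl$oc > 0, "organic carbon must be > 0 (its log is taken)")
  check("cec", tbl$cec >= 0, "CEC must be >= 0")
  check("clay", tbl$clay >= 0 & tbl$clay <= 100, "clay percent must lie in [0, 100]")
  check("background_pb", tbl$background_pb >= 0, "background Pb must be >= 0")
  if (anyDuplicated(tbl$soil_id)) {
    dup <- tbl$soil_id[duplicated(tbl$soil_id)][1]
    stop(sprintf("duplicate soil_id '%s' in soil table", dup), call. = FALSE)
  }
  invisible(tbl)
}

#' Read a soil property table
#'
#' Reads a CSV of soil physico-chemical properties. The file must carry the
#' header columns `soil_id`, `location`, `ph`, `oc_g_per_kg`,
#' `cec_cmol_per_kg`, `clay_pct`, `background_pb_mg_per_kg`; unknown extra
#' columns are preserved but ignored by every computation. Missing values are
#' errors, not NAs: the analysis assumes complete soil characterisation.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, `.` decimal).
#' @return A tibble with one row per soil and columns `soil_id` (character),
#'   `location`, `ph`, `oc` (g/kg), `cec` (cmol/kg), `clay` (percent) and
#'   `background_pb` (mg/kg), plus any extra input columns. Row order is
#'   preserved.
#' @seealso [reference_soils()] for the packaged 17-soil panel.
#' @examples
#' soils <- reference_soils()
#' tmp <- tempfile(fileext = ".csv")
#' write_soil_table(soils, tmp)
#' identical(read_soil_table(tmp), soils)
#' @export
read_soil_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(unname(.soil_col_map), names(raw))
  if (length(missing)) {
    stop("soil table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl <- raw
  names(tbl)[match(unname(.soil_col_map), names(tbl))] <- names(.soil_col_map)
  for (f in c("ph", "oc", "cec", "clay", "background_pb")) {
    v <- suppressWarnings(as.numeric(tbl[[f]]))
    bad <- which(is.na(v))
    if (length(bad)) .fail_field(bad[1], f, tbl[[f]][bad[1]], "non-numeric or missing")
    tbl[[f]] <- v
  }
  tbl$soil_id <- as.character(tbl$soil_id)
  tbl <- tbl[, c(names(.soil_col_map), setdiff(names(tbl), names(.soil_col_map)))]
  validate_soils(tbl)
  tibble::as_tibble(tbl)
}

#' Write a soil property table
#'
#' Inverse of [read_soil_table()]: writes the canonical unit-suffixed CSV
#' headers. Extra columns are carried along so read/write round-trips are
#' lossless.
#'
#' @param soils A soil tibble as returned by [read_soil_table()].
#' @param path Output CSV path.
#' @return `soils`, invisibly.
#' @export
write_soil_table <- function(soils, path) {
  out <- soils
  names(out)[match(names(.soil_col_map), names(out))] <- unname(.soil_col_map)
  readr::write_csv(out, path, progress = FALSE)
  invisible(soils)
}

#' The 17-soil reference panel
#'
#' The packaged panel of 17 Chinese agricultural soils spanning pH 4.9-8.8
#' and organic carbon 6.78-27.66 g/kg, on which the wheat pot experiment and
#' the fitted transfer models are based. Values are carried at their printed
#' precision.
#'
#' @return A tibble of 17 soil profiles (see [read_soil_table()] for columns).
#' @examples
#' soils <- reference_soils()
#' nrow(soils)   # 17
#' @export
reference_soils <- function() {
  path <- system.file("extdata", "soil_panel_17.csv", package = "wheatpb",
                      mustWork = TRUE)
  read_soil_table(path)
}
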