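# Normalization of BAFs to a reference soil scenario and the intra-species
# variability statistic.

#' Normalize BAFs to a reference soil scenario
#'
#' Transplants each observed BAF from its own soil to a common reference
#' scenario using the model's soil-property slopes:
#' `baf_norm = 10^(log10(baf) + a*(ph_ref - ph) + b*(log10(oc_ref) - log10(oc)))`.
#' This is the residual-preserving shift in log10 space — the unique map
#' that is the identity when the scenario equals the record's own soil and
#' removes exactly the soil-property terms of the transfer law. On data
#' generated exactly from those slopes, BAFs of one cultivar across any set
#' of soils collapse to a single value.
#'
#' @param records BAF record tibble (`soil_id`, `baf` required).
#' @param soils Soil tibble.
#' @param model A [transfer_model()] with slopes for `ph` and `log_oc`
#'   (only the slopes are used).
#' @param ph_ref Reference pH; default 7.0.
#' @param oc_ref Reference organic carbon, g/kg, `> 0`; default 15. The
#'   defaults sit mid-range of the pH 5-9, OC 5-25 g/kg window conventional
#'   for soil ecotoxicity normalization.
#' @return `records` with an added `baf_norm` column (strictly positive).
#' @export
normalize_baf <- function(records, soils, model, ph_ref = 7.0, oc_ref = 15) {
  stopifnot(inherits(model, "transfer_model"))
  .require_both_slopes(model)
  if (!is.numeric(oc_ref) || oc_ref <= 0) {
    stop("oc_ref must be > 0 (its log is taken)", call. = FALSE)
  }
  if (!is.numeric(ph_ref) || ph_ref < 0 || ph_ref > 14) {
    stop("ph_ref must lie in [0, 14]", call. = FALSE)
  }
  if (any(records$baf <= 0)) stop("all BAFs must be > 0", call. = FALSE)
  joined <- join_soils(records, soils)
  shift <- slope_ph(model) * (ph_ref - joined$ph) +
    slope_logoc(model) * (log10(oc_ref) - log10(joined$oc))
  out <- records
  out$baf_norm <- 10^(log10(records$baf) + shift)
  out
}

#' Intra-species variability statistic
#'
#' `f = sum_i (BAF_i - mean(BAF))^2 / ((n - 1) * mean(BAF)^2)`: the squared
#' coefficient of variation with the n-1 variance convention. Scale-free
#' (`f(c*x) = f(x)` for any `c > 0`), zero iff all inputs are equal.
#'
#' @param bafs Numeric vector of BAFs for one cultivar across `n >= 2` soil
#'   conditions; all `> 0`.
#' @return The dimensionless variability `f >= 0`.
#' @examples
#' intra_species_variability(c(0.001, 0.003))  # 0.5
#' @export
intra_species_variability <- function(bafs) {
  if (length(bafs) < 2) stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(bafs)) || any(bafs <= 0)) {
    stop("all BAFs must be finite and > 0", call. = FALSE)
  }
  m <- mean(bafs)
  if (m == 0) stop("mean BAF is 0", call. = FALSE)
  sum((bafs - m)^2) / ((length(bafs) - 1) * m^2)
}

#' Variability reduction from normalization
#'
#' For each cultivar, computes the intra-species variability of its raw BAFs
#' (`f_before`), of its normalized BAFs (`f_after`, via [normalize_baf()]),
#' and the reduction factor `f_before / f_after`. When normalization
#' collapses the BAFs exactly (`f_after = 0`, as on noise-free data) the
#' reduction factor is `Inf` and flagged via the `collapsed` column rather
#' than raised as an error.
#'
#' @inheritParams normalize_baf
#' @param records BAF record tibble with a `cultivar` column; cultivars with
#'   fewer than 2 records are skipped with a warning.
#' @return A tibble with one row per cultivar: `cultivar`, `n_conditions`,
#'   `f_before`, `f_after`, `reduction_factor`, `collapsed`.
#' @seealso [mean_reduction()] for the cross-cultivar average.
#' @export
variability_reduction <- function(records, soils, model,
                                  ph_ref = 7.0, oc_ref = 15) {
  if (!("cultivar" %in% names(records))) {
    stop("records must have a 'cultivar' column", call. = FALSE)
  }
  counts <- table(records$cultivar)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("cultivar(s) with fewer than 2 records skipped: ",
            paste(small, collapse = ", "), call. = FALSE)
    records <- records[!(records$cultivar %in% small), , drop = FALSE]
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(cultivar = character(), n_conditions = integer(),
                          f_before = double(), f_after = double(),
                          reduction_factor = double(), collapsed = logical()))
  }
  normed <- normalize_baf(records, soils, model, ph_ref, oc_ref)
  normed |>
    dplyr::group_by(.data$cultivar) |>
    dplyr::summarise(
      n_conditions = dplyr::n(),
      f_before = intra_species_variability(.data$baf),
      f_after = intra_species_variability(.data$baf_norm),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      # an f_after at rounding-noise level means the BAFs collapsed exactly
      collapsed = .data$f_after < 1e-20,
      reduction_factor = ifelse(.data$collapsed, Inf,
                                .data$f_before / .data$f_after)
    ) |>
    dplyr::select("cultivar", "n_conditions", "f_before", "f_after",
                  "reduction_factor", "collapsed")
}

#' Average variability reduction across cultivars
#'
#' Two conventions are offered for averaging per-cultivar reduction factors:
#' the arithmetic mean of the per-cultivar ratios `f_before / f_after`
#' (default) or the ratio of the mean `f_before` to the mean `f_after`.
#' Cultivars whose normalized BAFs collapsed exactly (`f_after = 0`) make
#' the mean infinite under the default convention.
#'
#' @param reduction A tibble from [variability_reduction()].
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return A single numeric reduction factor.
#' @export
mean_reduction <- function(reduction,
                           method = c("mean_of_ratios", "ratio_of_means")) {
  method <- match.arg(method)
  if (nrow(reduction) == 0) return(NA_real_)
  switch(method,
    mean_of_ratios = mean(reduction$reduction_factor),
    ratio_of_means = mean(reduction$f_before) / mean(reduction$f_after)
  )
}
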