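# Measured-vs-predicted validation: two-fold interval and R2.

#' Two-fold prediction interval check
#'
#' `TRUE` iff the measured/predicted ratio lies in `[0.5, 2]`, boundaries
#' inclusive — so the check is symmetric under swapping the two arguments.
#' Vectorized.
#'
#' @param measured,predicted Strictly positive BAFs.
#' @return Logical vector.
#' @examples
#' twofold_check(0.002, 0.001)   # TRUE (ratio exactly 2)
#' twofold_check(0.001, 0.0004)  # FALSE (ratio 2.5)
#' @export
twofold_check <- function(measured, predicted) {
  if (any(!is.finite(measured)) || any(measured <= 0) ||
      any(!is.finite(predicted)) || any(predicted <= 0)) {
    stop("measured and predicted BAFs must be finite and > 0", call. = FALSE)
  }
  ratio <- measured / predicted
  ratio >= 0.5 & ratio <= 2
}

#' Validate transfer-model predictions against measured BAFs
#'
#' Pairs each measured BAF with the prediction of its cultivar's model at
#' its soil and reports the fraction of pairs within the two-fold interval
#' and the R2 (squared Pearson correlation) between measured and predicted,
#' on the linear BAF scale (the headline figure) and on the log10 scale.
#' Records whose soil or cultivar cannot be resolved are excluded from the
#' statistics and listed in the report.
#'
#' @param records BAF record tibble with `soil_id`, `cultivar`, `baf`.
#' @param soils Soil tibble.
#' @param models Either a single [transfer_model()] applied to every record,
#'   or a named list of models keyed by cultivar.
#' @return An object of class `baf_validation`: use `glance()` for the
#'   summary row (`n`, `frac_within_twofold`, `r2_linear`, `r2_log10`),
#'   `tidy()` for the per-pair table, and `autoplot()` for the
#'   measured-vs-predicted scatter with the two-fold band.
#' @export
validate_transfer <- function(records, soils, models) {
  if (inherits(models, "transfer_model")) {
    model_for <- function(cv) models
    known <- unique(records$cultivar %||% "all")
  } else {
    stopifnot(is.list(models), !is.null(names(models)))
    model_for <- function(cv) models[[cv]]
    known <- names(models)
  }
  if (!("cultivar" %in% names(records))) records$cultivar <- "all"
  resolvable <- records$soil_id %in% soils$soil_id &
    (inherits(models, "transfer_model") | records$cultivar %in% known)
  excluded <- records[!resolvable, , drop = FALSE]
  kept <- records[resolvable, , drop = FALSE]
  if (nrow(kept) == 0) stop("no record resolves to both a soil and a model",
                            call. = FALSE)
  joined <- join_soils(kept, soils)
  joined$predicted <- purrr::map2_dbl(
    joined$cultivar, seq_len(nrow(joined)),
    function(cv, i) predict_baf(model_for(cv), joined[i, , drop = FALSE])
  )
  pairs <- tibble::tibble(
    soil_id = joined$soil_id,
    cultivar = joined$cultivar,
    treatment = joined$treatment %||% NA_character_,
    measured = joined$baf,
    predicted = joined$predicted,
    ratio = joined$baf / joined$predicted,
    within_twofold = twofold_check(joined$baf, joined$predicted)
  )
  r2_of <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    cor(x, y)^2
  }
  structure(
    list(
      pairs = pairs,
      n = nrow(pairs),
      frac_within_twofold = mean(pairs$within_twofold),
      r2_linear = r2_of(pairs$measured, pairs$predicted),
      r2_log10 = r2_of(log10(pairs$measured), log10(pairs$predicted)),
      excluded = excluded
    ),
    class = "baf_validation"
  )
}

#' @export
print.baf_validation <- function(x, ...) {
  cat("<baf_validation> ", x$n, " measured/predicted pairs\n",
      sprintf("  within 2-fold: %.1f%%\n", 100 * x$frac_within_twofold),
      sprintf("  R2 (linear): %.4g   R2 (log10): %.4g\n",
              x$r2_linear, x$r2_log10), sep = "")
  if (nrow(x$excluded)) {
    cat("  excluded (unresolved):", nrow(x$excluded), "record(s)\n")
  }
  invisible(x)
}

#' @method tidy baf_validation
#' @export
tidy.baf_validation <- function(x, ...) x$pairs

#' @method glance baf_validation
#' @export
glance.baf_validation <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    frac_within_twofold = x$frac_within_twofold,
    r2_linear = x$r2_linear,
    r2_log10 = x$r2_log10,
    n_excluded = nrow(x$excluded)
  )
}
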