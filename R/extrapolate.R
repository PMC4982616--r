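# Cross-cultivar extrapolation: slopes stay fixed, only the intrinsic
# sensitivity k is refit, minimizing squared error on the *linear* BAF scale
# (not log-scale OLS — the two differ in general, see the methods vignette).

# Linear-scale shape factors m_i = 10^(a*ph_i + b*log10(oc_i)).
.shape_factors <- function(records, soils, slope_ph, slope_logoc) {
  joined <- join_soils(records, soils)
  10^(slope_ph * joined$ph + slope_logoc * log10(joined$oc))
}

#' Refit only the intercept of a transfer model
#'
#' Holds the soil-property slopes fixed and finds the intrinsic sensitivity
#' `k` minimizing the linear-scale error sum of squares
#' `SSE(k) = sum_i (baf_i - 10^(a*ph_i + b*log10(oc_i) + k))^2`.
#' With `m_i = 10^(a*ph_i + b*log10(oc_i))` the objective is quadratic in
#' `t = 10^k`, so the minimizer is closed form:
#' `t* = sum(baf_i * m_i) / sum(m_i^2)`, `k = log10(t*)`.
#'
#' @param records BAF record tibble (all `baf > 0`), typically one cultivar
#'   and one treatment.
#' @param soils Soil tibble resolving every `soil_id`.
#' @param slope_ph,slope_logoc The fixed slopes `a` and `b` of the base
#'   model.
#' @return A one-row tibble with columns `intercept` (the fitted k), `sse`
#'   (achieved linear-scale SSE) and `n_obs`.
#' @examples
#' soils <- reference_soils()
#' two <- soils[soils$soil_id %in% c("5", "10"), ]
#' truth <- transfer_model(-0.121, -0.808, -1.74)
#' rec <- tibble::tibble(soil_id = two$soil_id,
#'                       baf = predict_baf(truth, two))
#' fit_intercept(rec, two, -0.121, -0.808)$intercept  # -1.74
#' @export
fit_intercept <- function(records, soils, slope_ph, slope_logoc) {
  if (nrow(records) == 0) stop("records must be non-empty", call. = FALSE)
  if (any(records$baf <= 0)) stop("all BAFs must be > 0", call. = FALSE)
  m <- .shape_factors(records, soils, slope_ph, slope_logoc)
  t_star <- sum(records$baf * m) / sum(m^2)
  k <- log10(t_star)
  tibble::tibble(
    intercept = k,
    sse = sum((records$baf - t_star * m)^2),
    n_obs = nrow(records)
  )
}

#' Grid-search oracle for the intercept fit
#'
#' Evaluates the same linear-scale SSE as [fit_intercept()] on a regular
#' grid of k values and returns the grid minimizer (ties broken toward the
#' smaller k). Retained as an independent check of the closed form: the two
#' agree within one grid step on every instance whose optimum lies inside
#' the grid.
#'
#' @inheritParams fit_intercept
#' @param k_lo,k_hi Grid bounds, `k_lo < k_hi`.
#' @param step Grid spacing, `> 0`.
#' @return A one-row tibble with `intercept` and `sse`.
#' @export
grid_intercept <- function(records, soils, slope_ph, slope_logoc,
                           k_lo = -5, k_hi = 0, step = 1e-4) {
  stopifnot(k_lo < k_hi, step > 0)
  if (nrow(records) == 0) stop("records must be non-empty", call. = FALSE)
  m <- .shape_factors(records, soils, slope_ph, slope_logoc)
  ks <- seq(k_lo, k_hi, by = step)
  sse <- vapply(ks, function(k) sum((records$baf - 10^k * m)^2), numeric(1))
  best <- which.min(sse)  # first minimum = smallest k on ties
  tibble::tibble(intercept = ks[best], sse = sse[best])
}

#' Extrapolate a transfer model to non-modeled cultivars
#'
#' For each cultivar in `records`, fits a cultivar-specific intrinsic
#' sensitivity via [fit_intercept()] while keeping the base model's slopes
#' bit-identical. The base model itself is never modified.
#'
#' @param base A fitted or transcribed [transfer_model()] with slopes for
#'   `ph` and `log_oc`.
#' @param records BAF record tibble with a `cultivar` column; each cultivar
#'   needs at least one record (cultivars present only as empty groups are
#'   skipped with a warning).
#' @param soils Soil tibble.
#' @return A tibble with one row per cultivar: `cultivar`, `intercept`,
#'   `sse`, `n_obs` and a list-column `model` holding the extrapolated
#'   [transfer_model()]s.
#' @export
extrapolate_models <- function(base, records, soils) {
  stopifnot(inherits(base, "transfer_model"))
  .require_both_slopes(base)
  a <- slope_ph(base)
  b <- slope_logoc(base)
  if (!("cultivar" %in% names(records))) {
    stop("records must have a 'cultivar' column", call. = FALSE)
  }
  empties <- if (is.factor(records$cultivar)) {
    setdiff(levels(records$cultivar), as.character(unique(records$cultivar)))
  } else character(0)
  if (length(empties)) {
    warning("cultivar(s) with zero records skipped: ",
            paste(empties, collapse = ", "), call. = FALSE)
  }
  out <- records |>
    dplyr::group_by(.data$cultivar) |>
    dplyr::group_modify(function(grp, key) {
      fit_intercept(grp, soils, a, b)
    }) |>
    dplyr::ungroup()
  out$model <- purrr::map2(out$cultivar, out$intercept, function(cv, k) {
    m <- transfer_model(coefficients = base$coefficients, intercept = k,
                        label = paste0(base$label,
                                       if (nzchar(base$label)) "/" else "",
                                       cv))
    m$n_obs <- sum(records$cultivar == cv)
    m
  })
  out
}
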