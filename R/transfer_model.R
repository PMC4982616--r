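# The log-linear transfer model: log10(BAF) = a*pH + b*log10(OC) + k.
# Represented as a small S3 object; slopes may in general cover any subset of
# the candidate soil predictors (ph, log_oc, cec, clay).

.candidate_predictors <- c("ph", "log_oc", "cec", "clay")

#' Construct a soil-to-grain transfer model
#'
#' Builds the log-linear model `log10(BAF) = a * pH + b * log10(OC) + k`
#' directly from coefficients, e.g. when transcribing a published model.
#' Fitted models are produced by [fit_transfer_model()] and
#' [stepwise_transfer_model()]; extrapolated ones by [extrapolate_models()].
#'
#' @param slope_ph Coefficient `a` on soil pH, or `NULL` if pH is not a
#'   predictor.
#' @param slope_logoc Coefficient `b` on log10(organic carbon), or `NULL`.
#' @param intercept Intercept `k`, the cultivar's intrinsic sensitivity.
#' @param label Free-text label (e.g. `"model1-lowPb"`).
#' @param r2 Coefficient of determination of the fit on the log10 scale,
#'   `NULL` for transcribed or extrapolated models.
#' @param n_obs Number of observations fitted, or `NULL`.
#' @param coefficients Alternative to `slope_ph`/`slope_logoc`: a named
#'   numeric vector of slopes over any subset of `ph`, `log_oc`, `cec`,
#'   `clay`.
#' @return An object of class `transfer_model`.
#' @examples
#' m1 <- transfer_model(-0.121, -0.808, -1.399, label = "low-Pb")
#' predict_baf(m1, reference_soils())
#' @export
transfer_model <- function(slope_ph = NULL, slope_logoc = NULL, intercept,
                           label = "", r2 = NULL, n_obs = NULL,
                           coefficients = NULL) {
  if (is.null(coefficients)) {
    coefficients <- c(
      if (!is.null(slope_ph)) c(ph = as.numeric(slope_ph)),
      if (!is.null(slope_logoc)) c(log_oc = as.numeric(slope_logoc))
    )
    if (is.null(coefficients)) coefficients <- setNames(numeric(0), character(0))
  }
  stopifnot(is.numeric(coefficients))
  unknown <- setdiff(names(coefficients), .candidate_predictors)
  if (length(unknown)) {
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept)) {
    stop("intercept must be a single finite number", call. = FALSE)
  }
  structure(
    list(
      coefficients = coefficients,
      intercept = as.numeric(intercept),
      predictors = names(coefficients),
      label = as.character(label),
      r2 = if (is.null(r2)) NULL else as.numeric(r2),
      n_obs = if (is.null(n_obs)) NULL else as.integer(n_obs),
      diagnostics = NULL
    ),
    class = "transfer_model"
  )
}

#' @export
print.transfer_model <- function(x, ...) {
  terms <- character(0)
  if ("ph" %in% names(x$coefficients)) {
    terms <- c(terms, sprintf("%+.4g pH", x$coefficients[["ph"]]))
  }
  if ("log_oc" %in% names(x$coefficients)) {
    terms <- c(terms, sprintf("%+.4g log10(OC)", x$coefficients[["log_oc"]]))
  }
  for (p in setdiff(names(x$coefficients), c("ph", "log_oc"))) {
    terms <- c(terms, sprintf("%+.4g %s", x$coefficients[[p]], p))
  }
  eq <- paste(c(terms, sprintf("%+.4g", x$intercept)), collapse = " ")
  cat("<transfer_model", if (nzchar(x$label)) paste0(" '", x$label, "'"), ">\n",
      "  log10(BAF) = ", sub("^\\+", "", eq), "\n", sep = "")
  if (!is.null(x$r2)) cat(sprintf("  R2 = %.4g (log10 scale), n = %s\n",
                                  x$r2, x$n_obs %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

slope_ph <- function(model) model$coefficients[["ph"]]
slope_logoc <- function(model) model$coefficients[["log_oc"]]

# Both published-slope accessors error clearly if the model dropped the term.
.require_both_slopes <- function(model) {
  missing <- setdiff(c("ph", "log_oc"), names(model$coefficients))
  if (length(missing)) {
    stop("model has no slope for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(model)
}

# Design matrix columns for a set of predictor names, from a soil table.
predictor_matrix <- function(soils, predictors) {
  cols <- lapply(predictors, function(p) {
    switch(p,
      ph = soils$ph,
      log_oc = log10(soils$oc),
      cec = soils$cec,
      clay = soils$clay,
      stop("unknown predictor: ", p, call. = FALSE)
    )
  })
  m <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (is.null(m)) m <- matrix(numeric(0), nrow = nrow(soils), ncol = 0)
  colnames(m) <- predictors
  m
}

#' Predict BAF from a transfer model
#'
#' Evaluates `10^(a*pH + b*log10(OC) + k)` (and any further retained slopes)
#' for each soil. Strictly positive by construction, and strictly decreasing
#' in pH and OC when both slopes are negative, as in the fitted wheat models.
#'
#' @param model A [transfer_model()].
#' @param soils A soil tibble ([read_soil_table()]); only the model's
#'   predictor columns are used.
#' @return Numeric vector of predicted dimensionless BAFs, one per soil row.
#' @export
predict_baf <- function(model, soils) {
  stopifnot(inherits(model, "transfer_model"))
  if (any(soils$oc <= 0)) stop("organic carbon must be > 0", call. = FALSE)
  10^predict_log_baf(model, soils)
}

predict_log_baf <- function(model, soils) {
  x <- predictor_matrix(soils, model$predictors)
  drop(x %*% model$coefficients) + model$intercept
}

#' Published transfer models for cultivar Xiaoyan 22
#'
#' The two reported log-linear Pb transfer models fitted on the 17-soil
#' reference panel for cultivar Xiaoyan 22: the low-Pb treatment model
#' (`log10 BAF = -0.121 pH - 0.808 log10 OC - 1.399`, R2 = 0.69) and the
#' high-Pb model (`log10 BAF = -0.151 pH - 0.740 log10 OC - 1.194`,
#' R2 = 0.80). Useful as generative truth for simulations and as the base
#' model for cross-cultivar extrapolation.
#'
#' @return A named list with elements `low` and `high`, each a
#'   [transfer_model()].
#' @examples
#' xiaoyan22_models()$low
#' @export
xiaoyan22_models <- function() {
  list(
    low = transfer_model(-0.121, -0.808, -1.399, label = "model1-lowPb",
                         r2 = 0.69, n_obs = 17),
    high = transfer_model(-0.151, -0.740, -1.194, label = "model2-highPb",
                          r2 = 0.80, n_obs = 17)
  )
}

#' Serialize / deserialize a transfer model
#'
#' Models round-trip through JSON at full double precision: every field of
#' `read_model(write_model(m, path))` equals the original exactly.
#'
#' @param model A [transfer_model()].
#' @param path JSON file path.
#' @return `write_model` returns `model` invisibly; `read_model` returns the
#'   reconstructed [transfer_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "transfer_model"))
  payload <- list(
    type = "transfer_model",
    predictors = model$predictors,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    label = model$label,
    r2 = model$r2,
    n_obs = model$n_obs
  )
  # I(17) = 17 significant digits: exact round-trip for IEEE doubles
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(model)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) stop("malformed model file: ", path,
                                               " (", conditionMessage(e), ")",
                                               call. = FALSE))
  needed <- c("type", "predictors", "coefficients", "intercept", "label")
  if (!is.list(payload) || !all(needed %in% names(payload)) ||
      !identical(payload$type, "transfer_model")) {
    stop("malformed model file: ", path, call. = FALSE)
  }
  coefs <- unlist(payload$coefficients)
  if (is.null(coefs)) coefs <- setNames(numeric(0), character(0))
  preds <- as.character(unlist(payload$predictors))
  transfer_model(
    coefficients = coefs[preds],
    intercept = payload$intercept,
    label = payload$label %||% "",
    r2 = payload$r2,
    n_obs = payload$n_obs
  )
}

#' @method tidy transfer_model
#' @export
tidy.transfer_model <- function(x, ...) {
  if (!is.null(x$diagnostics)) return(x$diagnostics)
  tibble::tibble(
    term = c(x$predictors, "(Intercept)"),
    estimate = c(unname(x$coefficients), x$intercept),
    std.error = NA_real_,
    statistic = NA_real_,
    p.value = NA_real_
  )
}

#' @method glance transfer_model
#' @export
glance.transfer_model <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    r.squared = x$r2 %||% NA_real_,
    rss = attr(x, "rss") %||% NA_real_,
    n_obs = x$n_obs %||% NA_integer_,
    n_predictors = length(x$predictors)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
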