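# OLS fitting of the log-linear transfer model and stepwise predictor
# selection by partial-F tests.

.zero_rss_tol <- 1e-12  # log10-scale RSS below this is treated as exact fit

# Assemble the per-record modelling frame: log10(baf) + predictor columns.
fitting_frame <- function(records, soils, predictors) {
  if (any(records$baf <= 0)) stop("all BAFs must be > 0 (log10 is taken)",
                                  call. = FALSE)
  joined <- join_soils(records, soils)
  x <- predictor_matrix(joined, predictors)
  data.frame(log_baf = log10(joined$baf), x, check.names = FALSE)
}

#' Fit the log-linear transfer model by OLS
#'
#' Ordinary least squares of `log10(BAF)` on the named soil predictors plus
#' an intercept; coefficients minimize the residual sum of squares on the
#' log10 scale, and R2 is reported on that scale. Candidate predictors are
#' `ph` (raw), `log_oc` (log10 of organic carbon), `cec` and `clay` (raw).
#'
#' @param records BAF record tibble (`soil_id`, `baf` required; typically one
#'   treatment at a time — treatments are never pooled implicitly).
#' @param soils Soil tibble resolving every `soil_id`.
#' @param predictors Ordered character vector of predictor names.
#' @param label Label stored on the fitted model.
#' @return A [transfer_model()] carrying fit diagnostics: `tidy()` gives the
#'   per-term coefficient table (estimate, std.error, statistic, p.value),
#'   `glance()` the R2, RSS and sizes.
#' @examples
#' soils <- reference_soils()
#' sim <- simulate_pot_experiment(soils, xiaoyan22_models()$low,
#'                                c(Xiaoyan22 = -1.399), sigma = 0)
#' fit <- fit_transfer_model(dplyr::filter(sim, treatment == "low"), soils)
#' tidy(fit)
#' @export
fit_transfer_model <- function(records, soils, predictors = c("ph", "log_oc"),
                               label = "") {
  if (length(predictors) == 0) stop("predictors must be non-empty", call. = FALSE)
  if (nrow(records) < length(predictors) + 2) {
    stop("need at least ", length(predictors) + 2, " records to fit ",
         length(predictors), " predictor(s)", call. = FALSE)
  }
  frame <- fitting_frame(records, soils, predictors)
  fit <- lm(log_baf ~ ., data = frame)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design: predictor(s) ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         " are collinear or constant", call. = FALSE)
  }
  # summary.lm warns on zero-residual fits; those are legitimate here
  s <- suppressWarnings(summary(fit))
  ct <- s$coefficients
  est <- coef(fit)
  ord <- c(predictors, "(Intercept)")
  rown <- ifelse(rownames(ct) == "(Intercept)", "(Intercept)",
                 sub("^`|`$", "", rownames(ct)))
  diag_tbl <- tibble::tibble(
    term = rown,
    estimate = ct[, "Estimate"],
    std.error = ct[, "Std. Error"],
    statistic = ct[, "t value"],
    p.value = ct[, "Pr(>|t|)"]
  )
  diag_tbl <- diag_tbl[match(ord, diag_tbl$term), ]
  model <- transfer_model(
    coefficients = setNames(unname(est[-1]), predictors)[predictors],
    intercept = unname(est[1]),
    label = label,
    r2 = s$r.squared,
    n_obs = nrow(frame)
  )
  model$diagnostics <- diag_tbl
  attr(model, "rss") <- sum(fit$residuals^2)
  model
}

# Partial-F p-value for adding `candidate` to the model with `current`
# predictors. Degenerate cases (zero-residual fits) follow a fixed
# convention: if the current fit is already exact no candidate can improve
# it (p = 1); if the augmented fit becomes exact the candidate's p is 0.
.enter_p_value <- function(frame_all, current, candidate) {
  f0 <- lm(log_baf ~ ., data = frame_all[, c("log_baf", current), drop = FALSE])
  f1 <- lm(log_baf ~ ., data = frame_all[, c("log_baf", current, candidate),
                                         drop = FALSE])
  if (anyNA(coef(f1))) return(list(p = 1, coef = 0))
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  df1 <- f1$df.residual
  cand_coef <- coef(f1)[[length(coef(f1))]]
  if (rss0 < .zero_rss_tol) return(list(p = 1, coef = cand_coef))
  if (rss1 < .zero_rss_tol || df1 == 0) {
    return(list(p = if (rss1 < .zero_rss_tol) 0 else 1, coef = cand_coef))
  }
  fstat <- ((rss0 - rss1) / 1) / (rss1 / df1)
  list(p = pf(fstat, 1, df1, lower.tail = FALSE), coef = cand_coef)
}

.remove_p_value <- function(frame_all, current, term) {
  keep <- setdiff(current, term)
  f0 <- lm(log_baf ~ ., data = frame_all[, c("log_baf", keep), drop = FALSE])
  f1 <- lm(log_baf ~ ., data = frame_all[, c("log_baf", current), drop = FALSE])
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  df1 <- f1$df.residual
  if (rss1 < .zero_rss_tol) {
    return(if (rss0 < .zero_rss_tol) 1 else 0)
  }
  fstat <- ((rss0 - rss1) / 1) / (rss1 / df1)
  pf(fstat, 1, df1, lower.tail = FALSE)
}

#' Stepwise selection of soil predictors
#'
#' Forward selection with backward elimination on partial-F p-values:
#' at each step the candidate with the smallest entry p-value joins if it is
#' below `alpha_enter` (ties broken by position in the caller's candidate
#' order, or by coefficient magnitude when an exact fit drives the p-values
#' to zero), then any retained term whose removal p-value exceeds
#' `alpha_remove` is dropped. The final model is refit by
#' [fit_transfer_model()] over the retained predictors.
#'
#' @inheritParams fit_transfer_model
#' @param candidates Ordered candidate predictor names, a subset of
#'   `c("ph", "log_oc", "cec", "clay")`.
#' @param alpha_enter P-value threshold to enter; default 0.05.
#' @param alpha_remove Threshold to stay; default 0.10. Must be
#'   `>= alpha_enter`.
#' @return A [transfer_model()] over the retained predictors. If no candidate
#'   reaches `alpha_enter`, an intercept-only model is returned with a
#'   warning and `attr(model, "status") == "intercept-only"`.
#' @export
stepwise_transfer_model <- function(records, soils,
                                    candidates = c("ph", "log_oc", "cec", "clay"),
                                    alpha_enter = 0.05, alpha_remove = 0.10,
                                    label = "") {
  stopifnot(alpha_enter <= alpha_remove)
  unknown <- setdiff(candidates, .candidate_predictors)
  if (length(unknown)) stop("unknown candidate(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  frame <- fitting_frame(records, soils, candidates)
  current <- character(0)
  repeat {
    changed <- FALSE
    remaining <- setdiff(candidates, current)
    if (length(remaining)) {
      trials <- lapply(remaining, function(cand)
        .enter_p_value(frame, current, cand))
      p <- vapply(trials, `[[`, numeric(1), "p")
      best_p <- min(p)
      if (best_p < alpha_enter) {
        tied <- which(p == best_p)
        pick <- if (best_p == 0 && length(tied) > 1) {
          mags <- abs(vapply(trials[tied], `[[`, numeric(1), "coef"))
          tied[which.max(mags)]
        } else {
          tied[1]  # first in the caller's candidate order
        }
        current <- c(current, remaining[pick])
        changed <- TRUE
      }
    }
    if (length(current) > 1) {
      p_out <- vapply(current, function(term)
        .remove_p_value(frame, current, term), numeric(1))
      worst <- which.max(p_out)
      if (p_out[worst] > alpha_remove) {
        current <- current[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(current) == 0) {
    warning("no candidate reached alpha_enter = ", alpha_enter,
            "; returning intercept-only model", call. = FALSE)
    mean_log <- mean(frame$log_baf)
    model <- transfer_model(coefficients = setNames(numeric(0), character(0)),
                            intercept = mean_log, label = label,
                            r2 = 0, n_obs = nrow(frame))
    attr(model, "status") <- "intercept-only"
    return(model)
  }
  current <- candidates[candidates %in% current]  # stable candidate order
  fit_transfer_model(records, soils, predictors = current, label = label)
}
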