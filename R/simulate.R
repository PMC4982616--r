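# Pot-experiment simulator: pH-class dependent Pb dosing and BAFs generated
# from the log-linear transfer law with multiplicative lognormal noise.

#' Pb dose for a soil and treatment level
#'
#' The spiking schedule of the pot experiment: no Pb for the control (CK);
#' for the low treatment 125, 150 or 175 mg/kg added to acidic (pH < 6.5),
#' neutral (6.5 <= pH <= 7.5) or alkaline (pH > 7.5) soils respectively; for
#' the high treatment 250, 300 or 350 mg/kg by the same classes. The class
#' boundaries 6.5 and 7.5 belong to the neutral class. Vectorized over `ph`
#' and `level` (recycled against each other).
#'
#' @param ph Soil pH in `[0, 14]`.
#' @param level Treatment level, one of `"CK"`, `"low"`, `"high"`
#'   (case-insensitive).
#' @return Added Pb in mg/kg.
#' @examples
#' assign_dose(4.9, "low")    # 125
#' assign_dose(6.93, "high")  # 300
#' assign_dose(8.8, "CK")     # 0
#' @export
assign_dose <- function(ph, level) {
  if (any(!is.finite(ph)) || any(ph < 0 | ph > 14)) {
    stop("ph must lie in [0, 14]", call. = FALSE)
  }
  level <- canonical_treatment(level)
  # class index: 1 acidic, 2 neutral, 3 alkaline
  cls <- ifelse(ph < 6.5, 1L, ifelse(ph <= 7.5, 2L, 3L))
  schedule <- rbind(CK = c(0, 0, 0), low = c(125, 150, 175),
                    high = c(250, 300, 350))
  n <- max(length(ph), length(level))
  schedule[cbind(match(rep_len(level, n), rownames(schedule)),
                 rep_len(cls, n))]
}

#' Nominal total soil Pb after spiking
#'
#' Background plus added Pb, assuming no losses over the equilibration
#' period (the simulator has no measurement step).
#'
#' @param background_pb Background soil Pb, mg/kg, `>= 0`.
#' @param added Added (spiked) Pb, mg/kg, `>= 0`.
#' @return Total soil Pb, mg/kg.
#' @export
total_soil_pb <- function(background_pb, added) {
  if (any(!is.finite(added)) || any(added < 0)) {
    stop("added Pb must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(background_pb)) || any(background_pb < 0)) {
    stop("background Pb must be finite and >= 0", call. = FALSE)
  }
  background_pb + added
}

#' Generate BAFs from a transfer model
#'
#' Draws one BAF per soil row from the generative law
#' `BAF = 10^(a*pH + b*log10(OC) + k + e)`, `e ~ Normal(0, sigma)`: additive
#' Gaussian noise on the log10 scale, i.e. multiplicative lognormal noise on
#' the BAF. With `sigma = 0` the result is the deterministic model
#' prediction. Results are always strictly positive.
#'
#' @param soils Soil tibble.
#' @param model A [transfer_model()].
#' @param sigma Standard deviation of the noise on log10(BAF), `>= 0`.
#' @param seed Integer seed; mandatory when `sigma > 0` (randomness is always
#'   explicitly seeded, never taken from the global stream).
#' @return Numeric vector of BAFs, one per soil row.
#' @examples
#' simulate_baf(reference_soils(), xiaoyan22_models()$low, sigma = 0)
#' @export
simulate_baf <- function(soils, model, sigma = 0, seed = NULL) {
  stopifnot(inherits(model, "transfer_model"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("sigma must be a single number >= 0", call. = FALSE)
  }
  mu <- predict_log_baf(model, soils)
  if (sigma == 0) return(10^mu)
  if (is.null(seed)) stop("seed is mandatory when sigma > 0", call. = FALSE)
  eps <- withr::with_seed(as.integer(seed), rnorm(length(mu), 0, sigma))
  10^(mu + eps)
}

#' Simulate a full pot experiment
#'
#' Generates the complete (soil x cultivar x treatment) design: each cultivar
#' shares the base model's soil-property slopes but has its own intrinsic
#' sensitivity (intercept), the treatment sets the Pb dose via
#' [assign_dose()], total soil Pb is background plus dose, the BAF comes
#' from the log-linear law with lognormal noise, and the grain concentration
#' is back-calculated as `grain_pb = baf * soil_pb_total` — so recomputing
#' [compute_baf()] on the output reproduces the generated BAFs exactly.
#'
#' @param soils Soil tibble.
#' @param base_model A [transfer_model()] supplying the slopes.
#' @param cultivar_intercepts Named numeric vector, cultivar name -> k.
#' @param sigma Noise s.d. on log10(BAF); default 0.1 gives fits with R2 in
#'   the range observed for real wheat data (about 0.7-0.8) on the 17-soil
#'   panel.
#' @param seed Integer seed; mandatory when `sigma > 0`.
#' @param treatments Subset of `c("CK", "low", "high")` to simulate.
#' @return A tibble with columns `soil_id`, `cultivar`, `treatment`,
#'   `dose_pb`, `soil_pb_total`, `grain_pb` and `baf`. Use
#'   [write_baf_table()] / [write_grain_table()] for the two standard CSV
#'   projections.
#' @examples
#' sim <- simulate_pot_experiment(reference_soils(), xiaoyan22_models()$low,
#'                                c(Xiaoyan22 = -1.399), sigma = 0)
#' nrow(sim)  # 17 soils x 1 cultivar x 3 treatments = 51
#' @export
simulate_pot_experiment <- function(soils, base_model, cultivar_intercepts,
                                    sigma = 0.1, seed = NULL,
                                    treatments = c("CK", "low", "high")) {
  stopifnot(nrow(soils) > 0)
  if (length(cultivar_intercepts) == 0 || is.null(names(cultivar_intercepts)) ||
      any(!nzchar(names(cultivar_intercepts)))) {
    stop("cultivar_intercepts must be a non-empty named numeric vector",
         call. = FALSE)
  }
  treatments <- canonical_treatment(treatments)
  design <- tidyr::expand_grid(
    cultivar = names(cultivar_intercepts),
    treatment = treatments,
    soil_id = soils$soil_id
  )
  design <- join_soils(design, soils)
  design$dose_pb <- assign_dose(design$ph, design$treatment)
  design$soil_pb_total <- total_soil_pb(design$background_pb, design$dose_pb)
  k <- cultivar_intercepts[design$cultivar]
  slopes <- base_model$coefficients
  mu <- drop(predictor_matrix(design, names(slopes)) %*% slopes) + k
  if (sigma > 0) {
    if (is.null(seed)) stop("seed is mandatory when sigma > 0", call. = FALSE)
    eps <- withr::with_seed(as.integer(seed), rnorm(nrow(design), 0, sigma))
  } else {
    eps <- 0
  }
  design$grain_pb <- 10^(mu + eps) * design$soil_pb_total
  # store the quotient so recomputing BAF from the grain table is bit-exact
  design$baf <- design$grain_pb / design$soil_pb_total
  design[, c("soil_id", "cultivar", "treatment", "dose_pb",
             "soil_pb_total", "grain_pb", "baf")]
}
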