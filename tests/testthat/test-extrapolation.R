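test_that("a single record pins the intercept exactly", {
  s <- ref_soils[3, ]
  m1 <- 10^(-0.121 * s$ph - 0.808 * log10(s$oc))
  rec <- tibble::tibble(soil_id = s$soil_id, baf = m1 * 10^-1.5)
  fit <- fit_intercept(rec, s, -0.121, -0.808)
  expect_equal(fit$intercept, -1.5, tolerance = 1e-12)
  expect_equal(fit$sse, 0, tolerance = 1e-30)
})

test_that("noise-free two-soil records recover the generating intercept to 1e-10", {
  for (trt in c("low", "high")) {
    base <- models_xy22[[if (trt == "low") "low" else "high"]]
    for (k in unique(published_sensitivities[[trt]])) {
      truth <- transfer_model(coefficients = base$coefficients, intercept = k)
      rec <- tibble::tibble(soil_id = extrap_soils$soil_id,
                            baf = predict_baf(truth, extrap_soils))
      fit <- fit_intercept(rec, extrap_soils,
                           slope_ph = base$coefficients[["ph"]],
                           slope_logoc = base$coefficients[["log_oc"]])
      expect_equal(fit$intercept, k, tolerance = 1e-10)
    }
  }
})

test_that("the closed form matches the grid oracle within one grid step", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    soils <- ref_soils[sample(17, n), ]
    a <- runif(1, -0.3, 0); b <- runif(1, -1.2, 0)
    baf <- 10^(a * soils$ph + b * log10(soils$oc) +
                 runif(1, -3, -0.5) + rnorm(n, 0, 0.15))
    rec <- tibble::tibble(soil_id = soils$soil_id, baf = baf)
    closed <- fit_intercept(rec, soils, a, b)
    grid <- grid_intercept(rec, soils, a, b, k_lo = -5, k_hi = 0, step = 1e-4)
    expect_lt(abs(closed$intercept - grid$intercept), 1e-4 + 1e-9)
    # the closed form attains an SSE no worse than the best grid point
    expect_lte(closed$sse, grid$sse + 1e-18)
  }
})

test_that("grid minimizer is locally optimal and tightens with the step", {
  soils <- ref_soils[c(2, 8, 14), ]
  rec <- tibble::tibble(soil_id = soils$soil_id, baf = c(1.1e-3, 6e-4, 4.2e-4))
  sse_at <- function(k) {
    m <- 10^(-0.121 * soils$ph - 0.808 * log10(soils$oc))
    sum((rec$baf - 10^k * m)^2)
  }
  g <- grid_intercept(rec, soils, -0.121, -0.808, step = 1e-3)
  expect_lte(g$sse, sse_at(g$intercept + 1e-3))
  expect_lte(g$sse, sse_at(g$intercept - 1e-3))
  closed <- fit_intercept(rec, soils, -0.121, -0.808)
  coarse <- grid_intercept(rec, soils, -0.121, -0.808, step = 2e-3)
  fine <- grid_intercept(rec, soils, -0.121, -0.808, step = 1e-3)
  expect_lte(abs(fine$intercept - closed$intercept),
             abs(coarse$intercept - closed$intercept) + 1e-3)
})

test_that("intercept fit is equivariant under scaling all BAFs", {
  soils <- ref_soils[c(1, 6, 11, 16), ]
  rec <- tibble::tibble(soil_id = soils$soil_id,
                        baf = c(1.5e-3, 9e-4, 5e-4, 3e-4))
  k0 <- fit_intercept(rec, soils, -0.121, -0.808)$intercept
  k10 <- fit_intercept(dplyr::mutate(rec, baf = baf * 10),
                       soils, -0.121, -0.808)$intercept
  expect_equal(k10, k0 + 1, tolerance = 1e-12)
})

test_that("linear-scale intercept fit differs from log-scale OLS refit", {
  # deliberately heteroscedastic on the linear scale: the linear-SSE fit
  # weights large BAFs more than log-scale OLS does
  soils <- ref_soils[c(1, 10), ]  # acidic vs alkaline -> very different m_i
  m <- 10^(-0.121 * soils$ph - 0.808 * log10(soils$oc))
  baf <- m * 10^c(-1.2, -1.9)  # soil-dependent log-residuals
  rec <- tibble::tibble(soil_id = soils$soil_id, baf = baf)
  k_linear <- fit_intercept(rec, soils, -0.121, -0.808)$intercept
  k_log <- mean(log10(baf) - log10(m))  # OLS intercept on the log10 scale
  expect_gt(abs(k_linear - k_log), 0.05)
})

test_that("extrapolation keeps base slopes bit-identical and recovers each k", {
  base <- models_xy22$low
  truth_ks <- published_sensitivities$low
  records <- purrr::imap_dfr(truth_ks, function(k, cv) {
    tibble::tibble(
      soil_id = extrap_soils$soil_id,
      cultivar = cv,
      treatment = "low",
      baf = predict_baf(
        transfer_model(coefficients = base$coefficients, intercept = k),
        extrap_soils)
    )
  })
  res <- extrapolate_models(base, records, ref_soils)
  expect_equal(nrow(res), 6)
  got <- setNames(res$intercept, res$cultivar)[names(truth_ks)]
  expect_equal(got, truth_ks, tolerance = 1e-10)
  # the recovered intercepts span the reported low-Pb range
  expect_equal(range(res$intercept), c(-1.74, -1.51), tolerance = 1e-10)
  for (m in res$model) {
    expect_identical(m$coefficients, base$coefficients)  # slope immutability
  }
  # base model object untouched
  expect_equal(base$intercept, -1.399)

  # a cultivar generated from the base model returns the base intercept
  rec0 <- noisefree_records(base, extrap_soils, cultivar = "base-like")
  res0 <- extrapolate_models(base, rec0, ref_soils)
  expect_equal(res0$intercept, base$intercept, tolerance = 1e-10)

  # empty factor levels are skipped with a warning
  records$cultivar <- factor(records$cultivar,
                             levels = c(names(truth_ks), "Ghost"))
  expect_warning(extrapolate_models(base, records, ref_soils), "Ghost")
})
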