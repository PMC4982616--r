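# Shared fixtures, built in code.

ref_soils <- reference_soils()
models_xy22 <- xiaoyan22_models()

# Noise-free BAF records for one cultivar over a soil panel.
noisefree_records <- function(model, soils = ref_soils, cultivar = "Xiaoyan22",
                              treatment = "low") {
  tibble::tibble(
    soil_id = soils$soil_id,
    cultivar = cultivar,
    treatment = treatment,
    baf = predict_baf(model, soils)
  )
}

# Independent normal-equations OLS oracle: solve X'X beta = X'y directly.
# Never calls lm().
normal_equations_fit <- function(y, x) {
  X <- cbind(1, x)
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Published intrinsic sensitivities of the six non-modeled cultivars, as
# printed: rows = low-Pb (model 1) and high-Pb (model 2).
published_sensitivities <- list(
  low = c("Zhengmai 9023" = -1.58, "Xumai 30" = -1.67, "Wanmai 52" = -1.74,
          "Shixin 618" = -1.58, "Jimai 22" = -1.58, "Hengmai 5229" = -1.51),
  high = c("Zhengmai 9023" = -1.45, "Xumai 30" = -1.54, "Wanmai 52" = -1.61,
           "Shixin 618" = -1.45, "Jimai 22" = -1.38, "Hengmai 5229" = -1.38)
)

# The two extrapolation soils (Jiangxi acidic, Shaanxi alkaline).
extrap_soils <- ref_soils[ref_soils$soil_id %in% c("5", "10"), ]
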