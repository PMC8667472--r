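test_that("variety split keeps replicates together at the 75/25 ratio", {
  ds <- make_feature_dataset(n_varieties = 80, seed = 1)
  sp <- split_by_variety(ds, seed = 11)
  expect_equal(nrow(sp$train), 120)
  expect_equal(nrow(sp$test), 40)
  expect_length(intersect(unique(sp$train$genotype),
                          unique(sp$test$genotype)), 0)

  for (seed in 1:50) {
    sp2 <- split_by_variety(ds, seed = seed)
    expect_length(intersect(unique(sp2$train$genotype),
                            unique(sp2$test$genotype)), 0)
  }
  # determinism
  expect_identical(split_by_variety(ds, seed = 5)$train_varieties,
                   split_by_variety(ds, seed = 5)$train_varieties)
})

test_that("small variety counts split by the rounding rule", {
  ds <- make_feature_dataset(n_varieties = 4, seed = 2)
  sp <- split_by_variety(ds, seed = 1)
  expect_equal(length(unique(sp$train$genotype)), 3)
  expect_equal(length(unique(sp$test$genotype)), 1)
  expect_error(split_by_variety(make_feature_dataset(n_varieties = 3)),
               ">= 4")
})

test_that("stepwise recovers an exact single-feature relation", {
  ds <- make_feature_dataset(n_varieties = 40, seed = 3,
                             target = function(f) 3 * f$lpi)
  m <- fit_smlr(ds)
  expect_identical(m$selected, "lpi")
  expect_equal(unname(coef(m$fit)["lpi"]), 3, tolerance = 1e-8)
  expect_equal(unname(coef(m$fit)["(Intercept)"]), 0, tolerance = 1e-8)
})

test_that("stepwise recovers a two-feature relation under small noise", {
  ds <- make_feature_dataset(n_varieties = 60, seed = 4,
                             target = function(f) 2 * f$lpi + 1 * f$vci,
                             noise_sd = 0.02)
  m <- fit_smlr(ds)
  expect_setequal(m$selected, c("lpi", "vci"))
  expect_equal(unname(coef(m$fit)[c("lpi", "vci")]), c(2, 1),
               tolerance = 0.1)
})

test_that("stepwise on pure noise warns and returns intercept-only often", {
  set.seed(5)
  ds <- make_feature_dataset(n_varieties = 30, seed = 5,
                             target = function(f) rnorm(nrow(f)))
  m <- tryCatch(fit_smlr(ds), warning = function(w) {
    expect_match(conditionMessage(w), "intercept-only")
    suppressWarnings(fit_smlr(ds))
  })
  expect_s3_class(m, "lai_smlr")
  expect_true(is.finite(m$train_r2))
})

test_that("PLSR at full rank reproduces ordinary least squares", {
  ds <- make_feature_dataset(n_varieties = 40, seed = 6,
                             target = function(f) {
                               2 * f$lpi - 0.5 * f$h_mean + 0.3 * f$cap
                             },
                             noise_sd = 0.1)
  m <- fit_plsr(ds, ncomp = 8)
  ols <- lm(lai_eff ~ lpi + h_mean + h_std + h_skew + h_q3 + vci +
              hull_volume + cap, data = ds)
  expect_equal(predict(m, ds), unname(predict(ols, ds)), tolerance = 1e-6)
})

test_that("PLSR finds a rank-1 relation with one component", {
  ds <- make_feature_dataset(n_varieties = 40, seed = 7,
                             target = function(f) 4 * f$lpi)
  m <- fit_plsr(ds, seed = 2)
  expect_gte(m$cv_r2, 0.99)
  ev <- evaluate_model(m, ds)
  expect_gte(ev$r2, 0.99)
})

test_that("PLSR stays stable under heavy feature collinearity", {
  ds <- make_feature_dataset(n_varieties = 50, seed = 8,
                             target = function(f) f$h_mean, noise_sd = 0.05)
  # h_std is built as 0.3 * h_mean + tiny noise: |r| > 0.9 by construction
  expect_gt(abs(cor(ds$h_std, ds$h_mean)), 0.9)
  m <- fit_plsr(ds, seed = 3)
  expect_true(all(is.finite(predict(m, ds))))
  expect_gte(evaluate_model(m, ds)$r2, 0.95)
})

test_that("linear SVR nails a noiseless linear target", {
  ds <- make_feature_dataset(n_varieties = 40, seed = 9,
                             target = function(f) 2 + 3 * f$lpi)
  sp <- split_by_variety(ds, seed = 1)
  m <- fit_svr(sp$train, kernel = "linear", seed = 1)
  expect_gte(evaluate_model(m, sp$test)$r2, 0.99)
})

test_that("RBF SVR explains a smooth monotone response with 5% noise", {
  ds <- make_feature_dataset(n_varieties = 60, seed = 10,
                             target = function(f) exp(1.5 * (1 - f$lpi)),
                             noise_sd = 0.05 * exp(0.75))
  sp <- split_by_variety(ds, seed = 2)
  m <- fit_svr(sp$train, kernel = "rbf", seed = 2)
  expect_gte(evaluate_model(m, sp$test)$r2, 0.9)
})

test_that("constant targets are handled by the R^2 = 0 convention", {
  ds <- make_feature_dataset(n_varieties = 20, seed = 11,
                             target = function(f) rep(2, nrow(f)))
  sp <- split_by_variety(ds, seed = 1)
  m <- fit_svr(sp$train, kernel = "linear", grid = small_svr_grid(),
               seed = 1)
  expect_warning(ev <- evaluate_model(m, sp$test), "zero-variance")
  expect_equal(ev$r2, 0)
  expect_true(is.finite(ev$rmse))
})

test_that("evaluation reproduces hand-computed R^2 and RMSE", {
  # internal scoring arithmetic on the spec's worked numbers
  expect_equal(caplidar:::r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  # and through a fitted model: y = x fit exactly, then applied to a test
  # set engineered to produce predictions (1, 2, 4)
  train <- tibble::tibble(lpi = c(1, 2, 3), lai_eff = c(1, 2, 3))
  m <- fit_smlr(train, features = "lpi")
  test <- tibble::tibble(lpi = c(1, 2, 4), lai_eff = c(1, 2, 3))
  ev <- evaluate_model(m, test)
  expect_equal(ev$rmse, sqrt(1 / 3), tolerance = 1e-8)
  expect_equal(ev$r2, 0.5, tolerance = 1e-8)
  # perfect and mean-only limits
  expect_equal(caplidar:::r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(caplidar:::r_squared(c(1, 2, 3), rep(2, 3)), 0)
})

test_that("broom methods return tidy one-row summaries", {
  ds <- make_feature_dataset(n_varieties = 30, seed = 12,
                             target = function(f) 3 * f$lpi,
                             noise_sd = 0.05)
  sp <- split_by_variety(ds, seed = 1)
  sm <- fit_smlr(sp$train)
  expect_true(all(c("term", "estimate", "p.value") %in% names(tidy(sm))))
  expect_equal(nrow(glance(sm)), 1)
  sv <- fit_svr(sp$train, kernel = "rbf", grid = small_svr_grid(), seed = 1)
  expect_true(all(c("cv_r2", "train_r2") %in% names(glance(sv))))
  pl <- fit_plsr(sp$train, seed = 1)
  expect_equal(nrow(glance(pl)), 1)
  expect_equal(nrow(tidy(pl)), 8)
})
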