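test_that("a single predictor forces unit importance weight", {
  p <- tiny_panel()
  spec <- predictor_spec(covariates = character(), outcome_lags = 2011)
  pm <- build_predictor_matrices(p, spec)
  v <- optimize_importance(pm, p)
  expect_equal(as.numeric(v), 1)
})

test_that("importance weights always live on the simplex", {
  p <- make_study_fixture("outpatient-like")
  pm <- build_predictor_matrices(p)
  v <- optimize_importance(pm, p, n_starts = 2, maxit = 60)
  expect_true(all(as.numeric(v) >= 0))
  expect_lt(abs(sum(as.numeric(v)) - 1), 1e-10)
})

test_that("nested optimization beats equal weights and matches a 1-D grid", {
  # two predictors -> the outer problem is one-dimensional: grid-search it
  p <- generate_panel(dgp_config(n_units = 6, sigma = 0.8, seed = 13))
  spec <- predictor_spec(covariates = "gdp_per_capita", outcome_lags = 2012)
  pm <- build_predictor_matrices(p, spec)
  m <- panel_meta(p)
  ymat <- outcome_matrix(p, units = c(pm$treated_unit, pm$donors),
                         years = m$pre_years)
  mspe_of <- function(v1) {
    w <- solve_weights(pm, c(v1, 1 - v1))$w
    mean((ymat[, 1] - as.numeric(ymat[, -1] %*% w))^2)
  }
  grid <- vapply(seq(0, 1, by = 0.001), mspe_of, numeric(1))
  v <- optimize_importance(pm, p, n_starts = 4, seed = 2)
  achieved <- attr(v, "mspe")
  expect_lte(achieved, mspe_of(0.5) + 1e-12)      # no worse than equal V
  expect_lte(achieved, min(grid) + 1e-6)          # matches the grid optimum
})

test_that("a duplicated donor yields a perfect counterfactual", {
  p <- duplicate_donor_panel()
  fit <- fit_synthetic_control(p, v = "equal")
  expect_lt(max(abs(fit$path$gap)), 1e-6)
  expect_lt(fit$pre_mspe, 1e-10)
})

test_that("noiseless in-hull treated unit is reproduced exactly pre-policy", {
  cfg <- dgp_config(tau = 0, sigma = 0, delta = 0, treated_in_hull = TRUE,
                    seed = 17)
  p <- generate_panel(cfg)
  fit <- fit_synthetic_control(p, v = "equal")
  pre_gaps <- fit$path$gap[fit$path$period == "pre"]
  expect_lt(max(abs(pre_gaps)), 1e-6)
  expect_lt(max(abs(fit$path$gap)), 1e-6)  # tau = 0: post gaps vanish too
})

test_that("study-scale fit satisfies the weight constraints", {
  p <- make_study_fixture("outpatient-like")
  fit <- fit_synthetic_control(p, v = "auto", n_starts = 2, maxit = 80)
  expect_true(all(fit$weights$w >= 0))
  expect_lt(abs(sum(fit$weights$w) - 1), 1e-8)
  expect_equal(fit$path$gap, fit$path$observed - fit$path$synthetic)
  expect_equal(fit$pre_mspe,
               mean(fit$path$gap[fit$path$year < 2013]^2))
})

test_that("adding a constant to every outcome shifts the synthetic path only", {
  p <- generate_panel(dgp_config(n_units = 8, sigma = 0.5, seed = 23,
                                 theta_base = 40))
  df <- tibble::as_tibble(p)
  df$drug_prop <- df$drug_prop + 12
  p2 <- as_panel(df, "drug_prop", "C01", 2013,
                 covariates = panel_meta(p)$covariates)
  f1 <- fit_synthetic_control(p, v = "equal")
  f2 <- fit_synthetic_control(p2, v = "equal")
  expect_equal(f2$weights$w, f1$weights$w, tolerance = 1e-6)
  expect_equal(f2$path$synthetic, f1$path$synthetic + 12, tolerance = 1e-6)
  expect_equal(f2$path$gap, f1$path$gap, tolerance = 1e-6)
})

test_that("effect summary arithmetic follows its definitions", {
  p <- tiny_panel()
  fit <- fit_synthetic_control(p, v = "equal")
  # overwrite the path with crafted gaps: (-2, -4, -6) over 3 post years
  fit$path <- tibble::tibble(
    year = 2009:2014,
    observed = c(41, 40, 40, 38, 36, 34),
    synthetic = c(41, 40, 40, 40, 40, 40),
    gap = observed - synthetic,
    period = rep(c("pre", "post"), each = 3)
  )
  fit$meta$policy_year <- 2012L
  fit$meta$pre_years <- 2009:2011
  fit$pre_mspe <- 0
  eff <- summarize_effect(fit, baseline_year = 2011)
  expect_equal(eff$mean_post_gap, -4)
  expect_equal(eff$mean_abs_effect, 4)
  expect_equal(eff$baseline_level, 40)
  expect_equal(eff$relative_effect, 10.0)

  # null effect
  fit$path$observed <- fit$path$synthetic
  fit$path$gap <- 0
  eff0 <- summarize_effect(fit, baseline_year = 2011)
  expect_equal(eff0$mean_post_gap, 0)
  expect_equal(eff0$relative_effect, 0)

  # zero baseline level is undefined
  fit$path$observed[fit$path$year == 2011] <- 0
  expect_error(summarize_effect(fit, baseline_year = 2011), "zero")
  expect_error(summarize_effect(fit, baseline_year = 2013), "pre-policy")
})

test_that("relative effect reproduces reported-style arithmetic", {
  # a 3.2 pp mean gap against a 34.8 pp baseline is a 9.2% relative effect
  expect_equal(round(relative_effect(-3.2, 34.8), 1), 9.2)
  # and a 7.7 pp gap against a 47.0 baseline is 16.4% at this precision
  expect_equal(round(relative_effect(-7.7, 47.0), 1), 16.4)
  expect_error(relative_effect(3, 0), "zero")
})

test_that("balance table columns are independent weighted means", {
  p <- make_study_fixture("null")
  fit <- fit_synthetic_control(p, v = "equal")
  bal <- balance_table(p, fit)
  pm <- fit$predictor_matrices
  w <- fit$weights$w
  # independent recomputation per predictor row
  for (i in seq_along(pm$row_names)) {
    expect_equal(bal$synthetic[bal$predictor == pm$row_names[i]],
                 sum(pm$X0_raw[i, ] * w))
    expect_equal(bal$donor_mean[bal$predictor == pm$row_names[i]],
                 mean(pm$X0_raw[i, ]))
  }
  # with hand-set equal weights the synthetic column IS the donor mean
  fit$weights$w[] <- 1 / length(w)
  bal_eq <- balance_table(p, fit)
  expect_equal(bal_eq$synthetic, bal_eq$donor_mean)
})

test_that("a duplicated donor carrying full weight equalizes balance columns", {
  p <- duplicate_donor_panel()
  fit <- fit_synthetic_control(p, v = "equal")
  bal <- balance_table(p, fit)
  expect_equal(bal$synthetic, bal$treated, tolerance = 1e-6)
})

test_that("poor pre-policy fit warns but does not fail", {
  p <- make_study_fixture("inpatient-like")  # treated sits ~10 pp below donors
  expect_warning(fit <- fit_synthetic_control(p, v = "equal"),
                 "poor pre-policy fit")
  expect_s3_class(fit, "scm_fit")
  # after the matching donor-level adjustment the warning goes away
  adj <- adjust_donor_level(p, 10)
  expect_no_warning(fit2 <- fit_synthetic_control(adj, v = "equal"))
  expect_lt(fit2$pre_mspe, fit$pre_mspe)
})
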