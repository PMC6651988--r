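test_that("identical configs generate byte-identical panels", {
  cfg <- dgp_config(seed = 77)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(p1, f1, sidecar = FALSE)
  write_panel(p2, f2, sidecar = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the draw
  p3 <- generate_panel(dgp_config(seed = 78))
  expect_false(identical(p1$drug_prop, p3$drug_prop))
})

test_that("the generator leaves the caller's RNG stream untouched", {
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_panel(dgp_config(seed = 5)))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("ground truth records every latent component", {
  cfg <- dgp_config(tau = -7.7, delta = -10, seed = 9)
  p <- generate_panel(cfg)
  gt <- attr(p, "ground_truth")
  expect_named(gt, c("tau_t", "delta", "f", "mu", "lambda", "theta",
                     "hull_weights", "seed", "config"))
  expect_equal(unname(gt$tau_t[as.character(2013:2015)]), rep(-7.7, 3))
  expect_equal(unname(gt$tau_t[as.character(2008:2012)]), rep(0, 5))
  expect_equal(gt$delta, -10)
  expect_length(gt$f, 13)
  expect_equal(gt$seed, 9L)
})

test_that("treatment only touches the treated unit in post years", {
  cfg0 <- dgp_config(tau = 0, seed = 31)
  cfg1 <- dgp_config(tau = -7.7, seed = 31)
  y0 <- outcome_matrix(generate_panel(cfg0))
  y1 <- outcome_matrix(generate_panel(cfg1))
  expect_equal(y1[, -1], y0[, -1])                      # donors identical
  expect_equal(y1[as.character(2008:2012), 1], y0[as.character(2008:2012), 1])
  expect_equal(y1[as.character(2013:2015), 1],
               y0[as.character(2013:2015), 1] - 7.7)
})

test_that("effect ramp profile scales linearly to tau", {
  p0 <- generate_panel(dgp_config(tau = 0, seed = 37))
  p1 <- generate_panel(dgp_config(tau = -6, effect_profile = "ramp", seed = 37))
  d <- outcome_matrix(p1)[, 1] - outcome_matrix(p0)[, 1]
  expect_equal(unname(d[as.character(2013:2015)]), c(-2, -4, -6))
})

test_that("noise-free covariates are exact affine functions of (f, mu)", {
  cfg <- dgp_config(sigma = 0, seed = 41)
  p <- generate_panel(cfg)
  gt <- attr(p, "ground_truth")
  df <- tibble::as_tibble(p)
  tc <- df$year - mean(unique(df$year))
  f <- gt$f[df$unit]; mu <- gt$mu[df$unit]
  # independent recomputation from the published calibration
  expect_equal(df$urbanization,
               unname(60 + 8 * (f - 1) + 0.6 * mu + 0.3 * f * tc))
  expect_equal(df$life_expectancy,
               unname(79.5 + 2.5 * (f - 1) + 0.15 * mu + 0.05 * f * tc))
  expect_equal(df$population,
               unname(5.5e6 + 2e6 * (f - 1) + 2e5 * mu + 2e4 * f * tc))
})

test_that("hull construction places the treated unit at a donor combination", {
  cfg <- dgp_config(treated_in_hull = TRUE, sigma = 0, tau = 0, seed = 43)
  p <- generate_panel(cfg)
  gt <- attr(p, "ground_truth")
  hw <- gt$hull_weights
  expect_equal(sum(hw), 1)
  expect_true(all(hw >= 0))
  expect_equal(unname(gt$f[1]), sum(hw * gt$f[-1]))
  expect_equal(unname(gt$mu[1]), sum(hw * gt$mu[-1]))
  # outcomes inherit the combination exactly in the noise-free null
  y <- outcome_matrix(p)
  expect_equal(unname(y[, 1]), unname(as.numeric(y[, -1] %*% hw)))
})

test_that("a persistent treated offset is restored by the matching adjustment", {
  p <- generate_panel(dgp_config(delta = -10, tau = 0, sigma = 0.5, seed = 47))
  m <- panel_meta(p)
  y <- outcome_matrix(p, years = m$pre_years)
  gap_before <- mean(y[, 1]) - mean(y[, -1])
  expect_lt(abs(gap_before + 10), 2.5)  # treated sits ~10 pp below the pool
  adj <- adjust_donor_level(p, 10)
  y2 <- outcome_matrix(adj, years = m$pre_years)
  expect_lt(abs(mean(y2[, 1]) - mean(y2[, -1])), 2.5)
})

test_that("invalid configurations are rejected", {
  expect_error(dgp_config(years = 2008:2010, policy_year = 2009), "pre-policy")
  expect_error(dgp_config(years = 2008:2012, policy_year = 2013), "pre-policy")
  expect_error(dgp_config(sigma = -1))
  expect_error(make_study_fixture("bogus"))
})

test_that("outcome clipping warns instead of silently truncating", {
  expect_warning(
    generate_panel(dgp_config(theta_base = 2, theta_trend = -1, seed = 3)),
    "clipped"
  )
})

test_that("study fixtures match their advertised regimes", {
  out <- make_study_fixture("outpatient-like")
  inp <- make_study_fixture("inpatient-like")
  nul <- make_study_fixture("null")
  expect_equal(attr(out, "ground_truth")$config$tau, -7.7)
  expect_equal(attr(inp, "ground_truth")$delta, -10)
  expect_equal(unname(attr(nul, "ground_truth")$tau_t["2015"]), 0)
  expect_equal(dim(outcome_matrix(out)), c(8, 13))
})
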