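test_that("as_panel validates structure and annotations", {
  p <- tiny_panel()
  m <- panel_meta(p)
  expect_s3_class(p, "scm_panel")
  expect_equal(m$treated_unit, "A")
  expect_equal(m$donors, c("B", "C", "D"))
  expect_equal(m$pre_years, 2008:2011)
  expect_equal(m$post_years, 2012:2013)

  grid <- expand.grid(unit = c("A", "B", "C"), year = 2008:2012,
                      stringsAsFactors = FALSE)
  grid$y <- 50

  # duplicate unit-year rows
  expect_error(
    as_panel(rbind(grid, grid[1, ]), "y", "A", 2011),
    "duplicate unit-year"
  )
  # treated unit absent
  expect_error(as_panel(grid, "y", "Z", 2011), "not present")
  # year gaps named
  expect_error(
    as_panel(grid[grid$year != 2010, ], "y", "A", 2011),
    "2010"
  )
  # too few donors
  expect_error(
    as_panel(grid[grid$unit != "C", ], "y", "A", 2011),
    "J >= 2"
  )
  # policy year must leave >= 2 pre and >= 1 post years
  expect_error(as_panel(grid, "y", "A", 2009), "pre-policy")
  expect_error(as_panel(grid, "y", "A", 2013), "pre-policy")
  # outcome range and missingness
  grid2 <- grid; grid2$y[1] <- 120
  expect_error(as_panel(grid2, "y", "A", 2011), "\\[0, 100\\]")
  grid3 <- grid; grid3$y[1] <- NA
  expect_error(as_panel(grid3, "y", "A", 2011), "missing outcome")
})

test_that("a minimal covariate-free panel is accepted", {
  grid <- expand.grid(unit = c("A", "B", "C"), year = 2008:2011,
                      stringsAsFactors = FALSE)
  grid$y <- 50 + seq_len(nrow(grid)) / 10
  p <- as_panel(grid, "y", "A", 2010)
  expect_equal(panel_meta(p)$covariates, character(0))
  expect_equal(nrow(p), 12)
})

test_that("adjust_donor_level shifts donors only and records provenance", {
  p <- tiny_panel()
  m <- panel_meta(p)

  # offset 0 is the identity
  expect_equal(tibble::as_tibble(adjust_donor_level(p, 0)),
               tibble::as_tibble(p))

  adj <- adjust_donor_level(p, 10)
  y0 <- outcome_matrix(p)
  y1 <- outcome_matrix(adj)
  expect_equal(y1[, "A"], y0[, "A"])                     # treated untouched
  expect_equal(y1[, m$donors], y0[, m$donors] - 10)      # donors shifted
  expect_equal(adj$gdp, p$gdp)                           # covariates untouched
  rec <- panel_meta(adj)$adjustment[[1]]
  expect_equal(rec$offset, 10)
  expect_equal(rec$mode, "additive")
  expect_false(rec$out_of_range)

  # definition on one donor's series: C starts at 50 and drops to 40
  expect_equal(unname(y0[c("2008", "2009"), "C"]), c(50, 48.5))
  expect_equal(unname(y1[c("2008", "2009"), "C"]), c(40, 38.5))

  # donor pre-period mean drops by exactly the offset
  pre <- m$pre_years
  expect_equal(mean(y1[as.character(pre), m$donors]),
               mean(y0[as.character(pre), m$donors]) - 10)
})

test_that("adjust_donor_level aligns a donor pool sitting 10 pp high", {
  # donors whose pre-period mean is 47.5, treated at 37.5: offset 10 aligns
  grid <- expand.grid(unit = c("T", "B", "C"), year = 2008:2012,
                      stringsAsFactors = FALSE)
  grid$y <- ifelse(grid$unit == "T", 37.5, 47.5)
  p <- as_panel(grid, "y", "T", 2011)
  adj <- adjust_donor_level(p, 10)
  y <- outcome_matrix(adj, years = 2008:2010)
  expect_equal(mean(y[, c("B", "C")]), 37.5)
  expect_equal(mean(y[, "T"]), 37.5)
})

test_that("adjust_donor_level is invertible and commutes with year subsets", {
  p <- make_study_fixture("outpatient-like")
  back <- adjust_donor_level(adjust_donor_level(p, 7.3), -7.3)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(p))

  sub_then_adj <- adjust_donor_level(
    as_panel(p[p$year <= 2014, ], "drug_prop", "C01", 2013,
             covariates = panel_meta(p)$covariates), 5)
  adj_then_sub <- adjust_donor_level(p, 5)
  expect_equal(
    tibble::as_tibble(sub_then_adj),
    tibble::as_tibble(adj_then_sub[adj_then_sub$year <= 2014, ])
  )
})

test_that("adjustment warns (not errors) when outcomes leave [0, 100]", {
  p <- tiny_panel()
  expect_warning(adj <- adjust_donor_level(p, 45), "outside \\[0, 100\\]")
  expect_true(panel_meta(adj)$adjustment[[1]]$out_of_range)
})

test_that("relative adjustment mode rescales donors", {
  p <- tiny_panel()
  adj <- adjust_donor_level(p, 10, mode = "relative")
  y0 <- outcome_matrix(p); y1 <- outcome_matrix(adj)
  expect_equal(y1[, "B"], y0[, "B"] * 0.9)
  expect_equal(y1[, "A"], y0[, "A"])
})

test_that("panels round-trip through the canonical long CSV", {
  p <- make_study_fixture("null")
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f1)
  p2 <- read_panel(f1, outcome = "drug_prop", treated_unit = "C01",
                   policy_year = 2013,
                   covariates = panel_meta(p)$covariates, layout = "long")
  # canonical formatting: write the reread panel again; files must be identical
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(outcome_matrix(p2), outcome_matrix(p), tolerance = 1e-12)
  # metadata sidecar exists and records the design
  meta <- jsonlite::read_json(paste0(f1, ".json"))
  expect_equal(meta$treated_unit, "C01")
  expect_equal(meta$policy_year, 2013)
})

test_that("wide CSV layout reads directly", {
  p <- tiny_panel()
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(p), f)
  p2 <- read_panel(f, outcome = "y", treated_unit = "A", policy_year = 2012,
                   covariates = "gdp", layout = "wide")
  expect_equal(tibble::as_tibble(p2), tibble::as_tibble(p))
})

test_that("long reader rejects duplicated keys", {
  p <- tiny_panel()
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f, sidecar = FALSE)
  long <- readr::read_csv(f, show_col_types = FALSE)
  readr::write_csv(rbind(long, long[3, ]), f)
  expect_error(
    read_panel(f, outcome = "y", treated_unit = "A", policy_year = 2012,
               layout = "long"),
    "duplicate"
  )
})
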