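# Shared fixtures and independent oracles for the test suite.

# Small hand-written panel: 4 units x 6 years (4 pre, 2 post), one covariate.
# Unit A is treated; outcomes are simple deterministic series.
tiny_panel <- function() {
  grid <- expand.grid(unit = c("A", "B", "C", "D"), year = 2008:2013,
                      stringsAsFactors = FALSE)
  base <- c(A = 40, B = 45, C = 50, D = 38)
  slope <- c(A = -1, B = -0.5, C = -1.5, D = -1)
  grid$y <- base[grid$unit] + slope[grid$unit] * (grid$year - 2008)
  grid$gdp <- c(A = 50, B = 60, C = 70, D = 45)[grid$unit] +
    0.5 * (grid$year - 2008)
  as_panel(grid, outcome = "y", treated_unit = "A", policy_year = 2012,
           covariates = "gdp")
}

# Panel in which the treated unit duplicates donor "B" exactly
# (outcomes and covariate), so a perfect synthetic control exists.
duplicate_donor_panel <- function() {
  p <- tiny_panel()
  df <- tibble::as_tibble(p)
  b <- df[df$unit == "B", c("year", "y", "gdp")]
  df$y[df$unit == "A"] <- b$y[match(df$year[df$unit == "A"], b$year)]
  df$gdp[df$unit == "A"] <- b$gdp[match(df$year[df$unit == "A"], b$year)]
  as_panel(df, outcome = "y", treated_unit = "A", policy_year = 2012,
           covariates = "gdp")
}

# Build a predictor_matrices object directly from matrices (already on the
# optimization scale), bypassing panel construction, for solver-level tests.
pm_from_matrices <- function(X1, X0, donors = NULL) {
  k <- length(X1)
  donors <- donors %||% paste0("D", seq_len(ncol(X0)))
  structure(list(
    X1 = as.numeric(X1), X0 = X0,
    X1_raw = as.numeric(X1), X0_raw = X0,
    row_names = paste0("p", seq_len(k)),
    center = rep(0, k), scale = rep(1, k),
    treated_unit = "T", donors = donors, k = k,
    spec = list(covariates = character(), outcome_lags = integer())
  ), class = "predictor_matrices")
}

# Independent brute-force oracle: minimum of the weighted matching distance
# over an exhaustive integer grid on the simplex with resolution `step`.
# Evaluated in chunks so J = 4 at step 0.001 stays within memory.
oracle_grid_objective <- function(X1, X0, v, step = 0.001) {
  J <- ncol(X0)
  n <- round(1 / step)
  v <- v / sum(v)
  obj_cols <- function(W) {
    # W: J x m matrix of simplex points (columns)
    D <- X1 - X0 %*% W
    colSums(v * D^2)
  }
  if (J == 2) {
    a <- 0:n
    W <- rbind(a, n - a) / n
    return(min(obj_cols(W)))
  }
  if (J == 3) {
    best <- Inf
    for (a in 0:n) {
      b <- 0:(n - a)
      W <- rbind(a, b, n - a - b) / n
      best <- min(best, min(obj_cols(W)))
    }
    return(best)
  }
  if (J == 4) {
    best <- Inf
    for (a in 0:n) {
      m <- n - a
      # all (b, c) with b + c <= m
      b <- rep.int(0:m, m:0 + 1L)
      c <- sequence(m:0 + 1L) - 1L
      W <- rbind(a, b, c, m - b - c) / n
      best <- min(best, min(obj_cols(W)))
    }
    return(best)
  }
  stop("oracle supports J <= 4")
}

`%||%` <- rlang::`%||%`
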