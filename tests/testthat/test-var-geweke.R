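# VAR fitting and the Geweke influence decomposition.

test_that("VAR(1) coefficients are recovered from a long realization", {
  A <- matrix(c(0.5, 0.2, 0, 0.4), 2, 2, byrow = TRUE)
  set.seed(1)
  n <- 5000
  x <- matrix(0, n, 2)
  for (t in 2:n) x[t, ] <- A %*% x[t - 1, ] + rnorm(2)
  fit <- fit_var(x, p = 1)
  expect_lt(max(abs(fit$A_eff[[1]] - A)), 0.05)
  expect_lt(max(abs(fit$A[[1]] + A)), 0.05)   # stored minus convention
  expect_lt(max(abs(fit$sigma_u - diag(2))), 0.1)
})

test_that("white noise yields coefficients within 3 standard errors of zero", {
  set.seed(2)
  x <- matrix(rnorm(3000 * 3), ncol = 3)
  fit <- fit_var(x, p = 2)
  for (i in 1:2) {
    expect_true(all(abs(fit$A_eff[[i]]) < 3 * fit$coef_se[[i]] + 1e-12))
  }
})

test_that("refitting a noise-free reconstruction reproduces the coefficients", {
  set.seed(3)
  n <- 400
  x <- matrix(0, n, 2)
  A <- matrix(c(0.4, -0.3, 0.25, 0.5), 2, 2)
  for (t in 2:n) x[t, ] <- A %*% x[t - 1, ] + rnorm(2, sd = 0.7)
  fit <- fit_var(x, p = 1)
  xc <- sweep(x, 2, fit$means)
  recon <- var_simulate(fit, fit$residuals, xc[1, , drop = FALSE])
  expect_equal(recon, unname(xc), tolerance = 1e-10)
  refit <- fit_var(recon, p = 1)
  expect_equal(refit$A_eff[[1]], fit$A_eff[[1]], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("short series and bad orders are rejected informatively", {
  expect_error(fit_var(matrix(rnorm(8), 4, 2), p = 1), "too short")
  expect_error(fit_var(matrix(rnorm(100), 50, 2), p = 0), "p")
})

test_that("the order selector finds a clear VAR(2) structure", {
  set.seed(4)
  n <- 3000
  x <- matrix(0, n, 2)
  for (t in 3:n) {
    x[t, ] <- c(0.2, 0) * x[t - 1, ] + c(0, 0.5) * x[t - 2, ] + rnorm(2)
  }
  expect_identical(as.integer(select_var_order(x, p_max = 4)), 2L)
})

test_that("independent white-noise series carry (almost) no influence", {
  set.seed(5)
  x <- rnorm(10000); y <- rnorm(10000)
  g <- geweke_measures(x, y, p = 1)
  expect_lt(g$F_x_to_y, 0.01)
  expect_lt(g$F_y_to_x, 0.01)
  expect_lt(g$F_instantaneous, 0.01)
})

test_that("the unit-lag closed form gives F = ln 2 in one direction only", {
  pair <- make_lagged_pair(50000, a = 1, seed = 6)
  g <- geweke_measures(pair$x, pair$y, p = 1)
  expect_lt(abs(g$F_x_to_y - log(2)), 0.02)
  expect_lt(g$F_y_to_x, 0.01)
  expect_lt(abs(g$F_total - (g$F_x_to_y + g$F_y_to_x + g$F_instantaneous)),
            1e-6)
})

test_that("measures match an explicit regression oracle for p = 1 and p = 2", {
  for (p in 1:2) {
    set.seed(10 + p)
    n <- 600
    x <- as.numeric(arima.sim(list(ar = 0.5), n))
    y <- 0.6 * c(rep(0, p), x[1:(n - p)]) + rnorm(n)
    g <- geweke_measures(x, y, p = p)
    o <- geweke_oracle(x, y, p)
    expect_equal(g$F_x_to_y, o$F_x_to_y, tolerance = 1e-10)
    expect_equal(g$F_y_to_x, o$F_y_to_x, tolerance = 1e-10)
    expect_equal(g$F_instantaneous, o$F_instantaneous, tolerance = 1e-10)
    expect_equal(g$F_total, o$F_total, tolerance = 1e-10)
  }
})

test_that("directional swap, antisymmetry and scale invariance are exact", {
  set.seed(12)
  x <- as.numeric(arima.sim(list(ar = 0.4), 800))
  y <- 0.5 * c(0, x[-800]) + as.numeric(arima.sim(list(ar = -0.3), 800))
  a <- geweke_measures(x, y, p = 2)
  b <- geweke_measures(y, x, p = 2)
  expect_equal(a$F_x_to_y, b$F_y_to_x, tolerance = 1e-12)
  expect_equal(a$F_y_to_x, b$F_x_to_y, tolerance = 1e-12)
  expect_equal(a$F_instantaneous, b$F_instantaneous, tolerance = 1e-12)
  expect_equal(a$dgci, -b$dgci, tolerance = 1e-12)
  s <- geweke_measures(17 * x, 0.002 * y, p = 2)
  expect_equal(s$F_x_to_y, a$F_x_to_y, tolerance = 1e-9)
  expect_equal(s$F_y_to_x, a$F_y_to_x, tolerance = 1e-9)
  expect_equal(s$F_instantaneous, a$F_instantaneous, tolerance = 1e-9)
})

test_that("all Geweke components are nonnegative across random systems", {
  set.seed(13)
  for (r in 1:20) {
    n <- 300
    x <- as.numeric(arima.sim(list(ar = runif(1, -0.6, 0.6)), n))
    y <- runif(1, -1, 1) * c(0, x[-n]) + rnorm(n)
    g <- geweke_measures(x, y, p = sample(1:3, 1))
    expect_gte(g$F_x_to_y, -1e-10)
    expect_gte(g$F_y_to_x, -1e-10)
    expect_gte(g$F_instantaneous, -1e-10)
    expect_lt(abs(g$F_total -
                    (g$F_x_to_y + g$F_y_to_x + g$F_instantaneous)), 1e-6)
  }
})

test_that("segments confine lagged pairs within their boundaries", {
  # dependence exists ONLY across the segment boundary: y's first sample of
  # segment 2 copies x's last sample of segment 1
  set.seed(14)
  n <- 400
  x <- rnorm(n); y <- rnorm(n)
  y[201] <- y[201] + 5 * x[200]
  segs <- list(1:200, 201:400)
  g_seg <- geweke_measures(x, y, p = 1, segments = segs)
  g_all <- geweke_measures(x, y, p = 1)
  expect_lt(g_seg$F_x_to_y, 0.03)      # boundary pair excluded
  expect_identical(g_seg$n_eff, 398L)
  # exact agreement with the segment-aware regression oracle
  o <- geweke_oracle(x, y, p = 1, segments = segs)
  expect_equal(g_seg$F_x_to_y, o$F_x_to_y, tolerance = 1e-10)
  expect_equal(g_seg$F_y_to_x, o$F_y_to_x, tolerance = 1e-10)
  expect_equal(g_seg$F_instantaneous, o$F_instantaneous, tolerance = 1e-10)
  # whole-series segments equal the default
  g_one <- geweke_measures(x, y, p = 1, segments = list(1:n))
  expect_equal(g_one$F_x_to_y, g_all$F_x_to_y, tolerance = 1e-12)
  # too-short segments are dropped with a warning
  expect_warning(geweke_measures(x, y, p = 1,
                                 segments = list(1:200, 399:400)),
                 "skipped")
  expect_error(geweke_measures(x, y, p = 1, segments = list(1:10, 5:20)),
               "nonoverlapping")
})
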