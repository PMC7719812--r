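# HRF, design matrix, GLM estimation and second-level ROI tests.

test_that("the canonical HRF kernel has the double-gamma shape", {
  h <- canonical_hrf(tr_s = 2)
  expect_equal(h$kernel[1], 0)                    # gamma density at lag 0
  expect_equal(max(h$kernel), 1)                  # unit-peak normalized
  expect_identical(h$times_s[which.max(h$kernel)], 6)  # peak near 6 s at TR=2
  expect_true(any(h$kernel < 0))                  # undershoot present
  expect_true(all(is.finite(h$kernel)))
  # finer sampling puts the peak at ~5 s (mode of the gamma difference)
  h01 <- canonical_hrf(tr_s = 0.1)
  expect_lt(abs(h01$times_s[which.max(h01$kernel)] - 5), 0.3)
  expect_error(canonical_hrf(disp_s = 0), "positive")
})

test_that("design-matrix columns equal brute-force boxcar convolution", {
  des <- build_fmri_session(1, 3, 4)
  hrf <- canonical_hrf(tr_s = 2)
  X <- build_design_matrix(des, hrf, drift_order = 0)
  for (cc in c("primed", "unprimed", "scrambled")) {
    box <- as.numeric(des$condition == cc)
    manual <- vapply(seq_along(box), function(t)
      sum(vapply(seq_along(hrf$kernel), function(k)
        if (t - k + 1 >= 1) hrf$kernel[k] * box[t - k + 1] else 0,
        numeric(1))), numeric(1))
    expect_equal(unname(X[, cc]), manual, tolerance = 1e-12)
    # causality: no response before first onset
    onset <- which(box == 1)[1]
    expect_true(all(X[seq_len(onset - 1), cc] == 0))
  }
  expect_error(build_design_matrix(des, hrf, conditions = "novelty"),
               "novelty")
})

test_that("an all-rest schedule yields only intercept and drift columns", {
  des <- build_fmri_session(1, 1, 1)
  des$condition[] <- "rest"
  X <- build_design_matrix(des, canonical_hrf(), drift_order = 2)
  expect_identical(colnames(X), c("intercept", "drift1", "drift2"))
})

test_that("noise-free GLM recovers generating betas to machine precision", {
  des <- build_fmri_session(2, 3, 2)
  X <- build_design_matrix(des, canonical_hrf())
  beta_true <- c(2, 1.5, -0.5, 0.8, 0.1, -0.2)
  y <- drop(unclass(X) %*% beta_true)
  fit <- fit_glm(y, X)
  expect_equal(drop(fit$beta), beta_true, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("betas and t statistics match an independent regression oracle", {
  des <- build_fmri_session(2, 3, 3)
  X <- build_design_matrix(des, canonical_hrf())
  set.seed(8)
  y <- rnorm(nrow(X))
  fit <- fit_glm(y, X)
  Xm <- unclass(X); attributes(Xm)[c("condition_columns", "schedule_length")] <- NULL
  ref <- lm(y ~ Xm + 0)
  expect_equal(unname(drop(fit$beta)), unname(coef(ref)), tolerance = 1e-8)
  con <- glm_contrast(fit, c(primed = 1, scrambled = -1))
  w <- as.numeric(colnames(X) %in% "primed") -
    as.numeric(colnames(X) %in% "scrambled")
  est <- sum(w * coef(ref))
  se <- sqrt(sum(w * (vcov(ref) %*% w)))
  expect_equal(con$estimate, est, tolerance = 1e-8)
  expect_equal(con$t, est / se, tolerance = 1e-8)
  expect_identical(con$df, nrow(X) - ncol(X))
  # residual orthogonality to the design
  resid <- y - drop(Xm %*% fit$beta)
  expect_lt(max(abs(crossprod(Xm, resid))), 1e-8)
})

test_that("row permutations and rank deficiency behave as expected", {
  des <- build_fmri_session(1, 3, 5)
  X <- build_design_matrix(des, canonical_hrf())
  set.seed(2); y <- rnorm(nrow(X))
  f1 <- fit_glm(y, X)
  perm <- sample(nrow(X))
  f2 <- fit_glm(y[perm], unclass(X)[perm, ])
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10, ignore_attr = TRUE)
  Xbad <- cbind(unclass(X), dup = unclass(X)[, 2])
  expect_error(fit_glm(y, Xbad), "rank deficient")
})

test_that("AR(1) prewhitening runs and is labeled", {
  des <- build_fmri_session(2, 3, 6)
  X <- build_design_matrix(des, canonical_hrf())
  set.seed(3)
  e <- as.numeric(arima.sim(list(ar = 0.4), nrow(X)))
  y <- drop(unclass(X) %*% c(1, 1, 0, 0, 0, 0)) + e
  fit <- fit_glm(y, X, whitening = "ar1")
  expect_identical(fit$whitening, "ar1")
  expect_gt(fit$rho, 0.1)
  expect_lt(fit$rho, 0.7)
})

test_that("ROI group tests reproduce the one/two-sample df conventions", {
  set.seed(9)
  n1 <- 21; n2 <- 19      # controls, patients
  masks <- list(DS = 1:5, PFC = 6:10)
  subs <- c(sprintf("c%02d", 1:n1), sprintf("p%02d", 1:n2))
  groups <- setNames(c(rep("control", n1), rep("patient", n2)), subs)
  contrasts <- lapply(subs, function(s) rnorm(10, mean = 0.5))
  names(contrasts) <- subs
  res <- contrast_and_group(contrasts, masks, groups,
                            group_order = c("control", "patient"))
  expect_identical(unique(res$df[res$test == "within:control"]), 20L)
  expect_identical(unique(res$df[res$test == "within:patient"]), 18L)
  expect_identical(unique(res$df[res$test == "between"]), 38L)
  # oracle: t.test agreement on one cell
  ds_vals <- vapply(contrasts, function(v) mean(v[1:5]), numeric(1))
  ctl <- ds_vals[groups == "control"]; pat <- ds_vals[groups == "patient"]
  tt <- t.test(ctl, mu = 0)
  row <- res[res$roi == "DS" & res$test == "within:control", ]
  expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
  tt2 <- t.test(ctl, pat, var.equal = TRUE)
  row2 <- res[res$roi == "DS" & res$test == "between", ]
  expect_equal(row2$t, unname(tt2$statistic), tolerance = 1e-10)
  expect_equal(row2$p, tt2$p.value, tolerance = 1e-10)
})

test_that("a condition effect injected in DS is localized to DS", {
  masks <- list(DS = 1:5, LOC = 6:10, PFC = 11:15, HIPP = 16:20)
  groups <- setNames(rep(c("control", "patient"), each = 10),
                     c(sprintf("c%02d", 1:10), sprintf("p%02d", 1:10)))
  hits_ds <- 0; hits_other <- 0; n_rep <- 20
  for (r in seq_len(n_rep)) {
    set.seed(400 + r)
    contrasts <- lapply(names(groups), function(s) {
      v <- rnorm(20, sd = 1)
      v[1:5] <- v[1:5] + 1.2      # DS effect only
      v
    })
    names(contrasts) <- names(groups)
    res <- contrast_and_group(contrasts, masks, groups)
    within <- res[grepl("^within", res$test), ]
    sig <- tapply(within$p < 0.05, within$roi, any)
    if (sig[["DS"]]) hits_ds <- hits_ds + 1
    if (any(sig[c("LOC", "PFC", "HIPP")])) hits_other <- hits_other + 1
  }
  expect_gte(hits_ds / n_rep, 0.9)
  expect_lt(hits_other / n_rep, 0.5)
})
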