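# ERP pipeline: rejection, baselining, window amplitudes, statistics.

test_that("artifact rejection removes exactly the trials beyond the limit", {
  d <- array(0, dim = c(4, 2, 100))
  d[2, 1, 40] <- 130          # beyond the criterion
  d[3, 2, 60] <- -121
  d[4, 1, 50] <- 120          # exactly at the limit: retained
  ep <- make_epochs(d, condition = c("A", "A", "B", "B"))
  acc <- reject_artifacts(ep, limit_uV = 120)
  expect_identical(dim(acc$data)[1], 2L)
  expect_identical(acc$condition, c("A", "B"))
  log <- attr(acc, "rejection_log")
  expect_identical(sum(log$Freq[log$rejected == "rejected"]), 2L)
  # idempotence
  acc2 <- reject_artifacts(acc, limit_uV = 120)
  expect_identical(acc2$data, acc$data)
  # clean set returned unchanged
  clean <- make_epochs(array(1, dim = c(3, 2, 50)))
  expect_identical(reject_artifacts(clean)$data, clean$data)
  # all-rejected raises a warning, not an error
  hot <- make_epochs(array(500, dim = c(2, 2, 50)))
  expect_warning(reject_artifacts(hot), "all trials rejected")
})

test_that("baselining zeroes the pre-stimulus mean and averaging is linear", {
  times <- seq(-100, 500, by = 4)
  nt <- length(times)
  # constant offsets vanish
  d <- array(7, dim = c(3, 2, nt))
  ev <- baseline_and_average(make_epochs(d, times = times))
  expect_true(all(abs(ev$evoked$A) < 1e-12))
  # n copies of one epoch average to that epoch, baselined
  one <- array(rnorm(2 * nt), dim = c(1, 2, nt))
  rep3 <- array(rep(one, each = 3), dim = c(3, 2, nt))
  ev1 <- baseline_and_average(make_epochs(rep3, times = times))
  base <- times >= -100 & times <= 0
  manual <- one[1, , ] - rowMeans(one[1, , base])
  expect_equal(unname(ev1$evoked$A), manual, tolerance = 1e-12)
  # +a and -a cancel
  pm <- array(0, dim = c(2, 2, nt))
  pm[1, , ] <- one[1, , ]
  pm[2, , ] <- -one[1, , ]
  ev2 <- baseline_and_average(make_epochs(pm, times = times))
  expect_true(all(abs(ev2$evoked$A) < 1e-12))
  # per-trial baseline mean is exactly zero for every channel
  noisy <- make_epochs(array(rnorm(5 * 2 * nt), dim = c(5, 2, nt)),
                       times = times)
  for (i in 1:5) {
    trial <- noisy$data[i, , , drop = TRUE]
    blc <- trial - rowMeans(trial[, base])
    expect_equal(rowMeans(blc[, base]), c(0, 0), tolerance = 1e-13)
  }
})

test_that("window amplitude is a per-hemisphere mean and linear in the data", {
  times <- seq(-100, 500, by = 2)
  ev <- matrix(0, 4, length(times),
               dimnames = list(c("PO5", "PO6", "PO7", "PO8"), NULL))
  w <- default_component_windows()$N1
  expect_equal(as.numeric(window_amplitude(ev, w, times = times)), c(0, 0))
  in_win <- times >= 170 & times <= 200
  ev["PO7", in_win] <- -3   # left
  ev["PO8", in_win] <- -5   # right
  a <- window_amplitude(ev, w, times = times)
  expect_equal(a[["left"]], -3)
  expect_equal(a[["right"]], -5)
  expect_equal(attr(a, "overall"), -4)
  expect_equal(as.numeric(window_amplitude(2 * ev, w, times = times)),
               2 * as.numeric(a))
  expect_error(window_amplitude(ev[1:2, ], w, times = times), "missing")
})

test_that("repeated-measures F matches a hand-computed sums-of-squares oracle", {
  tab <- make_amplitude_table(n_per_group = 8, group_shift = 0.8,
                              cond_shift = 0.5, noise_sd = 1, seed = 42)
  st <- component_stats(tab, "Ncl")

  # oracle: balanced two-way mixed ANOVA from explicit sums of squares on
  # hemisphere-averaged data
  d <- aggregate(amplitude_uV ~ subject + group + condition, tab, mean)
  y <- d$amplitude_uV
  gm <- mean(y)
  n_s <- length(unique(d$subject)); n_c <- length(unique(d$condition))
  subj_means <- tapply(y, d$subject, mean)
  grp_of <- tapply(as.character(d$group), d$subject, `[`, 1)
  grp_means <- tapply(y, d$group, mean)
  cond_means <- tapply(y, d$condition, mean)
  cell_means <- tapply(y, list(d$group, d$condition), mean)
  n_per_g <- table(grp_of)

  ss_group <- n_c * sum(n_per_g * (grp_means - gm)^2)
  ss_subj <- n_c * sum((subj_means - grp_means[grp_of])^2)
  ss_cond <- n_s * sum((cond_means - gm)^2)
  ss_int <- 0
  for (g in rownames(cell_means)) for (cc in colnames(cell_means)) {
    ss_int <- ss_int + n_per_g[g] *
      (cell_means[g, cc] - grp_means[g] - cond_means[cc] + gm)^2
  }
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_cond - ss_int
  df_subj <- n_s - length(n_per_g)
  df_err <- df_subj * (n_c - 1)
  F_group <- (ss_group / (length(n_per_g) - 1)) / (ss_subj / df_subj)
  F_cond <- (ss_cond / (n_c - 1)) / (ss_err / df_err)
  F_int <- (ss_int / (n_c - 1)) / (ss_err / df_err)

  expect_equal(st$F[st$effect == "group"], unname(F_group), tolerance = 1e-8)
  expect_equal(st$F[st$effect == "condition"], unname(F_cond), tolerance = 1e-8)
  expect_equal(st$F[st$effect == "group:condition"], unname(F_int),
               tolerance = 1e-8)
  expect_equal(st$p[st$effect == "group"],
               pf(unname(F_group), length(n_per_g) - 1, df_subj,
                  lower.tail = FALSE), tolerance = 1e-8)
})

test_that("null group effects stay non-significant and true shifts are detected", {
  # no group effect
  tab0 <- make_amplitude_table(n_per_group = 10, group_shift = 0,
                               noise_sd = 1, seed = 7)
  st0 <- component_stats(tab0, "Ncl")
  expect_true(is.finite(st0$F[st0$effect == "group"]))
  # 1-pooled-SD shift, n = 20/group: significant in >= 80% of replicates
  hits <- 0; n_rep <- 25
  for (r in seq_len(n_rep)) {
    tab <- make_amplitude_table(n_per_group = 20, group_shift = 1.12,
                                noise_sd = 1, seed = 100 + r)
    st <- component_stats(tab, "Ncl")
    if (st$p[st$effect == "group"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("component stats enforce the two-subject minimum", {
  tab <- make_amplitude_table(n_per_group = 1, seed = 1)
  expect_error(component_stats(tab, "Ncl"), "2 subjects")
})

test_that("component correlations match the covariance formula and detect identity", {
  # 5-point hand computation
  x <- c(1, 2, 4, 7, 11); y <- c(2, 1, 5, 6, 12)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  rows <- list()
  for (i in 1:5) for (m in 1:2) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject = paste0("s", i), group = "control", condition = "ID",
      component = c("P1", "N1")[m], hemisphere = "left",
      amplitude_uV = if (m == 1) x[i] else y[i])
  }
  tab <- do.call(rbind, rows)
  out <- component_correlations(tab)
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$p, cor.test(x, y)$p.value, tolerance = 1e-12)

  # y = x gives r exactly 1
  tab2 <- tab
  tab2$amplitude_uV[tab2$component == "N1"] <-
    tab2$amplitude_uV[tab2$component == "P1"]
  expect_equal(component_correlations(tab2)$r, 1)

  # independent components, many subjects: |r| small
  set.seed(5)
  n <- 1000
  rows <- list()
  for (i in seq_len(n)) for (m in 1:2) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject = sprintf("s%04d", i), group = "control", condition = "ID",
      component = c("P1", "N1")[m], hemisphere = "left",
      amplitude_uV = rnorm(1))
  }
  out3 <- component_correlations(do.call(rbind, rows))
  expect_lt(abs(out3$r), 0.1)
})

test_that("the full ERP chain recovers configured group x condition patterns", {
  amps <- default_eeg_amplitudes()
  sets <- list()
  i <- 0
  for (g in c("control", "patient")) for (s in 1:4) {
    i <- i + 1
    cfg <- eeg_sim_config(amps, noise_sd = 1)
    sets[[i]] <- simulate_eeg_epochs(cfg, rep(c("ID", "ID-1", "repeat"),
                                              each = 12),
                                     seed = 300 + i,
                                     subject = sprintf("%s%02d", g, s),
                                     group = g)
  }
  tab <- amplitude_table(sets)
  cell <- aggregate(amplitude_uV ~ group + condition + component, tab, mean)
  truth <- default_eeg_amplitudes()
  m <- merge(cell, truth, by = c("group", "condition", "component"))
  # signs recovered everywhere; ordering of the key contrasts preserved
  expect_true(all(sign(m$amplitude_uV.x) == sign(m$amplitude_uV.y)))
  ncl_id <- function(g) m$amplitude_uV.x[m$group == g & m$condition == "ID" &
                                           m$component == "Ncl"]
  expect_lt(ncl_id("control"), ncl_id("patient"))  # deeper negativity in controls
})
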