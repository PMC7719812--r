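# EEG and BOLD simulators: injection identities, linearity, determinism.

test_that("noise-free epochs return configured window amplitudes exactly", {
  amps <- data.frame(condition = "ID", component = c("P1", "N1", "Ncl"),
                     amplitude_uV = c(2.5, -3, -1.5))
  cfg <- eeg_sim_config(amps, noise_sd = 0)
  ep <- simulate_eeg_epochs(cfg, c("ID", "ID"), seed = 1)
  ev <- baseline_and_average(ep)
  w <- default_component_windows()
  for (i in seq_len(nrow(amps))) {
    a <- window_amplitude(ev$evoked$ID, w[[amps$component[i]]],
                          times = ev$times)
    expect_equal(attr(a, "overall"), amps$amplitude_uV[i], tolerance = 1e-6)
  }
})

test_that("component injection is linear and zero config gives zero epochs", {
  amps0 <- data.frame(condition = "A", component = "N1", amplitude_uV = 0)
  cfg0 <- eeg_sim_config(amps0, noise_sd = 0)
  ep0 <- simulate_eeg_epochs(cfg0, "A", seed = 1)
  expect_true(all(ep0$data == 0))

  mk <- function(a) {
    cfg <- eeg_sim_config(data.frame(condition = "A", component = "N1",
                                     amplitude_uV = a), noise_sd = 0)
    simulate_eeg_epochs(cfg, "A", seed = 1)$data
  }
  expect_equal(mk(-4), 2 * mk(-2))
})

test_that("window-mean estimate over noisy trials lands within 3 SEM", {
  amps <- data.frame(condition = "A", component = "N1", amplitude_uV = -3)
  noise_sd <- 5
  cfg <- eeg_sim_config(amps, noise_sd = noise_sd)
  n_trials <- 100
  ep <- simulate_eeg_epochs(cfg, rep("A", n_trials), seed = 21)
  ev <- baseline_and_average(ep)
  a <- attr(window_amplitude(ev$evoked$A, default_component_windows()$N1,
                             times = ev$times), "overall")
  # SEM of the window mean: baselining + averaging over trials, samples and
  # electrodes leaves sd <= noise_sd / sqrt(n_trials) per channel-sample;
  # use the conservative per-trial bound
  sem <- noise_sd / sqrt(n_trials)
  expect_lt(abs(a - (-3)), 3 * sem)
})

test_that("EEG simulation is reproducible and respects montage checks", {
  amps <- data.frame(condition = "A", component = "P1", amplitude_uV = 1)
  cfg <- eeg_sim_config(amps, noise_sd = 2)
  e1 <- simulate_eeg_epochs(cfg, c("A", "A"), seed = 4)
  e2 <- simulate_eeg_epochs(cfg, c("A", "A"), seed = 4)
  expect_identical(e1$data, e2$data)
  expect_error(eeg_sim_config(amps, channels = c("PO5", "PO6")), "PO7")
  expect_error(eeg_sim_config(amps, sfreq = 128), "sfreq")
})

test_that("epoch sets round-trip through the array + sidecar container", {
  amps <- data.frame(condition = c("A", "B"), component = "N1",
                     amplitude_uV = c(-1, -2))
  cfg <- eeg_sim_config(amps, noise_sd = 1)
  ep <- simulate_eeg_epochs(cfg, c("A", "B", "A"), seed = 2,
                            subject = "s05", group = "patient")
  tmp <- withr::local_tempdir()
  write_epochs(ep, file.path(tmp, "ep.tsv"))
  back <- read_epochs(file.path(tmp, "ep.tsv"))
  expect_equal(back$data, ep$data, tolerance = 1e-12)
  expect_identical(back$condition, ep$condition)
  expect_identical(back$subject, "s05")
})

test_that("a zero network with no noise or input yields all-zero series", {
  net <- network_model(matrix(0, 4, 4), sigma_u = 0)
  bc <- bold_sim_config(hrf = "identity", noise_sd = 0)
  des <- build_fmri_session(2, 3, 1)
  sim <- simulate_network_bold(net, bc, des, seed = 1)
  expect_true(all(sim$latents == 0))
  expect_true(all(sim$volume == 0))
})

test_that("unstable networks are rejected with the spectral radius named", {
  A <- diag(1.05, 4)
  expect_error(network_model(A), "spectral radius")
})

test_that("BOLD simulation is bit-reproducible for identical seeds", {
  net <- single_edge_network()
  bc <- bold_sim_config(noise_sd = 0.4)
  des <- build_fmri_session(2, 3, 1)
  s1 <- simulate_network_bold(net, bc, des, seed = 10)
  s2 <- simulate_network_bold(net, bc, des, seed = 10)
  expect_identical(s1$volume, s2$volume)
  s3 <- simulate_network_bold(net, bc, des, seed = 11)
  expect_false(identical(s1$volume, s3$volume))
})

test_that("with zero coupling, distinct ROI latents are uncorrelated at lag 1", {
  net <- network_model(matrix(0, 4, 4), sigma_u = 1)
  bc <- bold_sim_config(hrf = "identity", noise_sd = 0)
  des <- build_fmri_session(52, 3, 1)   # 2028 TRs
  sim <- simulate_network_bold(net, bc, des, seed = 3)
  x <- sim$latents
  n <- nrow(x)
  for (pair in list(c(1, 2), c(2, 3), c(1, 4))) {
    r <- cor(x[-n, pair[1]], x[-1, pair[2]])
    expect_lt(abs(r), 0.1)
  }
})

test_that("ROI masks are validated and ground truth is emitted", {
  expect_error(bold_sim_config(grid_dim = c(4, 2, 2),
                               roi_masks = list(DS = 1:3, LOC = 3:5)),
               "disjoint")
  expect_error(bold_sim_config(grid_dim = c(4, 2, 2),
                               roi_masks = list(DS = integer(0), LOC = 2L)),
               "nonempty")
  net <- single_edge_network(a = 0.3)
  bc <- bold_sim_config()
  sim <- simulate_network_bold(net, bc, build_fmri_session(1, 3, 1), 5)
  expect_equal(sim$ground_truth$A_eff[[1]]["PFC", "DS"], 0.3)
  expect_equal(sim$ground_truth$A[[1]]["PFC", "DS"], -0.3)
})
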