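# Synthetic epoched EEG with known component amplitudes.

#' Configure the EEG simulator
#'
#' Each simulated epoch is a sum of Gaussian-bump components (one per row of
#' the amplitude table that matches the trial's condition) injected at the
#' component's electrodes, plus white Gaussian noise on every channel. Bumps
#' are centered on the component's peak latency with a temporal spread
#' `bump_sd_ms` and scaled so that the mean over the component's measurement
#' window equals the configured amplitude exactly; window-mean extraction is
#' therefore an identity in the noise-free case.
#'
#' @param amplitudes Data frame with columns `condition`, `component`,
#'   `amplitude_uV` (optionally `group`). Signed amplitudes: negative for
#'   N1/Ncl by convention.
#' @param sfreq Sampling rate in Hz (>= 256; default 512).
#' @param channels Channel names; must include PO5, PO6, PO7, PO8.
#' @param window_ms Epoch extent `c(lo, hi)` in ms (default -100..500).
#' @param components Component windows as from [default_component_windows()].
#' @param noise_sd White-noise standard deviation in microvolts.
#' @param n_trials Trials per condition label occurrence (used by callers
#'   that expand labels; the simulator itself takes explicit labels).
#' @param bump_sd_ms Gaussian bump standard deviation in ms (default 10,
#'   i.e. full width at half maximum about 23 ms).
#' @return An object of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(amplitudes,
                           sfreq = 512,
                           channels = c("PO5", "PO6", "PO7", "PO8",
                                        "O1", "O2", "Pz", "Cz"),
                           window_ms = c(-100, 500),
                           components = default_component_windows(),
                           noise_sd = 5,
                           n_trials = 60,
                           bump_sd_ms = 10) {
  stopifnot(is.data.frame(amplitudes),
            all(c("condition", "component", "amplitude_uV") %in%
                  names(amplitudes)))
  if (sfreq < 256) stop("'sfreq' must be >= 256 Hz")
  req <- c("PO5", "PO6", "PO7", "PO8")
  if (!all(req %in% channels)) {
    stop("'channels' must include ", paste(req, collapse = ", "))
  }
  for (cw in components) {
    pk <- attr(cw, "peak_ms")
    if (!is.null(pk) && (pk < cw$window_ms[1] || pk > cw$window_ms[2])) {
      stop("component peak must lie inside its window: ", cw$name)
    }
    if (cw$window_ms[1] < window_ms[1] || cw$window_ms[2] > window_ms[2]) {
      stop("component window outside epoch extent: ", cw$name)
    }
  }
  structure(list(amplitudes = amplitudes, sfreq = sfreq, channels = channels,
                 window_ms = as.numeric(window_ms), components = components,
                 noise_sd = noise_sd, n_trials = n_trials,
                 bump_sd_ms = bump_sd_ms),
            class = "eeg_sim_config")
}

#' Simulate an epoch set
#'
#' @param config An [eeg_sim_config()].
#' @param condition_labels Character vector, one label per trial to simulate.
#' @param seed Integer seed.
#' @param subject,group Metadata attached to the result; if the amplitude
#'   table has a `group` column only its rows for `group` are used.
#' @return An [epoch_set()].
#' @export
simulate_eeg_epochs <- function(config, condition_labels, seed,
                                subject = "s01", group = "control") {
  stopifnot(inherits(config, "eeg_sim_config"))
  amp <- config$amplitudes
  if ("group" %in% names(amp)) amp <- amp[amp$group == group, , drop = FALSE]

  times <- seq(config$window_ms[1], config$window_ms[2],
               by = 1000 / config$sfreq)
  n_ch <- length(config$channels)
  n_tr <- length(condition_labels)
  rng <- local_rng(seed)

  # per-component unit waveform: window mean normalized to 1
  unit_wave <- lapply(config$components, function(cw) {
    pk <- attr(cw, "peak_ms")
    g <- exp(-(times - pk)^2 / (2 * config$bump_sd_ms^2))
    in_win <- times >= cw$window_ms[1] & times <= cw$window_ms[2]
    g / mean(g[in_win])
  })

  data <- array(0, dim = c(n_tr, n_ch, length(times)))
  for (tr in seq_len(n_tr)) {
    signal <- matrix(0, n_ch, length(times))
    rows <- amp[amp$condition == condition_labels[tr], , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      comp <- rows$component[r]
      cw <- config$components[[comp]]
      if (is.null(cw)) stop("unknown component in amplitude table: ", comp)
      ch_idx <- match(cw$electrodes, config$channels)
      signal[ch_idx, ] <- signal[ch_idx, ] +
        rep(rows$amplitude_uV[r] * unit_wave[[comp]], each = length(ch_idx))
    }
    if (config$noise_sd > 0) {
      signal <- signal + matrix(rng$rnorm(n_ch * length(times),
                                          sd = config$noise_sd),
                                n_ch, length(times))
    }
    data[tr, , ] <- signal
  }
  epoch_set(data, times, config$channels, condition_labels,
            subject = subject, group = group, sfreq = config$sfreq)
}
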