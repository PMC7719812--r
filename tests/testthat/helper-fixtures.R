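# Shared fixture builders. Everything is generated in code at test time.

make_pictures <- function(n = 10, n_segments = 100) {
  lapply(seq_len(n), function(i)
    picture(sprintf("pic%02d", i), n_segments))
}

# A tiny epoch set built from an explicit array.
make_epochs <- function(data, times = NULL, channels = NULL,
                        condition = NULL, ...) {
  d <- dim(data)
  if (is.null(times)) times <- seq(-100, 500, length.out = d[3])
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[2]))
  if (is.null(condition)) condition <- rep("A", d[1])
  epoch_set(data, times, channels, condition, ...)
}

# Simulate a bivariate system y[n] = a * x[n-1] + e[n] with unit-variance
# white x and e (the closed-form Geweke example).
make_lagged_pair <- function(n, a = 1, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  y <- a * c(0, x[-n]) + e
  list(x = x, y = y)
}

# Independent oracle for the Geweke measures: explicit lm() regressions with
# residual variances normalized by the number of target samples. Optional
# segments: per-segment standardization, lagged pairs only within segments.
geweke_oracle <- function(x, y, p, segments = NULL) {
  n <- length(x)
  if (is.null(segments)) segments <- list(seq_len(n))
  for (seg in segments) {
    x[seg] <- (x[seg] - mean(x[seg])) / sd(x[seg])
    y[seg] <- (y[seg] - mean(y[seg])) / sd(y[seg])
  }
  idx <- unlist(lapply(segments, function(s) s[-seq_len(p)]))
  lag_mat <- function(v) sapply(seq_len(p), function(i) v[idx - i])
  Xl <- lag_mat(x); Yl <- lag_mat(y)
  n_eff <- length(idx)
  rv <- function(fit) sum(resid(fit)^2) / n_eff
  f_y_own <- lm(y[idx] ~ Yl + 0)
  f_x_own <- lm(x[idx] ~ Xl + 0)
  f_y_both <- lm(y[idx] ~ Yl + Xl + 0)
  f_x_both <- lm(x[idx] ~ Yl + Xl + 0)
  s12 <- sum(resid(f_x_both) * resid(f_y_both)) / n_eff
  detj <- rv(f_x_both) * rv(f_y_both) - s12^2
  list(F_x_to_y = log(rv(f_y_own) / rv(f_y_both)),
       F_y_to_x = log(rv(f_x_own) / rv(f_x_both)),
       F_instantaneous = log(rv(f_x_both) * rv(f_y_both) / detj),
       F_total = log(rv(f_x_own) * rv(f_y_own) / detj))
}

# Amplitude table with configurable group/condition effects, built directly
# (no EEG simulation) for statistics tests.
make_amplitude_table <- function(n_per_group = 10, group_shift = 0,
                                 cond_shift = 0, noise_sd = 1, seed = 1,
                                 component = "Ncl",
                                 conditions = c("ID", "ID-1")) {
  set.seed(seed)
  rows <- list()
  for (g in c("control", "patient")) {
    for (s in seq_len(n_per_group)) {
      subj <- paste0(substr(g, 1, 3), s)
      subj_eff <- rnorm(1, sd = noise_sd / 2)
      for (cc in conditions) for (h in c("left", "right")) {
        mu <- subj_eff +
          (g == "patient") * group_shift +
          (cc == conditions[1]) * cond_shift
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, group = g, condition = cc,
          component = component, hemisphere = h,
          amplitude_uV = mu + rnorm(1, sd = noise_sd),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

# Single-edge network: `from` drives `to` with lag-1 coupling a.
single_edge_network <- function(from = "DS", to = "PFC", a = 0.35,
                                group = "control") {
  nodes <- c("DS", "LOC", "PFC", "HIPP")
  A <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  A[to, from] <- a
  network_model(A, sigma_u = 1, nodes = nodes, group = group,
                convention = "regression")
}
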