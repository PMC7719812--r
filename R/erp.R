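# ERP pipeline: artifact rejection, baselining/averaging, component-window
# amplitude extraction, and group/condition statistics.

#' Reject epochs exceeding an absolute amplitude criterion
#'
#' A trial is rejected iff any channel exceeds `|v| > limit_uV` strictly at
#' any sample inside `window_ms`. Trials that touch the limit exactly are
#' retained.
#'
#' @param epochs An [epoch_set()].
#' @param limit_uV Rejection threshold in microvolts (default 120).
#' @param window_ms Window screened for artifacts (default -100..500 ms).
#' @return The accepted [epoch_set()] with a `rejection_log` attribute: a
#'   data frame of kept/rejected counts per condition. If every trial is
#'   rejected a warning is raised and the (empty) set still carries the log.
#' @export
reject_artifacts <- function(epochs, limit_uV = 120,
                             window_ms = c(-100, 500)) {
  stopifnot(inherits(epochs, "epoch_set"))
  step <- stats::median(diff(epochs$times))
  if (window_ms[1] < min(epochs$times) - step / 2 ||
      window_ms[2] > max(epochs$times) + step) {
    stop("artifact window outside epoch extent")
  }
  in_win <- epochs$times >= window_ms[1] & epochs$times <= window_ms[2]
  n_tr <- dim(epochs$data)[1]
  bad <- vapply(seq_len(n_tr), function(i) {
    max(abs(epochs$data[i, , in_win])) > limit_uV
  }, logical(1))

  log <- as.data.frame(table(condition = epochs$condition,
                             rejected = factor(bad, levels = c(FALSE, TRUE),
                                               labels = c("kept", "rejected"))))
  out <- epochs
  out$data <- epochs$data[!bad, , , drop = FALSE]
  out$condition <- epochs$condition[!bad]
  attr(out, "rejection_log") <- log
  if (all(bad)) warning("all trials rejected by the artifact criterion")
  out
}

#' Baseline-correct and average epochs by condition
#'
#' Subtracts each trial's per-channel mean over the pre-stimulus interval
#' (-100..0 ms), then averages trials within each condition.
#'
#' @param epochs An [epoch_set()].
#' @param baseline_ms Baseline interval (default `c(-100, 0)`).
#' @return An object of class `evoked_set`: list with `evoked` (named list of
#'   channels x time matrices, one per condition), `n_trials` per condition,
#'   `times`, `channels`, `subject`, `group`. Conditions with zero accepted
#'   trials are reported in `missing`.
#' @export
baseline_and_average <- function(epochs, baseline_ms = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  base_idx <- epochs$times >= baseline_ms[1] & epochs$times <= baseline_ms[2]
  if (!any(base_idx)) stop("baseline interval contains no samples")
  conds <- unique(epochs$condition)
  evoked <- list(); n_trials <- integer(0); missing <- character(0)
  for (cc in conds) {
    sel <- which(epochs$condition == cc)
    if (length(sel) == 0L) { missing <- c(missing, cc); next }
    acc <- matrix(0, dim(epochs$data)[2], dim(epochs$data)[3])
    for (i in sel) {
      trial <- epochs$data[i, , , drop = TRUE]
      trial <- trial - rowMeans(trial[, base_idx, drop = FALSE])
      acc <- acc + trial
    }
    m <- acc / length(sel)
    rownames(m) <- epochs$channels
    evoked[[cc]] <- m
    n_trials[cc] <- length(sel)
  }
  structure(list(evoked = evoked, n_trials = n_trials, missing = missing,
                 times = epochs$times, channels = epochs$channels,
                 subject = epochs$subject, group = epochs$group),
            class = "evoked_set")
}

#' Mean amplitude of an evoked response in a component window
#'
#' Averages the evoked response over the window's samples and electrodes,
#' reported separately per hemisphere (odd electrode numbers = left, even =
#' right).
#'
#' @param evoked A channels x time matrix (rownames = channels) or an
#'   `evoked_set` element; `times` must be supplied for a bare matrix.
#' @param window A [component_window()].
#' @param times Sample times in ms (taken from an `evoked_set` if given one).
#' @return Named numeric vector `c(left = ..., right = ...)` in microvolts,
#'   with the all-electrode mean as attribute `"overall"`.
#' @export
window_amplitude <- function(evoked, window, times = NULL) {
  stopifnot(inherits(window, "component_window"))
  if (is.null(times)) stop("'times' must be provided")
  if (window$window_ms[1] < min(times) || window$window_ms[2] > max(times)) {
    stop("component window outside data extent")
  }
  if (!all(window$electrodes %in% rownames(evoked))) {
    stop("window electrodes missing from montage: ",
         paste(setdiff(window$electrodes, rownames(evoked)), collapse = ", "))
  }
  in_win <- times >= window$window_ms[1] & times <= window$window_ms[2]
  sub <- evoked[window$electrodes, in_win, drop = FALSE]
  hemi <- electrode_hemisphere(window$electrodes)
  out <- c(left = mean(sub[hemi == "left", , drop = FALSE]),
           right = mean(sub[hemi == "right", , drop = FALSE]))
  attr(out, "overall") <- mean(sub)
  out
}

#' Build an amplitude table across subjects
#'
#' Runs rejection, baselining/averaging and window extraction for each
#' subject's epoch set and collects one row per subject x condition x
#' component x hemisphere.
#'
#' @param epoch_sets List of [epoch_set()] objects (one per subject).
#' @param windows Component windows (default [default_component_windows()]).
#' @param limit_uV Artifact criterion passed to [reject_artifacts()].
#' @return Data frame with columns `subject`, `group`, `condition`,
#'   `component`, `hemisphere`, `amplitude_uV`.
#' @export
amplitude_table <- function(epoch_sets, windows = default_component_windows(),
                            limit_uV = 120) {
  rows <- list()
  for (es in epoch_sets) {
    acc <- reject_artifacts(es, limit_uV = limit_uV)
    ev <- baseline_and_average(acc)
    for (cc in names(ev$evoked)) {
      for (w in windows) {
        amp <- window_amplitude(ev$evoked[[cc]], w, times = ev$times)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = es$subject, group = es$group, condition = cc,
          component = w$name, hemisphere = names(amp),
          amplitude_uV = as.numeric(amp), stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Group and condition statistics for one ERP component
#'
#' Univariate repeated-measures F tests with group as the between-subject
#' factor and condition as the within-subject factor (hemispheres averaged
#' first by default, mirroring collapsed bar-chart reporting). The group
#' effect is tested against between-subject error, condition and
#' group x condition against the subject-by-condition error stratum. Effect
#' sizes are Cohen's d from cell means and the pooled SD.
#'
#' @param table Amplitude table from [amplitude_table()].
#' @param component Which component to analyze (e.g. "Ncl").
#' @param conditions Optional subset/order of condition labels.
#' @param collapse_hemispheres Average left/right before testing (default
#'   TRUE); otherwise hemisphere becomes a second within-subject factor.
#' @return Data frame with one row per effect (`group`, `condition`,
#'   `group:condition`): `F`, `df1`, `df2`, `p`, `cohens_d` (NA for effects
#'   with more than two levels), flagged `formulation = "univariate rm"`.
#' @export
component_stats <- function(table, component,
                            conditions = NULL,
                            collapse_hemispheres = TRUE) {
  dat <- table[table$component == component, , drop = FALSE]
  if (!is.null(conditions)) dat <- dat[dat$condition %in% conditions, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no rows for component ", component)
  if (collapse_hemispheres) {
    dat <- stats::aggregate(amplitude_uV ~ subject + group + condition,
                            data = dat, FUN = mean)
  }
  # listwise completeness per subject
  n_cond <- length(unique(dat$condition))
  counts <- table(dat$subject)
  per_hemi <- if (collapse_hemispheres) 1L else 2L
  complete <- names(counts)[counts == n_cond * per_hemi]
  dropped <- setdiff(unique(dat$subject), complete)
  dat <- dat[dat$subject %in% complete, , drop = FALSE]
  if (length(unique(dat$group)) < 2L ||
      min(table(unique(dat[, c("subject", "group")])$group)) < 2L) {
    stop("need at least 2 subjects per group")
  }
  dat$subject <- factor(dat$subject)
  dat$group <- factor(dat$group)
  dat$condition <- factor(dat$condition)

  form <- if (collapse_hemispheres) {
    amplitude_uV ~ group * condition + Error(subject / condition)
  } else {
    dat$hemisphere <- factor(dat$hemisphere)
    amplitude_uV ~ group * condition * hemisphere +
      Error(subject / (condition * hemisphere))
  }
  fit <- stats::aov(form, data = dat)
  sm <- summary(fit)

  extract <- function(effect) {
    for (stratum in sm) {
      tab <- stratum[[1]]
      rn <- trimws(rownames(tab))
      hit <- match(effect, rn)
      if (!is.na(hit) && !is.na(tab[hit, "F value"])) {
        resid_row <- match("Residuals", rn)
        return(c(F = tab[hit, "F value"], df1 = tab[hit, "Df"],
                 df2 = tab[resid_row, "Df"],
                 p = tab[hit, "Pr(>F)"]))
      }
    }
    c(F = NA, df1 = NA, df2 = NA, p = NA)
  }

  pooled_sd <- stats::sd(dat$amplitude_uV -
                           stats::ave(dat$amplitude_uV, dat$group,
                                      dat$condition))
  d_group <- {
    gm <- tapply(dat$amplitude_uV, dat$group, mean)
    if (length(gm) == 2L && pooled_sd > 0) abs(diff(gm)) / pooled_sd else NA
  }
  d_cond <- {
    cm <- tapply(dat$amplitude_uV, dat$condition, mean)
    if (length(cm) == 2L && pooled_sd > 0) abs(diff(cm)) / pooled_sd else NA
  }

  effects <- c("group", "condition", "group:condition")
  res <- t(vapply(effects, extract, numeric(4)))
  out <- data.frame(effect = effects, res,
                    cohens_d = c(d_group, d_cond, NA),
                    formulation = "univariate rm",
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dropped_subjects") <- dropped
  out
}

#' Pairwise correlations between component amplitudes, per group
#'
#' Pearson correlations (with two-tailed p) between per-subject component
#' amplitudes for every pair of component x condition measures, computed
#' separately within each group.
#'
#' @param table Amplitude table from [amplitude_table()]; hemispheres are
#'   averaged per subject before correlating.
#' @return Data frame with columns `group`, `measure1`, `measure2`, `n`,
#'   `r`, `p`.
#' @export
component_correlations <- function(table) {
  dat <- stats::aggregate(amplitude_uV ~ subject + group + condition + component,
                          data = table, FUN = mean)
  dat$measure <- paste(dat$condition, dat$component, sep = ".")
  out <- list()
  for (g in unique(dat$group)) {
    sub <- dat[dat$group == g, ]
    wide <- stats::reshape(sub[, c("subject", "measure", "amplitude_uV")],
                           idvar = "subject", timevar = "measure",
                           direction = "wide")
    meas <- sub("^amplitude_uV\\.", "", names(wide)[-1])
    mat <- as.matrix(wide[, -1, drop = FALSE])
    if (nrow(mat) < 3L) stop("need at least 3 subjects per group")
    for (i in seq_along(meas)) for (j in seq_along(meas)) {
      if (j <= i) next
      ct <- stats::cor.test(mat[, i], mat[, j])
      out[[length(out) + 1L]] <- data.frame(
        group = g, measure1 = meas[i], measure2 = meas[j],
        n = sum(stats::complete.cases(mat[, c(i, j)])),
        r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
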