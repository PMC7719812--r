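# Behavioral observer model for the ascending-method-of-limits closure task.

#' Construct an observer model
#'
#' A logistic psychometric observer for fragmented-picture identification.
#' Identification probability increases with image completeness, i.e.
#' decreases with fragmentation level:
#' `p(yes | level) = lapse/2 + (1 - lapse) * plogis(slope * (threshold - level))`
#' where `threshold` is `threshold_level` for novel sequences and
#' `threshold_level + priming_shift` for repeats — repetition priming lets
#' the observer identify at a more fragmented level. `slope = Inf` gives a
#' deterministic step observer that says yes iff `level <= threshold`.
#'
#' @param threshold_level Fragmentation level at 50% identification.
#' @param slope Positive psychometric slope (per level); `Inf` allowed.
#' @param priming_shift Threshold shift (levels, >= 0) applied to repeats.
#' @param lapse Lapse rate in \[0, 1).
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(threshold_level, slope = 4, priming_shift = 0,
                           lapse = 0) {
  stopifnot(is.numeric(threshold_level), length(threshold_level) == 1L,
            is.numeric(slope), slope > 0,
            is.numeric(priming_shift), priming_shift >= 0,
            is.numeric(lapse), lapse >= 0, lapse < 1)
  structure(list(threshold_level = threshold_level, slope = slope,
                 priming_shift = priming_shift, lapse = lapse),
            class = "observer_model")
}

p_identify <- function(observer, level, primed) {
  thr <- observer$threshold_level + if (primed) observer$priming_shift else 0
  if (is.infinite(observer$slope)) {
    p <- as.numeric(level <= thr)
  } else {
    p <- stats::plogis(observer$slope * (thr - level))
  }
  observer$lapse / 2 + (1 - observer$lapse) * p
}

#' Simulate AML behavior on ERP block designs
#'
#' Runs the ascending method of limits: within each picture sequence the
#' levels of the block's level schedule (most fragmented first) are presented
#' until the observer responds "yes", which terminates the sequence. Repeated
#' sequences use the primed threshold.
#'
#' @param observer An [observer_model()].
#' @param blocks A single `erp_block_design` or a list of them.
#' @param seed Integer seed.
#' @return Data frame with one row per presented image: `block`, `slot`,
#'   `picture_id`, `is_repeat`, `level`, `response` ("yes"/"no"), and
#'   `identified_level` (the level at which the sequence terminated, NA if
#'   never identified; constant within a sequence).
#' @export
simulate_behavior <- function(observer, blocks, seed) {
  if (!inherits(observer, "observer_model")) stop("'observer' must be an observer_model")
  if (inherits(blocks, "erp_block_design")) blocks <- list(blocks)
  if (!all(vapply(blocks, inherits, logical(1), "erp_block_design"))) {
    stop("'blocks' must be erp_block_design objects")
  }
  rng <- local_rng(seed)
  rows <- list()
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    levels_sched <- attr(blk, "level_schedule")
    for (i in seq_len(nrow(blk))) {
      id_level <- NA_integer_
      seq_rows <- list()
      for (lev in levels_sched) {
        p <- p_identify(observer, lev, primed = blk$is_repeat[i])
        yes <- rng$runif(1) < p
        seq_rows[[length(seq_rows) + 1L]] <- data.frame(
          block = b, slot = blk$slot[i], picture_id = blk$picture_id[i],
          is_repeat = blk$is_repeat[i], level = lev,
          response = if (yes) "yes" else "no",
          stringsAsFactors = FALSE
        )
        if (yes) { id_level <- lev; break }
      }
      seq_df <- do.call(rbind, seq_rows)
      seq_df$identified_level <- id_level
      rows[[length(rows) + 1L]] <- seq_df
    }
  }
  do.call(rbind, rows)
}

#' Fit an observer threshold from AML response data
#'
#' Maximum-likelihood fit of the logistic observer to simulated or recorded
#' AML responses, honoring the sequential stopping rule (each presented image
#' contributes one Bernoulli term; unpresented levels contribute nothing).
#'
#' @param responses Data frame from [simulate_behavior()] (columns `level`,
#'   `response`, `is_repeat`).
#' @param fit_priming If TRUE also estimate the priming shift from repeats.
#' @return List with `threshold_level`, `slope`, and (if requested)
#'   `priming_shift`, plus the negative log-likelihood `nll`.
#' @export
fit_observer_threshold <- function(responses, fit_priming = FALSE) {
  stopifnot(all(c("level", "response", "is_repeat") %in% names(responses)))
  yes <- responses$response == "yes"
  lev <- responses$level
  rep_ <- responses$is_repeat
  nll <- function(par) {
    thr <- par[1]; slope <- exp(par[2])
    shift <- if (fit_priming) exp(par[3]) else 0
    p <- stats::plogis(slope * (thr + shift * rep_ - lev))
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(ifelse(yes, log(p), log(1 - p)))
  }
  init <- c(mean(lev[yes]), log(2), if (fit_priming) log(0.5))
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  out <- list(threshold_level = fit$par[1], slope = exp(fit$par[2]),
              nll = fit$value)
  if (fit_priming) out$priming_shift <- exp(fit$par[3])
  out
}

#' Modal level of closure
#'
#' The participant-level summary used to pick the fragmentation level for
#' the primed fMRI condition: the mode of the per-sequence identification
#' levels (ties resolved toward the more fragmented level).
#'
#' @param responses Data frame from [simulate_behavior()].
#' @return Integer modal identification level (NA if nothing identified).
#' @export
modal_closure_level <- function(responses) {
  per_seq <- unique(responses[, c("block", "slot", "identified_level")])
  lv <- per_seq$identified_level
  lv <- lv[!is.na(lv)]
  if (length(lv) == 0L) return(NA_integer_)
  tab <- table(lv)
  winners <- as.integer(names(tab)[tab == max(tab)])
  max(winners)  # more fragmented = higher level
}
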