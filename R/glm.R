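# First-level GLM with canonical-HRF boxcar regressors, contrasts, ROI
# summaries, and second-level within/between-group t tests.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response minus scaled undershoot),
#' sampled at the TR and normalized to unit peak. Defaults follow the common
#' canonical parameterization: response peak 6 s, undershoot peak 16 s, unit
#' dispersions, peak:undershoot ratio 1/6, 32 s support.
#'
#' @param tr_s Sampling interval in seconds (default 2).
#' @param peak_s Response gamma shape (seconds; default 6).
#' @param undershoot_s Undershoot gamma shape (seconds; default 16).
#' @param disp_s,u_disp_s Dispersions of the two gammas (default 1 s).
#' @param ratio Undershoot amplitude relative to the response (default 1/6).
#' @param length_s Kernel support in seconds (default 32).
#' @return An object of class `hrf`: list with `kernel` (sampled impulse
#'   response starting at lag 0), `times_s`, and `params`.
#' @export
canonical_hrf <- function(tr_s = 2, peak_s = 6, undershoot_s = 16,
                          disp_s = 1, u_disp_s = 1, ratio = 1 / 6,
                          length_s = 32) {
  if (disp_s <= 0 || u_disp_s <= 0) stop("dispersions must be positive")
  t <- seq(0, length_s, by = tr_s)
  h <- stats::dgamma(t, shape = peak_s / disp_s, rate = 1 / disp_s) -
    ratio * stats::dgamma(t, shape = undershoot_s / u_disp_s,
                          rate = 1 / u_disp_s)
  h <- h / max(h)
  structure(list(kernel = h, times_s = t,
                 params = list(tr_s = tr_s, peak_s = peak_s,
                               undershoot_s = undershoot_s, disp_s = disp_s,
                               u_disp_s = u_disp_s, ratio = ratio,
                               length_s = length_s)),
            class = "hrf")
}

#' Build a first-level design matrix from a session schedule
#'
#' One regressor per non-rest condition: the condition's boxcar (1 during
#' its TRs) convolved causally with the HRF kernel, plus an intercept and
#' polynomial drift columns.
#'
#' @param design A `session_design` from [build_fmri_session()].
#' @param hrf An [canonical_hrf()] object (its `tr_s` should match the
#'   schedule's TR).
#' @param drift_order Polynomial drift order (default 2: linear + quadratic;
#'   0 for intercept only).
#' @param conditions Conditions to model; default every non-rest label in
#'   the schedule. An explicitly requested condition absent from the
#'   schedule is an error.
#' @return An object of class `design_matrix`: the numeric matrix (TRs x
#'   columns) with column names, plus attributes `condition_columns` and
#'   `schedule_length`.
#' @export
build_design_matrix <- function(design, hrf, drift_order = 2,
                                conditions = NULL) {
  stopifnot(inherits(design, "session_design"), inherits(hrf, "hrf"))
  present <- setdiff(unique(design$condition), "rest")
  if (is.null(conditions)) {
    conditions <- intersect(c("primed", "unprimed", "scrambled"), present)
    if (length(conditions) == 0L) conditions <- present
  }
  missing <- setdiff(conditions, present)
  if (length(missing) > 0L) {
    stop("condition(s) absent from schedule: ", paste(missing, collapse = ", "))
  }
  n <- nrow(design)
  cols <- list(intercept = rep(1, n))
  for (cc in conditions) {
    box <- as.numeric(design$condition == cc)
    cols[[cc]] <- causal_convolve(box, hrf$kernel)
  }
  if (drift_order >= 1) {
    tt <- seq_len(n) / n
    for (d in seq_len(drift_order)) {
      cols[[paste0("drift", d)]] <- tt^d - mean(tt^d)
    }
  }
  X <- do.call(cbind, cols)
  structure(X, condition_columns = conditions, schedule_length = n,
            class = c("design_matrix", "matrix", "array"))
}

#' Fit the GLM to one or many voxel time series
#'
#' Ordinary least squares per voxel, optionally preceded by a single-pass
#' AR(1) prewhitening using the lag-1 autocorrelation of the OLS residuals
#' pooled over voxels. (The full restricted-maximum-likelihood noise model
#' of standard fMRI packages is intentionally approximated by this two-step
#' scheme; output is labeled accordingly.)
#'
#' @param y Numeric vector (one voxel) or TRs x voxels matrix.
#' @param X A [build_design_matrix()] result (or plain full-rank matrix).
#' @param whitening `"none"` (default) or `"ar1"`.
#' @return An object of class `glm_fit`: `beta` (coefficients x voxels),
#'   `sigma2` (residual variance per voxel), `df`, `XtXinv`, `rho` (AR(1)
#'   coefficient used, 0 for none), `whitening`.
#' @export
fit_glm <- function(y, X, whitening = c("none", "ar1")) {
  whitening <- match.arg(whitening)
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  X <- unclass(X)
  attr(X, "condition_columns") <- NULL; attr(X, "schedule_length") <- NULL
  if (nrow(X) != nrow(y)) stop("rows of X must match length of y")
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) stop("design matrix is rank deficient")

  ols <- function(X, y) {
    qx <- qr(X)
    beta <- qr.coef(qx, y)
    resid <- y - X %*% beta
    list(beta = beta, resid = resid)
  }
  f <- ols(X, y)
  rho <- 0
  if (whitening == "ar1") {
    r <- f$resid
    num <- sum(r[-1, , drop = FALSE] * r[-nrow(r), , drop = FALSE])
    den <- sum(r^2)
    rho <- num / den
    W <- function(m) m[-1, , drop = FALSE] - rho * m[-nrow(m), , drop = FALSE]
    Xw <- W(X); yw <- W(y)
    f <- ols(Xw, yw)
    X <- Xw
  }
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(f$resid^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  rownames(f$beta) <- colnames(X)
  structure(list(beta = f$beta, sigma2 = sigma2, df = df,
                 XtXinv = XtXinv, rho = rho, whitening = whitening,
                 colnames = colnames(X)),
            class = "glm_fit")
}

#' Contrast estimates and t statistics from a GLM fit
#'
#' @param fit A [fit_glm()] result.
#' @param weights Named contrast weights over design columns (unnamed
#'   columns get weight 0), or a full-length numeric vector.
#' @return Data frame per voxel: `estimate`, `se`, `t`, `df`, `p`
#'   (two-tailed).
#' @export
glm_contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"))
  k <- length(fit$colnames)
  if (!is.null(names(weights))) {
    w <- numeric(k); names(w) <- fit$colnames
    unknown <- setdiff(names(weights), fit$colnames)
    if (length(unknown) > 0L) {
      stop("contrast names not in design: ", paste(unknown, collapse = ", "))
    }
    w[names(weights)] <- weights
  } else {
    if (length(weights) != k) stop("contrast length must match design columns")
    w <- weights
  }
  est <- drop(crossprod(w, fit$beta))
  se <- sqrt(fit$sigma2 * drop(t(w) %*% fit$XtXinv %*% w))
  tval <- est / se
  data.frame(estimate = est, se = se, t = tval, df = fit$df,
             p = 2 * stats::pt(-abs(tval), fit$df))
}

#' ROI summaries and second-level group tests (Table-2-style)
#'
#' For each subject the contrast estimate is averaged over each ROI's
#' voxels; within each group a one-sample t test (df = n - 1) asks whether
#' the ROI responds, and a two-sample pooled-variance t test
#' (df = n1 + n2 - 2) compares groups, signed as first group minus second
#' (pass controls first to mirror control-minus-patient reporting).
#'
#' @param subject_contrasts Named list (subject -> numeric vector of
#'   per-voxel contrast estimates).
#' @param roi_masks Named list (ROI -> voxel indices).
#' @param groups Named character vector or list mapping subject -> group
#'   label; exactly two groups.
#' @param group_order Optional length-2 ordering of group labels for the
#'   between-group sign (first minus second).
#' @return An object of class `roi_group_result`: data frame with one row
#'   per ROI x statistic (`within:<group>` and `between`): `roi`, `test`,
#'   `estimate`, `t`, `df`, `p`.
#' @export
contrast_and_group <- function(subject_contrasts, roi_masks, groups,
                               group_order = NULL) {
  groups <- unlist(groups)
  subs <- names(subject_contrasts)
  stopifnot(!is.null(subs), all(subs %in% names(groups)))
  glabs <- unique(groups[subs])
  if (length(glabs) != 2L) stop("exactly two groups are required")
  if (!is.null(group_order)) {
    stopifnot(setequal(group_order, glabs))
    glabs <- group_order
  }
  rows <- list()
  for (roi in names(roi_masks)) {
    idx <- roi_masks[[roi]]
    vals <- vapply(subject_contrasts, function(v) mean(v[idx]), numeric(1))
    by_group <- split(vals, groups[subs])
    for (g in glabs) {
      x <- by_group[[g]]
      n <- length(x)
      se <- stats::sd(x) / sqrt(n)
      tval <- mean(x) / se
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi, test = paste0("within:", g), estimate = mean(x),
        t = tval, df = n - 1L, p = 2 * stats::pt(-abs(tval), n - 1L),
        stringsAsFactors = FALSE
      )
    }
    x1 <- by_group[[glabs[1]]]; x2 <- by_group[[glabs[2]]]
    n1 <- length(x1); n2 <- length(x2)
    sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
      (n1 + n2 - 2)
    tval <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    rows[[length(rows) + 1L]] <- data.frame(
      roi = roi, test = "between", estimate = mean(x1) - mean(x2),
      t = tval, df = n1 + n2 - 2L,
      p = 2 * stats::pt(-abs(tval), n1 + n2 - 2L), stringsAsFactors = FALSE
    )
  }
  structure(do.call(rbind, rows), group_order = glabs,
            class = c("roi_group_result", "data.frame"))
}
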