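# Vector autoregressive model fitting.

#' Fit a VAR(p) by per-equation least squares
#'
#' Series are demeaned internally (the model is for zero-mean series). Each
#' equation is regressed on the stacked p lags of all components; the
#' innovation covariance is estimated from the residuals with a
#' degrees-of-freedom correction (`n_eff - k*p`). Coefficients are stored in
#' the minus-sign convention of the model equation
#' `x[n] = -sum_i A[i] x[n-i] + u[n]`; element `A_eff[[i]][to, from]`
#' (`A_eff = -A`) is the conventional regression weight of `from` at lag `i`
#' in the equation for `to`.
#'
#' @param series Numeric matrix, time x components (a vector is treated as
#'   one component).
#' @param p Model order (>= 1).
#' @return An object of class `var_model`: `p`, `A` (minus convention),
#'   `A_eff`, `sigma_u`, `coef_se`, `n_obs`, `n_eff`, `means`, `residuals`.
#' @export
fit_var <- function(series, p = 1) {
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  series <- as.matrix(series)
  n <- nrow(series); k <- ncol(series)
  p <- as.integer(p)
  if (p < 1L) stop("'p' must be >= 1")
  min_n <- p * k + p + 2L
  if (n <= min_n) {
    stop(sprintf("series too short: need more than %d observations for k=%d, p=%d",
                 min_n, k, p))
  }
  if (is.null(colnames(series))) colnames(series) <- paste0("x", seq_len(k))
  means <- colMeans(series)
  Xc <- sweep(series, 2, means)

  idx <- (p + 1):n
  Y <- Xc[idx, , drop = FALSE]
  Z <- do.call(cbind, lapply(seq_len(p), function(i) Xc[idx - i, , drop = FALSE]))
  n_eff <- length(idx)

  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("lagged design is rank deficient")
  B <- qr.coef(qz, Y)                     # (k*p) x k
  resid <- Y - Z %*% B
  df <- n_eff - k * p
  sigma_u <- crossprod(resid) / df
  ZtZinv <- chol2inv(qr.R(qz))
  coef_se <- sqrt(outer(diag(ZtZinv), diag(sigma_u)))

  A_eff <- lapply(seq_len(p), function(i) {
    a <- t(B[((i - 1) * k + 1):(i * k), , drop = FALSE])
    dimnames(a) <- list(colnames(series), colnames(series))
    a
  })
  A <- lapply(A_eff, function(a) -a)
  se <- lapply(seq_len(p), function(i) {
    s <- t(coef_se[((i - 1) * k + 1):(i * k), , drop = FALSE])
    dimnames(s) <- list(colnames(series), colnames(series))
    s
  })
  structure(list(p = p, A = A, A_eff = A_eff, sigma_u = sigma_u,
                 coef_se = se, n_obs = n, n_eff = n_eff, means = means,
                 residuals = resid),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> order %d, %d components, n = %d\n",
              x$p, ncol(x$sigma_u), x$n_obs))
  for (i in seq_len(x$p)) {
    cat(sprintf("A_eff[%d] (regression convention):\n", i))
    print(round(x$A_eff[[i]], 3))
  }
  invisible(x)
}

#' Simulate a series from a fitted (or constructed) VAR model
#'
#' Drives the model with supplied innovations, starting from supplied
#' initial values; with the fit's own residuals and the original first p
#' samples this reconstructs the fitted series exactly.
#'
#' @param model A `var_model`.
#' @param innovations n_eff x k matrix of innovation terms.
#' @param init p x k matrix of initial (demeaned) values.
#' @return (p + n_eff) x k matrix of demeaned series values.
#' @export
var_simulate <- function(model, innovations, init) {
  k <- ncol(model$sigma_u); p <- model$p
  stopifnot(ncol(innovations) == k, nrow(init) == p, ncol(init) == k)
  n <- nrow(innovations) + p
  x <- matrix(0, n, k)
  x[seq_len(p), ] <- init
  for (t in (p + 1):n) {
    acc <- innovations[t - p, ]
    for (i in seq_len(p)) acc <- acc + model$A_eff[[i]] %*% x[t - i, ]
    x[t, ] <- acc
  }
  x
}

#' Select a VAR order by information criterion
#'
#' Fits orders `1..p_max` and returns the order minimizing AIC or BIC
#' computed from the ML innovation covariance determinant.
#'
#' @param series Time x components matrix.
#' @param p_max Maximum order to consider.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return Integer chosen order with the criterion table as attribute
#'   `"criterion_table"`.
#' @export
select_var_order <- function(series, p_max = 5, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  k <- ncol(series); n <- nrow(series)
  vals <- vapply(seq_len(p_max), function(p) {
    fit <- fit_var(series, p)
    n_eff <- fit$n_eff
    sig_ml <- crossprod(fit$residuals) / n_eff
    ll <- log(max(det(sig_ml), .Machine$double.xmin))
    pen <- if (criterion == "aic") 2 else log(n_eff)
    ll + pen * p * k^2 / n_eff
  }, numeric(1))
  out <- which.min(vals)
  attr(out, "criterion_table") <- data.frame(p = seq_len(p_max),
                                             value = vals,
                                             criterion = criterion)
  out
}
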