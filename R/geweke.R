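# Geweke decomposition of linear dependence between two time series:
# directed terms F_{x->y}, F_{y->x} and the instantaneous term F_{x.y},
# each a log-ratio of prediction-residual (co)variances from nested
# autoregressions, with F_{x,y} = F_{x->y} + F_{y->x} + F_{x.y}.

# Normalize a series per segment: demean and scale to unit variance.
normalize_segments <- function(v, segments) {
  for (seg in segments) {
    s <- v[seg]
    s <- s - mean(s)
    sdv <- stats::sd(s)
    if (sdv > 0) s <- s / sdv
    v[seg] <- s
  }
  v
}

# Validate/derive the segment list: nonoverlapping runs of consecutive TRs,
# each long enough to contribute at least one lagged target (length > p + 1);
# shorter segments are dropped with a warning.
check_segments <- function(segments, n, p) {
  if (is.null(segments)) segments <- list(seq_len(n))
  segments <- lapply(segments, as.integer)
  all_idx <- unlist(segments)
  if (anyDuplicated(all_idx)) stop("segments must be nonoverlapping")
  if (any(all_idx < 1L | all_idx > n)) stop("segment index outside series")
  if (any(vapply(segments, function(s) any(diff(s) != 1L), logical(1)))) {
    stop("each segment must be a run of consecutive indices")
  }
  keep <- vapply(segments, function(s) length(s) >= p + 2L, logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " segment(s) shorter than p + 2 skipped")
    segments <- segments[keep]
  }
  if (length(segments) == 0L) stop("no usable segments remain")
  segments
}

# Core Gram-matrix computation of the Geweke measures between a reference
# series x and each column of Y, sharing every x-only quantity across
# columns. Lagged pairs never span a segment boundary. All residual
# variances use the common divisor n_eff so the additive decomposition
# F_total = F_xy + F_yx + F_inst holds exactly.
# Voxel-side preprocessing: everything that depends only on Y. Reused across
# surrogate reference series during map thresholding.
geweke_prepare_Y <- function(Y, p, segments, n) {
  p <- as.integer(p)
  segments <- check_segments(segments, n, p)
  for (seg in segments) {
    s <- Y[seg, , drop = FALSE]
    s <- sweep(s, 2, colMeans(s))
    sdv <- sqrt(colSums(s^2) / (length(seg) - 1L))
    sdv[sdv == 0] <- 1
    Y[seg, ] <- sweep(s, 2, sdv, "/")
  }
  targets <- unlist(lapply(segments, function(s) s[-seq_len(p)]))
  n_eff <- length(targets)
  if (n_eff <= 3L * p + 3L) {
    stop(sprintf("too few usable samples (%d) for p = %d; need > %d",
                 n_eff, p, 3L * p + 3L))
  }
  V <- ncol(Y)
  Y0 <- Y[targets, , drop = FALSE]
  Yl <- lapply(seq_len(p), function(i) Y[targets - i, , drop = FALSE])
  Syy <- colSums(Y0^2)
  Gyy <- array(0, c(p, p, V))
  cyy0 <- matrix(0, p, V)                                 # Yl_i' Y0
  for (i in seq_len(p)) {
    cyy0[i, ] <- colSums(Yl[[i]] * Y0)
    for (j in i:p) Gyy[i, j, ] <- colSums(Yl[[i]] * Yl[[j]])
  }
  for (i in seq_len(p)) for (j in seq_len(i - 1)) Gyy[i, j, ] <- Gyy[j, i, ]
  vy_own <- numeric(V)
  for (v in seq_len(V)) {
    Gv <- Gyy[, , v, drop = FALSE]; dim(Gv) <- c(p, p)
    vy_own[v] <- (Syy[v] - sum(cyy0[, v] * solve(Gv, cyy0[, v]))) / n_eff
  }
  list(p = p, segments = segments, targets = targets, n_eff = n_eff, V = V,
       Y0 = Y0, Yl = Yl, Syy = Syy, Gyy = Gyy, cyy0 = cyy0, vy_own = vy_own)
}

# Evaluate the Geweke measures of a reference series x against prepared Y.
geweke_eval_x <- function(prep, x) {
  p <- prep$p; targets <- prep$targets; n_eff <- prep$n_eff; V <- prep$V
  Y0 <- prep$Y0; Yl <- prep$Yl
  Syy <- prep$Syy; cyy0 <- prep$cyy0; vy_own <- prep$vy_own

  x <- normalize_segments(x, prep$segments)
  X0 <- x[targets]
  Xl <- vapply(seq_len(p), function(i) x[targets - i], numeric(n_eff))

  Gxx <- crossprod(Xl)                    # p x p
  cx0 <- drop(crossprod(Xl, X0))          # p
  Sxx <- sum(X0^2)
  vx_own <- (Sxx - sum(cx0 * solve(Gxx, cx0))) / n_eff

  Sxy <- drop(crossprod(Y0, X0))                          # V
  cyx0 <- matrix(0, p, V)                                 # Yl_i' X0
  Gyx <- array(0, c(p, p, V))                             # Yl_i' Xl_j
  for (i in seq_len(p)) {
    cyx0[i, ] <- drop(crossprod(Yl[[i]], X0))
    for (j in seq_len(p)) {
      Gyx[i, j, ] <- drop(crossprod(Yl[[i]], Xl[, j]))
    }
  }
  cxy0 <- crossprod(Xl, Y0)                               # p x V (Xl_j' Y0)

  if (p == 1L) {
    # closed-form 2x2 joint solves, vectorized over columns
    gyy <- prep$Gyy[1, 1, ]; gyx <- Gyx[1, 1, ]; gxx <- Gxx[1, 1]
    a_y <- cyy0[1, ]; a_x <- cxy0[1, ]        # rhs for the y equation
    b_y <- cyx0[1, ]; b_x <- cx0[1]           # rhs for the x equation
    D <- gyy * gxx - gyx^2
    s22 <- (Syy - (gxx * a_y^2 - 2 * gyx * a_y * a_x + gyy * a_x^2) / D) / n_eff
    s11 <- (Sxx - (gxx * b_y^2 - 2 * gyx * b_y * b_x + gyy * b_x^2) / D) / n_eff
    s12 <- (Sxy - (gxx * b_y * a_y - gyx * (b_y * a_x + b_x * a_y) +
                     gyy * b_x * a_x) / D) / n_eff
  } else {
  s11 <- numeric(V); s22 <- numeric(V)
  s12 <- numeric(V)
  for (v in seq_len(V)) {
    Gv <- prep$Gyy[, , v, drop = FALSE]; dim(Gv) <- c(p, p)

    # joint design [Yl, Xl]
    Gj <- rbind(cbind(Gv, matrix(Gyx[, , v], p, p)),
                cbind(t(matrix(Gyx[, , v], p, p)), Gxx))
    rhs_y <- c(cyy0[, v], cxy0[, v])
    rhs_x <- c(cyx0[, v], cx0)
    sol <- solve(Gj, cbind(rhs_y, rhs_x))
    s22[v] <- (Syy[v] - sum(rhs_y * sol[, 1])) / n_eff   # y | both pasts
    s11[v] <- (Sxx    - sum(rhs_x * sol[, 2])) / n_eff   # x | both pasts
    s12[v] <- (Sxy[v] - sum(rhs_x * sol[, 1])) / n_eff
  }
  }

  detj <- s11 * s22 - s12^2
  if (any(detj <= 0) || vx_own <= 0 || any(vy_own <= 0)) {
    stop("singular residual covariance; the series are (numerically) ",
         "linearly dependent")
  }
  list(
    F_x_to_y = unname(log(vy_own / s22)),
    F_y_to_x = unname(log(vx_own / s11)),
    F_instantaneous = unname(log(s11 * s22 / detj)),
    F_total = unname(log(vx_own * vy_own / detj)),
    n_eff = n_eff, p = p
  )
}

geweke_gram <- function(x, Y, p, segments = NULL) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  n <- length(x)
  if (nrow(Y) != n) stop("x and Y must have equal length")
  prep <- geweke_prepare_Y(Y, p, segments, n)
  geweke_eval_x(prep, x)
}

#' Geweke influence decomposition for a pair of series
#'
#' Computes the directed measures
#' `F_x_to_y = ln(var(y | own past) / var(y | both pasts))` and its
#' `y -> x` counterpart, the instantaneous term
#' `F_instantaneous = ln(var(x|pasts) var(y|pasts) / det Sigma_joint)`, and
#' the total linear dependence `F_total`, all from least-squares
#' autoregressions of order `p`. The decomposition
#' `F_total = F_x_to_y + F_y_to_x + F_instantaneous` holds exactly because
#' every variance is taken from the same joint fit with a common
#' normalization. Series are demeaned and variance-normalized per segment
#' before fitting (the measures are scale-invariant).
#'
#' @param x,y Numeric series of equal length.
#' @param p Autoregression order (default 1).
#' @param segments Optional list of runs of consecutive indices to analyze;
#'   lagged pairs never span a segment boundary.
#' @return An object of class `gci_result` with fields `F_x_to_y`,
#'   `F_y_to_x`, `F_instantaneous`, `F_total`, `dgci`
#'   (`F_x_to_y - F_y_to_x`), `p`, `n_eff`.
#' @export
geweke_measures <- function(x, y, p = 1, segments = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  g <- geweke_gram(x, matrix(y, ncol = 1), p, segments)
  structure(list(F_x_to_y = g$F_x_to_y[1], F_y_to_x = g$F_y_to_x[1],
                 F_instantaneous = g$F_instantaneous[1],
                 F_total = g$F_total[1],
                 dgci = g$F_x_to_y[1] - g$F_y_to_x[1],
                 p = g$p, n_eff = g$n_eff),
            class = "gci_result")
}

#' @export
print.gci_result <- function(x, ...) {
  cat(sprintf(paste0("<gci_result> p = %d, n_eff = %d\n",
                     "  F_x->y = %.4f  F_y->x = %.4f  F_x.y = %.4f",
                     "  (total %.4f, dGCI %+.4f)\n"),
              x$p, x$n_eff, x$F_x_to_y, x$F_y_to_x, x$F_instantaneous,
              x$F_total, x$dgci))
  invisible(x)
}

#' Pairwise Geweke measures between all node series
#'
#' @param series Time x node matrix (named columns).
#' @param p Autoregression order.
#' @param segments Optional segment list (see [geweke_measures()]).
#' @return Data frame with one row per unordered node pair: `from`, `to`
#'   (alphabetical reference ordering), `F_from_to`, `F_to_from`,
#'   `F_instantaneous`, `dgci` (positive = `from` drives `to`).
#' @export
pairwise_gci <- function(series, p = 1, segments = NULL) {
  series <- as.matrix(series)
  nodes <- colnames(series)
  if (is.null(nodes)) nodes <- paste0("x", seq_len(ncol(series)))
  rows <- list()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i) next
    g <- geweke_measures(series[, i], series[, j], p, segments)
    rows[[length(rows) + 1L]] <- data.frame(
      from = nodes[i], to = nodes[j],
      F_from_to = g$F_x_to_y, F_to_from = g$F_y_to_x,
      F_instantaneous = g$F_instantaneous, dgci = g$dgci,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
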