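# ROI-referenced Granger causality maps (GCM), difference maps (dGCM), and
# bootstrap + FDR thresholding.

# Coerce volume input (bold_sim, 4-D array, or voxels x time matrix) to a
# time x voxels matrix plus grid dimensions.
as_voxel_matrix <- function(volume) {
  if (inherits(volume, "bold_sim")) volume <- volume$volume
  if (is.array(volume) && length(dim(volume)) == 4L) {
    d <- dim(volume)
    list(Y = t(matrix(volume, prod(d[1:3]), d[4])), grid = d[1:3])
  } else if (is.matrix(volume)) {
    # voxels x time
    list(Y = t(volume), grid = c(nrow(volume), 1L, 1L))
  } else {
    stop("'volume' must be a bold_sim, 4-D array, or voxels x time matrix")
  }
}

#' Compute a difference Granger causality map for a reference ROI
#'
#' Takes the average time course of the reference ROI's voxels as `x` and
#' every voxel's time course as `y`, computes the Geweke measures per voxel,
#' and forms the influence difference `dGCI = F_x_to_y - F_y_to_x`: positive
#' values mean influence from the ROI to the voxel, negative from the voxel
#' to the ROI. Analysis can be restricted to condition segments; lagged
#' pairs spanning segment boundaries are excluded. Voxels inside the
#' reference mask are flagged (`in_reference`), not silently dropped.
#'
#' @param reference_roi Integer vector of linear voxel indices.
#' @param volume A `bold_sim`, 4-D array (`grid x time`), or voxels x time
#'   matrix.
#' @param p Autoregression order (default 1).
#' @param segments Optional list of runs of consecutive TR indices.
#' @return An object of class `dgcm_map`: `dgci`, `f_x_to_y`, `f_y_to_x`,
#'   `instantaneous` (per-voxel vectors), `in_reference`, `grid_dim`, `p`,
#'   `n_eff`, and the series needed for surrogate thresholding.
#' @export
compute_dgcm <- function(reference_roi, volume, p = 1, segments = NULL) {
  vm <- as_voxel_matrix(volume)
  Y <- vm$Y
  reference_roi <- as.integer(reference_roi)
  if (length(reference_roi) == 0L) stop("reference mask is empty")
  if (any(reference_roi < 1L | reference_roi > ncol(Y))) {
    stop("reference index outside volume")
  }
  x <- rowMeans(Y[, reference_roi, drop = FALSE])
  in_ref <- seq_len(ncol(Y)) %in% reference_roi
  # reference-mask voxels are flagged and excluded (their joint fit with the
  # ROI mean is degenerate); everything else is computed
  g <- geweke_gram(x, Y[, !in_ref, drop = FALSE], p, segments)
  expand <- function(v) { out <- rep(NA_real_, ncol(Y)); out[!in_ref] <- v; out }
  structure(list(
    dgci = expand(g$F_x_to_y - g$F_y_to_x),
    f_x_to_y = expand(g$F_x_to_y), f_y_to_x = expand(g$F_y_to_x),
    instantaneous = expand(g$F_instantaneous),
    in_reference = in_ref,
    grid_dim = vm$grid, p = g$p, n_eff = g$n_eff,
    reference_series = x, voxel_series = Y, segments = segments
  ), class = "dgcm_map")
}

#' @export
print.dgcm_map <- function(x, ...) {
  cat(sprintf("<dgcm_map> %d voxels, p = %d, n_eff = %d\n",
              length(x$dgci), x$p, x$n_eff))
  cat(sprintf("  dGCI range [%.3f, %.3f]\n",
              min(x$dgci, na.rm = TRUE), max(x$dgci, na.rm = TRUE)))
  if (!is.null(x$significant)) {
    cat(sprintf("  thresholded: %d significant voxels (B = %d, q = %g)\n",
                sum(x$significant), x$threshold$B, x$threshold$q))
  }
  invisible(x)
}

#' Threshold a dGCM by surrogate bootstrap and false discovery rate
#'
#' Builds a null distribution of the dGCI by recomputing the map on `B`
#' surrogates in which the reference series is circularly time-shifted
#' (uniform shift in `[p + 1, n - p - 1]`), which preserves its
#' autocorrelation while destroying cross-dependence with the voxels. The
#' null values are pooled over surrogates and voxels (the per-segment
#' standardization makes them exchangeable), giving each voxel a two-sided
#' p-value with resolution `1 / (B * n_voxels)`; Benjamini-Hochberg
#' correction at level `q` then yields the significance mask.
#'
#' @param map A `dgcm_map` from [compute_dgcm()].
#' @param B Number of surrogates (>= 100; also `1/B <= q` required so the
#'   attainable p-value resolution supports the requested level).
#' @param q FDR level (default 0.05).
#' @param seed Integer seed for the surrogate shifts.
#' @return The map with `p_values`, `significant` (logical mask) and
#'   `threshold` metadata (`B`, `q`, `seed`) filled in.
#' @export
threshold_map <- function(map, B = 200, q = 0.05, seed = 1) {
  stopifnot(inherits(map, "dgcm_map"))
  B <- as.integer(B)
  if (B < 100L) stop("'B' must be >= 100")
  if (1 / B > q) {
    stop(sprintf("B = %d too small for q = %g: attainable p resolution 1/B = %g exceeds q",
                 B, q, 1 / B))
  }
  n <- length(map$reference_series)
  lo <- map$p + 1L; hi <- n - map$p - 1L
  if (hi < lo) stop("series too short for surrogate shifts")
  rng <- local_rng(seed)
  shifts <- lo + rng$rint(B, hi - lo + 1L) - 1L

  use <- !map$in_reference
  Yu <- map$voxel_series[, use, drop = FALSE]
  obs <- abs(map$dgci[use])
  prep <- geweke_prepare_Y(Yu, map$p, map$segments, n)
  null_vals <- vector("list", B)
  for (b in seq_len(B)) {
    s <- shifts[b]
    x_b <- c(map$reference_series[(s + 1):n], map$reference_series[1:s])
    g <- geweke_eval_x(prep, x_b)
    null_vals[[b]] <- abs(g$F_x_to_y - g$F_y_to_x)
  }
  null_sorted <- sort(unlist(null_vals))
  n_null <- length(null_sorted)
  # p = (1 + #{null >= obs}) / (n_null + 1), via binary search on the
  # sorted pooled null
  below <- findInterval(obs, null_sorted, left.open = TRUE)
  p_use <- (1 + n_null - below) / (n_null + 1)
  padj_use <- stats::p.adjust(p_use, method = "BH")
  p_vals <- rep(NA_real_, length(map$dgci)); p_vals[use] <- p_use
  p_adj <- rep(NA_real_, length(map$dgci)); p_adj[use] <- padj_use
  map$p_values <- p_vals
  map$p_adjusted <- p_adj
  map$significant <- !is.na(p_adj) & p_adj <= q
  map$threshold <- list(B = B, q = q, seed = as.integer(seed),
                        scheme = "circular time-shift of reference")
  map
}

#' Write dGCM and instantaneous maps as NIfTI volumes
#'
#' @param map A `dgcm_map`.
#' @param prefix Output path prefix; writes `<prefix>_dgci.nii.gz`,
#'   `<prefix>_inst.nii.gz` and, if thresholded, `<prefix>_mask.nii.gz`.
#' @return Invisibly the paths written.
#' @export
write_dgcm_nifti <- function(map, prefix) {
  grid <- map$grid_dim
  paths <- character(0)
  wr <- function(vec, suffix) {
    pth <- paste0(prefix, "_", suffix, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(vec, dim = grid)), pth)
    pth
  }
  paths <- c(paths, wr(map$dgci, "dgci"), wr(map$instantaneous, "inst"))
  if (!is.null(map$significant)) {
    paths <- c(paths, wr(as.integer(map$significant), "mask"))
  }
  invisible(paths)
}

#' TR segments belonging to one condition's runs
#'
#' Returns the runs of a condition in a session schedule, each prepended
#' with `p` lead-in TRs so that order-`p` lagged pairs exist inside the
#' segment; cross-boundary pairs are excluded by the segment mechanism.
#'
#' @param design A `session_design`.
#' @param condition Condition label (e.g. "primed").
#' @param p Lead-in length (the VAR order to be used downstream).
#' @return List of integer TR index vectors.
#' @export
condition_segments <- function(design, condition, p = 1) {
  stopifnot(inherits(design, "session_design"))
  if (!condition %in% design$condition) {
    stop("condition absent from schedule: ", condition)
  }
  is_cond <- design$condition == condition
  r <- rle(is_cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- Map(function(s, e) max(1L, s - p):e,
              starts[r$values], ends[r$values])
  unname(segs)
}
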