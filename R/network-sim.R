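# Ground-truth latent VAR network and BOLD simulator.

#' Construct a latent network model
#'
#' A vector autoregressive (VAR) model over the four closure-network nodes
#' (DS, LOC, PFC, HIPP by default), driven by condition boxcar inputs:
#' `x[n] = -sum_i A[i] x[n-i] + C s[n] + u[n]`
#' where the stored coefficient matrices `A[i]` follow the minus-sign
#' convention of the model equation (the conventional regression
#' coefficients are `A_eff[i] = -A[i]`), `s[n]` are condition indicators and
#' `u[n]` is white noise with covariance `sigma_u`. Entry `A_eff[i][to, from]`
#' couples node `from` into node `to` at lag `i`.
#'
#' @param coefficients List of p square matrices (rows/cols named by nodes).
#' @param sigma_u Innovation covariance (positive semi-definite); a scalar is
#'   expanded to `scalar^2 * I` (i.e. interpreted as an innovation sd).
#' @param input_weights Nodes x conditions matrix of condition input gains
#'   (may be NULL for an input-free network).
#' @param nodes Node names; default `c("DS", "LOC", "PFC", "HIPP")`.
#' @param group Group label carried as metadata.
#' @param convention Either `"minus"` (matrices are already in the stored
#'   minus-sign form) or `"regression"` (matrices are conventional regression
#'   coefficients and are negated for storage). Default `"regression"`,
#'   which is how couplings are naturally written down.
#' @return An object of class `network_model`.
#' @export
network_model <- function(coefficients, sigma_u = 1, input_weights = NULL,
                          nodes = c("DS", "LOC", "PFC", "HIPP"),
                          group = "control",
                          convention = c("regression", "minus")) {
  convention <- match.arg(convention)
  if (is.matrix(coefficients)) coefficients <- list(coefficients)
  k <- length(nodes)
  stopifnot(all(vapply(coefficients, function(a)
    is.matrix(a) && all(dim(a) == k), logical(1))))
  A_eff <- if (convention == "minus") lapply(coefficients, function(a) -a)
           else coefficients
  if (length(sigma_u) == 1L) sigma_u <- diag(as.numeric(sigma_u)^2, k)
  stopifnot(all(dim(sigma_u) == k))
  if (max(abs(sigma_u - t(sigma_u))) > 1e-12) stop("'sigma_u' must be symmetric")
  if (min(eigen(sigma_u, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
    stop("'sigma_u' must be positive semi-definite")
  }
  rho <- companion_spectral_radius(A_eff)
  if (rho >= 1) {
    stop(sprintf("network is not stationary: companion spectral radius %.3f >= 1",
                 rho))
  }
  if (!is.null(input_weights)) {
    stopifnot(is.matrix(input_weights), nrow(input_weights) == k)
  }
  A_store <- lapply(A_eff, function(a) {
    dimnames(a) <- list(nodes, nodes); -a
  })
  structure(list(nodes = nodes, p = length(A_store), A = A_store,
                 sigma_u = sigma_u, input_weights = input_weights,
                 group = group, spectral_radius = rho),
            class = "network_model")
}

# Spectral radius of the VAR companion matrix built from regression-form
# coefficient matrices.
companion_spectral_radius <- function(A_eff) {
  k <- nrow(A_eff[[1]]); p <- length(A_eff)
  comp <- matrix(0, k * p, k * p)
  comp[1:k, ] <- do.call(cbind, A_eff)
  if (p > 1) comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# Regression-form coefficients of a stored (minus-convention) model.
var_coefficients <- function(model) lapply(model$A, function(a) -a)

#' Configure the BOLD observation model
#'
#' Maps latent node activity to a voxel grid: each ROI voxel carries the
#' (optionally HRF-convolved) latent series of its node times a local gain,
#' plus white observation noise; voxels outside every ROI are pure noise.
#' The nominal Talairach centers of the four closure ROIs are carried as
#' metadata labels only — the synthetic grid has its own voxel coordinates.
#'
#' @param grid_dim Integer length-3 voxel grid dimensions.
#' @param roi_masks Named list (node -> integer vector of linear voxel
#'   indices into the grid); masks must be disjoint and nonempty.
#' @param hrf Either `"canonical"` (double-gamma kernel sampled at TR) or
#'   `"identity"` (no hemodynamic convolution; useful for connectivity
#'   recovery tests free of the HRF confound).
#' @param noise_sd Observation noise sd.
#' @param gain_range Voxel gains are drawn uniformly from this range
#'   (default `c(1, 1)`, i.e. unit gains).
#' @param tr_ms Repetition time in ms.
#' @return An object of class `bold_sim_config`.
#' @export
bold_sim_config <- function(grid_dim = c(6, 6, 4),
                            roi_masks = default_roi_masks(grid_dim),
                            hrf = c("canonical", "identity"),
                            noise_sd = 0.5,
                            gain_range = c(1, 1),
                            tr_ms = 2000) {
  hrf <- match.arg(hrf)
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 1))
  nvox <- prod(grid_dim)
  all_idx <- unlist(roi_masks)
  if (any(vapply(roi_masks, length, integer(1)) == 0L)) {
    stop("ROI masks must be nonempty")
  }
  if (anyDuplicated(all_idx)) stop("ROI masks must be disjoint")
  if (any(all_idx < 1L | all_idx > nvox)) stop("mask index outside grid")
  structure(list(grid_dim = as.integer(grid_dim), roi_masks = roi_masks,
                 hrf = hrf, noise_sd = noise_sd, gain_range = gain_range,
                 tr_ms = tr_ms,
                 talairach_labels = list(DS = c(26, -79, 23),
                                         LOC = c(27, -59, -8),
                                         PFC = c(33, 4, 40),
                                         HIPP = c(26, -20, -20))),
            class = "bold_sim_config")
}

#' Default disjoint ROI masks on a synthetic grid
#'
#' Splits the first grid axis into four slabs, one per node, and takes every
#' voxel of the slab's first slice as that node's ROI.
#'
#' @param grid_dim Integer length-3 grid dimensions (first axis >= 4).
#' @param nodes Node names.
#' @return Named list of linear voxel index vectors.
#' @export
default_roi_masks <- function(grid_dim, nodes = c("DS", "LOC", "PFC", "HIPP")) {
  stopifnot(grid_dim[1] >= length(nodes))
  nvox_slice <- grid_dim[2] * grid_dim[3]
  masks <- lapply(seq_along(nodes), function(i) {
    # voxels with first coordinate == i (all j, k)
    as.integer(i + grid_dim[1] * (seq_len(nvox_slice) - 1L))
  })
  names(masks) <- nodes
  masks
}

#' Simulate network-driven BOLD data
#'
#' Runs the latent VAR at TR resolution over the session schedule (one VAR
#' step per TR), convolves each node's series with the configured HRF, and
#' observes it through the ROI voxel grid. Ground truth (coefficients,
#' innovation covariance, input weights, gains) is returned alongside the
#' data so recovery tests never reverse-engineer it.
#'
#' @param network A [network_model()].
#' @param config A [bold_sim_config()].
#' @param design A `session_design` from [build_fmri_session()].
#' @param seed Integer seed.
#' @param burn_in VAR burn-in steps discarded before the schedule (default 50).
#' @return An object of class `bold_sim`: list with `volume` (4-D array
#'   `grid x TR`), `latents` (TR x node matrix), `node_bold` (TR x node,
#'   HRF-convolved), `design`, `masks`, `ground_truth`.
#' @export
simulate_network_bold <- function(network, config, design, seed,
                                  burn_in = 50L) {
  stopifnot(inherits(network, "network_model"),
            inherits(config, "bold_sim_config"),
            inherits(design, "session_design"))
  k <- length(network$nodes)
  p <- network$p
  A_eff <- var_coefficients(network)
  n_tr <- nrow(design)
  n_tot <- n_tr + burn_in
  rng <- local_rng(seed)

  # condition inputs (zero during burn-in)
  input <- matrix(0, n_tot, k)
  if (!is.null(network$input_weights)) {
    conds <- colnames(network$input_weights)
    if (is.null(conds)) stop("'input_weights' must have condition colnames")
    s <- sapply(conds, function(cc) as.numeric(design$condition == cc))
    input[(burn_in + 1):n_tot, ] <- s %*% t(network$input_weights)
  }

  # innovations
  ev <- eigen(network$sigma_u, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  u <- if (max(abs(network$sigma_u)) == 0) matrix(0, n_tot, k)
       else matrix(rng$rnorm(n_tot * k), n_tot, k) %*% t(L)

  x <- matrix(0, n_tot, k)
  for (n in seq_len(n_tot)) {
    acc <- input[n, ] + u[n, ]
    for (i in seq_len(min(p, n - 1))) acc <- acc + A_eff[[i]] %*% x[n - i, ]
    x[n, ] <- acc
  }
  latents <- x[(burn_in + 1):n_tot, , drop = FALSE]
  colnames(latents) <- network$nodes

  node_bold <- if (config$hrf == "identity") {
    latents
  } else {
    kern <- canonical_hrf(tr_s = config$tr_ms / 1000)$kernel
    apply(latents, 2, function(v) causal_convolve(v, kern))
  }

  grid <- config$grid_dim
  nvox <- prod(grid)
  vol <- matrix(0, nvox, n_tr)
  gains <- list()
  for (node in names(config$roi_masks)) {
    idx <- config$roi_masks[[node]]
    g <- rng$runif(length(idx), config$gain_range[1], config$gain_range[2])
    gains[[node]] <- g
    vol[idx, ] <- outer(g, node_bold[, node])
  }
  if (config$noise_sd > 0) {
    vol <- vol + matrix(rng$rnorm(nvox * n_tr, sd = config$noise_sd),
                        nvox, n_tr)
  }
  volume <- array(vol, dim = c(grid, n_tr))

  structure(list(
    volume = volume, latents = latents, node_bold = node_bold,
    design = design, masks = config$roi_masks,
    ground_truth = list(A = network$A, A_eff = A_eff,
                        sigma_u = network$sigma_u,
                        input_weights = network$input_weights,
                        gains = gains, hrf = config$hrf,
                        group = network$group)
  ), class = "bold_sim")
}

# Causal discrete convolution truncated to the input length.
causal_convolve <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (kk in seq_along(kernel)) {
    lag <- kk - 1L
    if (lag >= n) break
    out[(lag + 1):n] <- out[(lag + 1):n] + kernel[kk] * x[1:(n - lag)]
  }
  out
}

#' Write a 4-D BOLD volume (and optional ROI label mask) as NIfTI
#'
#' @param sim A `bold_sim` (or plain 4-D array).
#' @param path Output NIfTI path for the 4-D series.
#' @param mask_path Optional path for an integer ROI label volume
#'   (1, 2, ... in mask order, 0 elsewhere).
#' @return Invisibly the path(s) written.
#' @export
write_bold_nifti <- function(sim, path, mask_path = NULL) {
  vol <- if (inherits(sim, "bold_sim")) sim$volume else sim
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  written <- path
  if (!is.null(mask_path) && inherits(sim, "bold_sim")) {
    grid <- dim(vol)[1:3]
    lab <- array(0L, dim = grid)
    for (i in seq_along(sim$masks)) lab[sim$masks[[i]]] <- i
    RNifti::writeNifti(RNifti::asNifti(lab), mask_path)
    written <- c(written, mask_path)
  }
  invisible(written)
}
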