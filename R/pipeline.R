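# End-to-end orchestration: simulate -> ERP -> GLM -> GCM -> report.

#' Default EEG component amplitude table
#'
#' Placeholder per-group, per-condition component amplitudes (microvolts)
#' that reproduce the qualitative pattern of the closure/priming findings:
#' a reduced closure negativity (Ncl) at identification in patients, an N1
#' repetition enhancement of equal size in both groups, and a P1 repetition
#' reduction present only in controls. Magnitudes are nominal, not
#' calibrated to any recorded dataset.
#'
#' @return Data frame with columns `group`, `condition`, `component`,
#'   `amplitude_uV`.
#' @export
default_eeg_amplitudes <- function() {
  tab <- expand.grid(group = c("control", "patient"),
                     condition = c("ID", "ID-1", "repeat"),
                     component = c("P1", "N1", "Ncl"),
                     stringsAsFactors = FALSE)
  amp <- c(
    "control.ID.P1" = 2.5, "control.ID-1.P1" = 2.5, "control.repeat.P1" = 1.5,
    "patient.ID.P1" = 1.5, "patient.ID-1.P1" = 1.5, "patient.repeat.P1" = 1.5,
    "control.ID.N1" = -2.0, "control.ID-1.N1" = -2.0, "control.repeat.N1" = -3.0,
    "patient.ID.N1" = -1.8, "patient.ID-1.N1" = -1.8, "patient.repeat.N1" = -2.8,
    "control.ID.Ncl" = -3.0, "control.ID-1.Ncl" = -1.0, "control.repeat.Ncl" = -2.8,
    "patient.ID.Ncl" = -1.5, "patient.ID-1.Ncl" = -0.8, "patient.repeat.Ncl" = -1.4
  )
  tab$amplitude_uV <- amp[paste(tab$group, tab$condition, tab$component,
                                sep = ".")]
  tab
}

#' Default group network models
#'
#' Ground-truth directed couplings expressing the qualitative group
#' difference in primed-image processing: controls route information
#' DS -> PFC -> LOC; patients show bidirectional DS <-> LOC coupling plus
#' HIPP -> DS inflow. All stimulus conditions drive DS (and LOC weakly).
#'
#' @param coupling Lag-1 coupling strength (default 0.35).
#' @param noise_sd Innovation standard deviation (default 1).
#' @return Named list of two [network_model()] objects (`control`,
#'   `patient`).
#' @export
default_networks <- function(coupling = 0.35, noise_sd = 1) {
  nodes <- c("DS", "LOC", "PFC", "HIPP")
  inputs <- matrix(0, 4, 3, dimnames = list(nodes,
                                            c("primed", "unprimed", "scrambled")))
  inputs["DS", ] <- 1
  inputs["LOC", c("primed", "unprimed")] <- 0.5
  mk <- function(edges, group) {
    A <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
    for (e in edges) A[e[2], e[1]] <- coupling   # from -> to
    network_model(A, sigma_u = noise_sd, input_weights = inputs,
                  nodes = nodes, group = group, convention = "regression")
  }
  list(
    control = mk(list(c("DS", "PFC"), c("PFC", "LOC")), "control"),
    patient = mk(list(c("DS", "LOC"), c("LOC", "DS"), c("HIPP", "DS")),
                 "patient")
  )
}

#' Assemble a pipeline run configuration
#'
#' Every stochastic stage receives a seed derived deterministically from the
#' master seed, so a config plus seed fully determines every output.
#'
#' @param seed Master seed.
#' @param n_control,n_patient Group sizes (defaults 21 and 19).
#' @param n_trials_per_condition EEG trials per condition per subject.
#' @param eeg_noise_sd EEG noise sd in microvolts.
#' @param amplitudes EEG amplitude table (see [default_eeg_amplitudes()]).
#' @param networks Group network models (see [default_networks()]).
#' @param bold BOLD observation config (see [bold_sim_config()]).
#' @param n_blocks,runs_per_block fMRI session structure.
#' @param observer_control,observer_patient Behavioral observers; the
#'   patient default has a higher (more complete) threshold with the same
#'   priming shift, matching preserved priming alongside impaired closure.
#' @param var_p VAR order for connectivity (default 1).
#' @param B,q Surrogate count and FDR level for map thresholding.
#' @param limit_uV ERP artifact criterion.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       n_control = 21, n_patient = 19,
                       n_trials_per_condition = 40,
                       eeg_noise_sd = 8,
                       amplitudes = default_eeg_amplitudes(),
                       networks = default_networks(),
                       bold = bold_sim_config(hrf = "canonical"),
                       n_blocks = 3, runs_per_block = 3,
                       observer_control = observer_model(4.5, slope = 2,
                                                         priming_shift = 1),
                       observer_patient = observer_model(3.7, slope = 2,
                                                         priming_shift = 1),
                       var_p = 1, B = 200, q = 0.05, limit_uV = 120) {
  structure(as.list(environment()), class = "run_config")
}

subject_ids <- function(config) {
  c(sprintf("ctl%02d", seq_len(config$n_control)),
    sprintf("pat%02d", seq_len(config$n_patient)))
}

subject_groups <- function(config) {
  ids <- subject_ids(config)
  g <- c(rep("control", config$n_control), rep("patient", config$n_patient))
  names(g) <- ids
  g
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes simulate -> ERP -> GLM -> GCM in order and writes all tables
#' (CSV), the effective config (JSON) and a run report (Markdown + JSON)
#' under `outdir`. Any stage failure aborts with a stage-named error.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, an object of class `run_report`: list of the
#'   per-stage tables and the ground-truth-vs-recovered summary.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  cfg_echo <- config
  cfg_echo$networks <- lapply(config$networks, function(nw)
    list(nodes = nw$nodes, p = nw$p, A_eff = lapply(nw$A, function(a) -a),
         group = nw$group))
  jsonlite::write_json(lapply(unclass(cfg_echo), function(x)
    if (is.function(x) || inherits(x, "bold_sim_config")) NULL else x),
    file.path(outdir, "config.json"), auto_unbox = TRUE, force = TRUE,
    digits = NA)

  groups <- subject_groups(config)
  ids <- names(groups)

  ## ---- simulate ----
  sim <- stage("simulate", {
    design <- build_fmri_session(config$n_blocks, config$runs_per_block,
                                 derive_seed(config$seed, "session"))
    pics <- lapply(1:10, function(i) picture(sprintf("pic%02d", i), 100))
    blocks <- lapply(1:4, function(b)
      build_erp_block(pics, derive_seed(config$seed, paste0("block", b))))
    behavior <- list(); epochs <- list(); bold <- list()
    conds <- rep(unique(config$amplitudes$condition),
                 each = config$n_trials_per_condition)
    for (s in ids) {
      g <- groups[[s]]
      obs <- if (g == "control") config$observer_control else config$observer_patient
      behavior[[s]] <- cbind(subject = s, group = g,
                             simulate_behavior(obs, blocks,
                                               derive_seed(config$seed,
                                                           paste0("beh", s))))
      ecfg <- eeg_sim_config(config$amplitudes,
                             noise_sd = config$eeg_noise_sd)
      epochs[[s]] <- simulate_eeg_epochs(ecfg, conds,
                                         derive_seed(config$seed,
                                                     paste0("eeg", s)),
                                         subject = s, group = g)
      bold[[s]] <- simulate_network_bold(config$networks[[g]], config$bold,
                                         design,
                                         derive_seed(config$seed,
                                                     paste0("bold", s)))
    }
    behavior_df <- do.call(rbind, behavior)
    wcsv(behavior_df, "behavior.csv")
    list(design = design, behavior = behavior_df, epochs = epochs,
         bold = bold)
  })

  ## ---- erp ----
  erp <- stage("erp", {
    amp <- amplitude_table(sim$epochs, limit_uV = config$limit_uV)
    wcsv(amp, "amplitudes.csv")
    stats_tabs <- lapply(c("P1", "N1", "Ncl"), function(cmp) {
      st <- component_stats(amp, cmp)
      cbind(component = cmp, st)
    })
    stats_df <- do.call(rbind, stats_tabs)
    wcsv(stats_df, "erp_stats.csv")
    corr <- component_correlations(amp)
    wcsv(corr, "erp_correlations.csv")
    list(amplitudes = amp, stats = stats_df, correlations = corr)
  })

  ## ---- glm ----
  glm_res <- stage("glm", {
    hrf <- canonical_hrf(tr_s = attr(sim$design, "tr_ms") / 1000)
    X <- build_design_matrix(sim$design, hrf)
    contrasts <- list()
    for (s in ids) {
      vm <- as_voxel_matrix(sim$bold[[s]])
      fit <- fit_glm(vm$Y, X)
      con <- glm_contrast(fit, c(primed = 1, scrambled = -1))
      contrasts[[s]] <- con$estimate
    }
    rgr <- contrast_and_group(contrasts, config$bold$roi_masks, groups,
                              group_order = c("control", "patient"))
    wcsv(as.data.frame(rgr), "roi_group.csv")
    rgr
  })

  ## ---- gcm ----
  gcm_res <- stage("gcm", {
    segs <- condition_segments(sim$design, "primed", config$var_p)
    tabs <- list()
    for (s in ids) {
      vm <- as_voxel_matrix(sim$bold[[s]])
      roi_means <- sapply(names(config$bold$roi_masks), function(r)
        rowMeans(vm$Y[, config$bold$roi_masks[[r]], drop = FALSE]))
      pg <- pairwise_gci(roi_means, p = config$var_p, segments = segs)
      tabs[[s]] <- data.frame(subject = s, group = groups[[s]],
                              connection = paste(pg$from, pg$to, sep = "->"),
                              value = pg$dgci,
                              F_from_to = pg$F_from_to,
                              F_to_from = pg$F_to_from,
                              stringsAsFactors = FALSE)
    }
    gci_table <- do.call(rbind, tabs)
    wcsv(gci_table, "gci_table.csv")
    gstats <- group_gci_stats(gci_table[, c("subject", "group", "connection",
                                            "value")])
    wcsv(as.data.frame(gstats), "group_gci.csv")
    edges <- gci_edge_list(gstats)
    wcsv(edges, "edge_list.csv")
    list(gci_table = gci_table, stats = gstats, edges = edges)
  })

  ## ---- report ----
  report <- stage("report", {
    truth_edges <- lapply(config$networks, function(nw) {
      a <- -nw$A[[1]]
      idx <- which(a != 0, arr.ind = TRUE)
      if (nrow(idx) == 0L) return(character(0))
      paste0(nw$nodes[idx[, 2]], "->", nw$nodes[idx[, 1]])
    })
    recovered <- lapply(split(gcm_res$stats, gcm_res$stats$group),
                        function(d) d$connection[!is.na(d$p_signed_rank) &
                                                   d$p_signed_rank < 0.05])
    summary <- list(
      seed = config$seed,
      group_sizes = c(control = config$n_control,
                      patient = config$n_patient),
      truth_edges = truth_edges,
      recovered_nonzero_median_connections = recovered,
      erp_effects = erp$stats[, c("component", "effect", "F", "p")]
    )
    jsonlite::write_json(summary, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
    md <- c(
      "# closurenet run report", "",
      sprintf("- master seed: %d", config$seed),
      sprintf("- groups: %d controls, %d patients",
              config$n_control, config$n_patient),
      sprintf("- VAR order p = %d, B = %d surrogates, FDR q = %g, artifact limit %g uV",
              config$var_p, config$B, config$q, config$limit_uV),
      "", "## Ground-truth directed edges",
      sprintf("- %s: %s", names(truth_edges),
              vapply(truth_edges, paste, character(1), collapse = ", ")),
      "", "## Stage outputs",
      "- behavior.csv, amplitudes.csv, erp_stats.csv, erp_correlations.csv",
      "- roi_group.csv, gci_table.csv, group_gci.csv, edge_list.csv"
    )
    writeLines(md, file.path(outdir, "report.md"))
    summary
  })

  invisible(structure(list(config = config, behavior = sim$behavior,
                           erp = erp, glm = glm_res, gcm = gcm_res,
                           summary = report),
                      class = "run_report"))
}
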