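# Presentation designs: ascending-method-of-limits (AML) ERP blocks and
# blocked fMRI session schedules.

# Timing constants for the ERP presentation stream (ms).
ERP_TIMING_MS <- list(image = 750, blank1 = 800, prompt = 200, blank2 = 2200)

#' Build one ERP block design
#'
#' A block presents 10 distinct picture sequences, of which 5 randomly chosen
#' ones are presented twice, for 15 sequence presentations in total. A
#' repeated sequence re-uses the identical fragment masks of its initial
#' presentation and follows it after either one or two intervening sequences,
#' determined at random. Within each sequence the image ascends from the most
#' fragmented level used (6) toward the complete end (level 3), terminating
#' early when the observer reports identification; the level schedule stored
#' here is the full 6, 5, 4, 3 ladder and termination is applied by the
#' observer at simulation (or acquisition) time.
#'
#' @param pictures List of exactly 10 [picture()] objects with distinct ids.
#' @param seed Integer seed controlling repeat selection, lags and ordering.
#' @return An object of class `erp_block_design`: a data frame with one row
#'   per sequence presentation (`slot`, `picture_id`, `is_repeat`,
#'   `repeat_lag`) plus attributes `level_schedule` and `timing_ms`.
#' @export
build_erp_block <- function(pictures, seed) {
  if (!is.list(pictures) || length(pictures) != 10L ||
      !all(vapply(pictures, inherits, logical(1), "picture"))) {
    stop("'pictures' must be a list of exactly 10 picture objects")
  }
  ids <- vapply(pictures, `[[`, character(1), "picture_id")
  if (anyDuplicated(ids)) stop("picture ids must be distinct")

  rng <- local_rng(seed)
  n_slots <- 15L

  schedule <- NULL
  for (attempt in seq_len(1000L)) {
    order_ids <- rng$sample(ids, 10L)
    repeated <- rng$sample(order_ids, 5L)
    slot_pic <- character(n_slots)   # "" = free
    slot_rep <- logical(n_slots)
    slot_lag <- rep(NA_integer_, n_slots)
    next_new <- 1L
    ok <- TRUE
    for (s in seq_len(n_slots)) {
      if (nzchar(slot_pic[s])) next            # a scheduled repeat
      if (next_new > 10L) { ok <- FALSE; break }  # dead end: nothing to show
      pic_id <- order_ids[next_new]
      next_new <- next_new + 1L
      slot_pic[s] <- pic_id
      if (pic_id %in% repeated) {
        lags <- rng$sample(c(1L, 2L), 2L)       # preferred lag first
        placed <- FALSE
        for (lag in lags) {
          target <- s + lag + 1L                # lag = intervening sequences
          if (target <= n_slots && !nzchar(slot_pic[target])) {
            slot_pic[target] <- pic_id
            slot_rep[target] <- TRUE
            slot_lag[target] <- lag
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
    }
    if (ok && next_new == 11L && all(nzchar(slot_pic))) {
      schedule <- data.frame(
        slot = seq_len(n_slots), picture_id = slot_pic,
        is_repeat = slot_rep, repeat_lag = slot_lag,
        stringsAsFactors = FALSE
      )
      break
    }
  }
  if (is.null(schedule)) stop("could not place repeats; internal error")

  structure(schedule,
            level_schedule = c(6L, 5L, 4L, 3L),
            timing_ms = ERP_TIMING_MS,
            seed = as.integer(seed),
            class = c("erp_block_design", "data.frame"))
}

#' Build a blocked fMRI session schedule at TR resolution
#'
#' Each stimulus block starts with `rest_length_tr` TRs of rest and contains
#' `runs_per_block` stimulus runs of `run_length_tr` consecutive TRs each,
#' separated by `rest_length_tr` TRs of rest. With three runs per block the
#' runs are one each of the primed, unprimed and scrambled conditions; the
#' run order within each block is randomized once by `run_order_seed` and
#' then fixed for every participant.
#'
#' @param n_blocks Number of stimulus blocks (>= 1).
#' @param runs_per_block Number of stimulus runs per block (>= 1).
#' @param run_order_seed Integer seed fixing the condition order.
#' @param run_length_tr Length of each stimulus run in TRs (default 9).
#' @param rest_length_tr Length of each rest period in TRs (default 4).
#' @param tr_ms Repetition time in ms (default 2000).
#' @return An object of class `session_design`: a data frame with columns
#'   `tr` (1-based index), `condition` (rest/primed/unprimed/scrambled),
#'   `block`, `run` (NA during rest), plus timing attributes.
#' @export
build_fmri_session <- function(n_blocks, runs_per_block, run_order_seed,
                               run_length_tr = 9L, rest_length_tr = 4L,
                               tr_ms = 2000) {
  n_blocks <- as.integer(n_blocks); runs_per_block <- as.integer(runs_per_block)
  if (is.na(n_blocks) || n_blocks < 1L) stop("'n_blocks' must be >= 1")
  if (is.na(runs_per_block) || runs_per_block < 1L) {
    stop("'runs_per_block' must be >= 1")
  }
  conditions <- c("primed", "unprimed", "scrambled")
  rng <- local_rng(run_order_seed)

  rows <- list()
  for (b in seq_len(n_blocks)) {
    base <- rep(conditions, length.out = runs_per_block)
    order_b <- rng$sample(base, runs_per_block)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = rep("rest", rest_length_tr), block = b, run = NA_integer_,
      stringsAsFactors = FALSE
    )
    for (r in seq_len(runs_per_block)) {
      if (r > 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          condition = rep("rest", rest_length_tr), block = b,
          run = NA_integer_, stringsAsFactors = FALSE
        )
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = rep(order_b[r], run_length_tr), block = b, run = r,
        stringsAsFactors = FALSE
      )
    }
  }
  sched <- do.call(rbind, rows)
  sched <- data.frame(tr = seq_len(nrow(sched)), sched,
                      stringsAsFactors = FALSE)
  structure(sched,
            tr_ms = tr_ms, run_length_tr = as.integer(run_length_tr),
            rest_length_tr = as.integer(rest_length_tr),
            n_blocks = n_blocks, runs_per_block = runs_per_block,
            total_tr = nrow(sched), seed = as.integer(run_order_seed),
            class = c("session_design", "data.frame"))
}

#' Write a presentation design as a tab-delimited table plus JSON header
#'
#' @param design An `erp_block_design` or `session_design`.
#' @param path Output path for the TSV table; a `.json` sidecar with the
#'   timing constants and seed is written next to it.
#' @return Invisibly, the two paths written.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  hdr <- attributes(design)
  hdr <- hdr[setdiff(names(hdr), c("names", "row.names", "class"))]
  json_path <- sub("\\.[^.]*$", "", path)
  json_path <- paste0(json_path, ".json")
  jsonlite::write_json(hdr, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(table = path, header = json_path))
}

#' Export fragment masks as run-length-encoded index lists in JSON
#'
#' @param frag A `fragment_sequence`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_fragment_masks <- function(frag, path) {
  rle_encode <- function(idx) {
    if (length(idx) == 0L) return(list())
    starts <- idx[c(1L, which(diff(idx) != 1L) + 1L)]
    lens <- rle(cumsum(c(TRUE, diff(idx) != 1L)))$lengths
    Map(function(s, l) list(start = s, length = l), starts, lens)
  }
  out <- list(
    picture_id = frag$picture_id, seed = frag$seed,
    levels = lapply(frag$levels, rle_encode)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
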