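# Nonparametric inference on Granger causality indices: Wilcoxon signed-rank
# (median vs zero, per group) and rank-sum (between groups), with median/IQR
# summaries.

#' Wilcoxon signed-rank test of a zero median
#'
#' Exact two-sided test by full enumeration of the sign-assignment
#' distribution (dynamic programming over rank sums) for up to `exact_max`
#' nonzero observations, otherwise a normal approximation with continuity
#' correction. Zeros are handled by the Pratt method: they are ranked with
#' the rest and then discarded, so ties and zeros shift the null
#' distribution correctly. Tied magnitudes get midranks in both branches.
#'
#' @param x Numeric sample.
#' @param exact_max Largest number of nonzero values for which the exact
#'   distribution is enumerated (default 25).
#' @return List with `statistic` (W+, sum of positive ranks), `n_nonzero`,
#'   `p` (two-sided; NA with `note` if all values are zero), `method`.
#' @export
signed_rank_test <- function(x, exact_max = 25) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("empty sample")
  r_all <- rank(abs(x))            # zeros included (Pratt)
  nz <- x != 0
  m <- sum(nz)
  if (m == 0L) {
    return(list(statistic = 0, n_nonzero = 0L, p = NA_real_,
                method = "signed-rank (Pratt)",
                note = "all differences zero; test undefined"))
  }
  ranks <- r_all[nz]
  W <- sum(ranks[x[nz] > 0])

  if (m <= exact_max) {
    # distribution of W+ over the 2^m equiprobable sign assignments;
    # midranks can be half-integers, so work on doubled ranks
    r2 <- as.integer(round(2 * ranks))
    total <- sum(r2)
    counts <- numeric(total + 1L)    # index = doubled rank sum + 1
    counts[1L] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
      counts <- counts + shifted
    }
    probs <- counts / 2^m
    w2 <- round(2 * W)
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "signed-rank (Pratt), exact enumeration"
  } else {
    mu <- sum(ranks) / 2
    # tie/zero-corrected variance: sum of squared (nonzero) ranks / 4
    sig <- sqrt(sum(ranks^2) / 4)
    z <- (W - mu - sign(W - mu) * 0.5) / sig
    p <- 2 * stats::pnorm(-abs(z))
    method <- "signed-rank (Pratt), normal approximation"
  }
  list(statistic = W, n_nonzero = m, p = p, method = method)
}

#' Median and inter-quartile range
#'
#' @param x Numeric sample.
#' @return Named vector `c(median, iqr)` (type-7 quantiles).
#' @export
median_iqr <- function(x) {
  c(median = stats::median(x), iqr = unname(stats::IQR(x)))
}

#' Group-level inference on per-subject GCI values
#'
#' For every connection: per-group median and IQR, a signed-rank test of a
#' zero median within each group, and a rank-sum (Mann-Whitney) test of the
#' between-group difference.
#'
#' @param gci_table Data frame with columns `subject`, `group`,
#'   `connection`, `value` (the per-subject GCI or dGCI for that
#'   connection).
#' @param min_n Minimum subjects per group (default 5; exact small-sample
#'   tests are unreliable below this).
#' @return An object of class `group_gci_stats`: data frame with one row
#'   per connection x group (`median`, `iqr`, `n`, `p_signed_rank`) and the
#'   per-connection `p_rank_sum` repeated on each row.
#' @export
group_gci_stats <- function(gci_table, min_n = 5) {
  stopifnot(all(c("subject", "group", "connection", "value") %in%
                  names(gci_table)))
  glabs <- unique(gci_table$group)
  if (length(glabs) != 2L) stop("exactly two groups are required")
  rows <- list()
  for (conn in unique(gci_table$connection)) {
    sub <- gci_table[gci_table$connection == conn, ]
    vals <- split(sub$value, factor(sub$group, levels = glabs))
    ns <- vapply(vals, length, integer(1))
    if (any(ns < min_n)) {
      stop(sprintf("connection %s: need >= %d subjects per group", conn, min_n))
    }
    rs <- suppressWarnings(
      stats::wilcox.test(vals[[1]], vals[[2]], exact = NULL)
    )$p.value
    for (g in glabs) {
      sr <- signed_rank_test(vals[[g]])
      mi <- median_iqr(vals[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        connection = conn, group = g, n = length(vals[[g]]),
        median = mi["median"], iqr = mi["iqr"],
        p_signed_rank = sr$p, p_rank_sum = rs,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  structure(do.call(rbind, rows), class = c("group_gci_stats", "data.frame"))
}

#' Edge list for redrawing the group connectivity graph
#'
#' Flattens [group_gci_stats()] output (computed on dGCI values for
#' reference-ordered pairs) into a per-group directed edge list: the edge
#' direction follows the sign of the group median dGCI.
#'
#' @param stats A `group_gci_stats` computed on connections named
#'   `"A->B"`-style reference pairs (see [pairwise_gci()], connection
#'   `paste(from, to, sep = "->")`).
#' @param alpha Significance level for inclusion flags (default 0.05).
#' @return Data frame `source`, `target`, `group`, `median`, `iqr`,
#'   `p_signed_rank`, `p_rank_sum`, `significant_within`,
#'   `differs_between`.
#' @export
gci_edge_list <- function(stats, alpha = 0.05) {
  stopifnot(inherits(stats, "group_gci_stats"))
  parts <- strsplit(stats$connection, "->", fixed = TRUE)
  src <- vapply(parts, `[`, character(1), 1)
  tgt <- vapply(parts, `[`, character(1), 2)
  flip <- !is.na(stats$median) & stats$median < 0
  data.frame(
    source = ifelse(flip, tgt, src), target = ifelse(flip, src, tgt),
    group = stats$group, median = stats$median, iqr = stats$iqr,
    p_signed_rank = stats$p_signed_rank, p_rank_sum = stats$p_rank_sum,
    significant_within = !is.na(stats$p_signed_rank) &
      stats$p_signed_rank < alpha,
    differs_between = stats$p_rank_sum < alpha,
    stringsAsFactors = FALSE
  )
}
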