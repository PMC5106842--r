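# Profile search of a protein sequence database.
#
# Motifs are placed greedily, longest first, by a sliding window: every
# allowed start (not overlapping a previously placed motif) is scored, the
# most significant per-window p-value wins (ties -> the N-terminal start),
# and the per-window p-value is corrected for the number of windows scanned.
# The per-motif sequence p-values are then combined with QFAST into one
# search score per sequence.

#' Search configuration and score thresholds
#'
#' Default thresholds follow standard practice for this score: only scores
#' <= 1e-5 are reported; <= 1e-8 is the generous cutoff below which hits are
#' near-certain superfamily members; <= 1e-14 (initial search) and <= 1e-16
#' (iterative searches) are the trusted cutoffs for high-confidence
#' functional-group membership.
#'
#' @param report_threshold Report scores at or below this value.
#' @param generous_threshold Generous membership cutoff.
#' @param trusted_threshold_initial Trusted cutoff, first search.
#' @param trusted_threshold_iterative Trusted cutoff, later iterations.
#' @param mode `"dasp3"` or `"legacy"` (recorded, informative).
#' @return A list of class `dasp_search_config`.
#' @export
search_config <- function(report_threshold = 1e-5,
                          generous_threshold = 1e-8,
                          trusted_threshold_initial = 1e-14,
                          trusted_threshold_iterative = 1e-16,
                          mode = c("dasp3", "legacy")) {
  mode <- match.arg(mode)
  th <- c(report_threshold, generous_threshold,
          trusted_threshold_initial, trusted_threshold_iterative)
  if (any(th <= 0 | th >= 1)) abort("Thresholds must lie in (0, 1).")
  if (!(trusted_threshold_initial <= generous_threshold &&
        generous_threshold <= report_threshold)) {
    abort("Expected trusted <= generous <= report thresholds.")
  }
  structure(
    list(report_threshold = report_threshold,
         generous_threshold = generous_threshold,
         trusted_threshold_initial = trusted_threshold_initial,
         trusted_threshold_iterative = trusted_threshold_iterative,
         mode = mode),
    class = "dasp_search_config"
  )
}

# allowed start positions (1-based) whose [s, s+L) window avoids all
# excluded 1-based half-open intervals (two-column matrix start,end)
allowed_starts <- function(n_starts, L, excluded) {
  ok <- rep(TRUE, n_starts)
  if (!is.null(excluded) && nrow(excluded) > 0L) {
    s <- seq_len(n_starts)
    for (i in seq_len(nrow(excluded))) {
      ok <- ok & (s + L <= excluded[i, 1] | s >= excluded[i, 2])
    }
  }
  which(ok)
}

#' Place one motif in a sequence by sliding window
#'
#' Scores every window whose extent does not intersect `excluded`
#' (0-based half-open intervals of previously placed motifs), picks the
#' most significant per-window p-value (ties -> smallest start) and corrects
#' it for the number of windows scanned. When no window is allowed the motif
#' is unplaced: position `NA`, p-values 1.
#'
#' @param sequence Character scalar, or an already [encode_sequence()]-coded
#'   integer vector.
#' @param pssm A `dasp_pssm`.
#' @param excluded Two-column matrix (or NULL) of 0-based half-open
#'   intervals closed to placement.
#' @param quiet Suppress the unplaced-motif warning.
#' @return One-row tibble: `position` (0-based start, `NA` if unplaced),
#'   `score`, `window_pvalue`, `n_windows`, `sequence_pvalue`, `placed`.
#' @export
place_motif <- function(sequence, pssm, excluded = NULL, quiet = FALSE) {
  idx <- if (is.character(sequence)) encode_sequence(sequence, pssm$alphabet)
  else sequence
  L <- pssm$length
  ws <- score_windows(idx, pssm$scores)
  excl1 <- if (is.null(excluded) || nrow(excluded) == 0L) NULL
  else cbind(excluded[, 1] + 1L, excluded[, 2] + 1L)
  ok <- allowed_starts(length(ws), L, excl1)
  if (length(ok) == 0L) {
    if (!quiet) warn("Motif could not be placed: no allowed window.")
    return(tibble(position = NA_integer_, score = NA_real_,
                  window_pvalue = 1, n_windows = 0L,
                  sequence_pvalue = 1, placed = FALSE))
  }
  best <- ok[which.max(ws[ok])]
  wp <- window_pvalue(ws[best], pssm$dist)
  tibble(position = best - 1L, score = ws[best], window_pvalue = wp,
         n_windows = length(ok),
         sequence_pvalue = sequence_pvalue(wp, length(ok)), placed = TRUE)
}

#' Score one sequence against all motifs of a profile
#'
#' Motifs are processed in decreasing length (ties -> N->C profile order);
#' each placement excludes its interval from later motifs. Unplaced motifs
#' contribute p = 1. The combined score is the QFAST combination of the
#' per-motif sequence p-values.
#'
#' @param sequence Character scalar.
#' @param pssms List of `dasp_pssm` from [profile_pssms()].
#' @param quiet Suppress per-motif placement warnings.
#' @return List with `combined_pvalue`, `colinear` (placed motifs in N->C
#'   profile order), and `placements`, a tibble with one row per motif
#'   (`block`, `length`, `is_key`, `position`, `score`, `window_pvalue`,
#'   `n_windows`, `sequence_pvalue`, `placed`).
#' @export
search_sequence <- function(sequence, pssms, quiet = TRUE) {
  idx <- encode_sequence(sequence, pssms[[1]]$alphabet)
  lens <- vapply(pssms, function(p) p$length, integer(1))
  blocks <- vapply(seq_along(pssms), function(i) {
    as.integer(attr(pssms[[i]], "block") %||% i)
  }, integer(1))
  ord <- order(-lens, blocks)
  excluded <- matrix(integer(0), ncol = 2)
  out <- vector("list", length(pssms))
  for (i in ord) {
    pm <- place_motif(idx, pssms[[i]], excluded = excluded, quiet = quiet)
    if (pm$placed) {
      excluded <- rbind(excluded, c(pm$position, pm$position + lens[i]))
    }
    out[[i]] <- mutate(pm, block = blocks[i], length = lens[i],
                       is_key = isTRUE(attr(pssms[[i]], "is_key")))
  }
  placements <- bind_rows(out) |>
    select("block", "length", "is_key", "position", "score",
           "window_pvalue", "n_windows", "sequence_pvalue", "placed") |>
    arrange(.data$block)
  pos <- placements$position[placements$placed]
  list(
    combined_pvalue = qfast_combine(placements$sequence_pvalue),
    colinear = length(pos) < 2L || !is.unsorted(pos, strictly = TRUE),
    placements = placements
  )
}

#' Read a protein FASTA file into a named character vector
#'
#' @param file Path to a (plain-text) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readAAStringSet(file)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Search a sequence database with an active-site profile
#'
#' Every record is scored with [search_sequence()]; records at or below the
#' report threshold are ranked by ascending combined p-value (ties broken by
#' id). A decade-binned histogram of all combined scores is attached.
#'
#' @param db Named character vector of sequences, or path to a FASTA file.
#' @param profile A `dasp_profile`.
#' @param config A [search_config()].
#' @param background,beta,scale Passed to [profile_pssms()] when `pssms` is
#'   not supplied.
#' @param pssms Optional precomputed list from [profile_pssms()].
#' @return Object of class `dasp_search`: list with `scores` (all records:
#'   `seq_id`, `length`, `combined_pvalue`, `n_placed`, `colinear`,
#'   `placements` list column), `reported` (the ranked subset), `histogram`
#'   (see [score_histogram()]), `config`, and `profile_glance`.
#' @export
search_database <- function(db, profile, config = search_config(),
                            background = dasp_background(),
                            beta = 1, scale = 100, pssms = NULL) {
  if (is.character(db) && length(db) == 1L && is.null(names(db)) &&
      file.exists(db)) {
    db <- read_fasta(db)
  }
  if (length(db) == 0L) abort("Empty sequence database.")
  ids <- names(db) %||% paste0("seq", seq_along(db))
  if (anyDuplicated(ids)) {
    warn("Duplicate sequence ids: de-duplicating with numeric suffixes.")
    ids <- make.unique(ids, sep = "_dup")
  }
  if (is.null(pssms)) {
    pssms <- profile_pssms(profile, background = background,
                           beta = beta, scale = scale)
  }
  res <- lapply(db, search_sequence, pssms = pssms, quiet = TRUE)
  scores <- tibble(
    seq_id = ids,
    length = nchar(unname(db)),
    combined_pvalue = unname(map_dbl(res, "combined_pvalue")),
    n_placed = unname(map_int(res, ~ sum(.x$placements$placed))),
    colinear = unname(map_lgl(res, "colinear")),
    placements = unname(map(res, "placements"))
  )
  reported <- scores |>
    filter(.data$combined_pvalue <= config$report_threshold) |>
    arrange(.data$combined_pvalue, .data$seq_id) |>
    mutate(rank = row_number()) |>
    select("rank", dplyr::everything())
  structure(
    list(scores = scores, reported = reported,
         histogram = score_histogram(scores$combined_pvalue),
         config = config, profile_glance = glance(profile)),
    class = "dasp_search"
  )
}

#' Decade-binned histogram of combined search scores
#'
#' Bin `b` counts sequences with `floor(log10(p)) == b`; a score of exactly
#' 1 falls in bin 0. Counts over all scored sequences sum to the database
#' size.
#'
#' @param pvalues Numeric vector of combined p-values in (0, 1\].
#' @return Tibble with `log10_bin` and `count`.
#' @export
score_histogram <- function(pvalues) {
  b <- floor(log10(pvalues))
  b[pvalues >= 1] <- 0
  tibble(log10_bin = as.integer(names(table(b))),
         count = as.integer(table(b))) |>
    arrange(.data$log10_bin)
}

#' @export
print.dasp_search <- function(x, ...) {
  cat(sprintf("Profile search: %d sequences scored, %d reported at p <= %g\n",
              nrow(x$scores), nrow(x$reported), x$config$report_threshold))
  if (nrow(x$reported) > 0L) {
    cat(sprintf("best hit: %s (p = %.3e)\n",
                x$reported$seq_id[1], x$reported$combined_pvalue[1]))
  }
  invisible(x)
}

#' Tidy the reported hits of a profile search
#'
#' @param x A `dasp_search`.
#' @param ... Unused.
#' @return Tibble of reported hits: `rank`, `seq_id`, `combined_pvalue`,
#'   `n_placed`, `colinear`.
#' @export
tidy.dasp_search <- function(x, ...) {
  select(x$reported, "rank", "seq_id", "combined_pvalue",
         "n_placed", "colinear")
}

#' One-row summary of a profile search
#'
#' @param x A `dasp_search`.
#' @param ... Unused.
#' @return Tibble with database size, reported/generous/trusted hit counts
#'   and the best score.
#' @export
glance.dasp_search <- function(x, ...) {
  p <- x$scores$combined_pvalue
  tibble(
    n_sequences = length(p),
    n_reported = nrow(x$reported),
    n_generous = sum(p <= x$config$generous_threshold),
    n_trusted = sum(p <= x$config$trusted_threshold_initial),
    best_pvalue = min(p)
  )
}

#' Histogram of search scores, in the standard presentation
#'
#' Bars count sequences per decade of the combined search score; dashed
#' lines mark the report, generous and trusted thresholds.
#'
#' @param object A `dasp_search`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dasp_search <- function(object, ...) {
  h <- object$histogram
  th <- log10(c(report = object$config$report_threshold,
                generous = object$config$generous_threshold,
                trusted = object$config$trusted_threshold_initial))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$log10_bin, y = .data$count)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_vline(xintercept = th, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "log10 combined search score", y = "sequences") +
    ggplot2::theme_minimal()
}

#' Fraction of hits whose motifs lie in the profile's N->C order
#'
#' For each reported sequence, the placed motifs (optionally restricted to
#' those of at least `min_motif_len` residues — the legacy-mode diagnostics
#' exclude length-3 or length-3-and-4 motifs) are checked for strictly
#' increasing positions in profile block order.
#'
#' @param search A `dasp_search` (with a non-empty report), or its `scores`
#'   tibble with a `placements` list column.
#' @param min_motif_len Only motifs at least this long are considered.
#' @return Fraction in \[0, 1\].
#' @export
fragment_order_fraction <- function(search, min_motif_len = 1L) {
  res <- if (inherits(search, "dasp_search")) search$reported else search
  if (nrow(res) == 0L) abort("No reported sequences to assess.")
  co <- map_lgl(res$placements, function(pl) {
    pl <- pl[pl$placed & pl$length >= min_motif_len, , drop = FALSE]
    pl <- pl[order(pl$block), , drop = FALSE]
    nrow(pl) < 2L || !is.unsorted(pl$position, strictly = TRUE)
  })
  mean(co)
}

#' Order-of-magnitude separation between members and non-members
#'
#' `log10` of the best (smallest) non-member score minus `log10` of the
#' worst (largest) member score. When no non-member is reported the
#' non-member score is floored at `floor` (just above the report cutoff).
#' Members missing from the results are scored at p = 1 and flagged with a
#' warning, driving the separation negative.
#'
#' @param search A `dasp_search`.
#' @param member_ids Character vector of known member sequence ids.
#' @param floor Score assumed for the best non-member when none is reported.
#' @return Separation in orders of magnitude (positive = members separate
#'   cleanly), with attribute `missing_members` listing flagged ids.
#' @export
separation_magnitude <- function(search, member_ids, floor = 1.01e-5) {
  if (length(member_ids) == 0L) abort("`member_ids` must be non-empty.")
  sc <- search$scores
  member_p <- sc$combined_pvalue[match(member_ids, sc$seq_id)]
  missing <- member_ids[is.na(member_p)]
  if (length(missing) > 0L) {
    warn(paste0("Member(s) absent from results, scored at p = 1: ",
                paste(missing, collapse = ", ")))
    member_p[is.na(member_p)] <- 1
  }
  nonmem <- search$reported[!search$reported$seq_id %in% member_ids, , drop = FALSE]
  best_nonmember <- if (nrow(nonmem) == 0L) floor else min(nonmem$combined_pvalue)
  out <- log10(best_nonmember) - log10(max(member_p))
  attr(out, "missing_members") <- missing
  out
}

#' Write reported search hits as TSV
#'
#' Columns: `rank`, `seq_id`, `combined_pvalue`, `motifs`
#' (`block:position:sequence_pvalue` triplets, `;`-joined, unplaced motifs
#' as `block:-:1`), `colinear`. Floats use scientific notation with 6
#' significant digits.
#'
#' @param search A `dasp_search`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_search_results <- function(search, file) {
  rep <- search$reported
  motifs <- map_chr(rep$placements, function(pl) {
    paste(sprintf("%d:%s:%s", pl$block,
                  ifelse(pl$placed, as.character(pl$position), "-"),
                  sprintf("%.5e", pl$sequence_pvalue)),
          collapse = ";")
  })
  lines <- c(
    "rank\tseq_id\tcombined_pvalue\tmotifs\tcolinear",
    sprintf("%d\t%s\t%.5e\t%s\t%d", rep$rank, rep$seq_id,
            rep$combined_pvalue, motifs, as.integer(rep$colinear))
  )
  writeLines(lines, file)
  invisible(file)
}

#' Write a score histogram as TSV
#'
#' @param search A `dasp_search` (or a histogram tibble).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_histogram <- function(search, file) {
  h <- if (inherits(search, "dasp_search")) search$histogram else search
  lines <- c("log10_bin\tcount",
             sprintf("%d\t%d", h$log10_bin, h$count))
  writeLines(lines, file)
  invisible(file)
}
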