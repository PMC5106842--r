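# Position-specific scoring matrices and the exact p-value machinery.
#
# Scores are log-odds against a background composition, with
# background-proportional pseudocounts, rounded to integer units of 1/100
# bit. Integer scores make the window-score distribution under the
# background exactly computable by dynamic programming (column-wise
# convolution), which is what the per-window p-values are read from.

#' Build a PSSM from the aligned rows of one motif block
#'
#' Cell (a, j) is `round(scale * log2((n_aj + beta * b_a) /
#' ((N_j + beta) * b_a)))` where `n_aj` counts residue `a` in column `j`,
#' `N_j` is the column's number of counted residues, `b_a` the background
#' frequency, and `beta` the total pseudocount mass (distributed in
#' proportion to the background). Letters outside the alphabet (`X`, gaps)
#' are not counted and score 0 when scanned.
#'
#' @param rows Character vector of equal-length motif rows.
#' @param background Named positive frequency vector defining the alphabet
#'   (default [dasp_background()]). Must have no zero entries.
#' @param beta Pseudocount mass (default 1).
#' @param scale Integer score units per bit times 1/100: default 100, i.e.
#'   scores in centibits.
#' @return Object of class `dasp_pssm`: list with `alphabet`, `length`,
#'   `scores` (alphabet x length integer matrix), `background`, `beta`,
#'   `scale`, `n_rows`, and `dist`, the exact background score distribution
#'   (see [exact_score_distribution()]).
#' @export
build_pssm <- function(rows, background = dasp_background(),
                       beta = 1, scale = 100) {
  if (length(rows) == 0L) abort("No rows to build a PSSM from.")
  if (length(unique(nchar(rows))) != 1L) abort("PSSM rows must have equal length.")
  if (is.null(names(background)) || any(background <= 0)) {
    abort("`background` must be a named vector of positive frequencies.")
  }
  background <- background / sum(background)
  alphabet <- names(background)
  L <- nchar(rows[1])
  chm <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
                nrow = length(rows), ncol = L, byrow = TRUE)
  counts <- vapply(seq_len(L), function(j) {
    tabulate(match(chm[, j], alphabet), nbins = length(alphabet))
  }, integer(length(alphabet)))
  rownames(counts) <- alphabet
  N <- colSums(counts)
  scores <- counts
  for (j in seq_len(L)) {
    scores[, j] <- as.integer(round(scale * log2(
      (counts[, j] + beta * background) / ((N[j] + beta) * background)
    )))
  }
  pssm <- structure(
    list(alphabet = alphabet, length = L, scores = scores,
         background = background, beta = beta, scale = scale,
         n_rows = length(rows), dist = NULL),
    class = "dasp_pssm"
  )
  pssm$dist <- exact_score_distribution(pssm)
  pssm
}

#' Exact distribution of the window score under the background
#'
#' Probability mass of the total score of a random sequence of the motif's
#' length with i.i.d. residues drawn from the background, computed exactly
#' by convolving the per-column score distributions over the integer score
#' lattice.
#'
#' @param pssm A `dasp_pssm`, or an integer score matrix (alphabet x
#'   positions) when `background` is supplied.
#' @param background Background frequencies matching the matrix rows (only
#'   when `pssm` is a plain matrix).
#' @return Object of class `dasp_score_dist`: list with `min_score`,
#'   `max_score`, `probs` (mass per integer score from min to max) and
#'   `tail` (upper-tail probabilities, `tail[i] = P(S >= min_score+i-1)`).
#' @export
exact_score_distribution <- function(pssm, background = NULL) {
  if (inherits(pssm, "dasp_pssm")) {
    scores <- pssm$scores
    background <- pssm$background
  } else {
    scores <- pssm
    if (is.null(background)) abort("Supply `background` with a raw score matrix.")
    background <- background / sum(background)
  }
  storage.mode(scores) <- "integer"
  probs <- 1
  minv <- 0L
  for (j in seq_len(ncol(scores))) {
    col <- scores[, j]
    cmin <- min(col)
    cmax <- max(col)
    n <- length(probs)
    newlen <- n + (cmax - cmin)
    newp <- numeric(newlen)
    for (a in seq_along(col)) {
      sh <- col[a] - cmin
      idx <- (1L + sh):(n + sh)
      newp[idx] <- newp[idx] + probs * background[a]
    }
    probs <- newp
    minv <- minv + cmin
  }
  structure(
    list(min_score = minv, max_score = minv + length(probs) - 1L,
         probs = probs, tail = rev(cumsum(rev(probs)))),
    class = "dasp_score_dist"
  )
}

#' Per-window p-value of an observed window score
#'
#' `P(S >= score)` for a random background window, from the exact score
#' distribution. Scores outside the achievable range are clamped to it, so
#' the minimum achievable score maps to 1 and the maximum to the (positive)
#' mass of the top score.
#'
#' @param score Numeric vector of observed window scores.
#' @param dist A `dasp_score_dist` (or a `dasp_pssm`, whose `dist` is used).
#' @return Numeric vector of p-values in (0, 1].
#' @export
window_pvalue <- function(score, dist) {
  if (inherits(dist, "dasp_pssm")) dist <- dist$dist
  idx <- ceiling(score) - dist$min_score + 1
  idx <- pmin(pmax(idx, 1), length(dist$tail))
  unname(dist$tail[idx])
}

#' Best-of-n-windows correction for a per-window p-value
#'
#' Converts the most significant per-window p-value into a per-sequence
#' p-value accounting for the number of windows scanned:
#' `1 - (1 - p)^n`, evaluated stably for small `p` via `log1p`/`expm1`.
#'
#' @param p Per-window p-value(s) in \[0, 1\].
#' @param n_windows Number of windows scanned (>= 1).
#' @return Per-sequence p-value(s).
#' @export
sequence_pvalue <- function(p, n_windows) {
  if (any(n_windows < 1)) abort("`n_windows` must be >= 1.")
  p <- pmin(pmax(p, 0), 1)
  -expm1(n_windows * log1p(-p))
}

#' Combine independent p-values with the QFAST statistic
#'
#' With `q` the product of the `n` p-values, the combined p-value is
#' `q * sum_{k=0}^{n-1} (-ln q)^k / k!` — the probability that a product of
#' `n` independent uniforms is at most `q`. Evaluated in log space so very
#' small products do not underflow.
#'
#' @param pvalues Non-empty numeric vector of p-values in (0, 1\]. Values
#'   <= 0 are clamped to the smallest positive double with a warning.
#' @return Combined p-value in (0, 1\].
#' @export
qfast_combine <- function(pvalues) {
  if (length(pvalues) == 0L) abort("`pvalues` must be non-empty.")
  if (any(!is.finite(pvalues)) || any(pvalues > 1)) {
    abort("All p-values must be finite and <= 1.")
  }
  if (any(pvalues <= 0)) {
    warn("p-value(s) <= 0 clamped to the smallest positive double.")
    pvalues[pvalues <= 0] <- .Machine$double.xmin
  }
  lnq <- sum(log(pvalues))
  if (lnq == 0) return(1)
  n <- length(pvalues)
  k <- 0:(n - 1)
  logterms <- k * log(-lnq) - lgamma(k + 1)
  m <- max(logterms)
  min(exp(lnq + m + log(sum(exp(logterms - m)))), 1)
}

#' PSSMs for every motif block of a profile
#'
#' @param profile A `dasp_profile`.
#' @param background,beta,scale Passed to [build_pssm()].
#' @return List of `dasp_pssm`, one per block, each annotated with
#'   attributes `block` (index) and `is_key`.
#' @export
profile_pssms <- function(profile, background = dasp_background(),
                          beta = 1, scale = 100) {
  lapply(profile$blocks, function(b) {
    p <- build_pssm(b$rows$row, background = background,
                    beta = beta, scale = scale)
    attr(p, "block") <- b$index
    attr(p, "is_key") <- b$is_key
    p
  })
}

#' @export
print.dasp_pssm <- function(x, ...) {
  cat(sprintf("PSSM: %d columns, %d rows, scale %d (log2 x %d), beta %g\n",
              x$length, x$n_rows, x$scale, x$scale, x$beta))
  cat(sprintf("score range [%d, %d]\n", x$dist$min_score, x$dist$max_score))
  invisible(x)
}

#' Tidy a PSSM into a long tibble of scores
#'
#' @param x A `dasp_pssm`.
#' @param ... Unused.
#' @return Tibble with `position`, `residue`, `score`.
#' @export
tidy.dasp_pssm <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$length), each = length(x$alphabet)),
    residue = rep(x$alphabet, x$length),
    score = as.vector(x$scores)
  )
}

#' Heatmap of a PSSM's log-odds scores
#'
#' @param object A `dasp_pssm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dasp_pssm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$residue, fill = .data$score
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "motif position", y = NULL,
                  fill = sprintf("score\n(1/%d bit)", object$scale)) +
    ggplot2::theme_minimal()
}

#' Write a PSSM as a MEME-like plain-text block
#'
#' Emits a background line, a letter-probability matrix (counts plus
#' pseudocounts, normalised) and the integer log-odds matrix, column per
#' alphabet letter.
#'
#' @param pssm A `dasp_pssm`.
#' @param file Output path or connection.
#' @param name Motif name written in the header.
#' @return `file`, invisibly.
#' @export
write_pssm <- function(pssm, file, name = "motif") {
  bg <- sprintf("%s %.5f", pssm$alphabet, pssm$background)
  freq <- exp2_rows(pssm)
  lines <- c(
    sprintf("MOTIF %s", name),
    paste0("background: ", paste(bg, collapse = " ")),
    sprintf("letter-probability matrix: alength= %d w= %d nsites= %d",
            length(pssm$alphabet), pssm$length, pssm$n_rows),
    apply(freq, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
    sprintf("log-odds matrix: alength= %d w= %d",
            length(pssm$alphabet), pssm$length),
    apply(pssm$scores, 2, function(col) paste(col, collapse = " "))
  )
  writeLines(lines, file)
  invisible(file)
}

# implied per-column letter probabilities: b_a * 2^(score/scale), renormalised
exp2_rows <- function(pssm) {
  f <- pssm$background * 2^(pssm$scores / pssm$scale)
  sweep(f, 2, colSums(f), "/")
}

#' Encode a protein sequence as alphabet indices
#'
#' @param sequence Character scalar.
#' @param alphabet Alphabet (default [aa_alphabet()]).
#' @return Integer vector; letters outside the alphabet (e.g. `X`) are `NA`
#'   and score 0 in windows.
#' @export
encode_sequence <- function(sequence, alphabet = aa_alphabet()) {
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], alphabet)
}

# scores of all windows (1-based starts) of an encoded sequence against an
# integer score matrix; NA letters contribute 0
score_windows <- function(idx, scores) {
  L <- ncol(scores)
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  acc <- numeric(n)
  for (j in seq_len(L)) {
    v <- scores[, j][idx[j:(j + n - 1L)]]
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  acc
}
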