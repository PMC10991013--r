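#' Frequencies of 0/1/2-point scores for one item
#'
#' @param scores Vector of item scores in `{0, 1, 2}`.
#' @return Named integer vector `c(freq0, freq1, freq2)` summing to `n`.
#' @export
item_frequencies <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop("no scores supplied")
  if (!all(scores %in% 0:2)) stop("item scores must be 0, 1 or 2")
  c(freq0 = sum(scores == 0), freq1 = sum(scores == 1), freq2 = sum(scores == 2))
}

#' Mean and sample variance of an item from its score frequencies
#'
#' The variance uses the n-1 denominator. With fewer than two observations
#' the variance is reported as `NA`.
#'
#' @param freqs Counts `c(freq0, freq1, freq2)`.
#' @return List with `n`, `mean` and `variance`.
#' @export
item_mean_variance <- function(freqs) {
  stopifnot(length(freqs) == 3L, all(freqs >= 0))
  n <- sum(freqs)
  if (n == 0L) stop("empty frequency table")
  m <- (freqs[[2L]] + 2 * freqs[[3L]]) / n
  v <- if (n < 2L) NA_real_ else
    sum(freqs * (c(0, 1, 2) - m)^2) / (n - 1)
  list(n = n, mean = m, variance = v)
}

#' Ratio of empirical to theoretical item difficulty
#'
#' Mean observed item score divided by the chance expectation
#' [expected_item_score()]; higher values indicate easier items because the
#' cohort outperforms random guessing by a larger factor. The ratio corrects
#' for differing door counts and one-point door sets across items.
#'
#' @param mean Mean observed score.
#' @param expected Expected score under uniform random choice (> 0).
#' @return `mean / expected`, full precision.
#' @export
difficulty_ratio <- function(mean, expected) {
  if (any(expected <= 0)) stop("expected score must be positive")
  mean / expected
}

#' Average difficulty ratio per item type
#'
#' @param item_stats Data frame with columns `item_type` and
#'   `difficulty_ratio` (one row per item), e.g. from [item_analysis()].
#' @return Data frame with `item_type` and `mean_difficulty_ratio`, ordered
#'   no-turn, single-turn, double-turn, full-turn.
#' @export
item_type_difficulty <- function(item_stats) {
  stopifnot(all(c("item_type", "difficulty_ratio") %in% names(item_stats)))
  lev <- c("no-turn", "single-turn", "double-turn", "full-turn")
  if (!all(item_stats$item_type %in% lev))
    stop("unknown item type(s): ",
         paste(setdiff(unique(item_stats$item_type), lev), collapse = ", "))
  agg <- tapply(item_stats$difficulty_ratio,
                factor(item_stats$item_type, levels = lev), mean)
  agg <- agg[!is.na(agg)]
  data.frame(item_type = names(agg), mean_difficulty_ratio = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Pair classification underlying Wilson's e, computed from the x-by-y
# contingency table in O(r*c) rather than O(n^2).
pair_counts <- function(x, y) {
  tab <- unclass(table(x, y))
  r <- nrow(tab); cc <- ncol(tab)
  n <- sum(tab)
  # csum[i,j] = sum(tab[1:i, 1:j]); r and cc are small (score categories)
  csum <- tab
  if (r > 1L) for (i in 2:r) csum[i, ] <- csum[i, ] + csum[i - 1L, ]
  if (cc > 1L) for (j in 2:cc) csum[, j] <- csum[, j] + csum[, j - 1L]
  lower <- function(i, j) if (i < 1L || j < 1L) 0 else csum[i, j]
  C <- 0; D <- 0
  for (i in seq_len(r)) for (j in seq_len(cc)) {
    nij <- tab[i, j]
    if (nij == 0) next
    below_below <- lower(i - 1L, j - 1L)
    below_above <- lower(i - 1L, cc) - lower(i - 1L, j)
    C <- C + nij * below_below
    D <- D + nij * below_above
  }
  ch2 <- function(k) k * (k - 1) / 2
  t_xy <- sum(ch2(tab))
  t_x <- sum(ch2(rowSums(tab))) - t_xy   # tied on x only
  t_y <- sum(ch2(colSums(tab))) - t_xy   # tied on y only
  list(C = C, D = D, t_x = t_x, t_y = t_y, t_xy = t_xy,
       total = ch2(n))
}

#' Wilson's e ordinal association coefficient
#'
#' Classifies all n(n-1)/2 observation pairs as concordant (C), discordant
#' (D), tied on x only, tied on y only, or tied on both, and returns
#' `(C - D) / (C + D + Tx + Ty)`: only pairs tied on *both* variables are
#' excluded from the denominator. Suited to associations between ordinal
#' variables with many tied ranks (such as 0/1/2 item scores) and at-least-
#' ordinal variables; with no ties it reduces to Kendall's tau-a.
#'
#' @param x,y Equal-length numeric vectors (at least ordinal).
#' @return e in `[-1, 1]`, or `NA` (with a warning) if every pair is tied
#'   on both variables.
#' @export
wilsons_e <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two complete observations")
  pc <- pair_counts(x, y)
  denom <- pc$C + pc$D + pc$t_x + pc$t_y
  if (denom == 0) {
    warning("Wilson's e undefined: all pairs tied on both variables")
    return(NA_real_)
  }
  (pc$C - pc$D) / denom
}

#' Corrected (rest-score) item-total correlations
#'
#' For each item, Wilson's e between the item score and the total score with
#' that item removed, so an item is never correlated with itself.
#'
#' @param scores Participants x items numeric matrix of 0/1/2 scores.
#' @return Named numeric vector of e values (NA for zero-variance items).
#' @export
corrected_item_total <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) stop("need at least two items")
  totals <- rowSums(scores)
  e <- vapply(seq_len(ncol(scores)), function(j) {
    rest <- totals - scores[, j]
    tryCatch(wilsons_e(scores[, j], rest),
             warning = function(w) NA_real_)
  }, numeric(1))
  names(e) <- colnames(scores)
  e
}

#' Per-item psychometric summary table
#'
#' Builds the item-level report: score frequencies, mean, sample variance,
#' chance expectation E, difficulty ratio M/E and Wilson's e corrected
#' item-total correlation.
#'
#' @param scores Participants x items matrix of 0/1/2 scores; column names
#'   must match the item ids in `configs`.
#' @param configs List of [item_config()] objects (main items), or `NULL`
#'   if `expected` is supplied directly.
#' @param expected Optional named vector of expected scores overriding the
#'   configuration-derived E (used when reproducing published tables whose
#'   printed E values are rounded).
#' @return Data frame with one row per item: `item_id`, `item_type`,
#'   `difficulty_ratio`, `mean`, `expected`, `freq0`, `freq1`, `freq2`,
#'   `variance`, `wilson_e`.
#' @export
item_analysis <- function(scores, configs = NULL, expected = NULL) {
  scores <- as.matrix(scores)
  ids <- colnames(scores)
  if (is.null(ids)) stop("score matrix must carry item ids as column names")
  if (!is.null(configs)) {
    configs <- validate_item_bank(configs)
    configs <- configs[vapply(configs, `[[`, logical(1), "is_main")]
    cfg_ids <- vapply(configs, `[[`, character(1), "item_id")
    if (!setequal(ids, cfg_ids))
      stop("score columns and item configuration do not match")
    configs <- configs[match(ids, cfg_ids)]
    types <- vapply(configs, `[[`, character(1), "item_type")
    E <- vapply(configs, expected_item_score, numeric(1))
  } else {
    types <- rep(NA_character_, length(ids))
    E <- rep(NA_real_, length(ids))
  }
  if (!is.null(expected)) {
    stopifnot(!is.null(names(expected)), all(ids %in% names(expected)))
    E <- as.numeric(expected[ids])
  }
  if (anyNA(E)) stop("expected scores unavailable: supply configs or expected")
  fr <- t(apply(scores, 2L, item_frequencies))
  mv <- apply(fr, 1L, item_mean_variance)
  means <- vapply(mv, `[[`, numeric(1), "mean")
  vars <- vapply(mv, `[[`, numeric(1), "variance")
  data.frame(
    item_id = ids, item_type = types,
    difficulty_ratio = difficulty_ratio(means, E),
    mean = means, expected = E,
    freq0 = fr[, 1L], freq1 = fr[, 2L], freq2 = fr[, 3L],
    variance = vars,
    wilson_e = corrected_item_total(scores),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Item summary from published frequency tables
#'
#' Variant of [item_analysis()] for the case where only the per-item score
#' frequencies and (rounded) expected values are available, not raw
#' participant-level scores; Wilson's e cannot be computed from marginals
#' and is returned as `NA`.
#'
#' @param freqs Data frame with columns `item_id`, `item_type`, `freq0`,
#'   `freq1`, `freq2`, `expected`.
#' @return Same layout as [item_analysis()].
#' @export
item_analysis_from_frequencies <- function(freqs) {
  need <- c("item_id", "item_type", "freq0", "freq1", "freq2", "expected")
  stopifnot(all(need %in% names(freqs)))
  mv <- apply(freqs[, c("freq0", "freq1", "freq2")], 1L, item_mean_variance)
  means <- vapply(mv, `[[`, numeric(1), "mean")
  vars <- vapply(mv, `[[`, numeric(1), "variance")
  data.frame(
    item_id = freqs$item_id, item_type = freqs$item_type,
    difficulty_ratio = difficulty_ratio(means, freqs$expected),
    mean = means, expected = freqs$expected,
    freq0 = freqs$freq0, freq1 = freqs$freq1, freq2 = freqs$freq2,
    variance = vars, wilson_e = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
}
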