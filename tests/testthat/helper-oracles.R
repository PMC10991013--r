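# Independent brute-force oracles and shared fixtures for the suite.

# O(n^2) pair classifier for Wilson's e: explicit double loop, kept
# independent of the contingency-table implementation in the package.
wilsons_e_oracle <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- txy <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) txy <- txy + 1
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) C <- C + 1
    else D <- D + 1
  }
  denom <- C + D + tx + ty
  if (denom == 0) return(NA_real_)
  (C - D) / denom
}

# Brute-force medcouple: enumerate all pairs xi <= m <= xj of distinct
# observations; median-tied pairs use the signed -1/0/+1 kernel.
medcouple_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- stats::median(x)
  tie_idx <- which(x == m)
  h <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!(x[i] <= m && x[j] >= m)) next
    if (x[i] == m && x[j] == m) {
      p <- length(tie_idx)
      ri <- match(i, tie_idx); rj <- match(j, tie_idx)
      h <- c(h, sign(ri + rj - 1L - p))
    } else {
      h <- c(h, ((x[j] - m) - (m - x[i])) / (x[j] - x[i]))
    }
  }
  stats::median(h)
}

# Published per-item summary table (frequencies, expected scores, printed
# values) used as input for exact-recomputation checks.
table2_fixture <- function() {
  path <- system.file("extdata", "table2_items.tsv", package = "vienna")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Half-up rounding, as used at report time.
rnd <- function(x, d = 2L) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d

# A small deterministic item bank with one item per turn type.
mini_bank <- function() {
  list(
    item_config("a", "no-turn", 4L, 1L),
    item_config("b", "single-turn", 10L, 2L, updating_doors = 3L),
    item_config("c", "double-turn", 19L, 5L, updating_doors = 6L,
                rotation_doors = 14L),
    item_config("d", "full-turn", 8L, 3L, updating_doors = c(2L, 4L),
                rotation_doors = 7L))
}
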