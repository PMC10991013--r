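#' Latent-normal thresholds from ordinal category frequencies
#'
#' Step one of two-step polychoric estimation: the cut-points on a latent
#' standard-normal scale are the normal quantiles of the cumulative category
#' proportions.
#'
#' @param freqs Category counts (ordered; at least two categories used).
#' @return Numeric vector of `k - 1` strictly increasing thresholds.
#' @export
latent_thresholds <- function(freqs) {
  freqs <- as.numeric(freqs)
  stopifnot(all(freqs >= 0), sum(freqs) > 0)
  p <- freqs / sum(freqs)
  if (sum(p > 0) < 2L)
    stop("degenerate margin: a single category holds all observations (zero variance)")
  stats::qnorm(cumsum(p)[-length(p)])
}

# Standard bivariate normal rectangle CDF P(X <= h, Y <= k) with
# correlation rho, by 64-node Gauss-Legendre quadrature of
# integral_{-8}^{h} phi(x) Phi((k - rho x)/sqrt(1 - rho^2)) dx.
# Absolute accuracy ~1e-10 on the correlations used here.
pbvn <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, abs(rho) < 1)
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  out <- numeric(n)
  s <- sqrt(1 - rho^2)
  gl <- gauss_legendre_64
  for (i in seq_len(n)) {
    hi <- h[i]; ki <- k[i]
    if (hi == Inf && ki == Inf) { out[i] <- 1; next }
    if (hi == -Inf || ki == -Inf) { out[i] <- 0; next }
    if (ki == Inf) { out[i] <- stats::pnorm(hi); next }
    if (hi == Inf) { out[i] <- stats::pnorm(ki); next }
    lo <- -8; up <- min(hi, 8)
    if (up <= lo) { out[i] <- 0; next }
    x <- (up + lo) / 2 + (up - lo) / 2 * gl$nodes
    w <- (up - lo) / 2 * gl$weights
    out[i] <- sum(w * stats::dnorm(x) * stats::pnorm((ki - rho * x) / s))
  }
  out
}

# Cell probabilities of a discretized bivariate normal given thresholds.
polychoric_cell_probs <- function(tx, ty, rho) {
  cx <- c(-Inf, tx, Inf); cy <- c(-Inf, ty, Inf)
  r <- length(cx) - 1L; cc <- length(cy) - 1L
  Fg <- matrix(pbvn(rep(cx, times = length(cy)), rep(cy, each = length(cx)), rho),
               nrow = length(cx))
  P <- Fg[2:(r + 1L), 2:(cc + 1L), drop = FALSE] -
    Fg[1:r, 2:(cc + 1L), drop = FALSE] -
    Fg[2:(r + 1L), 1:cc, drop = FALSE] +
    Fg[1:r, 1:cc, drop = FALSE]
  pmax(P, 0)
}

#' Two-step polychoric correlation from a contingency table
#'
#' Estimates the correlation of two latent standard-normal variables whose
#' discretizations produced the observed cross-table of two ordinal items.
#' Thresholds are fixed at the margin-implied normal quantiles (step one);
#' the correlation then maximizes the multinomial log-likelihood with cell
#' probabilities given by bivariate-normal rectangle integrals, over the
#' bounded interval [-0.999, 0.999] (step two).
#'
#' @param tab Contingency table (matrix of counts) of item x by item y;
#'   rows/columns with zero margin are dropped.
#' @return Object of class `vienna_polychoric`: list with `rho`,
#'   `thresholds_x`, `thresholds_y`, `loglik`, `converged`.
#' @export
polychoric_corr <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), sum(tab) > 0)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate table: fewer than two used categories on a margin")
  tx <- latent_thresholds(rowSums(tab))
  ty <- latent_thresholds(colSums(tab))
  negll <- function(rho) {
    P <- polychoric_cell_probs(tx, ty, rho)
    -sum(tab * log(pmax(P, 1e-12)))
  }
  bound <- 0.999
  opt <- stats::optimize(negll, interval = c(-bound, bound), tol = 1e-6)
  rho <- opt$minimum; ll <- -opt$objective
  # optimize() cannot land exactly on a boundary; monotone-perfect tables
  # belong there by contract.
  for (b in c(-bound, bound)) {
    llb <- -negll(b)
    if (llb > ll + 1e-9) { rho <- b; ll <- llb }
  }
  structure(list(rho = rho, thresholds_x = tx, thresholds_y = ty,
                 loglik = ll, converged = TRUE),
            class = "vienna_polychoric")
}

#' @export
print.vienna_polychoric <- function(x, ...) {
  cat(sprintf("Polychoric correlation: rho = %.4f (loglik %.2f)\n", x$rho, x$loglik))
  invisible(x)
}

#' Pairwise polychoric correlation matrix of an ordinal score table
#'
#' Zero-variance items cannot enter (their latent thresholds are undefined)
#' and are dropped with a message. Pairwise estimation does not guarantee a
#' positive semi-definite matrix at small n; negative eigenvalues are
#' clipped (tolerance 1e-8) and the matrix rescaled to unit diagonal, with
#' a message when a repair occurred.
#'
#' @param scores Participants x items matrix of ordinal scores.
#' @return Correlation matrix with attribute `"excluded"` naming dropped
#'   items.
#' @export
polychoric_matrix <- function(scores) {
  scores <- as.matrix(scores)
  keep <- apply(scores, 2L, function(s) stats::var(s, na.rm = TRUE) > 0)
  keep[is.na(keep)] <- FALSE
  excluded <- colnames(scores)[!keep]
  if (length(excluded) > 0L)
    message("dropping zero-variance item(s): ", paste(excluded, collapse = ", "))
  scores <- scores[, keep, drop = FALSE]
  k <- ncol(scores)
  if (k < 2L) stop("fewer than two items with variance remain")
  R <- diag(1, k)
  dimnames(R) <- list(colnames(scores), colnames(scores))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pc <- polychoric_corr(table(scores[, i], scores[, j]))
    R[i, j] <- R[j, i] <- pc$rho
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    message("pairwise polychoric matrix not positive semi-definite; ",
            "clipping negative eigenvalues")
    vals <- pmax(ev$values, 1e-8)
    R2 <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    R <- stats::cov2cor(R2)
    dimnames(R) <- list(colnames(scores), colnames(scores))
  }
  attr(R, "excluded") <- excluded
  R
}

#' Ordinal alpha from a correlation matrix
#'
#' Cronbach-type internal consistency computed on a (polychoric)
#' correlation matrix: `alpha = k/(k-1) * (1 - k/S)` with `S` the sum of
#' all matrix entries; equivalently `k * rbar / (1 + (k-1) * rbar)` for the
#' mean off-diagonal correlation `rbar`.
#'
#' @param R Symmetric correlation matrix with unit diagonal, k >= 2.
#' @return Alpha (<= 1), or `NA` with a warning when the matrix sum is
#'   non-positive.
#' @export
ordinal_alpha <- function(R) {
  R <- as.matrix(R)
  k <- ncol(R)
  stopifnot(k >= 2L, nrow(R) == k)
  if (max(abs(diag(R) - 1)) > 1e-8) stop("matrix must have unit diagonal")
  if (max(abs(R - t(R))) > 1e-8) stop("matrix must be symmetric")
  S <- sum(R)
  if (S <= 0) {
    warning("ordinal alpha undefined: matrix sum non-positive")
    return(NA_real_)
  }
  k / (k - 1) * (1 - k / S)
}

#' Polychoric ordinal alpha with item exclusion and bootstrap CI
#'
#' Full reliability pipeline over a participants x items ordinal score
#' table: items without variance are always excluded (their polychoric
#' correlations are undefined); optionally, items at or below a variance
#' threshold are excluded as well. Alpha is computed from the pairwise
#' polychoric matrix of the remaining items, with a percentile bootstrap
#' confidence interval over participants.
#'
#' @param scores Participants x items matrix of ordinal scores.
#' @param variance_threshold Optional; exclude items with sample variance
#'   <= this value (e.g. `0.05`). Zero-variance items are excluded
#'   regardless.
#' @param nboot Bootstrap resamples for the CI (default 1000); `0` skips
#'   the CI.
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return Object of class `vienna_alpha`: list with `alpha`, `ci_low`,
#'   `ci_high`, `k_items`, `items`, `excluded_items` (data frame of label
#'   and reason), `matrix`, `nboot`.
#' @export
alpha_pipeline <- function(scores, variance_threshold = NULL,
                           nboot = 1000L, conf = 0.95, seed = NULL) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("item", seq_len(ncol(scores)))
  v <- apply(scores, 2L, stats::var, na.rm = TRUE)
  reason <- rep(NA_character_, ncol(scores))
  reason[!is.na(v) & v == 0] <- "zero variance"
  if (!is.null(variance_threshold))
    reason[is.na(reason) & v <= variance_threshold] <-
      sprintf("variance <= %g", variance_threshold)
  excluded <- data.frame(item_id = colnames(scores)[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  keep <- is.na(reason)
  if (sum(keep) < 2L)
    stop("fewer than two items remain after exclusions (",
         paste(excluded$item_id, collapse = ", "), ")")
  kept <- scores[, keep, drop = FALSE]
  R <- suppressMessages(polychoric_matrix(kept))
  alpha <- ordinal_alpha(R)
  ci <- c(NA_real_, NA_real_)
  if (nboot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(kept)
    boots <- vapply(seq_len(nboot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      sb <- kept[idx, , drop = FALSE]
      ok <- apply(sb, 2L, function(s) stats::var(s) > 0)
      if (sum(ok) < 2L) return(NA_real_)
      tryCatch(ordinal_alpha(suppressMessages(polychoric_matrix(sb[, ok, drop = FALSE]))),
               error = function(e) NA_real_)
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(a, 1 - a), na.rm = TRUE))
  }
  structure(list(alpha = alpha, ci_low = ci[1L], ci_high = ci[2L],
                 k_items = ncol(kept), items = colnames(kept),
                 excluded_items = excluded, matrix = R, nboot = nboot),
            class = "vienna_alpha")
}

#' @export
print.vienna_alpha <- function(x, ...) {
  cat(sprintf("Polychoric ordinal alpha = %.2f", x$alpha))
  if (!is.na(x$ci_low))
    cat(sprintf(", 95%% CI [%.2f, %.2f] (%d bootstrap resamples)",
                x$ci_low, x$ci_high, x$nboot))
  cat(sprintf("\n%d items", x$k_items))
  if (nrow(x$excluded_items) > 0L)
    cat("; excluded: ",
        paste(sprintf("%s (%s)", x$excluded_items$item_id, x$excluded_items$reason),
              collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}
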