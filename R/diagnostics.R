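#' Sample skewness and excess kurtosis with standard-error z scores
#'
#' Adjusted Fisher-Pearson (sample-size corrected) skewness G1 and excess
#' kurtosis G2, each divided by its exact normal-theory standard error:
#' `SE(g1) = sqrt(6n(n-1) / ((n-2)(n+1)(n+3)))` and
#' `SE(g2) = sqrt(24n(n-1)^2 / ((n-3)(n-2)(n+3)(n+5)))`.
#'
#' @param x Numeric vector, n >= 4 (kurtosis SE needs n >= 4; its z is `NA`
#'   below that).
#' @return List with `skewness`, `kurtosis_excess`, `se_skew`, `se_kurt`,
#'   `z_skew`, `z_kurt`, `n`.
#' @export
shape_statistics <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) stop("need at least four observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance: shape statistics undefined")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * g2 + 6)
  se1 <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  se2 <- sqrt(24 * n * (n - 1)^2 / ((n - 3) * (n - 2) * (n + 3) * (n + 5)))
  list(skewness = G1, kurtosis_excess = G2, se_skew = se1, se_kurt = se2,
       z_skew = G1 / se1, z_kurt = G2 / se2, n = n)
}

#' Normality flag under the |z| < 3.29 rule
#'
#' A variable is treated as normally distributed when the absolute z scores
#' of both skewness and excess kurtosis fall strictly below 3.29, the
#' conventional threshold for medium sample sizes.
#'
#' @param z_skew,z_kurt z scores from [shape_statistics()].
#' @param threshold Decision threshold (default 3.29, exclusive).
#' @return Logical.
#' @export
normality_flag <- function(z_skew, z_kurt, threshold = 3.29) {
  stopifnot(is.finite(z_skew), is.finite(z_kurt))
  abs(z_skew) < threshold && abs(z_kurt) < threshold
}

#' Medcouple robust skewness measure
#'
#' Median of the kernel `h(xi, xj) = ((xj - m) - (m - xi)) / (xj - xi)`
#' over all pairs with `xi <= m <= xj`, where `m` is the sample median.
#' Pairs of observations both equal to the median use the standard signed
#' -1/0/+1 kernel indexed by their position among the ties. The medcouple
#' lies in [-1, 1]; 0 for symmetric samples, positive under right skew.
#' O(n^2) evaluation, adequate for cohort-sized samples.
#'
#' @param x Numeric vector, n >= 3, not all equal.
#' @return MC in `[-1, 1]`.
#' @export
medcouple <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 3L) stop("need at least three observations")
  if (x[1L] == x[n]) stop("all values equal: medcouple undefined")
  m <- stats::median(x)
  zL <- x[x < m] - m   # strictly below the median
  zU <- x[x > m] - m   # strictly above
  p <- sum(x == m)     # observations tied with the median
  h <- c(
    # mixed pairs: h = ((xj - m) - (m - xi)) / (xj - xi) = (zj + zi)/(zj - zi)
    if (length(zL) > 0L && length(zU) > 0L)
      as.vector(outer(zL, zU, function(a, b) (b + a) / (b - a))),
    # a median-tied observation paired below/above gives -1 / +1 exactly
    rep(-1, p * length(zL)),
    rep(+1, p * length(zU)))
  if (p > 1L) {
    # distinct pairs among the p median-tied observations use the signed
    # special kernel: sign(i + j - 1 - p) over 1 <= i < j <= p
    ij <- utils::combn(p, 2L)
    h <- c(h, sign(ij[1L, ] + ij[2L, ] - 1L - p))
  }
  stats::median(h)
}

#' Adjusted boxplot outlier detection for skewed distributions
#'
#' Skewness-adjusted Tukey fences: with medcouple MC >= 0 the fences are
#' `[Q1 - 1.5 exp(-4 MC) IQR, Q3 + 1.5 exp(3 MC) IQR]`; with MC < 0,
#' `[Q1 - 1.5 exp(-3 MC) IQR, Q3 + 1.5 exp(4 MC) IQR]`. With MC = 0 this
#' is exactly the classical 1.5 IQR rule. Values strictly outside the
#' fences are flagged. Quartiles use linear interpolation
#' (`quantile(type = 7)`).
#'
#' @param x Numeric vector (names, if present, label the outliers), n >= 4.
#' @param coef Fence coefficient (default 1.5).
#' @return Object of class `vienna_outliers`: list with `method`, `fences`,
#'   `outlier_ids`, `outlier_values`, `medcouple`.
#' @export
adjusted_boxplot <- function(x, coef = 1.5) {
  ids <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
  keep <- !is.na(x)
  x2 <- x[keep]; ids <- ids[keep]
  if (length(x2) < 4L) stop("need at least four observations")
  q <- stats::quantile(x2, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  if (iqr == 0) {
    warning("zero interquartile range: no outliers flagged")
    return(structure(list(method = "adjusted_boxplot", fences = c(q[1L], q[2L]),
                          outlier_ids = character(0), outlier_values = numeric(0),
                          medcouple = NA_real_),
                     class = "vienna_outliers"))
  }
  mc <- medcouple(x2)
  if (mc >= 0) {
    fences <- c(q[1L] - coef * exp(-4 * mc) * iqr, q[2L] + coef * exp(3 * mc) * iqr)
  } else {
    fences <- c(q[1L] - coef * exp(-3 * mc) * iqr, q[2L] + coef * exp(4 * mc) * iqr)
  }
  out <- x2 < fences[1L] | x2 > fences[2L]
  structure(list(method = "adjusted_boxplot", fences = fences,
                 outlier_ids = ids[out], outlier_values = unname(x2[out]),
                 medcouple = mc),
            class = "vienna_outliers")
}

#' Outliers by distance from the mean in standard deviations
#'
#' Flags values outside `mean(x) +/- k * sd(x)`; the symmetric rule used as
#' a feasibility check on approximately normal scores.
#'
#' @param x Numeric vector, n >= 2.
#' @param k Multiplier (default 2.5).
#' @return Object of class `vienna_outliers` (see [adjusted_boxplot()]).
#' @export
sd_rule_outliers <- function(x, k = 2.5) {
  ids <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
  keep <- !is.na(x)
  x2 <- x[keep]; ids <- ids[keep]
  if (length(x2) < 2L) stop("need at least two observations")
  m <- mean(x2); s <- stats::sd(x2)
  fences <- c(m - k * s, m + k * s)
  out <- x2 < fences[1L] | x2 > fences[2L]
  structure(list(method = "sd_rule", fences = fences,
                 outlier_ids = ids[out], outlier_values = unname(x2[out]),
                 medcouple = NA_real_),
            class = "vienna_outliers")
}

#' @export
print.vienna_outliers <- function(x, ...) {
  cat(sprintf("%s: fences [%.3f, %.3f]; %d outlier(s)%s\n",
              x$method, x$fences[1L], x$fences[2L], length(x$outlier_ids),
              if (length(x$outlier_ids) > 0)
                paste0(": ", paste(x$outlier_ids, collapse = ", ")) else ""))
  invisible(x)
}

#' Floor and ceiling effects against the theoretical score range
#'
#' @param x Observed scores.
#' @param min_possible,max_possible Theoretical bounds of the score.
#' @return List with counts and proportions of observations exactly at each
#'   bound.
#' @export
floor_ceiling <- function(x, min_possible, max_possible) {
  x <- x[!is.na(x)]
  stopifnot(min_possible < max_possible)
  if (any(x < min_possible | x > max_possible))
    stop("observed value outside the theoretical range [",
         min_possible, ", ", max_possible, "]")
  n <- length(x)
  list(n = n,
       floor_count = sum(x == min_possible),
       ceiling_count = sum(x == max_possible),
       floor_proportion = sum(x == min_possible) / n,
       ceiling_proportion = sum(x == max_possible) / n)
}

#' Descriptive and shape diagnostics for one variable
#'
#' One row of a descriptive table: mean, SD, median, MAD (unscaled, i.e.
#' the raw median absolute deviation without the 1.4826 normal-consistency
#' factor), range, standard error of the mean, skewness and excess kurtosis
#' with their z scores, and the normality flag under the 3.29 rule.
#'
#' @param x Numeric vector, n >= 4.
#' @param mad_constant Scale factor for the MAD (default 1 = unscaled;
#'   use 1.4826 for normal consistency).
#' @return Data frame with one row.
#' @export
distribution_diagnostics <- function(x, mad_constant = 1) {
  x <- x[!is.na(x)]
  sh <- shape_statistics(x)
  data.frame(
    n = sh$n, mean = mean(x), sd = stats::sd(x),
    median = stats::median(x),
    mad = stats::mad(x, constant = mad_constant),
    min = min(x), max = max(x),
    se_mean = stats::sd(x) / sqrt(sh$n),
    skewness = sh$skewness, z_skew = sh$z_skew,
    kurtosis_excess = sh$kurtosis_excess, z_kurt = sh$z_kurt,
    normal = normality_flag(sh$z_skew, sh$z_kurt))
}
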