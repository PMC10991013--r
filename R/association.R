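#' Choose Pearson or Spearman by the 3.29 normality rule
#'
#' Pearson's product-moment correlation is used only when both variables
#' pass the normality flag (absolute skewness and kurtosis z scores below
#' 3.29); otherwise Spearman's rho.
#'
#' @param x_diag,y_diag Rows from [distribution_diagnostics()] (or any list
#'   with a logical `normal` element).
#' @return `"pearson"` or `"spearman"`.
#' @export
choose_coefficient <- function(x_diag, y_diag) {
  stopifnot(is.logical(x_diag$normal), is.logical(y_diag$normal))
  if (isTRUE(x_diag$normal) && isTRUE(y_diag$normal)) "pearson" else "spearman"
}

#' Partial correlation controlling for one or more variables
#'
#' Correlation between the residuals of `x` and `y` after linear projection
#' on the control variables (equivalent to the recursive partial-correlation
#' formula for a single control). Spearman's variant ranks all variables
#' first. Cases with missing values in any involved variable are dropped
#' (pairwise-complete per analysis; missings are never imputed).
#'
#' @param x,y Numeric vectors.
#' @param controls Numeric vector, matrix or data frame of control
#'   variables (at least one).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame with `estimate`, `statistic` (t), `df`, `p_value`,
#'   `n`, `n_controls`, `method`.
#' @export
partial_corr <- function(x, y, controls, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  Z <- as.matrix(as.data.frame(controls))
  if (ncol(Z) < 1L) stop("at least one control variable is required")
  stopifnot(length(x) == length(y), nrow(Z) == length(x))
  keep <- stats::complete.cases(x, y, Z)
  x <- x[keep]; y <- y[keep]; Z <- Z[keep, , drop = FALSE]
  n <- length(x)
  k <- ncol(Z)
  if (n <= k + 2L) stop("too few complete cases for ", k, " control(s)")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); Z <- apply(Z, 2L, rank)
  }
  qz <- qr(cbind(1, Z))
  if (qz$rank < k + 1L) stop("control set is singular (collinear controls)")
  rx <- stats::resid(stats::lm.fit(cbind(1, Z), x))
  ry <- stats::resid(stats::lm.fit(cbind(1, Z), y))
  r <- stats::cor(rx, ry)
  df <- n - k - 2L
  tval <- r * sqrt(df / (1 - r^2))
  data.frame(estimate = r, statistic = tval, df = df,
             p_value = 2 * stats::pt(-abs(tval), df),
             n = n, n_controls = k, method = method,
             stringsAsFactors = FALSE)
}

#' Average-performance composite over a test battery
#'
#' For evaluating one test's specific association with the navigation
#' score, the remaining battery is collapsed into a composite: each
#' component is z-standardized within the cohort, direction-aligned so that
#' higher always means better, and averaged per participant over the
#' non-missing components. The evaluated test (and the navigation score
#' itself) are excluded via `exclude`.
#'
#' @param battery Data frame of numeric test scores (participants x tests).
#' @param exclude Character vector of column names to leave out.
#' @param sign_map Optional named numeric vector of +1/-1 per column
#'   (default +1): -1 marks tests where higher raw values mean worse
#'   performance.
#' @return Numeric vector of composite scores (NA when every component is
#'   missing for a participant), with attribute `"components"`.
#' @export
average_performance_composite <- function(battery, exclude = character(0),
                                          sign_map = NULL) {
  battery <- as.data.frame(battery)
  use <- setdiff(names(battery), exclude)
  if (length(use) < 2L) stop("fewer than two component tests remain")
  Z <- vapply(use, function(nm) {
    v <- battery[[nm]]
    s <- if (!is.null(sign_map) && nm %in% names(sign_map)) sign_map[[nm]] else 1
    sdv <- stats::sd(v, na.rm = TRUE)
    if (is.na(sdv) || sdv == 0) {
      warning("component ", nm, " has zero variance; composite contribution is 0")
      return(rep(0, nrow(battery)))
    }
    s * (v - mean(v, na.rm = TRUE)) / sdv
  }, numeric(nrow(battery)))
  comp <- rowMeans(Z, na.rm = TRUE)
  comp[!is.finite(comp)] <- NA_real_
  attr(comp, "components") <- use
  comp
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment; a validating wrapper around
#' `stats::p.adjust(method = "BH")` that keeps the original order.
#'
#' @param p Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Independent-samples t test from summary statistics
#'
#' Pooled-variance two-sample t test computed from group means, standard
#' deviations and sizes, as needed when only published summaries are
#' available; df = n1 + n2 - 2, two-tailed p.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @return Data frame with `t`, `df`, `p_value`, `mean_diff`.
#' @export
ttest_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- m1 - m2
  if (se == 0) {
    if (d == 0) {
      tval <- 0
    } else {
      warning("zero pooled variance with unequal means: t is infinite")
      tval <- sign(d) * Inf
    }
  } else {
    tval <- d / se
  }
  data.frame(t = tval, df = df,
             p_value = 2 * stats::pt(-abs(tval), df),
             mean_diff = d)
}

#' Homogeneity-of-variance check (Levene's test)
#'
#' Levene's test on absolute deviations from the group means (delegated to
#' `car::leveneTest(center = mean)`); homogeneity is accepted when
#' p >= .05, the precondition for the pooled-variance t test.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor/vector (>= 2 groups, each n >= 2).
#' @return List with `statistic` (F), `df`, `p_value`, `homogeneous`.
#' @export
levene_check <- function(values, groups) {
  groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs at least two observations")
  lt <- car::leveneTest(values ~ groups, center = mean)
  list(statistic = lt[["F value"]][1L],
       df = c(lt[["Df"]][1L], lt[["Df"]][2L]),
       p_value = lt[["Pr(>F)"]][1L],
       homogeneous = lt[["Pr(>F)"]][1L] >= 0.05)
}

#' Z test for the difference of two regression coefficients
#'
#' Normal-theory comparison of two (standardized) regression coefficients
#' with their standard errors: `Z = (b1 - b2) / sqrt(se1^2 + se2^2)`.
#'
#' @param b1,se1 First coefficient and its standard error (> 0).
#' @param b2,se2 Second coefficient and its standard error (> 0).
#' @return Data frame with `z` and two-tailed `p_value`.
#' @export
clogg_z <- function(b1, se1, b2, se2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  data.frame(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Correlation battery of a score against a set of variables
#'
#' For each variable: the coefficient type is chosen by the 3.29 normality
#' rule ([choose_coefficient()]), the plain correlation and, when controls
#' are supplied, partial correlations are computed on pairwise-complete
#' cases, and p values are Benjamini-Hochberg adjusted within the battery
#' (one family per column, the default) or across all columns.
#'
#' @param score Numeric outcome vector (e.g. total navigation score).
#' @param battery Data frame of covariates (participants in rows).
#' @param age Optional numeric vector: partial correlations controlling for
#'   age are added.
#' @param composite_exclude Optional character vector naming battery
#'   columns that are *tests* entering the average-performance composite;
#'   when given, partial correlations controlling for the composite
#'   (excluding the evaluated test) are added for those columns.
#' @param sign_map Passed to [average_performance_composite()].
#' @param family `"per_column"` (default) adjusts each correlation column
#'   separately; `"pooled"` adjusts all p values as one family.
#' @return Data frame, one row per battery variable.
#' @export
association_battery <- function(score, battery, age = NULL,
                                composite_exclude = NULL, sign_map = NULL,
                                family = c("per_column", "pooled")) {
  family <- match.arg(family)
  battery <- as.data.frame(battery)
  sd_diag <- distribution_diagnostics(score)
  one <- function(v) {
    keep <- stats::complete.cases(score, v)
    vy <- v[keep]; vs <- score[keep]
    meth <- tryCatch(
      choose_coefficient(sd_diag, distribution_diagnostics(vy)),
      error = function(e) "spearman")
    ct <- stats::cor.test(vs, vy, method = meth, exact = FALSE)
    data.frame(method = meth, estimate = unname(ct$estimate),
               p_value = ct$p.value, n = length(vs), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(names(battery), function(nm) {
    r0 <- one(battery[[nm]])
    row <- data.frame(variable = nm, r0, stringsAsFactors = FALSE)
    if (!is.null(age)) {
      pa <- tryCatch(partial_corr(score, battery[[nm]], age, method = r0$method),
                     error = function(e) NULL)
      row$r_partial_age <- if (is.null(pa)) NA_real_ else pa$estimate
      row$p_partial_age <- if (is.null(pa)) NA_real_ else pa$p_value
    }
    if (!is.null(composite_exclude) && nm %in% composite_exclude) {
      comp <- average_performance_composite(
        battery[, composite_exclude, drop = FALSE],
        exclude = nm, sign_map = sign_map)
      pc <- tryCatch(partial_corr(score, battery[[nm]], comp, method = r0$method),
                     error = function(e) NULL)
      row$r_partial_composite <- if (is.null(pc)) NA_real_ else pc$estimate
      row$p_partial_composite <- if (is.null(pc)) NA_real_ else pc$p_value
    } else if (!is.null(composite_exclude)) {
      row$r_partial_composite <- NA_real_
      row$p_partial_composite <- NA_real_
    }
    row
  }))
  pcols <- intersect(c("p_value", "p_partial_age", "p_partial_composite"),
                     names(res))
  if (family == "pooled") {
    all_p <- unlist(res[pcols])
    adj <- bh_adjust(all_p)
    m <- matrix(adj, nrow = nrow(res))
    for (i in seq_along(pcols))
      res[[sub("^p", "p_adj", pcols[i])]] <- m[, i]
  } else {
    for (pc in pcols) res[[sub("^p", "p_adj", pc)]] <- bh_adjust(res[[pc]])
  }
  rownames(res) <- NULL
  res
}
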