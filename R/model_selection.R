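#' Forced-entry multiple regression
#'
#' Ordinary least squares with all predictors entered simultaneously.
#' Predictors are z-standardized by default so coefficients are on a
#' per-SD scale (the outcome stays on its raw scale and the intercept is
#' the outcome mean); set `standardize = FALSE` for raw-scale slopes.
#' Cases with missing values are dropped listwise.
#'
#' @param y Numeric outcome.
#' @param X Data frame or matrix of predictors (no constant columns).
#' @param standardize Standardize predictors to unit variance (default TRUE).
#' @param conf Confidence level for coefficient intervals (default 0.95).
#' @return Object of class `vienna_ols`: list with `coefficients` (data
#'   frame: term, b, ci_low, ci_high, t, p_value), `r_squared`,
#'   `adj_r_squared`, `f_statistic`, `df`, `n`, `predictors`, `fit` (the
#'   underlying `lm`), `standardize`.
#' @export
forced_entry_ols <- function(y, X, standardize = TRUE, conf = 0.95) {
  X <- as.data.frame(X)
  if (ncol(X) < 1L) stop("no predictors supplied")
  stopifnot(length(y) == nrow(X))
  keep <- stats::complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(X) + 1L) stop("need n > p + 1 complete cases")
  const <- vapply(X, function(v) stats::sd(v) == 0, logical(1))
  if (any(const))
    stop("constant predictor(s): ", paste(names(X)[const], collapse = ", "))
  if (standardize) X[] <- lapply(X, function(v) (v - mean(v)) / stats::sd(v))
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  # embed the data in the stored call so step()/update() can re-evaluate it
  fit$call$data <- dat
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    b = sm$coefficients[, 1L],
    ci_low = ci[, 1L], ci_high = ci[, 2L],
    t = sm$coefficients[, 3L],
    p_value = sm$coefficients[, 4L],
    row.names = NULL, stringsAsFactors = FALSE)
  fstat <- if (is.null(sm$fstatistic)) c(NA_real_, NA_real_, NA_real_) else sm$fstatistic
  structure(list(coefficients = coefs,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 f_statistic = unname(fstat[1L]),
                 df = unname(fstat[2:3]),
                 n = n, predictors = names(X), fit = fit,
                 standardize = standardize),
            class = "vienna_ols")
}

#' @export
print.vienna_ols <- function(x, ...) {
  cat(sprintf("OLS: %d predictors, n = %d, R^2 = %.3f, F(%g, %g) = %.2f\n",
              length(x$predictors), x$n, x$r_squared, x$df[1L], x$df[2L],
              x$f_statistic))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Variance comparison of nested regression models
#'
#' F test for the loss of explained variance when dropping predictors:
#' `F = (Delta SSR / Delta df) / (SSE_full / df_full)`, with `Delta R^2`
#' reported alongside. Models must be fitted on the same cases and the
#' reduced predictor set must be a subset of the full set.
#'
#' @param full,reduced Objects from [forced_entry_ols()].
#' @return Data frame with `delta_r2`, `f`, `df1`, `df2`, `p_value`.
#' @export
nested_anova <- function(full, reduced) {
  stopifnot(inherits(full, "vienna_ols"), inherits(reduced, "vienna_ols"))
  if (!all(reduced$predictors %in% full$predictors))
    stop("models are not nested: reduced predictors must be a subset of the full set")
  if (full$n != reduced$n)
    stop("models were fitted on different numbers of cases")
  sse_full <- sum(stats::resid(full$fit)^2)
  sse_red <- sum(stats::resid(reduced$fit)^2)
  df_full <- stats::df.residual(full$fit)
  df1 <- stats::df.residual(reduced$fit) - df_full
  delta_r2 <- full$r_squared - reduced$r_squared
  if (df1 == 0L) {
    return(data.frame(delta_r2 = 0, f = 0, df1 = 0, df2 = df_full, p_value = 1))
  }
  f <- ((sse_red - sse_full) / df1) / (sse_full / df_full)
  data.frame(delta_r2 = delta_r2, f = f, df1 = df1, df2 = df_full,
             p_value = stats::pf(f, df1, df_full, lower.tail = FALSE))
}

#' Backward predictor reduction by p value with a nested-ANOVA stop rule
#'
#' Starting from the forced-entry model, predictors with p values at or
#' above the liberal threshold (default .10) are dropped and the model is
#' refitted; if the liberal threshold would drop nothing, the stricter
#' fallback (default .05) is applied. Reduction stops when the reduced
#' model explains significantly less variance than its predecessor (the
#' predecessor is returned, stop reason `"delta R2 significant"`) or when
#' all retained predictors are significant at .05.
#'
#' @param y,X,standardize As in [forced_entry_ols()].
#' @param keep_threshold Liberal retention threshold (default 0.10: keep
#'   predictors with p < .10).
#' @param fallback Stricter threshold used when the liberal one drops
#'   nothing (default 0.05).
#' @param alpha Significance level for the stop rules (default 0.05).
#' @return Object of class `vienna_reduction`: list with `model` (final
#'   [forced_entry_ols()] fit), `trace` (data frame: step, predictors,
#'   dropped, rule, nested-F and p), `stop_reason`.
#' @export
reduce_by_p <- function(y, X, keep_threshold = 0.10, fallback = 0.05,
                        alpha = 0.05, standardize = TRUE) {
  X <- as.data.frame(X)
  current <- forced_entry_ols(y, X, standardize = standardize)
  trace <- data.frame(step = 0L,
                      predictors = paste(current$predictors, collapse = "+"),
                      dropped = "", rule = "full model",
                      f = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    co <- current$coefficients
    co <- co[co$term != "(Intercept)", ]
    if (all(co$p_value < alpha)) {
      stop_reason <- "all predictors significant"
      break
    }
    drop_lib <- co$term[co$p_value >= keep_threshold]
    rule <- sprintf("p >= %.2f", keep_threshold)
    if (length(drop_lib) == 0L) {
      drop_lib <- co$term[co$p_value >= fallback]
      rule <- sprintf("p >= %.2f (fallback)", fallback)
    }
    if (length(drop_lib) == 0L || length(drop_lib) == nrow(co)) {
      if (length(drop_lib) == nrow(co)) {
        warning("reduction would drop every predictor; returning current model")
        stop_reason <- "all predictors would be dropped"
      } else {
        stop_reason <- "no predictor met the drop rule"
      }
      break
    }
    keep_terms <- setdiff(current$predictors, drop_lib)
    candidate <- forced_entry_ols(
      stats::model.frame(current$fit)$.y,
      stats::model.frame(current$fit)[keep_terms],
      standardize = FALSE)  # already standardized in the first fit
    an <- nested_anova(current, candidate)
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(
      step = step_i, predictors = paste(keep_terms, collapse = "+"),
      dropped = paste(drop_lib, collapse = "+"), rule = rule,
      f = an$f, p_value = an$p_value, stringsAsFactors = FALSE))
    if (an$p_value < alpha) {
      stop_reason <- "delta R2 significant"
      break
    }
    current <- candidate
  }
  structure(list(model = current, trace = trace, stop_reason = stop_reason),
            class = "vienna_reduction")
}

#' @export
print.vienna_reduction <- function(x, ...) {
  cat("Backward reduction by p value\n")
  print(x$trace, digits = 3)
  cat("stop reason:", x$stop_reason, "\n")
  print(x$model)
  invisible(x)
}

#' Backward stepwise regression by AIC
#'
#' Repeatedly removes the predictor whose removal lowers the Akaike
#' information criterion the most, stopping when no removal lowers it
#' (delegated to `stats::step(direction = "backward")` on the forced-entry
#' fit; Gaussian log-likelihood AIC, so comparisons across nested fits on
#' identical cases are valid).
#'
#' @param y,X,standardize As in [forced_entry_ols()].
#' @return Object of class `vienna_ols` for the selected model, with the
#'   retained predictor names in `$predictors` (empty if intercept-only).
#' @export
aic_backward <- function(y, X, standardize = TRUE) {
  X <- as.data.frame(X)
  full <- forced_entry_ols(y, X, standardize = standardize)
  sel <- stats::step(full$fit, direction = "backward", trace = 0)
  kept <- setdiff(attr(stats::terms(sel), "term.labels"), character(0))
  if (length(kept) == 0L) {
    sm <- summary(sel)
    co <- stats::coef(sm)
    out <- structure(list(
      coefficients = data.frame(term = rownames(co), b = co[, 1L],
                                ci_low = stats::confint(sel)[, 1L],
                                ci_high = stats::confint(sel)[, 2L],
                                t = co[, 3L], p_value = co[, 4L],
                                row.names = NULL, stringsAsFactors = FALSE),
      r_squared = 0, adj_r_squared = 0, f_statistic = NA_real_,
      df = c(NA_real_, NA_real_), n = full$n, predictors = character(0),
      fit = sel, standardize = standardize), class = "vienna_ols")
    return(out)
  }
  forced_entry_ols(stats::model.frame(full$fit)$.y,
                   stats::model.frame(full$fit)[kept],
                   standardize = FALSE)
}
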