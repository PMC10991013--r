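#' Read an item configuration table
#'
#' Expects a delimited text file with header columns `item_id`,
#' `item_type`, `n_doors`, `correct_door`, `updating_doors`,
#' `rotation_doors` and optionally `is_main`; the door-set columns hold
#' semicolon-separated 1-based door ids (empty for none). Every record is
#' validated through [item_config()], and validation failures name the
#' offending line.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return List of [item_config()] objects.
#' @export
read_item_config <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("item_id", "item_type", "n_doors", "correct_door",
            "updating_doors", "rotation_doors")
  if (!all(need %in% names(df)))
    stop("item config file lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  parse_set <- function(s) {
    s <- trimws(s)
    if (is.na(s) || s == "") integer(0)
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1L]])
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      item_config(df$item_id[i], df$item_type[i],
                  as.integer(df$n_doors[i]), as.integer(df$correct_door[i]),
                  updating_doors = parse_set(df$updating_doors[i]),
                  rotation_doors = parse_set(df$rotation_doors[i]),
                  is_main = if ("is_main" %in% names(df))
                    as.logical(df$is_main[i]) else TRUE),
      error = function(e)
        stop("invalid item configuration at line ", i + 1L, " of ", path,
             ": ", conditionMessage(e), call. = FALSE))
  }
  validate_item_bank(out)
}

#' Write an item configuration table
#'
#' Inverse of [read_item_config()]; round-trips losslessly.
#'
#' @param configs List of [item_config()] objects.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @export
write_item_config <- function(configs, path, sep = "\t") {
  configs <- validate_item_bank(configs)
  df <- do.call(rbind, lapply(configs, function(cfg) data.frame(
    item_id = cfg$item_id, item_type = cfg$item_type,
    n_doors = cfg$n_doors, correct_door = cfg$correct_door,
    updating_doors = paste(cfg$updating_doors, collapse = ";"),
    rotation_doors = paste(cfg$rotation_doors, collapse = ";"),
    is_main = cfg$is_main, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format response table
#'
#' Delimited text with header `participant_id`, `item_id`, `chosen_door`;
#' duplicate (participant, item) rows are rejected, malformed door values
#' are rejected rather than coerced.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Data frame with character ids and integer `chosen_door`.
#' @export
read_responses <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("participant_id", "item_id", "chosen_door")
  if (!all(need %in% names(df)))
    stop("response file lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$participant_id <- as.character(df$participant_id)
  df$item_id <- as.character(df$item_id)
  door <- suppressWarnings(as.integer(df$chosen_door))
  bad <- which(is.na(door) & !is.na(df$chosen_door))
  if (length(bad) > 0L)
    stop("non-integer chosen_door at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  df$chosen_door <- door
  dup <- duplicated(df[, c("participant_id", "item_id")])
  if (any(dup))
    stop("duplicate (participant, item) response row(s), first at data row ",
         which(dup)[1L])
  df
}

#' Read a wide covariate table
#'
#' Delimited text with a `participant_id` column and one column per
#' covariate; empty cells become `NA` and are preserved (never imputed) so
#' downstream analyses stay pairwise-complete.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Data frame, `participant_id` as character, covariates numeric.
#' @export
read_covariates <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"participant_id" %in% names(df))
    stop("covariate file lacks a participant_id column")
  if (anyDuplicated(df$participant_id))
    stop("duplicate participant_id rows in covariate file")
  df$participant_id <- as.character(df$participant_id)
  for (nm in setdiff(names(df), "participant_id")) {
    v <- df[[nm]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & !is.na(v)))
        stop("non-numeric value in covariate column ", nm)
      df[[nm]] <- num
    }
  }
  df
}

#' Write a cohort's files in the formats the readers consume
#'
#' Emits `items.tsv`, `responses.tsv` and `covariates.tsv` for a simulated
#' cohort, so the full pipeline can be exercised end-to-end from files.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vienna_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(items = file.path(dir, "items.tsv"),
             responses = file.path(dir, "responses.tsv"),
             covariates = file.path(dir, "covariates.tsv"))
  write_item_config(cohort$config$items, paths[["items"]])
  utils::write.table(cohort$responses, paths[["responses"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$covariates, paths[["covariates"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

format_report <- function(df, digits = 2L) {
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- round_half_up(df[[nm]], digits)
  df
}

#' Run the full evaluation pipeline
#'
#' Executes the analysis stages in their canonical order on file inputs or
#' in-memory tables: scoring, distribution diagnostics and outlier checks
#' on the total score and error counts, item analysis, polychoric ordinal
#' alpha (always excluding zero-variance items, plus the configured
#' variance-threshold variant), the association battery with
#' Benjamini-Hochberg correction, and the regression reduction when enough
#' complete predictors exist. Reports are written as TSV (rounded to 2
#' decimals) next to machine-readable full-precision TSVs, plus a JSON run
#' log carrying the seed and options.
#'
#' @param items Item configuration: path or list of [item_config()]s.
#' @param responses Long response table: path or data frame.
#' @param covariates Optional covariate table: path or data frame.
#' @param out_dir Output directory for reports; `NULL` writes nothing.
#' @param variance_threshold Item-variance threshold for the reliability
#'   variant (default 0.05).
#' @param outlier_method `"sd_rule"` (default) or `"adjusted_boxplot"` for
#'   the total-score feasibility check.
#' @param nboot Bootstrap resamples for the alpha CI (default 200 at
#'   pipeline level; see [alpha_pipeline()]).
#' @param regression_predictors Optional character vector of covariate
#'   columns to enter the forced-entry regression and backward reduction;
#'   `NULL` skips the regression stage.
#' @param seed Seed recorded in the run log and used for the bootstrap.
#' @return Object of class `vienna_pipeline` (list of stage results).
#' @export
run_pipeline <- function(items, responses, covariates = NULL, out_dir = NULL,
                         variance_threshold = 0.05,
                         outlier_method = c("sd_rule", "adjusted_boxplot"),
                         nboot = 200L, regression_predictors = NULL,
                         seed = 1L) {
  outlier_method <- match.arg(outlier_method)
  if (is.character(items)) items <- read_item_config(items)
  items <- validate_item_bank(items)
  if (is.character(responses)) responses <- read_responses(responses)
  if (!is.null(covariates) && is.character(covariates))
    covariates <- read_covariates(covariates)

  scored <- score_cohort(items, responses)
  totals <- stats::setNames(scored$summary$total, scored$summary$participant_id)
  max_total <- 2L * sum(vapply(items, `[[`, logical(1), "is_main"))

  diagnostics <- rbind(
    cbind(variable = "total", distribution_diagnostics(scored$summary$total)),
    cbind(variable = "rotation_errors",
          distribution_diagnostics(scored$summary$n_rotation)),
    cbind(variable = "updating_errors",
          distribution_diagnostics(scored$summary$n_updating)))
  outliers <- if (outlier_method == "sd_rule") sd_rule_outliers(totals)
              else adjusted_boxplot(totals)
  fc <- floor_ceiling(scored$summary$total, 0L, max_total)

  items_tab <- item_analysis(scored$scores, configs = items)
  type_tab <- item_type_difficulty(items_tab)
  reliability <- alpha_pipeline(scored$scores, nboot = nboot, seed = seed)
  reliability_variant <- tryCatch(
    alpha_pipeline(scored$scores, variance_threshold = variance_threshold,
                   nboot = nboot, seed = seed),
    error = function(e) NULL)

  assoc <- NULL
  if (!is.null(covariates)) {
    m <- merge(scored$summary[, c("participant_id", "total")], covariates,
               by = "participant_id", sort = FALSE)
    battery <- m[, setdiff(names(m), c("participant_id", "total", "age")),
                 drop = FALSE]
    assoc <- association_battery(m$total, battery,
                                 age = if ("age" %in% names(m)) m$age else NULL)
  }

  regression <- NULL
  if (!is.null(covariates) && !is.null(regression_predictors)) {
    m <- merge(scored$summary[, c("participant_id", "total")], covariates,
               by = "participant_id", sort = FALSE)
    missing_cols <- setdiff(regression_predictors, names(m))
    if (length(missing_cols) > 0L)
      stop("regression stage: unknown predictor(s) ",
           paste(missing_cols, collapse = ", "))
    cc <- stats::complete.cases(m[, c("total", regression_predictors)])
    regression <- list(
      reduction = reduce_by_p(m$total[cc],
                              m[cc, regression_predictors, drop = FALSE]),
      aic = aic_backward(m$total[cc],
                         m[cc, regression_predictors, drop = FALSE]),
      n = sum(cc))
  }

  result <- structure(
    list(scored = scored, diagnostics = diagnostics, outliers = outliers,
         floor_ceiling = fc, items = items_tab, item_types = type_tab,
         reliability = reliability, reliability_variant = reliability_variant,
         associations = assoc, regression = regression, seed = seed),
    class = "vienna_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name, digits = 2L) {
      utils::write.table(format_report(df, digits),
                         file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(df, file.path(out_dir, paste0(name, "_full.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    wt(diagnostics, "diagnostics")
    wt(items_tab[, c("item_id", "item_type", "difficulty_ratio", "mean",
                     "expected", "freq0", "freq1", "freq2", "variance",
                     "wilson_e")], "items")
    wt(type_tab, "item_types")
    wt(scored$summary, "scores")
    if (!is.null(assoc)) wt(assoc, "associations")
    rel <- data.frame(variant = "exclude zero variance",
                      alpha = reliability$alpha, ci_low = reliability$ci_low,
                      ci_high = reliability$ci_high, k = reliability$k_items,
                      excluded = paste(reliability$excluded_items$item_id,
                                       collapse = ";"))
    if (!is.null(reliability_variant))
      rel <- rbind(rel, data.frame(
        variant = sprintf("variance > %g", variance_threshold),
        alpha = reliability_variant$alpha,
        ci_low = reliability_variant$ci_low,
        ci_high = reliability_variant$ci_high,
        k = reliability_variant$k_items,
        excluded = paste(reliability_variant$excluded_items$item_id,
                         collapse = ";")))
    wt(rel, "reliability")
    if (!is.null(regression)) {
      wt(regression$reduction$model$coefficients, "regression")
      utils::write.table(regression$reduction$trace,
                         file.path(out_dir, "regression_trace.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    log <- list(seed = seed, n_participants = nrow(scored$summary),
                n_items = ncol(scored$scores),
                outlier_method = outlier_method,
                variance_threshold = variance_threshold, nboot = nboot,
                package_version = as.character(utils::packageVersion("vienna")),
                r_version = as.character(getRversion()))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

#' @export
print.vienna_pipeline <- function(x, ...) {
  s <- x$scored$summary
  cat(sprintf("VIENNA pipeline: n = %d participants, %d items\n",
              nrow(s), ncol(x$scored$scores)))
  cat(sprintf("total score: mean %.2f, sd %.2f; %d outlier(s) by %s\n",
              mean(s$total), stats::sd(s$total),
              length(x$outliers$outlier_ids), x$outliers$method))
  cat(sprintf("ordinal alpha: %.2f (%d items)\n",
              x$reliability$alpha, x$reliability$k_items))
  if (!is.null(x$associations))
    cat(sprintf("associations: %d variables tested\n", nrow(x$associations)))
  if (!is.null(x$regression))
    cat(sprintf("regression: %d predictors retained (%s)\n",
                length(x$regression$reduction$model$predictors),
                x$regression$reduction$stop_reason))
  invisible(x)
}
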