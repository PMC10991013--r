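#' Default 12-item bank for simulation
#'
#' A synthetic door geometry for the standard 12-item form: three items per
#' turn type, door counts and one-point door sets chosen so each item's
#' chance expectation matches the published per-item expected scores at two
#' decimals. The true layouts are not published, so these geometries are a
#' stand-in with the same scoring structure (every item has at least one
#' updating and one rotation door).
#'
#' @return List of 12 [item_config()] objects (i1..i12).
#' @export
default_item_bank <- function() {
  spec <- list(
    #        id     type           n  correct updating    rotation
    list("i1", "no-turn", 8L, 2L, 3L, 6L),
    list("i2", "no-turn", 11L, 3L, 4L, 8L),
    list("i3", "no-turn", 19L, 5L, 6L, 14L),
    list("i4", "single-turn", 20L, 4L, c(3L, 5L), c(13L, 14L)),
    list("i5", "single-turn", 11L, 6L, 7L, 1L),
    list("i6", "single-turn", 14L, 5L, 4L, 12L),
    list("i7", "double-turn", 19L, 9L, 10L, 18L),
    list("i8", "double-turn", 14L, 6L, c(5L, 7L), c(12L, 13L)),
    list("i9", "double-turn", 21L, 8L, 9L, 19L),
    list("i10", "full-turn", 5L, 2L, 3L, 5L),
    list("i11", "full-turn", 13L, 4L, c(3L, 5L, 6L), c(10L, 11L, 12L)),
    list("i12", "full-turn", 8L, 3L, 4L, 7L))
  lapply(spec, function(s)
    item_config(s[[1L]], s[[2L]], s[[3L]], s[[4L]],
                updating_doors = s[[5L]], rotation_doors = s[[6L]]))
}

#' Default covariate battery specification
#'
#' Loadings of each simulated questionnaire/test on the latent navigation
#' trait theta and on standardized age, residual noise filling the variance
#' to 1, and per-variable missingness rates mirroring systematic refusals
#' observed with demanding visuospatial tests.
#'
#' @return Data frame with columns `name`, `theta_loading`, `age_loading`,
#'   `missing_rate`, `direction` (+1 higher = better, -1 higher = worse).
#' @export
default_covariate_spec <- function() {
  d <- function(name, lt, la, mr = 0, dir = 1)
    data.frame(name = name, theta_loading = lt, age_loading = la,
               missing_rate = mr, direction = dir, stringsAsFactors = FALSE)
  rbind(
    d("years_education", 0.10, 0.00),
    d("cpi_total", -0.08, 0.00, dir = -1),
    d("fsbsod", 0.35, 0.00),
    d("gds", -0.05, 0.00, mr = 3 / 79, dir = -1),
    d("mmse", 0.40, -0.15),
    d("rocf_copy", 0.35, -0.10),
    d("rocf_delayed", 0.20, -0.10),
    d("block_span_forward", 0.35, -0.10),
    d("block_span_backward", 0.45, -0.15),
    d("tap_speed", 0.10, -0.10),
    d("mrt", 0.40, -0.15, mr = 4 / 79),
    d("ptsot", 0.50, -0.15, mr = 1 / 79),
    d("fpt_productivity", 0.45, -0.15),
    d("fpt_flexibility", 0.08, 0.00),
    d("fpt_strategy", 0.25, -0.05))
}

#' Simulation configuration for a synthetic navigation cohort
#'
#' Defines the generative model: participant ages are uniform on
#' `age_range`; the latent navigation trait is
#' `theta = beta_age * z(age) + sqrt(1 - beta_age^2) * noise` (standard
#' normal marginally); correct-door probability follows a logistic item
#' response model `P(correct) = plogis(a * (theta - b_item))` with item
#' difficulties `b` non-decreasing on average across turn types; on an
#' error, a one-point door is chosen with item-specific probability
#' `w_one`, split between rotation and updating doors by weights modulated
#' by two deficit traits (each correlated `-trait_corr` with theta), and
#' the remaining mass falls uniformly on the zero-point doors.
#'
#' @param n_participants Cohort size.
#' @param age_range Two-element numeric, uniform age range in years.
#' @param beta_age Loading of standardized age on theta (negative: older
#'   participants navigate worse).
#' @param items List of [item_config()] objects.
#' @param a Item discrimination (shared).
#' @param b Named or positional numeric vector of item difficulties on the
#'   latent scale, one per item.
#' @param w_one Per-item probability that an error lands on a one-point
#'   door (values in `[0, 1]`).
#' @param rotation_share Baseline share of one-point errors routed to
#'   rotation doors (before deficit modulation).
#' @param kappa Strength of the deficit-trait modulation of error routing.
#' @param trait_corr Correlation magnitude between theta and each deficit
#'   trait (deficits load on -theta).
#' @param covariates Covariate specification, see [default_covariate_spec()].
#' @return Object of class `vienna_simconfig`.
#' @export
sim_config <- function(n_participants = 79L,
                       age_range = c(50, 85),
                       beta_age = -0.55,
                       items = default_item_bank(),
                       a = 1.3,
                       b = NULL,
                       w_one = NULL,
                       rotation_share = 0.7,
                       kappa = 0.5,
                       trait_corr = 0.4,
                       covariates = default_covariate_spec()) {
  items <- validate_item_bank(items)
  k <- length(items)
  if (is.null(b)) stop("item difficulties b must be supplied (see default_vienna_profile())")
  if (is.null(w_one)) w_one <- rep(0.6, k)
  stopifnot(length(b) == k, length(w_one) == k,
            all(w_one >= 0 & w_one <= 1),
            length(age_range) == 2L, age_range[1L] < age_range[2L],
            abs(beta_age) <= 1, a > 0, trait_corr >= 0, trait_corr <= 1,
        rotation_share >= 0, rotation_share <= 1)
  types <- vapply(items, `[[`, character(1), "item_type")
  lev <- c("no-turn", "single-turn", "double-turn", "full-turn")
  bt <- tapply(b, factor(types, levels = lev), mean)
  bt <- bt[!is.na(bt)]
  if (is.unsorted(bt, strictly = FALSE))
    stop("type-mean difficulty b must be non-decreasing across turn types")
  for (i in seq_len(k)) {
    it <- items[[i]]
    n_one <- length(it$updating_doors) + length(it$rotation_doors)
    n_zero <- it$n_doors - 1L - n_one
    if (w_one[i] > 0 && n_one == 0L)
      stop("item ", it$item_id, ": one-point error weight on empty door sets")
    if (w_one[i] < 1 && n_zero == 0L)
      stop("item ", it$item_id, ": zero-point error weight but no zero-point doors")
  }
  structure(list(n_participants = as.integer(n_participants),
                 age_range = age_range, beta_age = beta_age, items = items,
                 a = a, b = unname(b), w_one = unname(w_one),
                 rotation_share = rotation_share, kappa = kappa,
                 trait_corr = trait_corr, covariates = covariates),
            class = "vienna_simconfig")
}

#' Default cohort profile
#'
#' The study-condition profile used throughout the test suite: 79
#' participants aged 50-85, an age effect of -0.55 on the latent trait, and
#' item difficulties calibrated once so the simulated total score lies in
#' the upper range (long-run mean about 19.4, SD about 2.6) without floor
#' or ceiling effects, with right-skewed, low-frequency updating errors.
#'
#' @param n_participants Cohort size (default 79).
#' @return A [sim_config()] object.
#' @export
default_vienna_profile <- function(n_participants = 79L) {
  # difficulties per item (latent scale); type means non-decreasing
  b <- c(-2.95, -2.60, -3.05,      # no-turn
         -3.40, -1.95, -1.85,      # single-turn
         -1.25, -0.80, 1.20,       # double-turn
         -0.60, -0.05, -0.15)      # full-turn
  # probability an error scores one point, per item
  w_one <- c(0.90, 0.90, 0.10, 0.60, 0.56, 0.90,
             0.67, 0.33, 0.34, 0.68, 0.90, 0.76)
  sim_config(n_participants = n_participants, a = 1.2, b = b, w_one = w_one)
}

#' Simulate a synthetic cohort
#'
#' Draws ages, latent traits, door choices, and a covariate battery under a
#' [sim_config()]. Door choices are passed through the scoring module
#' ([score_cohort()]), never scored directly, so scores are consistent with
#' the rubric by construction. Randomness uses fixed sub-seeds per block
#' (ages/traits, item responses, covariates, missingness), so the covariate
#' battery can change without perturbing the item draws.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return Object of class `vienna_cohort`: list with `participants`
#'   (age, traits, total, error counts), `responses` (long chosen-door
#'   table), `scores` and `errors` matrices, `covariates` (battery with
#'   missingness), and `config`/`seed`.
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "vienna_simconfig"))
  seed <- as.integer(seed)
  n <- config$n_participants
  items <- config$items
  k <- length(items)
  pid <- sprintf("p%03d", seq_len(n))

  set.seed(seed %% 2147483040L)
  age <- stats::runif(n, config$age_range[1L], config$age_range[2L])
  z_age <- (age - mean(config$age_range)) /
    sqrt(diff(config$age_range)^2 / 12)
  theta <- config$beta_age * z_age +
    sqrt(1 - config$beta_age^2) * stats::rnorm(n)
  rc <- config$trait_corr
  rot_def <- rc * (-theta) + sqrt(1 - rc^2) * stats::rnorm(n)
  upd_def <- rc * (-theta) + sqrt(1 - rc^2) * stats::rnorm(n)

  set.seed((seed + 1L) %% 2147483040L)
  chosen <- matrix(NA_integer_, n, k)
  for (j in seq_len(k)) {
    it <- items[[j]]
    p_corr <- stats::plogis(config$a * (theta - config$b[j]))
    u <- stats::runif(n)
    correct <- u < p_corr
    # one-point vs zero-point routing for the errors
    one_point <- stats::runif(n) < config$w_one[j]
    has_rot <- length(it$rotation_doors) > 0L
    has_upd <- length(it$updating_doors) > 0L
    w_rot <- if (has_rot) config$rotation_share * exp(config$kappa * rot_def) else 0
    w_upd <- if (has_upd) (1 - config$rotation_share) * exp(config$kappa * upd_def) else 0
    p_rot <- w_rot / (w_rot + w_upd)
    to_rot <- stats::runif(n) < p_rot
    zero_doors <- setdiff(seq_len(it$n_doors),
                          c(it$correct_door, it$updating_doors, it$rotation_doors))
    pick <- function(set, m) set[sample.int(length(set), m, replace = TRUE)]
    door <- integer(n)
    door[correct] <- it$correct_door
    idx_one <- !correct & one_point
    idx_rot <- idx_one & to_rot
    idx_upd <- idx_one & !to_rot
    idx_zero <- !correct & !one_point
    if (any(idx_rot)) door[idx_rot] <- pick(it$rotation_doors, sum(idx_rot))
    if (any(idx_upd)) door[idx_upd] <- pick(it$updating_doors, sum(idx_upd))
    if (any(idx_zero)) door[idx_zero] <- pick(zero_doors, sum(idx_zero))
    chosen[, j] <- door
  }
  responses <- data.frame(
    participant_id = rep(pid, times = k),
    item_id = rep(vapply(items, `[[`, character(1), "item_id"), each = n),
    chosen_door = as.integer(chosen),
    stringsAsFactors = FALSE)
  scored <- score_cohort(items, responses)

  set.seed((seed + 2L) %% 2147483040L)
  cs <- config$covariates
  cov <- data.frame(participant_id = pid, age = age, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cs))) {
    lt <- cs$theta_loading[i]; la <- cs$age_loading[i]
    res_var <- max(0, 1 - lt^2 - la^2)
    v <- lt * theta + la * z_age + sqrt(res_var) * stats::rnorm(n)
    cov[[cs$name[i]]] <- cs$direction[i] * v
  }

  set.seed((seed + 3L) %% 2147483040L)
  for (i in seq_len(nrow(cs))) {
    mr <- cs$missing_rate[i]
    if (mr > 0) {
      miss <- stats::runif(n) < mr
      cov[[cs$name[i]]][miss] <- NA_real_
    }
  }

  participants <- data.frame(
    participant_id = pid, age = age, theta = theta,
    rotation_deficit = rot_def, updating_deficit = upd_def,
    stringsAsFactors = FALSE)
  participants <- merge(participants, scored$summary, by = "participant_id",
                        sort = FALSE)
  structure(list(participants = participants, responses = responses,
                 scores = scored$scores, errors = scored$errors,
                 covariates = cov, config = config, seed = seed),
            class = "vienna_cohort")
}

#' @export
print.vienna_cohort <- function(x, ...) {
  cat(sprintf("Simulated navigation cohort: n = %d, %d items, seed %d\n",
              nrow(x$participants), ncol(x$scores), x$seed))
  cat(sprintf("total score: mean %.2f, sd %.2f, range %d-%d\n",
              mean(x$participants$total), stats::sd(x$participants$total),
              min(x$participants$total), max(x$participants$total)))
  invisible(x)
}

#' Cross-table of a discretized bivariate normal pair
#'
#' Fixture generator for polychoric-recovery checks: draws `n` bivariate
#' standard-normal pairs with correlation `rho`, discretizes each margin at
#' the given thresholds, and returns the contingency table.
#'
#' @param rho Latent correlation, `|rho| < 1`.
#' @param thresholds_x,thresholds_y Strictly increasing cut-points.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A contingency table (matrix of counts).
#' @export
simulate_ordinal_pair <- function(rho, thresholds_x, thresholds_y, n, seed = 1L) {
  stopifnot(abs(rho) < 1, n > 0,
            !is.unsorted(thresholds_x, strictly = TRUE),
            !is.unsorted(thresholds_y, strictly = TRUE))
  set.seed(as.integer(seed) %% 2147483040L)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cx <- cut(z1, c(-Inf, thresholds_x, Inf), labels = FALSE)
  cy <- cut(z2, c(-Inf, thresholds_y, Inf), labels = FALSE)
  table(factor(cx, levels = seq_len(length(thresholds_x) + 1L)),
        factor(cy, levels = seq_len(length(thresholds_y) + 1L)))
}
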