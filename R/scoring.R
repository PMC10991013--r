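#' Define the door layout and scoring rubric of one VIENNA trial
#'
#' A VIENNA trial shows a first-person hallway traversal next to an
#' allocentric map; the participant indicates the door at which the video
#' ended. Each item is characterised by the number of candidate doors on the
#' map, the correct door (2 points), a set of one-point doors parallel or
#' adjacent to the correct one (spatial *updating* errors), and a set of
#' one-point doors opposite to it (perspective *rotation* errors). Every
#' other door scores 0.
#'
#' @param item_id Item label, e.g. `"i1"`.
#' @param item_type Turn complexity of the trial: `"no-turn"`,
#'   `"single-turn"`, `"double-turn"` or `"full-turn"` (one 180 degree turn).
#' @param n_doors Number of doors on the allocentric map (1-based ids).
#' @param correct_door Door id awarded 2 points.
#' @param updating_doors Integer door ids awarded 1 point as updating errors.
#' @param rotation_doors Integer door ids awarded 1 point as rotation errors.
#' @param is_main Logical; main items enter the 0-24 total score, practice
#'   and instruction trials do not.
#' @return An object of class `vienna_item`.
#' @examples
#' item_config("i1", "no-turn", n_doors = 8, correct_door = 3,
#'             updating_doors = 4, rotation_doors = 7)
#' @export
item_config <- function(item_id, item_type, n_doors, correct_door,
                        updating_doors = integer(0), rotation_doors = integer(0),
                        is_main = TRUE) {
  item_type <- match.arg(item_type,
                         c("no-turn", "single-turn", "double-turn", "full-turn"))
  n_doors <- as.integer(n_doors)
  correct_door <- as.integer(correct_door)
  updating_doors <- sort(unique(as.integer(updating_doors)))
  rotation_doors <- sort(unique(as.integer(rotation_doors)))
  if (length(n_doors) != 1L || is.na(n_doors) || n_doors < 1L)
    stop("item ", item_id, ": n_doors must be a positive integer")
  all_ids <- c(correct_door, updating_doors, rotation_doors)
  if (any(is.na(all_ids)) || any(all_ids < 1L) || any(all_ids > n_doors))
    stop("item ", item_id, ": door identifiers must lie in 1..", n_doors)
  if (correct_door %in% c(updating_doors, rotation_doors))
    stop("item ", item_id, ": correct door may not appear in a one-point set")
  if (length(intersect(updating_doors, rotation_doors)) > 0L)
    stop("item ", item_id, ": updating and rotation door sets overlap")
  if (1L + length(updating_doors) + length(rotation_doors) > n_doors)
    stop("item ", item_id, ": more scored doors than doors on the map")
  structure(
    list(item_id = as.character(item_id), item_type = item_type,
         n_doors = n_doors, correct_door = correct_door,
         updating_doors = updating_doors, rotation_doors = rotation_doors,
         is_main = isTRUE(is_main)),
    class = "vienna_item")
}

#' @export
print.vienna_item <- function(x, ...) {
  cat(sprintf("VIENNA item %s (%s): %d doors, correct %d, updating {%s}, rotation {%s}%s\n",
              x$item_id, x$item_type, x$n_doors, x$correct_door,
              paste(x$updating_doors, collapse = ","),
              paste(x$rotation_doors, collapse = ","),
              if (x$is_main) "" else " [practice]"))
  invisible(x)
}

#' Score a single door choice
#'
#' Applies the VIENNA rubric: the correct door is awarded two points; a door
#' from the updating set or the rotation set is awarded one point with the
#' corresponding error type; any other door is awarded zero points
#' (error type `"other"`).
#'
#' @param config A [item_config()] object.
#' @param chosen Chosen door id (1-based).
#' @param participant_id Optional label used in error messages and output.
#' @return A list with `participant_id`, `item_id`, `points` (0, 1 or 2) and
#'   `error_type` (`"none"`, `"updating"`, `"rotation"` or `"other"`).
#' @export
score_response <- function(config, chosen, participant_id = NA_character_) {
  stopifnot(inherits(config, "vienna_item"))
  chosen <- as.integer(chosen)
  if (length(chosen) != 1L || is.na(chosen) || chosen < 1L || chosen > config$n_doors)
    stop("invalid response for participant ", participant_id, ", item ",
         config$item_id, ": door ", chosen, " not in 1..", config$n_doors)
  if (chosen == config$correct_door) {
    points <- 2L; error_type <- "none"
  } else if (chosen %in% config$updating_doors) {
    points <- 1L; error_type <- "updating"
  } else if (chosen %in% config$rotation_doors) {
    points <- 1L; error_type <- "rotation"
  } else {
    points <- 0L; error_type <- "other"
  }
  list(participant_id = participant_id, item_id = config$item_id,
       points = points, error_type = error_type)
}

#' Aggregate one participant's responses to the total VIENNA score
#'
#' The total score is the sum of item points over the main items
#' (0-24 for the standard 12-item form); counts of updating and rotation
#' errors are recorded as auxiliary outcomes. A missing response to a
#' configured main item is scored 0 with error type `"other"` and a warning,
#' duplicated or unknown item responses are rejected.
#'
#' @param configs List of [item_config()] objects.
#' @param responses Data frame with columns `item_id` and `chosen_door`.
#' @param participant_id Participant label.
#' @return A list with `participant_id`, `total`, `n_updating`,
#'   `n_rotation`, `n_items_scored` and a per-item data frame `items`.
#' @export
score_participant <- function(configs, responses, participant_id = NA_character_) {
  configs <- validate_item_bank(configs)
  ids <- vapply(configs, `[[`, character(1), "item_id")
  responses <- as.data.frame(responses)
  stopifnot(all(c("item_id", "chosen_door") %in% names(responses)))
  responses$item_id <- as.character(responses$item_id)
  if (anyDuplicated(responses$item_id))
    stop("participant ", participant_id, ": duplicate responses for item(s) ",
         paste(unique(responses$item_id[duplicated(responses$item_id)]), collapse = ", "))
  unknown <- setdiff(responses$item_id, ids)
  if (length(unknown) > 0L)
    stop("participant ", participant_id, ": response(s) to unconfigured item(s) ",
         paste(unknown, collapse = ", "))

  main <- vapply(configs, `[[`, logical(1), "is_main")
  rows <- lapply(configs[main], function(cfg) {
    i <- match(cfg$item_id, responses$item_id)
    if (is.na(i)) {
      warning("participant ", participant_id, ": no response for item ",
              cfg$item_id, "; scored 0 (other)", call. = FALSE)
      list(participant_id = participant_id, item_id = cfg$item_id,
           points = 0L, error_type = "other")
    } else {
      score_response(cfg, responses$chosen_door[i], participant_id)
    }
  })
  items <- data.frame(
    participant_id = participant_id,
    item_id = vapply(rows, `[[`, character(1), "item_id"),
    points = vapply(rows, `[[`, integer(1), "points"),
    error_type = vapply(rows, `[[`, character(1), "error_type"),
    stringsAsFactors = FALSE)
  list(participant_id = participant_id,
       total = sum(items$points),
       n_updating = sum(items$error_type == "updating"),
       n_rotation = sum(items$error_type == "rotation"),
       n_items_scored = nrow(items),
       items = items)
}

#' Score a long-format response table for a whole cohort
#'
#' @param configs List of [item_config()] objects.
#' @param responses Long data frame with columns `participant_id`,
#'   `item_id`, `chosen_door`.
#' @return A list with `scores` (participants x main items point matrix),
#'   `errors` (matching error-type matrix) and `summary` (per-participant
#'   totals and error counts).
#' @export
score_cohort <- function(configs, responses) {
  configs <- validate_item_bank(configs)
  responses <- as.data.frame(responses)
  stopifnot(all(c("participant_id", "item_id", "chosen_door") %in% names(responses)))
  responses$participant_id <- as.character(responses$participant_id)
  pid <- unique(responses$participant_id)
  scored <- lapply(pid, function(p)
    score_participant(configs, responses[responses$participant_id == p,
                                         c("item_id", "chosen_door")], p))
  item_ids <- scored[[1L]]$items$item_id
  scores <- t(vapply(scored, function(s) s$items$points, integer(length(item_ids))))
  errors <- t(vapply(scored, function(s) s$items$error_type, character(length(item_ids))))
  dimnames(scores) <- dimnames(errors) <- list(pid, item_ids)
  summary <- data.frame(
    participant_id = pid,
    total = vapply(scored, `[[`, numeric(1), "total"),
    n_updating = vapply(scored, `[[`, numeric(1), "n_updating"),
    n_rotation = vapply(scored, `[[`, numeric(1), "n_rotation"),
    n_items_scored = vapply(scored, `[[`, numeric(1), "n_items_scored"),
    stringsAsFactors = FALSE, row.names = NULL)
  list(scores = scores, errors = errors, summary = summary)
}

#' Expected item score under uniform random door choice
#'
#' The chance expectation of an item, used as the denominator of the
#' difficulty ratio: with `d` doors of which one scores 2 points and `u + r`
#' score 1 point, a participant guessing uniformly at random expects
#' `(2 + u + r) / d` points. Computed in exact arithmetic; no rounding.
#'
#' @param config A [item_config()] object.
#' @return Expected points in `(0, 2]`.
#' @examples
#' cfg <- item_config("x", "no-turn", n_doors = 10, correct_door = 1,
#'                    updating_doors = 2)
#' expected_item_score(cfg)  # 0.3
#' @export
expected_item_score <- function(config) {
  stopifnot(inherits(config, "vienna_item"))
  (2 + length(config$updating_doors) + length(config$rotation_doors)) / config$n_doors
}

validate_item_bank <- function(configs) {
  if (inherits(configs, "vienna_item")) configs <- list(configs)
  stopifnot(is.list(configs), length(configs) > 0L,
            all(vapply(configs, inherits, logical(1), "vienna_item")))
  ids <- vapply(configs, `[[`, character(1), "item_id")
  if (anyDuplicated(ids))
    stop("duplicate item ids in configuration: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  configs
}
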