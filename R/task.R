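#' Build the eight-stimulus set of the delayed-reward task
#'
#' The task pairs eight stimuli, four rewarded immediately and four with a
#' two-trial delayed reward. Within each delay class the starting rewards are
#' 4, 1, -1 and -4, each used exactly once. Which stimulus id gets which
#' delay class and starting value is decided by `seed`.
#'
#' @param seed Integer seed controlling the class/start-value assignment.
#' @return A tibble with one row per stimulus: `id` (0-7), `delay_class`
#'   (`"immediate"` or `"delayed"`), `delay` (0 or 2 trials) and
#'   `start_value`.
#' @examples
#' stimulus_set(seed = 1)
#' @export
stimulus_set <- function(seed = 1L) {
  with_seed(seed, {
    immediate_ids <- sort(sample(0:7, 4L))
    starts <- c(4L, 1L, -1L, -4L)
    out <- tibble::tibble(
      id = 0:7,
      delay_class = ifelse(0:7 %in% immediate_ids, "immediate", "delayed")
    )
    out$start_value <- NA_integer_
    out$start_value[out$delay_class == "immediate"] <- sample(starts)
    out$start_value[out$delay_class == "delayed"] <- sample(starts)
    out$delay <- ifelse(out$delay_class == "immediate", 0L, 2L)
    out[, c("id", "delay_class", "delay", "start_value")]
  })
}

#' Generate an integer-rounded Gaussian reward random walk
#'
#' Each stimulus's reward starts at its assigned starting value and drifts by
#' independent zero-mean Gaussian steps. The latent trajectory accumulates
#' unrounded; the reward delivered on screen each trial is the latent value
#' rounded to the nearest integer (half away from zero).
#'
#' @param stimset Stimulus set from [stimulus_set()].
#' @param n_trials Number of trials (rows) in the walk.
#' @param step_scale Standard deviation of the per-trial Gaussian step.
#'   The default 0.5 corresponds to a step variance of 0.25.
#' @param seed Integer seed for the walk.
#' @param walk_id Integer label for the walk (sessions reference walks by id).
#' @return An object of class `reward_walk`: a list with `walk_id`,
#'   `step_scale`, and `latent` / `delivered` matrices of size
#'   `n_trials x 8` (columns ordered by stimulus id).
#' @examples
#' s <- stimulus_set(1)
#' w <- reward_walk(s, n_trials = 10, seed = 1)
#' w$delivered[1, ]
#' @export
reward_walk <- function(stimset, n_trials = 336L, step_scale = 0.5,
                        seed = 1L, walk_id = 1L) {
  stopifnot(n_trials >= 1)
  if (!is.numeric(step_scale) || step_scale <= 0) {
    stop("`step_scale` must be a positive number.", call. = FALSE)
  }
  start <- stimset$start_value[order(stimset$id)]
  latent <- with_seed(seed, {
    steps <- matrix(rnorm((n_trials - 1L) * 8L, 0, step_scale),
                    nrow = n_trials - 1L, ncol = 8L)
    apply(rbind(start, steps), 2, cumsum)
  })
  latent <- matrix(latent, nrow = n_trials, ncol = 8L,
                   dimnames = list(NULL, as.character(0:7)))
  structure(
    list(walk_id = as.integer(walk_id), step_scale = step_scale,
         latent = latent, delivered = round_half_away(latent)),
    class = "reward_walk"
  )
}

#' @export
print.reward_walk <- function(x, ...) {
  cat("<reward_walk> id", x$walk_id, "-", nrow(x$latent), "trials x 8 stimuli,",
      "step sd", x$step_scale, "\n")
  invisible(x)
}

#' Build a balanced, shuffled pair schedule
#'
#' Every distinct unordered pair of stimuli appears exactly `n_repeats`
#' times, in a uniformly shuffled order. With the task defaults (8 stimuli,
#' 12 repeats) this yields the 28 unique pairs and 336 trials.
#'
#' @param n_stimuli Number of stimuli (ids `0:(n_stimuli-1)`).
#' @param n_repeats Times each unordered pair is presented.
#' @param seed Integer seed for the shuffle.
#' @return A tibble with columns `t` (0-based trial index), `pair_a`,
#'   `pair_b` (stimulus ids, `pair_a < pair_b`).
#' @examples
#' nrow(trial_schedule(8, 12, seed = 1))
#' @export
trial_schedule <- function(n_stimuli = 8L, n_repeats = 12L, seed = 1L) {
  stopifnot(n_stimuli >= 2, n_repeats >= 1)
  pairs <- utils::combn(seq_len(n_stimuli) - 1L, 2L)
  idx <- rep(seq_len(ncol(pairs)), times = n_repeats)
  idx <- with_seed(seed, sample(idx))
  tibble::tibble(
    t = seq_along(idx) - 1L,
    pair_a = pairs[1L, idx],
    pair_b = pairs[2L, idx]
  )
}

#' Render the feedback shown on one trial
#'
#' The immediate component is the current choice's delivered reward at `t`
#' when that choice is immediate-class; the delayed component is the reward
#' that the choice made two trials earlier earned at its own trial (`t - 2`),
#' arriving now, when that earlier choice is delayed-class. In the conjoint
#' condition only the summed total is shown to the learner; in the disjoint
#' condition the two components are displayed separately. Both components are
#' recorded in either condition (the condition governs what the models may
#' use, not what the record stores).
#'
#' @param choice_t Stimulus id chosen at trial `t`, or `NA` for an omitted
#'   response.
#' @param choice_tm2 Stimulus id chosen at trial `t - 2`, or `NA`.
#' @param walk A [reward_walk()].
#' @param t 0-based trial index.
#' @param stimset Stimulus set from [stimulus_set()].
#' @param condition `"conjoint"` or `"disjoint"`.
#' @return One-row tibble with `imm_feedback`, `del_feedback` (integer or
#'   `NA` when absent), `total_feedback`, and `condition`.
#' @examples
#' s <- stimulus_set(1)
#' w <- reward_walk(s, 10, seed = 1)
#' imm <- s$id[s$delay_class == "immediate"][1]
#' del <- s$id[s$delay_class == "delayed"][1]
#' render_feedback(imm, del, w, t = 2, s, "conjoint")
#' @export
render_feedback <- function(choice_t, choice_tm2, walk, t, stimset, condition) {
  condition <- match.arg(condition, c("conjoint", "disjoint"))
  stopifnot(t >= 0, t < nrow(walk$delivered))
  cls <- function(id) stimset$delay_class[match(id, stimset$id)]
  imm <- NA_real_
  if (!is.na(choice_t) && cls(choice_t) == "immediate") {
    imm <- walk$delivered[t + 1L, choice_t + 1L]
  }
  del <- NA_real_
  if (!is.na(choice_tm2) && cls(choice_tm2) == "delayed") {
    if (t - 2L < 0L) {
      stop("a delayed-class `choice_tm2` requires t >= 2.", call. = FALSE)
    }
    del <- walk$delivered[t - 1L, choice_tm2 + 1L]
  }
  tibble::tibble(
    imm_feedback = unname(imm),
    del_feedback = unname(del),
    total_feedback = sum(imm, del, na.rm = TRUE),
    condition = condition
  )
}

session_columns <- c("participant_id", "condition", "stage", "walk_id", "t",
                     "pair_a", "pair_b", "choice",
                     "imm_feedback", "del_feedback", "total_feedback")

# Validate a trial-level session table; errors name the offending row.
validate_sessions <- function(sessions) {
  missing <- setdiff(session_columns, names(sessions))
  if (length(missing)) {
    stop("session table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_cond <- !sessions$condition %in% c("conjoint", "disjoint")
  if (any(bad_cond)) {
    stop("unknown condition label in row ", which(bad_cond)[1], ": '",
         sessions$condition[which(bad_cond)[1]], "'", call. = FALSE)
  }
  bad <- !is.na(sessions$choice) &
    sessions$choice != sessions$pair_a & sessions$choice != sessions$pair_b
  if (any(bad)) {
    stop("choice outside the offered pair in row ", which(bad)[1],
         call. = FALSE)
  }
  invisible(sessions)
}

#' Read or write trial-level session tables
#'
#' Sessions are stored as plain CSV, one row per trial, with columns
#' `participant_id`, `condition`, `stage`, `walk_id`, `t` (0-based),
#' `pair_a`, `pair_b`, `choice`, `imm_feedback`, `del_feedback`,
#' `total_feedback`. Empty cells mean an absent feedback component or an
#' omitted choice. Reading validates the schema (condition labels, choice
#' within the offered pair) and errors name the first offending row.
#'
#' @param path File path of the CSV.
#' @param sessions A session tibble as produced by [simulate_session()] or
#'   [generate_study()].
#' @return `read_sessions()` returns the validated tibble; `write_sessions()`
#'   returns `sessions` invisibly.
#' @export
read_sessions <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      condition = readr::col_character(),
      stage = readr::col_integer(),
      walk_id = readr::col_integer(),
      t = readr::col_integer(),
      pair_a = readr::col_integer(),
      pair_b = readr::col_integer(),
      choice = readr::col_integer(),
      imm_feedback = readr::col_double(),
      del_feedback = readr::col_double(),
      total_feedback = readr::col_double()
    ),
    progress = FALSE
  )
  validate_sessions(out)
  out
}

#' @rdname read_sessions
#' @export
write_sessions <- function(sessions, path) {
  validate_sessions(sessions)
  readr::write_csv(sessions[, session_columns], path, progress = FALSE)
  invisible(sessions)
}

#' Split a multi-session trial table into single sessions
#'
#' Splits by participant, condition and stage (in first-appearance order)
#' and sorts each session's trials by `t`. Useful for feeding multi-session
#' tibbles to per-session functions like [run_model()] and [fit_session()].
#'
#' @param sessions Multi-session trial tibble.
#' @return A named list of single-session tibbles.
#' @export
split_sessions <- function(sessions) {
  key <- paste(sessions$participant_id, sessions$condition, sessions$stage,
               sep = "\r")
  lapply(split(sessions, factor(key, levels = unique(key))), function(s) {
    s[order(s$t), ]
  })
}
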