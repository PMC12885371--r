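#' Sample generative model parameters
#'
#' Draws each free parameter of the requested variant independently from the
#' generative distributions used for the simulation studies: learning rates
#' from Beta(1, 2), strategy weights from Gamma(shape 3, scale 1), and decay
#' rates from Beta(2, 3). `beta_min` optionally truncates the weight
#' distribution from below (rejection sampling) to yield informative,
#' low-noise choosers.
#'
#' @param n Number of parameter sets to draw.
#' @param variant Model variant; see [ca_params()].
#' @param seed Optional integer seed.
#' @param beta_min Lower truncation for strategy-weight draws.
#' @return A tibble with one row per draw: `variant` plus the six parameter
#'   columns (non-free parameters fixed at 0). Convert a row with
#'   [as_ca_params()].
#' @examples
#' sample_params(3, "eligibility", seed = 1)
#' @export
sample_params <- function(n = 1, variant = "hybrid", seed = NULL,
                          beta_min = 0) {
  variant <- match.arg(variant, ca_variants)
  free <- free_param_names(variant)
  draw_rate <- function(k) rbeta(k, 1, 2)
  draw_decay <- function(k) rbeta(k, 2, 3)
  draw_beta <- function(k) {
    x <- rgamma(k, shape = 3, scale = 1)
    while (any(bad <- x < beta_min)) {
      x[bad] <- rgamma(sum(bad), shape = 3, scale = 1)
    }
    x
  }
  with_seed(seed, {
    theta <- vapply(free, function(nm) {
      if (grepl("^alpha", nm)) draw_rate(n)
      else if (grepl("^lambda", nm)) draw_decay(n)
      else draw_beta(n)
    }, numeric(n))
    theta <- matrix(theta, nrow = n, dimnames = list(NULL, free))
    out <- purrr::map(seq_len(n),
                      function(i) params_from_theta(variant, theta[i, ]))
    dplyr::bind_rows(purrr::map(out, function(p) {
      tibble::as_tibble(p[c("variant", "alpha_elg", "lambda_elg", "beta_elg",
                            "alpha_tab", "lambda_tab", "beta_tab")])
    }))
  })
}

#' Convert a one-row parameter tibble to a `ca_params` object
#'
#' @param x One-row tibble (or named list) with a `variant` column and the
#'   six parameter columns.
#' @return A [ca_params()] object.
#' @export
as_ca_params <- function(x) {
  if (inherits(x, "ca_params")) return(x)
  ca_params(x$variant[[1]],
            alpha_elg = x$alpha_elg[[1]], lambda_elg = x$lambda_elg[[1]],
            beta_elg = x$beta_elg[[1]], alpha_tab = x$alpha_tab[[1]],
            lambda_tab = x$lambda_tab[[1]], beta_tab = x$beta_tab[[1]])
}

#' Simulate an agent playing one session
#'
#' Runs the model forward over a pair schedule: on each trial the choice is
#' sampled from the hybrid softmax distribution, feedback is rendered from
#' the reward walk (including the two-trial delayed queue), and the learner
#' updates. Returns the session as a trial-level tibble matching the CSV
#' schema of [read_sessions()].
#'
#' @param params A [ca_params()] object (or one-row tibble from
#'   [sample_params()]).
#' @param schedule Pair schedule from [trial_schedule()].
#' @param walk Reward walk from [reward_walk()].
#' @param stimset Stimulus set from [stimulus_set()].
#' @param condition `"conjoint"` or `"disjoint"`.
#' @param seed Optional integer seed for the sampled choices.
#' @param participant_id,stage Session labels.
#' @param window,skip_absent Passed to the model; see [run_model()].
#' @return A session tibble.
#' @export
simulate_session <- function(params, schedule, walk, stimset, condition,
                             seed = NULL, participant_id = "sim", stage = 1L,
                             window = 5, skip_absent = FALSE) {
  params <- as_ca_params(params)
  condition <- match.arg(condition, c("conjoint", "disjoint"))
  n <- nrow(schedule)
  stopifnot(n <= nrow(walk$delivered))
  win <- if (is.infinite(window)) -1L else as.integer(window)
  imm_class <- stimset$delay_class[order(stimset$id)] == "immediate"
  with_seed(seed, {
    v <- rep(0, 8); e <- rep(0, 8); Q <- matrix(0, 2, 8)
    buf_e <- NULL; buf_t <- NULL
    choice <- integer(n)
    imm_f <- del_f <- tot_f <- numeric(n)
    for (i in seq_len(n)) {
      x_e <- v
      x_t <- Q[1, ] + Q[2, ]
      if (win != 0) {
        z_e <- normalize_values(x_e, buf_e)
        z_t <- normalize_values(x_t, buf_t)
      } else {
        z_e <- x_e; z_t <- x_t
      }
      opt <- c(schedule$pair_a[i], schedule$pair_b[i]) + 1L
      p <- choice_probabilities(z_e[opt], z_t[opt], params$beta_elg,
                                params$beta_tab)
      ch <- if (runif(1) < p[1]) schedule$pair_a[i] else schedule$pair_b[i]
      choice[i] <- ch
      imm_f[i] <- if (imm_class[ch + 1L]) walk$delivered[i, ch + 1L] else NA_real_
      ch2 <- if (i > 2) choice[i - 2L] else NA_integer_
      del_f[i] <- if (!is.na(ch2) && !imm_class[ch2 + 1L]) {
        walk$delivered[i - 2L, ch2 + 1L]
      } else NA_real_
      tot_f[i] <- sum(imm_f[i], del_f[i], na.rm = TRUE)
      st <- elig_step(v, e, ch + 1L, tot_f[i], params$alpha_elg,
                      params$lambda_elg)
      v <- st$v; e <- st$e
      pe <- tab_prediction_errors(Q, ch + 1L,
                                  if (is.na(ch2)) NA else ch2 + 1L,
                                  imm_f[i], del_f[i], tot_f[i], condition,
                                  skip_absent)
      Q <- tab_update(Q, ch + 1L, if (is.na(ch2)) NA else ch2 + 1L,
                      pe$delta0, pe$delta2, params$alpha_tab,
                      params$lambda_tab)
      if (win != 0) {
        buf_e <- rbind(buf_e, x_e)
        buf_t <- rbind(buf_t, x_t)
        if (win > 0 && nrow(buf_e) > win) {
          buf_e <- buf_e[-1, , drop = FALSE]
          buf_t <- buf_t[-1, , drop = FALSE]
        }
      }
    }
    tibble::tibble(
      participant_id = participant_id, condition = condition,
      stage = as.integer(stage), walk_id = walk$walk_id,
      t = schedule$t, pair_a = schedule$pair_a, pair_b = schedule$pair_b,
      choice = choice, imm_feedback = imm_f, del_feedback = del_f,
      total_feedback = tot_f
    )
  })
}

#' Regenerate model choices on observed task sequences
#'
#' Posterior-predictive simulation: for each source session, replays the
#' same pair sequence and reward walk `n_iter` times with choices sampled
#' from the model under that session's parameter set. Rows are tagged with
#' an `iteration` id.
#'
#' @param params_list List (or tibble, one row per session) of parameter
#'   sets, aligned with the sessions.
#' @param sessions Multi-session trial tibble.
#' @param walks List of [reward_walk()] objects indexed by `walk_id`.
#' @param stimset Stimulus set shared by all sessions.
#' @param n_iter Iterations per session (default 25).
#' @param seed Integer seed; each session/iteration gets a derived child
#'   seed.
#' @param window,skip_absent Passed to the model.
#' @return A tibble of generated sessions with an `iteration` column.
#' @export
simulate_posterior_iterations <- function(params_list, sessions, walks,
                                          stimset, n_iter = 25, seed = 1L,
                                          window = 5, skip_absent = FALSE) {
  sess <- split_sessions(sessions)
  if (tibble::is_tibble(params_list)) {
    params_list <- purrr::map(seq_len(nrow(params_list)),
                              function(i) as_ca_params(params_list[i, ]))
  }
  if (length(params_list) != length(sess)) {
    stop("need one parameter set per session (", length(sess),
         " sessions, ", length(params_list), " parameter sets).",
         call. = FALSE)
  }
  purrr::list_rbind(purrr::imap(sess, function(s, key) {
    j <- match(key, names(sess))
    p <- as_ca_params(params_list[[j]])
    w <- walks[[s$walk_id[1]]]
    sched <- tibble::tibble(t = s$t, pair_a = s$pair_a, pair_b = s$pair_b)
    purrr::list_rbind(purrr::map(seq_len(n_iter), function(it) {
      out <- simulate_session(
        p, sched, w, stimset, s$condition[1],
        seed = ca_seed(seed, "ppc", j, it),
        participant_id = s$participant_id[1], stage = s$stage[1],
        window = window, skip_absent = skip_absent
      )
      out$iteration <- it
      out
    }))
  }))
}

#' Simulate a full counterbalanced synthetic study
#'
#' Builds the task (stimuli, three reward walks, per-session pair
#' schedules), draws generative parameters per session, and simulates two
#' sessions per participant -- one per feedback condition, with condition
#' order counterbalanced so that half the cohort (rounded up) starts with
#' disjoint. Each session is independently assigned one of the walks.
#'
#' @param n_participants Number of simulated participants (>= 2).
#' @param variant Generating model variant.
#' @param n_stimuli,n_repeats Schedule structure (defaults 8 and 12: 28
#'   pairs, 336 trials).
#' @param n_walks Number of reward walks to generate (default 3).
#' @param step_scale Walk step standard deviation.
#' @param beta_min Lower truncation for strategy-weight draws.
#' @param seed Integer master seed; all component seeds derive from it.
#' @param window,skip_absent Passed to the simulated learners.
#' @param shared_params If `TRUE`, a participant's two sessions share one
#'   parameter draw (for order-effect experiments); default draws
#'   independently per session.
#' @return An object of class `ca_study`: list with `sessions` (trial
#'   tibble), `params` (one row per session with the generative draw),
#'   `stimset`, and `walks`.
#' @examples
#' st <- generate_study(2, variant = "eligibility", seed = 1)
#' dplyr::count(st$sessions, participant_id, condition)
#' @export
generate_study <- function(n_participants, variant = "hybrid",
                           n_stimuli = 8L, n_repeats = 12L, n_walks = 3L,
                           step_scale = 0.5, beta_min = 0, seed = 1L,
                           window = 5, skip_absent = FALSE,
                           shared_params = FALSE) {
  stopifnot(n_participants >= 2)
  stimset <- stimulus_set(ca_seed(seed, "stimset"))
  n_trials <- choose(n_stimuli, 2) * n_repeats
  walks <- purrr::map(seq_len(n_walks), function(k) {
    reward_walk(stimset, n_trials, step_scale, seed = ca_seed(seed, "walk", k),
                walk_id = k)
  })
  # alternate starting condition: odd participants start disjoint
  first_cond <- rep(c("disjoint", "conjoint"), length.out = n_participants)
  sessions <- list(); params <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("sim%03d", p)
    conds <- c(first_cond[p], setdiff(c("disjoint", "conjoint"), first_cond[p]))
    shared <- sample_params(1, variant, seed = ca_seed(seed, "params", p),
                            beta_min = beta_min)
    for (stg in 1:2) {
      par_tbl <- if (shared_params) shared else {
        sample_params(1, variant, seed = ca_seed(seed, "params", p, stg),
                      beta_min = beta_min)
      }
      wid <- 1L + ca_seed(seed, "walkpick", p, stg) %% n_walks
      sched <- trial_schedule(n_stimuli, n_repeats,
                              seed = ca_seed(seed, "schedule", p, stg))
      s <- simulate_session(
        as_ca_params(par_tbl), sched, walks[[wid]], stimset, conds[stg],
        seed = ca_seed(seed, "choices", p, stg), participant_id = pid,
        stage = stg, window = window, skip_absent = skip_absent
      )
      sessions[[length(sessions) + 1L]] <- s
      params[[length(params) + 1L]] <- dplyr::mutate(
        par_tbl, participant_id = pid, condition = conds[stg],
        stage = as.integer(stg), walk_id = wid, .before = 1
      )
    }
  }
  structure(list(sessions = purrr::list_rbind(sessions),
                 params = purrr::list_rbind(params),
                 stimset = stimset, walks = walks, seed = seed),
            class = "ca_study")
}

#' @export
print.ca_study <- function(x, ...) {
  np <- length(unique(x$sessions$participant_id))
  cat("<ca_study>", np, "participants x 2 sessions,",
      nrow(x$sessions), "trials total\n")
  invisible(x)
}
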