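#' Session-level behavioral performance metrics
#'
#' Optimal choice is the proportion of responded trials on which the chosen
#' stimulus's delivered walk value at that trial was at least the other
#' option's (ties count as optimal: no wrong answer exists on such trials).
#' Average outcome is the chosen option's generative (delivered walk) reward
#' at the choice trial, averaged over responded trials.
#'
#' @param sessions Multi-session trial tibble.
#' @param walks List of [reward_walk()] objects indexed by `walk_id` (or a
#'   single walk).
#' @return A tibble with one row per session: `participant_id`,
#'   `condition`, `stage`, `optimal_choice`, `average_outcome`.
#' @export
behavioral_metrics <- function(sessions, walks) {
  if (inherits(walks, "reward_walk")) walks <- list(walks)
  purrr::list_rbind(purrr::map(split_sessions(sessions), function(s) {
    w <- walks[[s$walk_id[1]]]
    resp <- !is.na(s$choice)
    if (!any(resp)) stop("session has no responded trials.", call. = FALSE)
    row <- s$t + 1L
    ch_val <- w$delivered[cbind(row, s$choice + 1L)]
    other <- ifelse(s$choice == s$pair_a, s$pair_b, s$pair_a)
    ot_val <- w$delivered[cbind(row, other + 1L)]
    tibble::tibble(
      participant_id = s$participant_id[1], condition = s$condition[1],
      stage = s$stage[1],
      optimal_choice = mean(ch_val[resp] >= ot_val[resp]),
      average_outcome = mean(ch_val[resp])
    )
  }))
}

#' Extract delayed-choice reappearance (stay/switch) events
#'
#' Scans each session for trials where a delayed-class stimulus was chosen
#' and the same stimulus was offered again exactly three trials later. Each
#' event records whether the participant stayed with that stimulus at
#' `t + 3` and the feedback valence at the origin trial (`reward_0F`) and
#' two trials forward (`reward_2F`), where strictly positive displayed
#' feedback codes `"+"` and zero or negative codes `"-"`.
#'
#' The 2F valence is the feedback that actually reports the origin choice's
#' delayed reward: the displayed delayed component at `t + 2` in disjoint,
#' the displayed total at `t + 2` in conjoint (`conjoint_valence =
#' "component"` instead uses the underlying delayed component recorded by
#' the simulator). The 0F valence is the feedback experienced right after
#' the origin choice -- the displayed total at `t` in both conditions by
#' default. Because a delayed-class choice leaves the immediate box empty,
#' coding disjoint 0F from the immediate component alone
#' (`disjoint_0F = "component"`) makes that factor degenerate; it is kept
#' as an option for sensitivity checks only.
#'
#' @param sessions Multi-session trial tibble.
#' @param stimset Stimulus set from [stimulus_set()].
#' @param conjoint_valence Source of conjoint 2F valence: displayed
#'   `"total"` (default) or latent `"component"`.
#' @param disjoint_0F Source of disjoint 0F valence: displayed `"total"`
#'   (default) or immediate `"component"`.
#' @return A tibble of events: session keys, `t`, `reappear_t`, `stim`,
#'   `stay` (0/1), `reward_0F`, `reward_2F`.
#' @export
extract_stay_events <- function(sessions, stimset,
                                conjoint_valence = c("total", "component"),
                                disjoint_0F = c("total", "component")) {
  conjoint_valence <- match.arg(conjoint_valence)
  disjoint_0F <- match.arg(disjoint_0F)
  delayed_ids <- stimset$id[stimset$delay_class == "delayed"]
  valence <- function(x) ifelse(!is.na(x) & x > 0, "+", "-")
  empty <- tibble::tibble(
    participant_id = character(), condition = character(), stage = integer(),
    t = integer(), reappear_t = integer(), stim = integer(),
    stay = integer(), reward_0F = character(), reward_2F = character()
  )
  out <- purrr::list_rbind(purrr::map(split_sessions(sessions), function(s) {
    n <- nrow(s)
    keep <- which(!is.na(s$choice) & s$choice %in% delayed_ids)
    keep <- keep[keep + 3L <= n]
    if (!length(keep)) return(NULL)
    reoffer <- s$choice[keep] == s$pair_a[keep + 3L] |
      s$choice[keep] == s$pair_b[keep + 3L]
    keep <- keep[reoffer & !is.na(s$choice[keep + 3L])]
    if (!length(keep)) return(NULL)
    disjoint <- s$condition[1] == "disjoint"
    r0 <- if (disjoint && disjoint_0F == "component") {
      s$imm_feedback[keep]
    } else {
      s$total_feedback[keep]
    }
    r2 <- if (disjoint || conjoint_valence == "component") {
      s$del_feedback[keep + 2L]
    } else {
      s$total_feedback[keep + 2L]
    }
    tibble::tibble(
      participant_id = s$participant_id[1], condition = s$condition[1],
      stage = s$stage[1], t = s$t[keep], reappear_t = s$t[keep + 3L],
      stim = s$choice[keep],
      stay = as.integer(s$choice[keep + 3L] == s$choice[keep]),
      reward_0F = valence(r0), reward_2F = valence(r2)
    )
  }))
  if (is.null(out) || nrow(out) == 0) empty else out
}

#' Stay/switch signature regression
#'
#' Expands each reappearance event into two rows (time `0F` with the origin
#' valence; time `2F` with the delayed-arrival valence) and fits a pooled
#' fixed-effects logistic regression of staying on the full
#' condition x time x reward interaction. Returns Wald odds-ratio
#' confidence intervals and the raw cell-level stay proportions. Complete
#' separation is reported via a warning, never silently corrected.
#'
#' @param events Event tibble from [extract_stay_events()].
#' @return An object of class `ca_signature`: list with `tidy`
#'   (coefficients, odds ratios, 95% CI, p-values), `cells` (stay
#'   proportion per condition x time x reward cell), and the fitted `model`.
#' @export
stay_signature_regression <- function(events) {
  long <- tidyr::pivot_longer(events, c("reward_0F", "reward_2F"),
                              names_to = "time", values_to = "reward")
  long$time <- ifelse(long$time == "reward_0F", "0F", "2F")
  # constant factors (e.g. a single-condition event set) are dropped from
  # the interaction rather than erroring
  rhs <- c("condition", "time", "reward")
  rhs <- rhs[vapply(rhs, function(v) length(unique(long[[v]])) > 1,
                    logical(1))]
  form <- if (length(rhs)) {
    stats::reformulate(paste(rhs, collapse = "*"), response = "stay")
  } else {
    stay ~ 1
  }
  fit <- glm(form, family = binomial(), data = long)
  if (!fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE)) {
    warning("possible complete separation in the stay/switch regression; ",
            "coefficients may be unstable.", call. = FALSE)
  }
  cells <- dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$time, .data$reward),
    p_stay = mean(.data$stay), n = dplyr::n(), .groups = "drop"
  )
  structure(list(tidy = tidy_logistic(fit), cells = cells, model = fit),
            class = "ca_signature")
}

# Wald odds-ratio table for a fitted binomial glm; aliased (rank-deficient)
# terms are reported with NA estimates rather than dropped silently.
tidy_logistic <- function(fit) {
  cf <- coef(fit)
  se <- rep(NA_real_, length(cf))
  ok <- !is.na(cf)
  se[ok] <- sqrt(diag(vcov(fit)))[names(cf)[ok]]
  z <- cf / se
  tibble::tibble(
    term = names(cf), estimate = unname(cf), std_error = unname(se),
    odds_ratio = exp(unname(cf)),
    conf_low = exp(unname(cf - qnorm(0.975) * se)),
    conf_high = exp(unname(cf + qnorm(0.975) * se)),
    p_value = 2 * stats::pnorm(-abs(unname(z)))
  )
}

#' @export
print.ca_signature <- function(x, ...) {
  cat("<ca_signature> logistic regression,", nrow(x$cells), "cells\n")
  print(as.data.frame(x$tidy))
  invisible(x)
}

# Pair-type label from the delay classes of the two offered stimuli.
pair_type_of <- function(pair_a, pair_b, stimset) {
  cls <- stimset$delay_class[order(stimset$id)]
  a_del <- cls[pair_a + 1L] == "delayed"
  b_del <- cls[pair_b + 1L] == "delayed"
  dplyr::case_when(
    a_del & b_del ~ "Del v Del",
    !a_del & !b_del ~ "Imm v Imm",
    TRUE ~ "Mixed"
  )
}

#' Model predictive accuracy by pair type
#'
#' Joins model-generated sessions (e.g. from
#' [simulate_posterior_iterations()]) to the observed sessions by session
#' keys and trial, classifies each trial's offered pair as delayed vs
#' delayed, immediate vs immediate, or mixed, and reports the proportion of
#' trials where the generated choice matches the observed choice, per pair
#' type (averaged over iterations).
#'
#' @param generated Generated session tibble with an `iteration` column.
#' @param observed Observed session tibble sharing the schedules.
#' @param stimset Stimulus set from [stimulus_set()].
#' @return A tibble with `pair_type`, `accuracy`, `n_trials`.
#' @export
pairtype_accuracy <- function(generated, observed, stimset) {
  keys <- c("participant_id", "condition", "stage", "t")
  joined <- dplyr::inner_join(
    dplyr::rename(generated, gen_choice = "choice"),
    dplyr::select(observed, dplyr::all_of(keys), obs_pair_a = "pair_a",
                  obs_pair_b = "pair_b", obs_choice = "choice"),
    by = keys
  )
  if (nrow(joined) != nrow(generated) ||
      any(joined$pair_a != joined$obs_pair_a |
          joined$pair_b != joined$obs_pair_b)) {
    stop("generated and observed sessions do not share schedules.",
         call. = FALSE)
  }
  joined$pair_type <- pair_type_of(joined$pair_a, joined$pair_b, stimset)
  keep <- !is.na(joined$obs_choice) & !is.na(joined$gen_choice)
  dplyr::summarise(
    dplyr::group_by(joined[keep, ], .data$pair_type),
    accuracy = mean(.data$gen_choice == .data$obs_choice),
    n_trials = dplyr::n(), .groups = "drop"
  )
}

#' Attach per-trial model choice probabilities to observed sessions
#'
#' Computes, for each observed session, the probability each strategy
#' assigns to the first option of the offered pair (`pair_a`), using a
#' single parameter set per strategy. Used to build the design matrix for
#' [choice_prediction_regression()].
#'
#' @param sessions Observed multi-session tibble.
#' @param params_elg,params_tab [ca_params()] objects for the eligibility
#'   and tabular strategies.
#' @param window,skip_absent Passed to [run_model()].
#' @return `sessions` with added columns `p_elg` and `p_tab`.
#' @export
model_choice_probs <- function(sessions, params_elg, params_tab, window = 5,
                               skip_absent = FALSE) {
  purrr::list_rbind(purrr::map(split_sessions(sessions), function(s) {
    s$p_elg <- run_model(s, params_elg, window = window,
                         skip_absent = skip_absent)$trials$p_a
    s$p_tab <- run_model(s, params_tab, window = window,
                         skip_absent = skip_absent)$trials$p_a
    s
  }))
}

#' Choice-prediction regression
#'
#' Pooled fixed-effects logistic regression of the observed binary choice
#' (chose `pair_a`) on the two strategies' predicted probabilities,
#' condition, and their interactions:
#' `choice ~ condition * (p_elg + p_tab)`.
#'
#' @param data Trial tibble with columns `choice`, `pair_a`, `condition`,
#'   `p_elg`, `p_tab` (see [model_choice_probs()]).
#' @return A `ca_signature` object (tidy odds-ratio table + fitted model).
#' @export
choice_prediction_regression <- function(data) {
  keep <- !is.na(data$choice)
  data <- data[keep, ]
  if (any(!is.finite(data$p_elg)) || any(!is.finite(data$p_tab))) {
    stop("non-finite model predictions.", call. = FALSE)
  }
  data$choice_a <- as.integer(data$choice == data$pair_a)
  form <- if (length(unique(data$condition)) > 1) {
    choice_a ~ condition * (p_elg + p_tab)
  } else {
    choice_a ~ p_elg + p_tab
  }
  fit <- glm(form, family = binomial(), data = data)
  td <- tidy_logistic(fit)
  if (any(is.na(td$estimate))) {
    warning("rank-deficient design: some terms are aliased and reported ",
            "as NA.", call. = FALSE)
  }
  structure(list(tidy = td, cells = NULL, model = fit),
            class = "ca_signature")
}

#' Credit-assignment gradient over recent selections
#'
#' For every trial (from the fourth) whose last four choices are all
#' distinct and responded, records the one-step value change the model
#' applied between this trial and the next to the options selected at lags
#' 0 through 3, grouped by the valence of the current trial's prediction
#' error. The eligibility trace spreads geometrically decaying credit over
#' the sequence; the tabular model credits only lags 0 and 2, skipping the
#' systematically irrelevant lags 1 and 3.
#'
#' @param sessions Multi-session trial tibble.
#' @param params A [ca_params()] object.
#' @param strategy Which value function to difference: `"eligibility"`
#'   (`v`) or `"tabular"` (`Q(0, a) + Q(2, a)`).
#' @param window,skip_absent Passed to [run_model()].
#' @return A tibble with `condition`, `valence`, `lag`, `mean_credit`, `n`.
#' @export
credit_gradient <- function(sessions, params,
                            strategy = c("eligibility", "tabular"),
                            window = 5, skip_absent = FALSE) {
  strategy <- match.arg(strategy)
  rows <- purrr::list_rbind(purrr::map(split_sessions(sessions), function(s) {
    run <- run_model(s, params, window = window, skip_absent = skip_absent)
    W <- if (strategy == "eligibility") run$v else run$q0 + run$q2
    n <- nrow(s)
    if (n < 5) return(NULL)
    ch <- s$choice
    out <- list()
    for (i in 4:(n - 1)) {
      idx <- (i - 3):i
      if (any(is.na(ch[idx])) || anyDuplicated(ch[idx])) next
      if (strategy == "eligibility") {
        delta <- s$total_feedback[i] - run$v[i, ch[i] + 1L]
      } else {
        r0 <- if (s$condition[1] == "disjoint") {
          ifelse(is.na(s$imm_feedback[i]), 0, s$imm_feedback[i])
        } else s$total_feedback[i]
        delta <- r0 - (run$q0[i, ch[i] + 1L])
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        condition = s$condition[1],
        valence = ifelse(delta > 0, "+", "-"),
        lag = 0:3,
        credit = W[i + 1L, ch[i - (0:3)] + 1L] - W[i, ch[i - (0:3)] + 1L]
      )
    }
    purrr::list_rbind(out)
  }))
  if (is.null(rows) || nrow(rows) == 0) {
    return(tibble::tibble(condition = character(), valence = character(),
                          lag = integer(), mean_credit = numeric(),
                          n = integer()))
  }
  dplyr::summarise(
    dplyr::group_by(rows, .data$condition, .data$valence, .data$lag),
    mean_credit = mean(.data$credit), n = dplyr::n(), .groups = "drop"
  )
}

#' Paired condition contrasts of fitted parameters
#'
#' Two-tailed paired t-tests (conjoint minus disjoint) with Cohen's d for
#' each fitted parameter, pairing sessions by participant. Zero
#' within-pair variance is flagged as degenerate rather than tested.
#'
#' @param fits_conjoint,fits_disjoint Tibbles of per-participant fits
#'   (rows from [fit_study()]), one per condition, with a `fit`
#'   list-column or `participant_id` plus parameter columns.
#' @return A tibble with `term`, `df`, `t`, `p_value`, `conf_low`,
#'   `conf_high`, `cohens_d`, `degenerate`.
#' @export
parameter_condition_tests <- function(fits_conjoint, fits_disjoint) {
  grab <- function(fits) {
    if ("fit" %in% names(fits)) {
      purrr::list_rbind(purrr::map(fits$fit, function(f) {
        dplyr::mutate(tidy(f), participant_id = f$participant_id)
      }))
    } else {
      fits
    }
  }
  a <- grab(fits_conjoint)
  b <- grab(fits_disjoint)
  terms <- intersect(unique(a$term), unique(b$term))
  purrr::list_rbind(purrr::map(terms, function(tm) {
    x <- a[a$term == tm, c("participant_id", "estimate")]
    y <- b[b$term == tm, c("participant_id", "estimate")]
    m <- dplyr::inner_join(x, y, by = "participant_id",
                           suffix = c("_conjoint", "_disjoint"))
    if (nrow(m) < nrow(x) || nrow(m) < nrow(y)) {
      stop("unpaired inputs: participants differ across conditions.",
           call. = FALSE)
    }
    d <- m$estimate_conjoint - m$estimate_disjoint
    if (sd(d) == 0) {
      return(tibble::tibble(term = tm, df = length(d) - 1L, t = NA_real_,
                            p_value = NA_real_, conf_low = mean(d),
                            conf_high = mean(d), cohens_d = NA_real_,
                            degenerate = TRUE))
    }
    tt <- t.test(d)
    tibble::tibble(
      term = tm, df = as.integer(tt$parameter), t = unname(tt$statistic),
      p_value = tt$p.value, conf_low = tt$conf.int[1],
      conf_high = tt$conf.int[2], cohens_d = mean(d) / sd(d),
      degenerate = FALSE
    )
  }))
}
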