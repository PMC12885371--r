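#' Parameter-recovery study
#'
#' For each synthetic dataset: draw a generative parameter set from the
#' simulation prior, simulate one session per requested condition on a
#' freshly shuffled schedule, refit the same variant, and record the
#' (true, recovered) pair for every free parameter. Summaries report the
#' Pearson correlation and mean bias (recovered minus true) per parameter,
#' pooled and per condition.
#'
#' @param variant Model variant to simulate and refit.
#' @param n_datasets Number of generative draws (the full-scale study uses
#'   300; scale down for quick runs).
#' @param conditions Conditions to simulate per draw.
#' @param beta_min Lower truncation of the generative strategy-weight draw
#'   (informative choosers recover better).
#' @param n_stimuli,n_repeats,step_scale Task structure.
#' @param window,skip_absent Model settings.
#' @param seed Master seed.
#' @param ... Passed to [fit_session()] (e.g. `max_gen`).
#' @return An object of class `ca_recovery`: list with `pairs` (tibble of
#'   `dataset`, `condition`, `term`, `true`, `recovered`) and `summary`
#'   (per-parameter correlation and bias). Supports [autoplot()].
#' @export
run_parameter_recovery <- function(variant, n_datasets = 300L,
                                   conditions = c("conjoint", "disjoint"),
                                   beta_min = 0, n_stimuli = 8L,
                                   n_repeats = 12L, step_scale = 0.5,
                                   window = 5, skip_absent = FALSE,
                                   seed = 1L, ...) {
  conditions <- match.arg(conditions, c("conjoint", "disjoint"),
                          several.ok = TRUE)
  if (n_datasets == 0) {
    empty <- tibble::tibble(dataset = integer(), condition = character(),
                            term = character(), true = numeric(),
                            recovered = numeric())
    empty_sum <- tibble::tibble(term = character(), condition = character(),
                                r = numeric(), bias = numeric(),
                                n = integer())
    return(structure(list(pairs = empty, summary = empty_sum,
                          variant = variant), class = "ca_recovery"))
  }
  stimset <- stimulus_set(ca_seed(seed, "stimset"))
  n_trials <- choose(n_stimuli, 2) * n_repeats
  walks <- purrr::map(1:3, function(k) {
    reward_walk(stimset, n_trials, step_scale,
                seed = ca_seed(seed, "walk", k), walk_id = k)
  })
  rows <- list()
  for (i in seq_len(n_datasets)) {
    truth <- sample_params(1, variant, seed = ca_seed(seed, "truth", i),
                           beta_min = beta_min)
    true_theta <- unlist(truth[1, free_param_names_for_tbl(variant)])
    for (cond in conditions) {
      sched <- trial_schedule(n_stimuli, n_repeats,
                              seed = ca_seed(seed, "sched", i, cond))
      wid <- 1L + ca_seed(seed, "walkpick", i, cond) %% 3L
      sess <- simulate_session(as_ca_params(truth), sched, walks[[wid]],
                               stimset, cond,
                               seed = ca_seed(seed, "sim", i, cond),
                               participant_id = sprintf("rec%03d", i),
                               window = window, skip_absent = skip_absent)
      fit <- fit_session(sess, variant, window = window,
                         skip_absent = skip_absent,
                         seed = ca_seed(seed, "fit", i, cond), ...)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dataset = i, condition = cond, term = names(fit$theta),
        true = unname(true_theta), recovered = unname(fit$theta)
      )
    }
  }
  pairs <- purrr::list_rbind(rows)
  summarise_rec <- function(df, label) {
    dplyr::summarise(
      dplyr::group_by(df, .data$term),
      condition = label,
      r = stats::cor(.data$true, .data$recovered),
      bias = mean(.data$recovered - .data$true),
      n = dplyr::n(), .groups = "drop"
    )
  }
  summary <- dplyr::bind_rows(
    summarise_rec(pairs, "pooled"),
    purrr::list_rbind(purrr::map(split(pairs, pairs$condition),
                                 function(d) summarise_rec(d, d$condition[1])))
  )
  structure(list(pairs = pairs, summary = summary, variant = variant),
            class = "ca_recovery")
}

# Free-parameter columns of a sample_params() tibble, in fitting order.
free_param_names_for_tbl <- function(variant) {
  nm <- free_param_names(variant)
  # shared-parameter variants store the shared draw in the *_elg columns
  nm[nm == "alpha"] <- "alpha_elg"
  nm[nm == "lambda"] <- "lambda_elg"
  nm
}

#' @export
print.ca_recovery <- function(x, ...) {
  cat("<ca_recovery>", x$variant, "model,",
      length(unique(x$pairs$dataset)), "datasets\n")
  print(as.data.frame(x$summary[x$summary$condition == "pooled", ]))
  invisible(x)
}

#' Cross-model recovery (confusion matrix)
#'
#' Simulates sessions from each generating variant, fits every candidate
#' variant to each simulated session, and tabulates how often each
#' criterion (AIC and BIC) selects each candidate. Ties are broken toward
#' the variant with fewer parameters.
#'
#' @param variants Generating/candidate variants.
#' @param n_sims Simulated sessions per generating variant.
#' @param beta_min Lower truncation of generative strategy weights.
#' @param conditions Conditions cycled across simulations.
#' @inheritParams run_parameter_recovery
#' @return An object of class `ca_confusion`: list with `wins` (tibble of
#'   per-simulation winners) and `matrix` (named list of row-normalized
#'   confusion matrices, one per criterion).
#' @export
run_model_recovery <- function(variants = c("eligibility", "tabular", "hybrid"),
                               n_sims = 25L,
                               conditions = c("conjoint", "disjoint"),
                               beta_min = 0, n_stimuli = 8L, n_repeats = 12L,
                               step_scale = 0.5, window = 5,
                               skip_absent = FALSE, seed = 1L, ...) {
  stimset <- stimulus_set(ca_seed(seed, "stimset"))
  n_trials <- choose(n_stimuli, 2) * n_repeats
  walks <- purrr::map(1:3, function(k) {
    reward_walk(stimset, n_trials, step_scale,
                seed = ca_seed(seed, "walk", k), walk_id = k)
  })
  k_of <- vapply(variants, function(v) length(free_param_names(v)), numeric(1))
  rows <- list()
  for (g in variants) {
    for (i in seq_len(n_sims)) {
      cond <- conditions[1L + (i - 1L) %% length(conditions)]
      truth <- sample_params(1, g, seed = ca_seed(seed, "truth", g, i),
                             beta_min = beta_min)
      sched <- trial_schedule(n_stimuli, n_repeats,
                              seed = ca_seed(seed, "sched", g, i))
      wid <- 1L + ca_seed(seed, "walkpick", g, i) %% 3L
      sess <- simulate_session(as_ca_params(truth), sched, walks[[wid]],
                               stimset, cond,
                               seed = ca_seed(seed, "sim", g, i),
                               window = window, skip_absent = skip_absent)
      ics <- purrr::map(variants, function(v) {
        fit <- fit_session(sess, v, window = window,
                           skip_absent = skip_absent,
                           seed = ca_seed(seed, "fit", g, i, v), ...)
        c(aic = fit$aic, bic = fit$bic)
      })
      aic <- vapply(ics, `[[`, numeric(1), "aic")
      bic <- vapply(ics, `[[`, numeric(1), "bic")
      pick <- function(vals) {
        hit <- which(vals == min(vals))
        variants[hit[which.min(k_of[hit])]]  # ties -> simpler model
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        generator = g, sim = i, condition = cond,
        winner_aic = pick(aic), winner_bic = pick(bic)
      )
    }
  }
  wins <- purrr::list_rbind(rows)
  conf <- function(col) {
    m <- table(factor(wins$generator, levels = variants),
               factor(wins[[col]], levels = variants))
    sweep(unclass(m), 1, rowSums(m), "/")
  }
  structure(list(wins = wins,
                 matrix = list(aic = conf("winner_aic"),
                               bic = conf("winner_bic")),
                 variants = variants),
            class = "ca_confusion")
}

#' @export
print.ca_confusion <- function(x, ...) {
  cat("<ca_confusion> rows = generating model, cols = winner\nAIC:\n")
  print(round(x$matrix$aic, 3))
  cat("BIC:\n")
  print(round(x$matrix$bic, 3))
  invisible(x)
}
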