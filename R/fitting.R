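#' Session negative log-likelihood
#'
#' Minus the sum of natural-log choice probabilities over responded trials,
#' with probabilities from [run_model()]. A floor of `1e-12` inside the log
#' keeps the value finite during optimizer exploration.
#'
#' @inheritParams run_model
#' @return Non-negative scalar.
#' @examples
#' # an all-betas-zero model assigns 1/2 to every choice
#' @export
negative_log_likelihood <- function(session, params, window = 5,
                                    skip_absent = FALSE) {
  run <- run_model(session, params, window = window,
                   skip_absent = skip_absent)
  p <- run$trials$p_choice
  -sum(log(pmax(p[!is.na(p)], 1e-12)))
}

# Precompute the plain-vector form of a session for the optimizer hot path.
session_arrays <- function(session) {
  session <- session[order(session$t), ]
  list(
    pa = as.integer(session$pair_a), pb = as.integer(session$pair_b),
    ch = ifelse(is.na(session$choice), -1L, as.integer(session$choice)),
    imm = as.numeric(session$imm_feedback),
    del = as.numeric(session$del_feedback),
    tot = as.numeric(session$total_feedback),
    disjoint = as.integer(session$condition[1] == "disjoint"),
    resp = !is.na(session$choice)
  )
}

# Map a free-parameter vector to the canonical 6-parameter vector
# (alpha_elg, lambda_elg, beta_elg, alpha_tab, lambda_tab, beta_tab)
# without constructor overhead; mirrors params_from_theta().
theta_to_parvec <- function(variant, theta) {
  switch(variant,
    eligibility = c(theta[1], theta[2], theta[3], 0, 0, 0),
    tabular     = c(0, 0, 0, theta[1], theta[2], theta[3]),
    hybrid      = theta,
    hybrid_1L   = c(theta[1], theta[2], theta[3], theta[1], theta[4], theta[5]),
    hybrid_1D   = c(theta[1], theta[2], theta[3], theta[1], theta[2], theta[4])
  )
}

nll_from_arrays <- function(arr, parvec, win, skip_absent) {
  res <- ca_engine_cpp(arr$pa, arr$pb, arr$ch, arr$imm, arr$del, arr$tot,
                       arr$disjoint, parvec, win, as.integer(skip_absent),
                       0L)
  -sum(log(pmax(res$p_choice[arr$resp], 1e-12)))
}

# Log penalty prior over the free parameters of a variant:
# Gamma(1.25, scale 1) on each strategy weight, Beta(1.25, 1.25) on each
# learning/decay rate. -Inf at the rate bounds and at beta = 0.
penalty_log_prior <- function(theta, variant) {
  nm <- free_param_names(variant)
  lp <- 0
  for (j in seq_along(nm)) {
    lp <- lp + if (grepl("^beta", nm[j])) {
      dgamma(theta[j], shape = 1.25, scale = 1, log = TRUE)
    } else {
      dbeta(theta[j], 1.25, 1.25, log = TRUE)
    }
  }
  lp
}

param_bounds <- function(variant) {
  nm <- free_param_names(variant)
  is_beta <- grepl("^beta", nm)
  list(lower = ifelse(is_beta, 0, 1e-6),
       upper = ifelse(is_beta, 20, 1 - 1e-6),
       names = nm)
}

#' Bounded global minimization by differential evolution
#'
#' A standard rand/1/bin differential-evolution optimizer with reflecting
#' bounds. Declares convergence when the best objective value improves by
#' less than `reltol` (relatively) for `steady_limit` consecutive
#' generations.
#'
#' @param fn Objective function of a numeric vector; smaller is better.
#' @param lower,upper Bound vectors.
#' @param seed Optional integer seed.
#' @param pop_size Population size (default 15 x dimension).
#' @param max_gen Generation cap.
#' @param f,cr Mutation factor and crossover rate.
#' @param reltol Relative convergence tolerance.
#' @param steady_limit Consecutive stalled generations required to stop.
#' @return List with `par`, `value`, `iterations`, `converged`.
#' @export
de_optimize <- function(fn, lower, upper, seed = NULL, pop_size = NULL,
                        max_gen = 300L, f = 0.8, cr = 0.9, reltol = 1e-8,
                        steady_limit = 25L) {
  d <- length(lower)
  pop_size <- pop_size %||% (15L * d)
  reflect <- function(x) {
    x <- ifelse(x < lower, 2 * lower - x, x)
    x <- ifelse(x > upper, 2 * upper - x, x)
    pmin(pmax(x, lower), upper)
  }
  with_seed(seed, {
    pop <- t(replicate(pop_size, runif(d, lower, upper)))
    fit <- apply(pop, 1, fn)
    steady <- 0L
    gen <- 0L
    while (gen < max_gen) {
      gen <- gen + 1L
      best_prev <- min(fit)
      for (i in seq_len(pop_size)) {
        idx <- sample.int(pop_size - 1L, 3L)
        idx[idx >= i] <- idx[idx >= i] + 1L
        mut <- reflect(pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ]))
        cross <- runif(d) < cr
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, mut, pop[i, ])
        ft <- fn(trial)
        if (ft <= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- ft
        }
      }
      best <- min(fit)
      steady <- if (best_prev - best < reltol * (abs(best) + reltol)) {
        steady + 1L
      } else 0L
      if (steady >= steady_limit) break
    }
    b <- which.min(fit)
    list(par = pop[b, ], value = fit[b], iterations = gen,
         converged = steady >= steady_limit)
  })
}

#' Fit a model variant to one session by penalized maximum likelihood
#'
#' Minimizes `nll - sum(log prior)` over the bounded parameter space
#' (rates in `[1e-6, 1 - 1e-6]`, weights in `[0, 20]`) with
#' [de_optimize()]. The reported `nll`, AIC, BIC and pseudo-R^2 use the
#' unpenalized likelihood at the optimum; the penalty acts only as a
#' regularizer. Pseudo-R^2 is computed against the uniform-choice null over
#' responded trials: `1 - nll / (n * log(2))`.
#'
#' @inheritParams run_model
#' @param variant Model variant to fit; see [ca_params()].
#' @param seed Integer seed for the optimizer (refits reproduce exactly).
#' @param pop_size,max_gen,reltol Optimizer settings; see [de_optimize()].
#' @param penalized_metrics If `TRUE`, AIC/BIC are computed from the
#'   penalized objective instead of the raw likelihood.
#' @return An object of class `ca_fit` with the fitted [ca_params()],
#'   `nll`, `objective`, `k`, `n`, `aic`, `bic`, `pseudo_r2` and optimizer
#'   diagnostics. Supports [tidy()] and [glance()].
#' @export
fit_session <- function(session, variant = "hybrid", window = 5,
                        skip_absent = FALSE, seed = 1L, pop_size = NULL,
                        max_gen = 300L, reltol = 1e-8,
                        penalized_metrics = FALSE) {
  validate_sessions(session)
  n_resp <- sum(!is.na(session$choice))
  if (n_resp < 1) stop("session has no responded trials.", call. = FALSE)
  b <- param_bounds(variant)
  arr <- session_arrays(session)
  win <- if (is.infinite(window)) -1L else as.integer(window)
  is_beta <- grepl("^beta", b$names)
  objective <- function(theta) {
    lp <- sum(dgamma(theta[is_beta], shape = 1.25, scale = 1, log = TRUE)) +
      sum(dbeta(theta[!is_beta], 1.25, 1.25, log = TRUE))
    if (!is.finite(lp)) return(1e10)
    val <- nll_from_arrays(arr, theta_to_parvec(variant, theta), win,
                           skip_absent) - lp
    if (!is.finite(val)) 1e10 else val
  }
  opt <- de_optimize(objective, b$lower, b$upper, seed = seed,
                     pop_size = pop_size, max_gen = max_gen, reltol = reltol)
  params <- params_from_theta(variant, opt$par)
  nll <- negative_log_likelihood(session, params, window = window,
                                 skip_absent = skip_absent)
  k <- length(b$lower)
  ll_for_ic <- if (penalized_metrics) opt$value else nll
  structure(list(
    params = params,
    theta = setNames(opt$par, b$names),
    variant = variant,
    nll = nll,
    objective = opt$value,
    k = k,
    n = n_resp,
    aic = 2 * k + 2 * ll_for_ic,
    bic = k * log(n_resp) + 2 * ll_for_ic,
    pseudo_r2 = 1 - nll / (n_resp * log(2)),
    window = window,
    participant_id = session$participant_id[1],
    condition = session$condition[1],
    stage = session$stage[1],
    optimizer = list(seed = seed, iterations = opt$iterations,
                     converged = opt$converged)
  ), class = "ca_fit")
}

#' @export
print.ca_fit <- function(x, ...) {
  cat("<ca_fit>", x$variant, "model |", x$participant_id, x$condition,
      "\n  nll", round(x$nll, 2), "| AIC", round(x$aic, 1), "| pseudo-R2",
      round(x$pseudo_r2, 3), "| converged:", x$optimizer$converged, "\n")
  invisible(x)
}

#' @rdname fit_session
#' @param x A `ca_fit` object.
#' @param ... Unused.
#' @export
tidy.ca_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' @rdname fit_session
#' @export
glance.ca_fit <- function(x, ...) {
  tibble::tibble(
    participant_id = x$participant_id, condition = x$condition,
    stage = x$stage, variant = x$variant, k = x$k, n = x$n,
    nll = x$nll, objective = x$objective, aic = x$aic, bic = x$bic,
    pseudo_r2 = x$pseudo_r2, iterations = x$optimizer$iterations,
    converged = x$optimizer$converged
  )
}

#' Fit every session in a study table
#'
#' Convenience wrapper mapping [fit_session()] over the sessions of a
#' multi-session tibble; optimizer seeds derive from `seed` per session.
#'
#' @param sessions Multi-session trial tibble.
#' @param variant Model variant.
#' @param seed Master seed.
#' @param ... Passed to [fit_session()].
#' @return A tibble with one row per session ([glance()] columns) and a
#'   `fit` list-column holding the `ca_fit` objects.
#' @export
fit_study <- function(sessions, variant = "hybrid", seed = 1L, ...) {
  sess <- split_sessions(sessions)
  fits <- purrr::imap(sess, function(s, key) {
    fit_session(s, variant, seed = ca_seed(seed, "fit", variant, key), ...)
  })
  out <- purrr::list_rbind(purrr::map(fits, glance))
  out$fit <- unname(fits)
  out
}

#' Compare fitted model variants per condition
#'
#' For each condition, reports each variant's mean AIC and mean pseudo-R^2,
#' flags the best (lowest mean AIC) variant, and attaches paired Wilcoxon
#' signed-rank p-values comparing each variant's per-session AICs to the
#' best variant's.
#'
#' @param fits Tibble of per-session fit summaries (rows from
#'   [glance()]/[fit_study()] for two or more variants over the same
#'   sessions).
#' @return A tibble with columns `condition`, `variant`, `mean_aic`,
#'   `mean_pseudo_r2`, `best`, `p_vs_best`.
#' @export
compare_models <- function(fits) {
  need <- c("participant_id", "condition", "stage", "variant", "aic",
            "pseudo_r2")
  missing <- setdiff(need, names(fits))
  if (length(missing)) {
    stop("`fits` is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  purrr::list_rbind(purrr::map(split(fits, fits$condition), function(fc) {
    wide <- split(fc, fc$variant)
    sets <- purrr::map(wide, function(w) sort(paste(w$participant_id, w$stage)))
    if (length(unique(sets)) != 1) {
      stop("variants were not fitted to matching session sets in condition ",
           fc$condition[1], call. = FALSE)
    }
    means <- dplyr::summarise(
      dplyr::group_by(fc, .data$variant),
      mean_aic = mean(.data$aic),
      mean_pseudo_r2 = mean(.data$pseudo_r2), .groups = "drop"
    )
    best_v <- means$variant[which.min(means$mean_aic)]
    best_aic <- wide[[best_v]]$aic[order(paste(wide[[best_v]]$participant_id,
                                               wide[[best_v]]$stage))]
    means$best <- means$variant == best_v
    means$p_vs_best <- unname(vapply(means$variant, function(v) {
      if (v == best_v) return(NA_real_)
      a <- wide[[v]]$aic[order(paste(wide[[v]]$participant_id,
                                     wide[[v]]$stage))]
      d <- a - best_aic
      if (all(d == 0)) return(1)
      suppressWarnings(wilcox.test(a, best_aic, paired = TRUE)$p.value)
    }, numeric(1)))
    means$condition <- fc$condition[1]
    means[, c("condition", "variant", "mean_aic", "mean_pseudo_r2", "best",
              "p_vs_best")]
  }))
}
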