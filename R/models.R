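ca_variants <- c("eligibility", "tabular", "hybrid", "hybrid_1L", "hybrid_1D")

#' Model parameter sets
#'
#' Bundles the six free parameters of the hybrid learner: learning rates
#' (`alpha_elg`, `alpha_tab` in \[0,1\]), decay rates (`lambda_elg`,
#' `lambda_tab` in \[0,1\]) and softmax strategy weights (`beta_elg`,
#' `beta_tab` >= 0). Single-strategy variants force the other strategy's
#' weight to zero; `hybrid_1L` shares the learning rate across strategies
#' and `hybrid_1D` additionally shares the decay rate.
#'
#' @param variant One of `"eligibility"`, `"tabular"`, `"hybrid"`,
#'   `"hybrid_1L"`, `"hybrid_1D"`.
#' @param alpha_elg,lambda_elg,beta_elg Eligibility-trace learning rate,
#'   trace decay, and strategy weight.
#' @param alpha_tab,lambda_tab,beta_tab Tabular learning rate, delayed-slot
#'   decay, and strategy weight.
#' @return An object of class `ca_params`.
#' @examples
#' ca_params("eligibility", alpha_elg = 0.3, lambda_elg = 0.5, beta_elg = 5)
#' @export
ca_params <- function(variant = "hybrid",
                      alpha_elg = 0.3, lambda_elg = 0.5, beta_elg = 3,
                      alpha_tab = 0.3, lambda_tab = 0.5, beta_tab = 3) {
  variant <- match.arg(variant, ca_variants)
  if (variant == "eligibility") beta_tab <- 0
  if (variant == "tabular") beta_elg <- 0
  if (variant %in% c("hybrid_1L", "hybrid_1D")) alpha_tab <- alpha_elg
  if (variant == "hybrid_1D") lambda_tab <- lambda_elg
  p <- list(variant = variant,
            alpha_elg = alpha_elg, lambda_elg = lambda_elg, beta_elg = beta_elg,
            alpha_tab = alpha_tab, lambda_tab = lambda_tab, beta_tab = beta_tab)
  rates <- unlist(p[c("alpha_elg", "lambda_elg", "alpha_tab", "lambda_tab")])
  if (any(rates < 0 | rates > 1)) {
    stop("learning and decay rates must lie in [0, 1].", call. = FALSE)
  }
  if (p$beta_elg < 0 || p$beta_tab < 0) {
    stop("strategy weights must be non-negative.", call. = FALSE)
  }
  structure(p, class = "ca_params")
}

#' @export
print.ca_params <- function(x, ...) {
  cat("<ca_params>", x$variant, "\n")
  v <- unlist(x[setdiff(names(x), "variant")])
  print(round(v, 4))
  invisible(x)
}

# Free parameters of each variant, in fitting order.
free_param_names <- function(variant) {
  switch(variant,
    eligibility = c("alpha_elg", "lambda_elg", "beta_elg"),
    tabular     = c("alpha_tab", "lambda_tab", "beta_tab"),
    hybrid      = c("alpha_elg", "lambda_elg", "beta_elg",
                    "alpha_tab", "lambda_tab", "beta_tab"),
    hybrid_1L   = c("alpha", "lambda_elg", "beta_elg", "lambda_tab", "beta_tab"),
    hybrid_1D   = c("alpha", "lambda", "beta_elg", "beta_tab"),
    stop("unknown variant: ", variant, call. = FALSE)
  )
}

# Expand a free-parameter vector (fitting order) into a full ca_params.
params_from_theta <- function(variant, theta) {
  nm <- free_param_names(variant)
  theta <- setNames(as.numeric(theta), nm)
  g <- function(x, default = 0) if (x %in% nm) theta[[x]] else default
  switch(variant,
    eligibility = ca_params(variant, alpha_elg = g("alpha_elg"),
                            lambda_elg = g("lambda_elg"), beta_elg = g("beta_elg"),
                            alpha_tab = 0, lambda_tab = 0, beta_tab = 0),
    tabular = ca_params(variant, alpha_tab = g("alpha_tab"),
                        lambda_tab = g("lambda_tab"), beta_tab = g("beta_tab"),
                        alpha_elg = 0, lambda_elg = 0, beta_elg = 0),
    hybrid = ca_params(variant, alpha_elg = g("alpha_elg"),
                       lambda_elg = g("lambda_elg"), beta_elg = g("beta_elg"),
                       alpha_tab = g("alpha_tab"), lambda_tab = g("lambda_tab"),
                       beta_tab = g("beta_tab")),
    hybrid_1L = ca_params(variant, alpha_elg = g("alpha"),
                          lambda_elg = g("lambda_elg"), beta_elg = g("beta_elg"),
                          lambda_tab = g("lambda_tab"), beta_tab = g("beta_tab")),
    hybrid_1D = ca_params(variant, alpha_elg = g("alpha"),
                          lambda_elg = g("lambda"), beta_elg = g("beta_elg"),
                          beta_tab = g("beta_tab"))
  )
}

param_vector <- function(params) {
  unlist(params[c("alpha_elg", "lambda_elg", "beta_elg",
                  "alpha_tab", "lambda_tab", "beta_tab")])
}

#' One replacing-eligibility-trace learning step
#'
#' Computes the reward prediction error against the pre-update value of the
#' chosen action, resets the chosen action's trace to 1 while decaying all
#' other traces by `lambda`, then updates every action's value by
#' `alpha * delta * trace`.
#'
#' @param v Numeric vector of action values.
#' @param e Numeric vector of traces (same length, values in \[0,1\]).
#' @param chosen 1-based index of the chosen action.
#' @param reward Displayed total reward on the trial.
#' @param alpha,lambda Learning and decay rates in \[0,1\].
#' @return List with updated `v`, `e`, and the prediction error `delta`.
#' @examples
#' elig_step(rep(0, 8), rep(0, 8), chosen = 3, reward = 4, alpha = 0.25,
#'           lambda = 0.5)
#' @export
elig_step <- function(v, e, chosen, reward, alpha, lambda) {
  delta <- reward - v[chosen]
  e <- lambda * e
  e[chosen] <- 1
  v <- v + alpha * delta * e
  list(v = v, e = e, delta = delta)
}

#' Tabular prediction errors for the two delay slots
#'
#' The tabular learner holds delay-indexed values `Q(d, a)` for d = 0
#' (immediate) and d = 2 (two-trial delayed); the one-trial delay has no
#' slot. In the conjoint condition both prediction errors compare the same
#' displayed total against `Q(0, a_t)` and `Q(2, a_tm2)`. In the disjoint
#' condition the immediate component (or 0 when absent) is compared to
#' `Q(0, a_t)` and the delayed component (or 0) to `Q(2, a_tm2)`; with
#' `skip_absent = TRUE` an absent component produces no prediction error
#' instead of a zero-reward one.
#'
#' @param Q 2 x n matrix of values, rows `d = 0` and `d = 2`.
#' @param a_t 1-based index of the current choice, or `NA`.
#' @param a_tm2 1-based index of the choice two trials back, or `NA`.
#' @param imm,del,total Displayed feedback components (`NA` = absent) and
#'   total.
#' @param condition `"conjoint"` or `"disjoint"`.
#' @param skip_absent In disjoint, skip updates for absent components.
#' @return List with `delta0` and `delta2` (`NULL` when no update applies).
#' @export
tab_prediction_errors <- function(Q, a_t, a_tm2, imm, del, total, condition,
                                  skip_absent = FALSE) {
  condition <- match.arg(condition, c("conjoint", "disjoint"))
  delta0 <- delta2 <- NULL
  if (condition == "conjoint") {
    if (!is.na(a_t)) delta0 <- total - Q[1, a_t]
    if (!is.na(a_tm2)) delta2 <- total - Q[2, a_tm2]
  } else {
    if (!is.na(a_t) && !(skip_absent && is.na(imm))) {
      delta0 <- ifelse(is.na(imm), 0, imm) - Q[1, a_t]
    }
    if (!is.na(a_tm2) && !(skip_absent && is.na(del))) {
      delta2 <- ifelse(is.na(del), 0, del) - Q[2, a_tm2]
    }
  }
  list(delta0 = delta0, delta2 = delta2)
}

#' Apply tabular value updates
#'
#' `Q(0, a_t)` moves by `alpha * delta0`; `Q(2, a_tm2)` moves by
#' `alpha * lambda * delta2` (only the delayed slot is discounted by the
#' decay rate). Entries for other actions -- including the action chosen one
#' trial ago -- are never touched.
#'
#' @inheritParams tab_prediction_errors
#' @param delta0,delta2 Prediction errors from [tab_prediction_errors()]
#'   (`NULL` = no update).
#' @param alpha,lambda Tabular learning and decay rates.
#' @return The updated `Q` matrix.
#' @export
tab_update <- function(Q, a_t, a_tm2, delta0, delta2, alpha, lambda) {
  if (!is.null(delta0) && !is.na(a_t)) {
    Q[1, a_t] <- Q[1, a_t] + alpha * delta0
  }
  if (!is.null(delta2) && !is.na(a_tm2)) {
    Q[2, a_tm2] <- Q[2, a_tm2] + alpha * lambda * delta2
  }
  Q
}

#' Locally z-normalize a value vector against recent history
#'
#' Values entering the softmax are scaled relative to the recent history of
#' the same value function: the mean and (population) standard deviation are
#' pooled over every entry of the buffered snapshots from prior trials.
#' With an empty buffer the values pass through unchanged; with zero spread
#' only the mean is removed.
#'
#' @param current Numeric vector of decision-time values.
#' @param buffer Matrix of prior-trial snapshots (one row per trial), or
#'   `NULL` when no history exists.
#' @return The normalized vector.
#' @examples
#' normalize_values(c(3, 1), rbind(c(0, 2)))
#' @export
normalize_values <- function(current, buffer) {
  if (is.null(buffer) || nrow(buffer) == 0) return(current)
  m <- mean(buffer)
  s <- sqrt(mean((buffer - m)^2))
  if (s == 0) s <- 1
  (current - m) / s
}

#' Softmax choice probabilities for the offered pair
#'
#' The two strategies are combined at decision time: each option's score is
#' `beta_elg * z_elg + beta_tab * z_tab`, and the two scores enter a softmax.
#'
#' @param z_elg,z_tab Length-2 normalized values of the offered options
#'   under the eligibility and tabular strategies.
#' @param beta_elg,beta_tab Non-negative strategy weights.
#' @return Length-2 vector of probabilities summing to 1.
#' @examples
#' choice_probabilities(c(1, 0), c(0, 0), beta_elg = 1, beta_tab = 0)
#' @export
choice_probabilities <- function(z_elg, z_tab, beta_elg, beta_tab) {
  u <- beta_elg * z_elg + beta_tab * z_tab
  if (any(!is.finite(u))) stop("non-finite decision values.", call. = FALSE)
  u <- u - max(u)
  exp(u) / sum(exp(u))
}

#' Run a learning model over one session
#'
#' Iterates the trials of a single session in order: normalizes the
#' decision-time values of the offered pair within the trailing `window`
#' trials, computes hybrid softmax choice probabilities, and applies the
#' eligibility-trace update (driven by the displayed total in both
#' conditions) and the tabular double update (condition-dependent feedback).
#' Omitted-response trials contribute no likelihood term and no value
#' update; traces still decay.
#'
#' @param session A single-session trial tibble (one participant, one
#'   condition).
#' @param params A [ca_params()] object.
#' @param window Normalization window in trials: 0 disables scaling, `Inf`
#'   pools over the whole preceding task. Default 5.
#' @param skip_absent See [tab_prediction_errors()].
#' @param engine `"cpp"` (compiled, used by the fitting routines) or `"r"`
#'   (reference implementation composed from the exported primitive steps).
#'   Both produce identical output.
#' @return An object of class `ca_run`: list with `trials` (tibble of `t`,
#'   `pair_a`, `pair_b`, `choice`, `p_a` = probability of `pair_a`,
#'   `p_choice` = probability of the made choice) and decision-time
#'   trajectories `v`, `e`, `q0`, `q2` (`(n+1) x 8`; the last row is the
#'   post-session state).
#' @export
run_model <- function(session, params, window = 5, skip_absent = FALSE,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  validate_sessions(session)
  if (length(unique(paste(session$participant_id, session$condition,
                          session$stage))) != 1) {
    stop("`session` must contain exactly one session; see split_sessions().",
         call. = FALSE)
  }
  session <- session[order(session$t), ]
  win <- if (is.infinite(window)) -1L else as.integer(window)
  condition_disjoint <- as.integer(session$condition[1] == "disjoint")
  if (engine == "cpp") {
    res <- ca_engine_cpp(
      as.integer(session$pair_a), as.integer(session$pair_b),
      ifelse(is.na(session$choice), -1L, as.integer(session$choice)),
      as.numeric(session$imm_feedback), as.numeric(session$del_feedback),
      as.numeric(session$total_feedback),
      condition_disjoint, param_vector(params), win, as.integer(skip_absent)
    )
  } else {
    res <- ca_engine_r(session, params, win, skip_absent)
  }
  trials <- tibble::tibble(
    t = session$t, pair_a = session$pair_a, pair_b = session$pair_b,
    choice = session$choice, p_a = res$p_a, p_choice = res$p_choice
  )
  structure(list(trials = trials, v = res$v, e = res$e,
                 q0 = res$q0, q2 = res$q2, params = params,
                 condition = session$condition[1], window = window),
            class = "ca_run")
}

#' @export
print.ca_run <- function(x, ...) {
  cat("<ca_run>", x$params$variant, "model,", nrow(x$trials), "trials,",
      x$condition, "condition\n")
  print(utils::head(x$trials, 5))
  invisible(x)
}

# Pure-R engine: composes the exported primitive operations trial by trial.
ca_engine_r <- function(session, params, win, skip_absent) {
  n <- nrow(session)
  v <- rep(0, 8); e <- rep(0, 8); Q <- matrix(0, 2, 8)
  buf_e <- NULL; buf_t <- NULL
  V <- E <- Q0 <- Q2 <- matrix(0, n + 1L, 8L)
  p_a <- p_choice <- rep(NA_real_, n)
  disjoint <- session$condition[1] == "disjoint"
  choices <- ifelse(is.na(session$choice), NA_integer_, session$choice)
  for (i in seq_len(n)) {
    V[i, ] <- v; E[i, ] <- e; Q0[i, ] <- Q[1, ]; Q2[i, ] <- Q[2, ]
    x_e <- v
    x_t <- Q[1, ] + Q[2, ]
    if (win != 0) {
      z_e <- normalize_values(x_e, buf_e)
      z_t <- normalize_values(x_t, buf_t)
    } else {
      z_e <- x_e; z_t <- x_t
    }
    opt <- c(session$pair_a[i], session$pair_b[i]) + 1L
    p <- choice_probabilities(z_e[opt], z_t[opt], params$beta_elg,
                              params$beta_tab)
    p_a[i] <- p[1]
    ch <- choices[i]
    if (!is.na(ch)) {
      p_choice[i] <- if (ch == session$pair_a[i]) p[1] else p[2]
      total <- session$total_feedback[i]
      st <- elig_step(v, e, ch + 1L, total, params$alpha_elg,
                      params$lambda_elg)
      v <- st$v; e <- st$e
      a_tm2 <- if (i > 2) choices[i - 2L] else NA_integer_
      pe <- tab_prediction_errors(
        Q, ch + 1L, if (is.na(a_tm2)) NA else a_tm2 + 1L,
        session$imm_feedback[i], session$del_feedback[i], total,
        session$condition[1], skip_absent
      )
      Q <- tab_update(Q, ch + 1L, if (is.na(a_tm2)) NA else a_tm2 + 1L,
                      pe$delta0, pe$delta2, params$alpha_tab,
                      params$lambda_tab)
    } else {
      e <- params$lambda_elg * e
    }
    if (win != 0) {
      buf_e <- rbind(buf_e, x_e)
      buf_t <- rbind(buf_t, x_t)
      if (win > 0) {
        if (nrow(buf_e) > win) buf_e <- buf_e[-1, , drop = FALSE]
        if (nrow(buf_t) > win) buf_t <- buf_t[-1, , drop = FALSE]
      }
    }
  }
  V[n + 1L, ] <- v; E[n + 1L, ] <- e; Q0[n + 1L, ] <- Q[1, ]; Q2[n + 1L, ] <- Q[2, ]
  list(p_a = p_a, p_choice = p_choice, v = V, e = E, q0 = Q0, q2 = Q2)
}
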