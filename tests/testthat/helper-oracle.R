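# Independent brute-force trajectory oracle. Deliberately written from the
# model definitions alone -- full history kept, statistics recomputed from
# scratch each trial with explicit loops -- so it shares no code with the
# package engines it checks.

oracle_run <- function(session, pars, window = 5, skip_absent = FALSE) {
  session <- session[order(session$t), ]
  n <- nrow(session)
  v <- rep(0, 8)
  e <- rep(0, 8)
  q <- matrix(0, 2, 8) # rows: delay 0, delay 2
  hist_v <- list()     # decision-time value snapshots, one per past trial
  hist_q <- list()
  p_choice <- rep(NA_real_, n)
  p_a <- rep(NA_real_, n)
  disjoint <- session$condition[1] == "disjoint"

  zscore <- function(x, history) {
    if (window == 0) return(x)
    if (length(history) == 0) return(x)
    if (is.finite(window)) {
      from <- max(1, length(history) - window + 1)
      history <- history[from:length(history)]
    }
    pool <- c()
    for (h in history) pool <- c(pool, h)
    m <- sum(pool) / length(pool)
    s2 <- 0
    for (p in pool) s2 <- s2 + (p - m)^2
    s <- sqrt(s2 / length(pool))
    if (s == 0) s <- 1
    (x - m) / s
  }

  for (i in seq_len(n)) {
    zs_e <- zscore(v, hist_v)
    zs_t <- zscore(q[1, ] + q[2, ], hist_q)
    a <- session$pair_a[i] + 1
    b <- session$pair_b[i] + 1
    ua <- pars$beta_elg * zs_e[a] + pars$beta_tab * zs_t[a]
    ub <- pars$beta_elg * zs_e[b] + pars$beta_tab * zs_t[b]
    pa <- exp(ua) / (exp(ua) + exp(ub))
    p_a[i] <- pa
    hist_v[[i]] <- v
    hist_q[[i]] <- q[1, ] + q[2, ]
    ch <- session$choice[i]
    if (is.na(ch)) {
      e <- pars$lambda_elg * e
      next
    }
    p_choice[i] <- if (ch == session$pair_a[i]) pa else 1 - pa
    r_tot <- session$total_feedback[i]
    # eligibility
    delta <- r_tot - v[ch + 1]
    for (k in 1:8) e[k] <- pars$lambda_elg * e[k]
    e[ch + 1] <- 1
    for (k in 1:8) v[k] <- v[k] + pars$alpha_elg * delta * e[k]
    # tabular
    a2 <- if (i >= 3) session$choice[i - 2] else NA
    if (disjoint) {
      imm <- session$imm_feedback[i]
      if (!(skip_absent && is.na(imm))) {
        r0 <- if (is.na(imm)) 0 else imm
        q[1, ch + 1] <- q[1, ch + 1] +
          pars$alpha_tab * (r0 - q[1, ch + 1])
      }
      dl <- session$del_feedback[i]
      if (!is.na(a2) && !(skip_absent && is.na(dl))) {
        r2 <- if (is.na(dl)) 0 else dl
        q[2, a2 + 1] <- q[2, a2 + 1] +
          pars$alpha_tab * pars$lambda_tab * (r2 - q[2, a2 + 1])
      }
    } else {
      q[1, ch + 1] <- q[1, ch + 1] + pars$alpha_tab * (r_tot - q[1, ch + 1])
      if (!is.na(a2)) {
        q[2, a2 + 1] <- q[2, a2 + 1] +
          pars$alpha_tab * pars$lambda_tab * (r_tot - q[2, a2 + 1])
      }
    }
  }
  list(p_a = p_a, p_choice = p_choice, v = v, e = e, q = q)
}

oracle_nll <- function(session, pars, window = 5, skip_absent = FALSE) {
  p <- oracle_run(session, pars, window, skip_absent)$p_choice
  -sum(log(p[!is.na(p)]))
}
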