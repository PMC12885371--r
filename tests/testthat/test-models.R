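test_that("eligibility step follows the replacing-trace update rule", {
  st <- elig_step(rep(0, 8), rep(0, 8), chosen = 3, reward = 4, alpha = 0.25,
                  lambda = 0.5)
  expect_equal(st$delta, 4)
  expect_equal(st$v[3], 1)
  expect_equal(st$v[-3], rep(0, 7))
  expect_equal(st$e[3], 1)

  # lambda = 0: only the chosen action's value can move
  v <- runif(8); e <- runif(8)
  st0 <- elig_step(v, e, chosen = 5, reward = 2, alpha = 0.7, lambda = 0)
  expect_equal(st0$v[-5], v[-5])
  expect_equal(st0$e[-5], rep(0, 7))
})

test_that("three-trial eligibility hand sequence matches the cranked table", {
  # rewards 4, -1, 1 on actions A, B, A with alpha = lambda = 0.5
  v <- rep(0, 8); e <- rep(0, 8)
  s1 <- elig_step(v, e, 1, 4, 0.5, 0.5)
  s2 <- elig_step(s1$v, s1$e, 2, -1, 0.5, 0.5)
  s3 <- elig_step(s2$v, s2$e, 1, 1, 0.5, 0.5)
  expect_equal(s3$v[1], 1.375)
  expect_equal(s3$v[2], -0.6875)
  expect_equal(s3$v[3:8], rep(0, 6))
  expect_equal(s3$e[1], 1)
  expect_equal(s3$e[2], 0.5)
})

test_that("tabular prediction errors split by condition", {
  Q <- matrix(0, 2, 8)
  Q[1, 2] <- 1; Q[2, 5] <- 0
  pe <- tab_prediction_errors(Q, a_t = 2, a_tm2 = 5, imm = 3, del = -4,
                              total = -1, "disjoint")
  expect_equal(pe$delta0, 2)
  expect_equal(pe$delta2, -4)

  Q2 <- matrix(0, 2, 8)
  Q2[1, 2] <- 2; Q2[2, 5] <- 1
  pe2 <- tab_prediction_errors(Q2, 2, 5, imm = NA, del = NA, total = 5,
                               "conjoint")
  expect_equal(pe2$delta0, 3)
  expect_equal(pe2$delta2, 4)

  # first trials: no two-back choice, no delayed-slot error
  pe3 <- tab_prediction_errors(Q, 2, NA, imm = 1, del = NA, total = 1,
                               "disjoint")
  expect_null(pe3$delta2)
})

test_that("tabular update touches only the two signal entries", {
  Q <- matrix(0, 2, 8)
  out <- tab_update(Q, a_t = 4, a_tm2 = 6, delta0 = 2, delta2 = -4,
                    alpha = 0.5, lambda = 0.8)
  expect_equal(out[1, 4], 1)      # no lambda at d = 0
  expect_equal(out[2, 6], -1.6)   # alpha * lambda * delta2
  out[1, 4] <- 0; out[2, 6] <- 0
  expect_equal(out, Q)            # everything else untouched
})

test_that("windowed z-normalization pools prior-trial entries", {
  expect_equal(normalize_values(c(3, 1), rbind(c(0, 2))), c(2, 0))
  # degenerate spread: only the mean is removed
  expect_equal(normalize_values(c(4, 7), rbind(c(5, 5), c(5, 5))), c(-1, 2))
  # no history: identity
  expect_equal(normalize_values(c(4, 7), NULL), c(4, 7))
})

test_that("softmax over the offered pair behaves at its landmarks", {
  expect_equal(choice_probabilities(c(9, -3), c(2, 8), 0, 0), c(0.5, 0.5))
  p <- choice_probabilities(c(1, 0), c(0, 0), 1, 0)
  expect_equal(p, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))))
  expect_equal(choice_probabilities(c(1, 1), c(2, 2), 3, 4), c(0.5, 0.5))
  expect_error(choice_probabilities(c(NaN, 1), c(0, 0), 1, 1), "finite")
})

test_that("compiled and reference engines agree on random sessions", {
  for (seed in c(3, 11)) {
    for (cond in c("conjoint", "disjoint")) {
      fx <- sim_session(seed, cond)
      for (win in c(0, 5, Inf)) {
        rc <- run_model(fx$session, fx$params, window = win, engine = "cpp")
        rr <- run_model(fx$session, fx$params, window = win, engine = "r")
        expect_equal(rc$trials$p_choice, rr$trials$p_choice,
                     tolerance = 1e-12)
        expect_equal(rc$v, rr$v, tolerance = 1e-12)
        expect_equal(rc$q0, rr$q0, tolerance = 1e-12)
        expect_equal(rc$q2, rr$q2, tolerance = 1e-12)
      }
    }
  }
})

test_that("run_model matches the brute-force oracle on hand sessions", {
  pars <- ca_params("hybrid", alpha_elg = 0.4, lambda_elg = 0.6,
                    beta_elg = 2, alpha_tab = 0.3, lambda_tab = 0.7,
                    beta_tab = 1.5)
  for (cond in c("conjoint", "disjoint")) {
    s <- hand_session(
      pair_a = c(0, 1, 0, 2, 0), pair_b = c(4, 5, 4, 6, 4),
      choice = c(4, 1, 0, 6, 4),
      imm = c(NA, 2, -1, NA, NA), del = c(NA, NA, 3, NA, -2),
      condition = cond
    )
    for (eng in c("cpp", "r")) {
      run <- run_model(s, pars, window = 5, engine = eng)
      orc <- oracle_run(s, pars, window = 5)
      expect_equal(run$trials$p_choice, orc$p_choice, tolerance = 1e-12)
      expect_equal(run$v[6, ], orc$v, tolerance = 1e-12)
      expect_equal(run$q0[6, ], orc$q[1, ], tolerance = 1e-12)
      expect_equal(run$q2[6, ], orc$q[2, ], tolerance = 1e-12)
    }
  }
})

test_that("trace decays geometrically while an action goes unchosen", {
  fx <- sim_session(4, "conjoint")
  pars <- fx$params
  run <- run_model(fx$session, pars, window = 5)
  ch <- fx$session$choice
  # find an action chosen once then unchosen for >= 5 trials
  for (i in seq_len(nrow(fx$session) - 5)) {
    a <- ch[i]
    if (is.na(a) || any(ch[(i + 1):(i + 5)] == a, na.rm = TRUE)) next
    # decision-time trace at trial i+1+k is lambda^k (set to 1 after trial i)
    for (k in 0:4) {
      expect_equal(run$e[i + 1 + k, a + 1], pars$lambda_elg^k,
                   tolerance = 1e-12)
    }
    break
  }
})

test_that("choice probabilities are invariant to reward rescaling", {
  fx <- sim_session(6, "disjoint")
  run1 <- run_model(fx$session, fx$params, window = 5)
  scaled <- fx$session
  scaled$imm_feedback <- scaled$imm_feedback * 7
  scaled$del_feedback <- scaled$del_feedback * 7
  scaled$total_feedback <- scaled$total_feedback * 7
  run2 <- run_model(scaled, fx$params, window = 5)
  # compare trials where both strategies' normalization buffers (the five
  # prior decision-time snapshots) had non-degenerate spread
  ok <- vapply(20:336, function(i) {
    sd(run1$v[(i - 5):(i - 1), ]) > 1e-6 &&
      sd(run1$q0[(i - 5):(i - 1), ] + run1$q2[(i - 5):(i - 1), ]) > 1e-6
  }, logical(1))
  keep <- (20:336)[ok]
  expect_gt(length(keep), 100)
  expect_equal(run1$trials$p_a[keep], run2$trials$p_a[keep],
               tolerance = 1e-9)
})

test_that("with constant reward and no trace spread, value converges to it", {
  n <- 40
  s <- hand_session(pair_a = rep(0, n), pair_b = rep(1, n),
                    choice = rep(0, n), imm = rep(6, n), del = rep(NA, n),
                    condition = "disjoint")
  pars <- ca_params("eligibility", alpha_elg = 0.3, lambda_elg = 0,
                    beta_elg = 1)
  run <- run_model(s, pars, window = 0)
  vals <- run$v[, 1]
  expect_true(all(diff(vals) >= -1e-12))
  expect_equal(vals[n + 1], 6, tolerance = 1e-3)
})

test_that("omitted responses decay traces but freeze values", {
  s <- hand_session(pair_a = c(0, 0, 0), pair_b = c(1, 1, 1),
                    choice = c(0, NA, 0), imm = c(4, NA, 4),
                    del = rep(NA, 3), condition = "disjoint")
  pars <- ca_params("hybrid", alpha_elg = 0.5, lambda_elg = 0.5,
                    beta_elg = 1, alpha_tab = 0.5, lambda_tab = 0.5,
                    beta_tab = 1)
  run <- run_model(s, pars, window = 0)
  expect_true(is.na(run$trials$p_choice[2]))
  expect_equal(run$v[3, ], run$v[2, ])      # no value update on omission
  expect_equal(run$q0[3, ], run$q0[2, ])
  expect_equal(run$e[3, 1], 0.5 * run$e[2, 1])  # trace still decays
})

test_that("parameter-set constructors enforce variant constraints", {
  p <- ca_params("eligibility", beta_tab = 9)
  expect_equal(p$beta_tab, 0)
  p2 <- ca_params("tabular", beta_elg = 9)
  expect_equal(p2$beta_elg, 0)
  p3 <- ca_params("hybrid_1L", alpha_elg = 0.2, alpha_tab = 0.9)
  expect_equal(p3$alpha_tab, 0.2)
  p4 <- ca_params("hybrid_1D", lambda_elg = 0.3, lambda_tab = 0.9)
  expect_equal(p4$lambda_tab, 0.3)
  expect_error(ca_params("hybrid", alpha_elg = 1.2), "rates")
  expect_error(ca_params("hybrid", beta_elg = -1), "non-negative")
})
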