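test_that("behavioral metrics match a hand-enumerated session", {
  stimset <- tibble::tibble(
    id = 0:7, delay_class = rep(c("immediate", "delayed"), each = 4),
    delay = rep(c(0L, 2L), each = 4),
    start_value = c(4L, 1L, -1L, -4L, 4L, 1L, -1L, -4L)
  )
  walk <- reward_walk(stimset, 4, step_scale = 1e-9, seed = 1)
  # delivered values are the constant start values: 4,1,-1,-4,4,1,-1,-4
  s <- hand_session(pair_a = c(0, 1, 2, 0), pair_b = c(4, 5, 3, 1),
                    choice = c(0, 5, 2, 1), imm = c(4, NA, -1, 1),
                    del = c(NA, NA, 1, NA), condition = "disjoint")
  m <- behavioral_metrics(s, walk)
  # optimal: t0 tie (4 vs 4) counts, t1 1 vs 1 tie counts, t2 -1 > -4,
  # t3 1 < 4 not optimal -> 3/4
  expect_equal(m$optimal_choice, 0.75)
  expect_equal(m$average_outcome, mean(c(4, 1, -1, 1)))
})

test_that("oracle and anti-oracle agents bracket the optimal-choice range", {
  fx <- sim_session(3, "conjoint")
  s <- fx$session
  row <- s$t + 1
  better <- ifelse(fx$walk$delivered[cbind(row, s$pair_a + 1)] >=
                     fx$walk$delivered[cbind(row, s$pair_b + 1)],
                   s$pair_a, s$pair_b)
  worse <- ifelse(better == s$pair_a, s$pair_b, s$pair_a)
  s$choice <- better
  expect_equal(behavioral_metrics(s, fx$walk)$optimal_choice, 1)
  s$choice <- worse
  # ties count as optimal for either option
  ties <- fx$walk$delivered[cbind(row, s$pair_a + 1)] ==
    fx$walk$delivered[cbind(row, s$pair_b + 1)]
  expect_equal(behavioral_metrics(s, fx$walk)$optimal_choice, mean(ties))
})

test_that("stay events capture engineered lag-3 reappearances", {
  stimset <- tibble::tibble(
    id = 0:7, delay_class = rep(c("immediate", "delayed"), each = 4),
    delay = rep(c(0L, 2L), each = 4),
    start_value = c(4L, 1L, -1L, -4L, 4L, 1L, -1L, -4L)
  )
  # one delayed choice (id 4) at t=0 that reappears at t=3 and is re-chosen;
  # positive delayed arrival (+3) at t=2; negative immediate (-1) at t=0
  s <- hand_session(pair_a = c(0, 1, 2, 0), pair_b = c(4, 5, 3, 4),
                    choice = c(4, 1, 2, 4),
                    imm = c(NA, 1, -1, NA), del = c(NA, NA, 3, NA),
                    condition = "disjoint")
  ev <- extract_stay_events(s, stimset)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$stim, 4L)
  expect_equal(ev$stay, 1L)
  expect_equal(ev$reward_0F, "-")  # nothing displayed at the origin trial
  expect_equal(ev$reward_2F, "+")

  # the component reading of disjoint 0F is degenerate by construction
  ev_c <- extract_stay_events(s, stimset, disjoint_0F = "component")
  expect_equal(ev_c$reward_0F, "-")

  # immediate-class-only choices yield no events
  s2 <- s
  s2$choice <- c(0L, 1L, 2L, 0L)
  expect_equal(nrow(extract_stay_events(s2, stimset)), 0)

  # no reappearance at exactly t + 3 -> no event
  s3 <- s
  s3$pair_a[4] <- 1L
  s3$pair_b[4] <- 2L
  s3$choice[4] <- 1L
  expect_equal(nrow(extract_stay_events(s3, stimset)), 0)

  # conjoint valence uses displayed totals by default
  s4 <- s
  s4$condition <- "conjoint"
  ev4 <- extract_stay_events(s4, stimset)
  expect_equal(ev4$reward_0F, "-")  # total at t = 0 is 0
  expect_equal(ev4$reward_2F, "+")  # total at t = 2 is 2
})

test_that("stay regression reproduces the 2x2 cross-product odds ratio", {
  # single binary predictor: stay/switch 30/10 under +, 20/20 under -
  ev <- tibble::tibble(
    participant_id = "p", condition = "disjoint", stage = 1L,
    t = seq_len(80), reappear_t = seq_len(80) + 3L, stim = 4L,
    stay = c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 20)),
    reward_0F = c(rep("+", 40), rep("-", 40)),
    reward_2F = c(rep("+", 40), rep("-", 40))
  )
  fit <- glm(stay ~ reward_0F, family = binomial(), data = ev)
  or <- exp(-coef(fit)[["reward_0F-"]])
  expect_equal(or, 3, tolerance = 1e-8)

  # the same oracle via the package regression on a collapsed design
  long_or <- stay_signature_regression(ev)
  est <- long_or$tidy
  expect_true(all(c("(Intercept)") %in% est$term))
  expect_equal(exp(-est$estimate[est$term == "reward-"]), 3,
               tolerance = 1e-6)
})

test_that("null stay data produce near-unit odds ratios", {
  set.seed(42)
  n <- 20000
  ev <- tibble::tibble(
    participant_id = "p", condition = sample(c("conjoint", "disjoint"), n,
                                             replace = TRUE),
    stage = 1L, t = seq_len(n), reappear_t = seq_len(n) + 3L, stim = 4L,
    stay = stats::rbinom(n, 1, 0.5),
    reward_0F = sample(c("+", "-"), n, replace = TRUE),
    reward_2F = sample(c("+", "-"), n, replace = TRUE)
  )
  sig <- stay_signature_regression(ev)
  ors <- sig$tidy$odds_ratio[sig$tidy$term != "(Intercept)"]
  expect_true(all(abs(log(ors)) < 0.35))
  expect_true(all(sig$cells$p_stay > 0.4 & sig$cells$p_stay < 0.6))
})

test_that("tabular agents in disjoint weight delayed valence most at 2F", {
  st <- generate_study(10, variant = "tabular", beta_min = 3, seed = 77)
  dis <- st$sessions[st$sessions$condition == "disjoint", ]
  ev <- extract_stay_events(dis, st$stimset)
  gap <- function(tm) {
    sub <- if (tm == "0F") {
      tapply(ev$stay, ev$reward_0F, mean)
    } else {
      tapply(ev$stay, ev$reward_2F, mean)
    }
    sub[["+"]] - sub[["-"]]
  }
  expect_gt(gap("2F"), gap("0F"))
  expect_gt(gap("2F"), 0)
})

test_that("pair-type accuracy counts and landmark values are exact", {
  st <- generate_study(2, variant = "eligibility", seed = 13)
  params_list <- purrr::map(seq_len(nrow(st$params)),
                            function(i) as_ca_params(st$params[i, ]))
  gen <- simulate_posterior_iterations(params_list, st$sessions, st$walks,
                                       st$stimset, n_iter = 1, seed = 5)
  # 4 delayed and 4 immediate stimuli: 6 + 6 within-class pair kinds x 12
  # repeats = 72 trials each; 16 mixed kinds x 12 = 192, per session
  acc <- pairtype_accuracy(gen, st$sessions, st$stimset)
  expect_setequal(acc$pair_type, c("Del v Del", "Imm v Imm", "Mixed"))
  n_sessions <- nrow(st$sessions) / 336
  expect_equal(sort(acc$n_trials),
               sort(c(72, 72, 192) * n_sessions))

  self <- pairtype_accuracy(dplyr::mutate(st$sessions, iteration = 1),
                            st$sessions, st$stimset)
  expect_equal(self$accuracy, rep(1, 3))

  flipped <- dplyr::mutate(
    st$sessions, iteration = 1,
    choice = ifelse(choice == pair_a, pair_b, pair_a)
  )
  anti <- pairtype_accuracy(flipped, st$sessions, st$stimset)
  expect_equal(anti$accuracy, rep(0, 3))

  broken <- dplyr::mutate(gen, pair_a = rev(pair_a), pair_b = rev(pair_b))
  expect_error(pairtype_accuracy(broken, st$sessions, st$stimset),
               "schedules")
})

test_that("choice regression recovers a planted generating strategy", {
  st <- generate_study(6, variant = "tabular", beta_min = 3, seed = 99)
  pe <- ca_params("eligibility", alpha_elg = 0.3, lambda_elg = 0.4,
                  beta_elg = 3)
  pt <- ca_params("tabular", alpha_tab = 0.3, lambda_tab = 0.4,
                  beta_tab = 3)
  probs <- model_choice_probs(st$sessions, pe, pt)
  sig <- choice_prediction_regression(probs)
  est <- sig$tidy
  b_tab <- est$estimate[est$term == "p_tab"]
  b_elg <- est$estimate[est$term == "p_elg"]
  expect_gt(b_tab, 0)
  expect_gt(b_tab, b_elg)

  # constant predictors are aliased and reported, not silently dropped
  degenerate <- dplyr::mutate(probs, p_elg = 0.5, p_tab = 0.5)
  expect_warning(choice_prediction_regression(degenerate), "rank-deficient")
})

test_that("credit gradient shows geometric decay and tabular skipping", {
  # fixed positive reward, cyclic distinct choices
  n <- 41
  pa <- rep(c(0, 1, 2, 3), length.out = n)
  pb <- rep(c(4, 5, 6, 7), length.out = n)
  s <- hand_session(pair_a = pa, pair_b = pb, choice = pa,
                    imm = rep(10, n), del = rep(NA, n),
                    condition = "disjoint")
  pe <- ca_params("eligibility", alpha_elg = 0.3, lambda_elg = 0.8,
                  beta_elg = 1)
  ge <- credit_gradient(s, pe, strategy = "eligibility")
  # the geometric ratio holds within each prediction-error valence group
  checked <- 0
  for (vl in unique(ge$valence)) {
    sub <- ge[ge$valence == vl, ]
    sub <- sub[order(sub$lag), ]
    if (nrow(sub) < 4) next
    for (k in 2:4) {
      expect_equal(sub$mean_credit[k] / sub$mean_credit[k - 1], 0.8,
                   tolerance = 1e-10)
    }
    checked <- checked + 1
  }
  expect_gte(checked, 1)

  pt <- ca_params("tabular", alpha_tab = 0.3, lambda_tab = 0.8,
                  beta_tab = 1)
  gt <- credit_gradient(s, pt, strategy = "tabular")
  gt <- gt[order(gt$lag), ]
  expect_true(all(gt$mean_credit[gt$lag %in% c(1, 3)] == 0))
  expect_true(all(abs(gt$mean_credit[gt$lag == 0]) > 0))

  frozen <- ca_params("eligibility", alpha_elg = 0, lambda_elg = 0.8,
                      beta_elg = 1)
  g0 <- credit_gradient(s, frozen, strategy = "eligibility")
  expect_true(all(g0$mean_credit == 0))
})

test_that("paired parameter contrasts match the closed-form t and d", {
  x <- c(0.42, 0.55, 0.31, 0.62, 0.48, 0.39, 0.58, 0.44, 0.51, 0.36)
  y <- c(0.40, 0.60, 0.28, 0.70, 0.50, 0.35, 0.66, 0.48, 0.49, 0.42)
  fc <- tibble::tibble(participant_id = sprintf("p%d", 1:10),
                       term = "beta_tab", estimate = x)
  fd <- tibble::tibble(participant_id = sprintf("p%d", 1:10),
                       term = "beta_tab", estimate = y)
  out <- parameter_condition_tests(fc, fd)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$cohens_d, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(out$df, 9L)

  # identical vectors: a degenerate zero-variance contrast
  same <- parameter_condition_tests(fc, fc)
  expect_true(same$degenerate)

  odd <- fd[1:9, ]
  expect_error(parameter_condition_tests(fc, odd), "unpaired")
})
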