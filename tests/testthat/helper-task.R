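# Shared fixture builders: a small task universe and hand-built sessions.

make_task <- function(seed = 1, n_trials = 336) {
  stimset <- stimulus_set(seed)
  list(
    stimset = stimset,
    walk = reward_walk(stimset, n_trials, seed = seed + 100),
    schedule = trial_schedule(8, 12, seed = seed + 200)
  )
}

# Build a session tibble directly from vectors (feedback supplied by hand).
hand_session <- function(pair_a, pair_b, choice, imm, del, condition,
                         participant_id = "hand", stage = 1L, walk_id = 1L) {
  n <- length(pair_a)
  tibble::tibble(
    participant_id = participant_id, condition = condition,
    stage = as.integer(stage), walk_id = as.integer(walk_id),
    t = seq_len(n) - 1L, pair_a = as.integer(pair_a),
    pair_b = as.integer(pair_b), choice = as.integer(choice),
    imm_feedback = as.numeric(imm), del_feedback = as.numeric(del),
    total_feedback = ifelse(is.na(imm), 0, imm) + ifelse(is.na(del), 0, del)
  )
}

# A quick simulated session for property tests.
sim_session <- function(seed, condition = "disjoint", variant = "hybrid",
                        n_repeats = 12, ...) {
  stimset <- stimulus_set(seed)
  n <- choose(8, 2) * n_repeats
  walk <- reward_walk(stimset, n, seed = seed + 1)
  sched <- trial_schedule(8, n_repeats, seed = seed + 2)
  pars <- as_ca_params(sample_params(1, variant, seed = seed + 3, ...))
  list(
    session = simulate_session(pars, sched, walk, stimset, condition,
                               seed = seed + 4),
    params = pars, stimset = stimset, walk = walk, schedule = sched
  )
}
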