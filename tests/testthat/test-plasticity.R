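test_that("the Hebbian term is the gated rate product", {
  expect_equal(hebbian_term(0, 50, 10), 0)
  expect_equal(hebbian_term(20, 20, 10), 400)
  expect_equal(hebbian_term(3, 3, 10), 0)          # 9 < 10, below threshold
  # the two gating modes differ exactly for asymmetric rate pairs
  expect_equal(hebbian_term(1, 30, 10, mode = "rates"), 0)
  expect_equal(hebbian_term(1, 30, 10, mode = "product"), 30)
  # vectorized
  expect_equal(hebbian_term(c(20, 3), c(20, 3), 10), c(400, 0))
})

test_that("traces decay exponentially when the Hebbian term is silent", {
  Tval <- 0.002
  out <- simulate_trace(rep(0, 1000), tau_a = 800, eta_a = 1, Tmax_a = 0.0033,
                       dt = 1, T0 = Tval)
  # Euler decay factor, compounded
  expect_equal(out[1000], Tval * (1 - 1 / 800)^1000, tolerance = 1e-10)
  expect_lt(abs(out[800] - Tval * exp(-1)), 2e-6)
})

test_that("constant drive relaxes to the analytic fixed point", {
  p <- default_config()$plasticity$rec
  H <- 50   # modest product, keeps the fixed point away from the clamp
  fp <- trace_fixed_point(H, p$tau_p, p$eta_p, p$Tmax_p)
  out <- simulate_trace(rep(H, 20000), p$tau_p, p$eta_p, p$Tmax_p, dt = 1)
  expect_equal(out[20000], fp$value, tolerance = 1e-3 * fp$value)
  # relaxation time constant tau/(1 + eta H): value at t = tau_eff is 1-1/e
  k <- round(fp$tau_eff)
  expect_equal(out[k] / fp$value, 1 - exp(-1), tolerance = 0.01)
  # strong drive saturates at Tmax
  sat <- simulate_trace(rep(5000, 2000), p$tau_p, p$eta_p, p$Tmax_p, dt = 1)
  expect_equal(max(sat), p$Tmax_p, tolerance = 0.005)  # eta H >> 1 limit
  expect_true(all(sat >= 0 & sat <= p$Tmax_p))
})

test_that("coarse trace integration agrees with a dt/100 brute force", {
  p <- default_config()$plasticity$rec
  H <- 100
  coarse <- simulate_trace(rep(H, 2000), p$tau_p, p$eta_p, p$Tmax_p, dt = 1)
  fine <- simulate_trace(rep(H, 200000), p$tau_p, p$eta_p, p$Tmax_p, dt = 0.01)
  expect_lt(abs(coarse[2000] - fine[200000]) / fine[200000], 0.01)
})

test_that("reward accumulation is antisymmetric in the two traces", {
  traces <- list(T_p = rep(0.002, 5), T_d = rep(0.002, 5),
                 pending_dw = numeric(5), refractory_until = -1)
  same <- accumulate_reward_update(traces, reward_active = TRUE, eta = 0.16)
  expect_equal(same$pending_dw, numeric(5))        # T_p = T_d: no change
  traces$T_p <- rep(0.003, 5)
  pot <- accumulate_reward_update(traces, reward_active = TRUE, eta = 0.16)
  expect_true(all(pot$pending_dw > 0))             # LTP excess potentiates
  off <- accumulate_reward_update(traces, reward_active = FALSE, eta = 0.16)
  expect_equal(off$pending_dw, numeric(5))         # outside reward: frozen
  ended <- accumulate_reward_update(traces, reward_active = TRUE, eta = 0.16,
                                    window_end = 750, trace_refractory = 25)
  expect_equal(ended$T_p, rep(0, 5))               # traces consumed
  expect_equal(ended$T_d, rep(0, 5))
  expect_equal(ended$refractory_until, 775)
})

test_that("weight commits clip at zero and clear the accumulator", {
  traces <- list(T_p = 0, T_d = 0, pending_dw = c(0.1, -0.5),
                 refractory_until = -1)
  out <- commit_weights(c(0.2, 0.2), traces)
  expect_equal(out$w, c(0.3, 0))                   # clipped below at 0
  expect_equal(out$traces$pending_dw, c(0, 0))
  nothing <- commit_weights(c(0.2), list(T_p = 0, T_d = 0, pending_dw = 0))
  expect_equal(nothing$w, 0.2)
})

test_that("engine traces match the R reference dynamics on logged synapses", {
  # run a short training with trace logging, then re-integrate the logged
  # pre/post rates through the R-level rule (gating, Euler step, consumption
  # at reward-window ends, trace refractory) and compare
  cfg <- default_config()
  net <- build_network(n_columns = 2, config = cfg, seed = 31)
  seq2 <- fixture_sequence("two_element")
  tr <- run_training(net, seq2, n_trials = 12, seed = 32,
                     record_rates = 12L, log_traces = TRUE)
  rw <- schedule_rewards(seq2, cfg)
  any_active <- FALSE
  for (k in seq_len(nrow(tr$log_edges))) {
    cls <- tr$classes[tr$log_edges[k, 1], ]
    ts <- if (cls$class == "T_T") cfg$plasticity$rec else cfg$plasticity$ff
    m <- tr$trace_logs[[12]][[k]]
    n <- nrow(m)
    Tp_ref <- numeric(n); Td_ref <- numeric(n)
    Tp <- 0; Td <- 0
    ref_until <- -1
    rwi <- 1
    for (b in seq_len(n)) {
      tb <- b  # plast_dt = 1 ms, bins end at integer times
      if (rwi <= nrow(rw) && tb >= rw$t_end[rwi]) {
        Tp <- 0; Td <- 0
        ref_until <- rw$t_end[rwi] + cfg$reward$trace_refractory
        rwi <- rwi + 1
      }
      if (tb >= ref_until) {
        H <- hebbian_term(m[b, 1], m[b, 2], ts$r_th)
        Tp <- update_trace(Tp, H, ts$tau_p, ts$eta_p, ts$Tmax_p, 1)
        Td <- update_trace(Td, H, ts$tau_d, ts$eta_d, ts$Tmax_d, 1)
      }
      Tp_ref[b] <- Tp; Td_ref[b] <- Td
    }
    expect_equal(m[, 3], Tp_ref, tolerance = 1e-10)
    expect_equal(m[, 4], Td_ref, tolerance = 1e-10)
    if (max(Tp_ref) > 0) any_active <- TRUE
  }
  expect_true(any_active)  # at least one logged synapse was actually driven
})

test_that("weights are committed once per trial and never negative", {
  net <- build_network(n_columns = 2, seed = 33)
  seq2 <- fixture_sequence("two_element")
  tr <- run_training(net, seq2, n_trials = 5, seed = 34)
  expect_true(all(unlist(lapply(tr$net$classes, `[[`, "w")) >= 0))
  # per-trial class means move only at trial boundaries: 5 rows, one per trial
  expect_equal(nrow(tr$class_w), 5)
})

test_that("learning-parameter randomization stays inside the spread", {
  cfg <- default_config()
  same <- randomize_learning_params(cfg$plasticity, spread = 0)
  expect_equal(same$rec, cfg$plasticity$rec)
  set.seed(40)
  for (i in 1:20) {
    rnd <- randomize_learning_params(cfg$plasticity, spread = 20)
    for (p in c("tau_p", "tau_d", "eta_p", "eta_d")) {
      expect_true(rnd$rec[[p]] >= 0.8 * cfg$plasticity$rec[[p]] &&
                  rnd$rec[[p]] <= 1.2 * cfg$plasticity$rec[[p]])
    }
  }
  # per-trial mode draws distinct values each trial
  set.seed(41)
  mat <- colseq:::learning_param_matrix(cfg, 50, "per_trial", 20)
  expect_equal(nrow(unique(mat)), 50)
  inst <- colseq:::learning_param_matrix(cfg, 50, "per_instance", 20)
  expect_equal(nrow(unique(inst)), 1)
})
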