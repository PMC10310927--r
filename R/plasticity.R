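# Reward-gated eligibility-trace plasticity: reference semantics.
#
# The fast path lives in the C++ engine; the functions here define the rule
# on plain R objects and are what the engine is tested against.  Trace
# dynamics use the published activation rates verbatim; rates enter the
# trace ODE in spk/ms (the Hebbian product in Hz^2 is converted by 1e-6),
# which makes the printed eta values produce traces that saturate within
# tens of milliseconds of sustained co-activation, as the learning rule
# requires.

HZ2_TO_MS2 <- 1e-6

#' Thresholded Hebbian term
#'
#' Product of pre- and postsynaptic firing rates, gated by the activation
#' threshold `r_th`.  With `mode = "rates"` (default) both rates must exceed
#' `r_th` (spks/sec) for the term to be active; with `mode = "product"` the
#' gate is applied to the product itself.  The rate gate is what makes the
#' threshold protect against noise-driven potentiation: a single spontaneous
#' spike lifts the filtered rate of a neuron to `1000/tau_r` = 25 spks/sec,
#' so a 20 spks/sec threshold is crossed by single noise spikes while a
#' 30 spks/sec threshold is not.
#'
#' @param r_i,r_j pre- and postsynaptic rates (spks/sec); vectorized.
#' @param r_th activation threshold (spks/sec).
#' @param mode `"rates"` or `"product"`.
#' @return the Hebbian term `H` (Hz^2), zero where gated.
#' @examples
#' hebbian_term(20, 20, 10)  # 400
#' hebbian_term(3, 3, 10)    # 0
#' @export
hebbian_term <- function(r_i, r_j, r_th, mode = c("rates", "product")) {
  mode <- match.arg(mode)
  stopifnot(all(r_i >= 0), all(r_j >= 0))
  H <- r_i * r_j
  gate <- if (mode == "rates") (r_i > r_th) & (r_j > r_th) else H > r_th
  H * gate
}

#' One Euler step of the eligibility-trace dynamics
#'
#' Integrates `tau_a dT/dt = -T + eta_a H (Tmax_a - T)` for one step of
#' length `dt` and clamps the result to `[0, Tmax_a]`.  `H` is the Hebbian
#' term in Hz^2 as returned by [hebbian_term()]; `eta_a` is the activation
#' rate exactly as published.
#'
#' @param T_a current trace value (vectorized).
#' @param H Hebbian term (Hz^2).
#' @param tau_a trace time constant (ms).
#' @param eta_a activation rate.
#' @param Tmax_a saturation level.
#' @param dt step (ms).
#' @return updated trace value(s).
#' @export
update_trace <- function(T_a, H, tau_a, eta_a, Tmax_a, dt = 1) {
  h <- eta_a * H * HZ2_TO_MS2
  T_new <- T_a + (dt / tau_a) * (-T_a + h * (Tmax_a - T_a))
  pmin(pmax(T_new, 0), Tmax_a)
}

#' Integrate a trace over a Hebbian time series
#'
#' Convenience loop over [update_trace()]; `H` is sampled on a regular grid
#' of resolution `dt`.
#'
#' @param H numeric vector of Hebbian terms (Hz^2), one per step.
#' @inheritParams update_trace
#' @param T0 initial value.
#' @return numeric vector of trace values after each step.
#' @export
simulate_trace <- function(H, tau_a, eta_a, Tmax_a, dt = 1, T0 = 0) {
  out <- numeric(length(H))
  T_a <- T0
  for (k in seq_along(H)) {
    T_a <- update_trace(T_a, H[k], tau_a, eta_a, Tmax_a, dt)
    out[k] <- T_a
  }
  out
}

#' Closed-form fixed point of the trace dynamics under constant H
#'
#' For constant Hebbian drive the trace relaxes to
#' `eta H' Tmax / (1 + eta H')` with time constant `tau / (1 + eta H')`
#' (where `H'` is `H` in the internal spk/ms units).
#'
#' @inheritParams update_trace
#' @return list with `value` and `tau_eff`.
#' @export
trace_fixed_point <- function(H, tau_a, eta_a, Tmax_a) {
  h <- eta_a * H * HZ2_TO_MS2
  list(value = h * Tmax_a / (1 + h), tau_eff = tau_a / (1 + h))
}

#' Reward-gated accumulation of weight changes
#'
#' While the global reward signal is active, the prospective weight change
#' of every plastic synapse grows by `eta (T_p - T_d) dt`; outside reward
#' nothing accumulates.  At the end of a reward window the traces are
#' consumed (reset to zero) and trace activation enters a refractory period.
#'
#' @param traces list with numeric fields `T_p`, `T_d`, `pending_dw` and
#'   scalar `refractory_until`.
#' @param reward_active is the reward gate open during this step?
#' @param eta learning rate.
#' @param dt step (ms).
#' @param window_end if non-`NULL`, the reward window ends at this time:
#'   traces are consumed and the refractory clock set to
#'   `window_end + trace_refractory`.
#' @param trace_refractory refractory duration (ms).
#' @return the updated trace list.
#' @export
accumulate_reward_update <- function(traces, reward_active, eta, dt = 1,
                                     window_end = NULL, trace_refractory = 25) {
  if (reward_active)
    traces$pending_dw <- traces$pending_dw + eta * (traces$T_p - traces$T_d) * dt
  if (!is.null(window_end)) {
    traces$T_p[] <- 0
    traces$T_d[] <- 0
    traces$refractory_until <- window_end + trace_refractory
  }
  traces
}

#' Commit accumulated weight changes at a trial boundary
#'
#' Adds the pending per-synapse changes to the weights, clips the result
#' below at zero and zeroes the accumulator.  Called once per trial: weights
#' are frozen within a trial and only move at its end.
#'
#' @param w numeric weight vector (nS).
#' @param traces trace list as in [accumulate_reward_update()].
#' @return list with `w` and the cleared `traces`.
#' @export
commit_weights <- function(w, traces) {
  w <- pmax(w + traces$pending_dw, 0)
  traces$pending_dw[] <- 0
  list(w = w, traces = traces)
}
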