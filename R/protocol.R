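# Stimulus construction, reward scheduling and trial orchestration.

#' Define a stimulus sequence
#'
#' An ordered list of (column, duration) elements.  Element onsets within a
#' trial are contiguous: element i+1 starts when element i ends.
#'
#' @param columns integer vector of column indices, one per element; each
#'   element must map to a distinct column (unique stimulus-column mapping).
#' @param durations element durations in ms; must exceed the 50 ms stimulus
#'   pulse.
#' @param pulse_len stimulus pulse length (ms).
#' @return object of class `stim_sequence` with `elements` (data.frame
#'   `column`, `duration`, `onset`) and `total` duration.
#' @examples
#' make_sequence(1:4, c(500, 1000, 700, 1800))
#' @export
make_sequence <- function(columns, durations, pulse_len = 50) {
  stopifnot(length(columns) == length(durations), length(columns) >= 1)
  if (anyDuplicated(columns))
    stop("each element must map to a distinct column")
  if (any(durations <= pulse_len))
    stop("element durations must exceed the stimulus pulse (", pulse_len, " ms)")
  elements <- data.frame(column = as.integer(columns), duration = durations,
                         onset = cumsum(c(0, durations[-length(durations)])))
  structure(list(elements = elements, total = sum(durations),
                 pulse_len = pulse_len),
            class = "stim_sequence")
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat("<stim_sequence>", nrow(x$elements), "elements,",
      x$total, "ms total\n")
  print(x$elements, row.names = FALSE)
  invisible(x)
}

#' Canonical task sequences
#'
#' @param kind one of `"four_interval"` (four intervals 500/1000/700/1800 ms),
#'   `"robustness"` (four 700 ms elements), `"scaling"` (three 700 ms),
#'   `"two_element"` (two 700 ms), `"half_second"` (two 500 ms).
#' @return a `stim_sequence`.
#' @export
fixture_sequence <- function(kind = c("four_interval", "robustness", "scaling",
                                      "two_element", "half_second")) {
  kind <- match.arg(kind)
  durs <- switch(kind,
    four_interval = c(500, 1000, 700, 1800),
    robustness = rep(700, 4),
    scaling = rep(700, 3),
    two_element = rep(700, 2),
    half_second = rep(500, 2))
  make_sequence(seq_along(durs), durs)
}

#' Poisson stimulus events for one element
#'
#' Generates independent 50 ms Poisson trains at `nu_in` spks/sec, one per
#' afferent.  In the baseline and all-to-all variants the input targets both
#' the Timer and the I_T population of the element's column; in the
#' local-inhibition variant only the Timer cells receive input.  Uses R's
#' RNG.
#'
#' @param net a `col_network`.
#' @param column stimulated column.
#' @param onset pulse onset within the trial (ms).
#' @param trial trial index tag for the event matrix.
#' @param w_in input weight override (nS); defaults to the configured value.
#' @return event matrix with columns `trial`, `neuron`, `time`, `weight`,
#'   `channel`.
#' @export
make_stimulus <- function(net, column, onset = 0, trial = 1, w_in = NULL) {
  cfg <- net$config
  w_in <- w_in %||% cfg$weights$w_in
  targets <- neuron_ids(net, "T", column)
  if (net$variant != "local_inhibition")
    targets <- c(targets, neuron_ids(net, "IT", column))
  pulse <- cfg$protocol$pulse_len
  nu <- cfg$protocol$nu_in
  n_spk <- stats::rpois(length(targets), nu * pulse / 1000)
  tot <- sum(n_spk)
  if (tot == 0) return(empty_events())
  cbind(trial = trial, neuron = rep(targets, n_spk),
        time = onset + runif(tot) * pulse, weight = w_in, channel = 2)
}

#' Reward schedule for a sequence
#'
#' One 25 ms reward window per element boundary, delayed by `d_reward`
#' (25 ms): interior element offsets coincide with the next onsets, and a
#' final window follows the last element's offset.  The window at t = 0 (the
#' first element's onset) is included by default; it is inert because all
#' traces start at zero.
#'
#' @param seq a `stim_sequence`.
#' @param config a [default_config()] list (for the reward timing block).
#' @return data.frame with `t_start`, `t_end` (ms, trial-relative).
#' @examples
#' schedule_rewards(make_sequence(1, 700))  # windows at [25, 50) and [725, 750)
#' @export
schedule_rewards <- function(seq, config = default_config()) {
  stopifnot(inherits(seq, "stim_sequence"))
  rw <- config$reward
  boundaries <- cumsum(seq$elements$duration)
  if (isTRUE(rw$at_t0)) boundaries <- c(0, boundaries)
  out <- data.frame(t_start = boundaries + rw$d_reward,
                    t_end = boundaries + rw$d_reward + rw$duration)
  if (nrow(out) > 1 && any(out$t_start[-1] < out$t_end[-nrow(out)]))
    stop("reward windows overlap: element shorter than the reward cycle")
  out
}

# events for all trials of a phase (training: all elements; recall: cue only)
phase_events <- function(net, seq, n_trials, cue_only = FALSE, w_in = NULL) {
  ev <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    els <- if (cue_only) seq$elements[1, , drop = FALSE] else seq$elements
    ev[[tr]] <- do.call(rbind, lapply(seq_len(nrow(els)), function(i)
      make_stimulus(net, els$column[i], els$onset[i], trial = tr, w_in = w_in)))
  }
  out <- do.call(rbind, ev)
  if (is.null(out)) empty_events() else out
}

#' Randomize learning parameters
#'
#' Draws each trace time constant and activation rate independently and
#' uniformly within `spread` percent of its baseline value, as in the
#' robustness analysis of the learning rule.
#'
#' @param plasticity the `plasticity` block of a configuration.
#' @param spread half-width of the uniform interval, in percent.
#' @return the perturbed plasticity block.
#' @export
randomize_learning_params <- function(plasticity, spread = 20) {
  stopifnot(spread >= 0)
  f <- function() runif(1, 1 - spread / 100, 1 + spread / 100)
  for (set in c("rec", "ff"))
    for (p in c("tau_p", "tau_d", "eta_p", "eta_d"))
      plasticity[[set]][[p]] <- plasticity[[set]][[p]] * f()
  plasticity
}

# n_trials x 8 matrix of absolute learning parameters for the engine
learning_param_matrix <- function(cfg, n_trials,
                                  mode = c("none", "per_trial", "per_instance"),
                                  spread = 20) {
  mode <- match.arg(mode)
  if (mode == "none") return(NULL)
  one_row <- function(pl) c(pl$rec$tau_p, pl$rec$tau_d, pl$rec$eta_p,
                            pl$rec$eta_d, pl$ff$tau_p, pl$ff$tau_d,
                            pl$ff$eta_p, pl$ff$eta_d)
  if (mode == "per_instance") {
    r <- one_row(randomize_learning_params(cfg$plasticity, spread))
    return(matrix(rep(r, each = n_trials), nrow = n_trials))
  }
  t(vapply(seq_len(n_trials), function(i)
    one_row(randomize_learning_params(cfg$plasticity, spread)),
    numeric(8)))
}

class_meta <- function(net) {
  data.frame(
    name = vapply(net$classes, `[[`, "", "name"),
    class = vapply(net$classes, `[[`, "", "class"),
    src_col = vapply(net$classes, `[[`, 0, "src_col"),
    tgt_col = vapply(net$classes, `[[`, 0, "tgt_col"),
    plastic = vapply(net$classes, `[[`, FALSE, "plastic"),
    n_edges = vapply(net$classes, function(cl) length(cl$pre), 0),
    row.names = NULL)
}

#' Train a network on a sequence
#'
#' Runs `n_trials` training trials.  Each trial resets the neuronal state and
#' the eligibility traces, stimulates the columns at their element onsets
#' with 50 ms Poisson pulses, evolves dynamics with plasticity and the
#' global reward schedule, and commits the accumulated weight changes at the
#' trial end.
#'
#' @param net a `col_network`.
#' @param seq a `stim_sequence` (consistent with the network's variant and
#'   column count).
#' @param n_trials number of training trials (100 in the standard protocol).
#' @param seed integer seed controlling input Poisson draws and simulation
#'   noise.
#' @param randomize learning-parameter randomization mode: `"none"`,
#'   `"per_trial"` (fresh draw each trial) or `"per_instance"` (one draw).
#' @param spread randomization half-width in percent.
#' @param record_spikes,record_rates integer vectors of trial indices to
#'   record in full.
#' @param log_traces log rates and both traces for one designated synapse
#'   per plastic class on the trials in `record_rates`.
#' @return object of class `training_result` with the trained network
#'   (`$net`), per-trial per-class mean weights (`$class_w`), committed
#'   per-trial mean weight change (`$trial_dw`), class metadata, and any
#'   recordings.
#' @export
run_training <- function(net, seq, n_trials = 100, seed = 1,
                         randomize = "none", spread = 20,
                         record_spikes = integer(0),
                         record_rates = integer(0), log_traces = FALSE) {
  stopifnot(inherits(net, "col_network"), inherits(seq, "stim_sequence"))
  if (max(seq$elements$column) > net$n_columns)
    stop("sequence references column beyond the network")
  cfg <- net$config
  set.seed(seed)
  rewards <- schedule_rewards(seq, cfg)
  trial_ms <- seq$total + cfg$reward$d_reward + cfg$reward$duration
  if (n_trials == 0)
    return(structure(list(net = net, classes = class_meta(net),
                          class_w = NULL, trial_dw = NULL, n_trials = 0,
                          seq = seq, seed = seed),
                     class = "training_result"))
  events <- phase_events(net, seq, n_trials)
  lp <- learning_param_matrix(cfg, n_trials, randomize, spread)
  log_edges <- NULL
  if (log_traces) {
    pl_idx <- which(vapply(net$classes, `[[`, FALSE, "plastic"))
    log_edges <- cbind(pl_idx, 1L)
  }
  enet <- as_engine_net(net)
  opts <- engine_opts(net, n_trials, record_spikes = record_spikes,
                      record_rates = record_rates,
                      log_trials = if (log_traces) record_rates else integer(0),
                      log_edges = log_edges, learning_params = lp)
  res <- cpp_run_phase(enet, events, as.matrix(rewards), as.integer(n_trials),
                       trial_ms, TRUE, as.double(seed), opts)
  meta <- class_meta(net)
  colnames(res$class_w_mean) <- meta$name
  colnames(res$trial_dw) <- meta$name
  # write learned weights back into the network
  for (i in seq_along(net$classes))
    net$classes[[i]]$w <- res$final_weights[[i]]
  structure(list(
    net = net, classes = meta, class_w = res$class_w_mean,
    trial_dw = res$trial_dw, pop_spike_count = res$pop_spike_count,
    spikes = res$spikes, rates = res$rates, rate_times = res$rate_times,
    trace_logs = res$trace_logs, log_edges = log_edges,
    n_trials = n_trials, seq = seq, seed = seed),
    class = "training_result")
}

#' @export
print.training_result <- function(x, ...) {
  cat("<training_result>", x$n_trials, "trials on",
      nrow(x$seq$elements), "elements\n")
  if (!is.null(x$class_w)) {
    pl <- x$classes$plastic
    w <- x$class_w[x$n_trials, pl]
    cat("  final plastic means (nS):\n")
    print(round(w, 4))
  }
  invisible(x)
}

#' Cued recall of a trained sequence
#'
#' Replays the sequence from a single 50 ms cue to the first element's
#' column, with plasticity and reward disabled.  Each trial starts from the
#' reset state.
#'
#' @param net a trained `col_network` (e.g. `run_training(...)$net`).
#' @param seq the training `stim_sequence` (defines the cue column and the
#'   expected onset grid for analysis).
#' @param n_trials number of recall trials (50 in the standard protocol).
#' @param seed integer seed.
#' @param margin extra simulated time after the nominal sequence end (ms).
#' @param record_spikes trial indices for full spike records (defaults to
#'   all trials).
#' @return object of class `recall_result` with per-trial population rate
#'   matrices (`$rates`, time bin x population), spike records (`$spikes`),
#'   `rate_times`, the populations table and the expected onset grid.
#' @export
run_recall <- function(net, seq, n_trials = 50, seed = 1, margin = NULL,
                       record_spikes = seq_len(n_trials)) {
  stopifnot(inherits(net, "col_network"), inherits(seq, "stim_sequence"))
  cfg <- net$config
  margin <- margin %||% cfg$protocol$recall_margin
  set.seed(seed)
  trial_ms <- seq$total + margin
  events <- phase_events(net, seq, n_trials, cue_only = TRUE)
  enet <- as_engine_net(net)
  opts <- engine_opts(net, n_trials, record_spikes = record_spikes,
                      record_rates = seq_len(n_trials))
  res <- cpp_run_phase(enet, events, matrix(numeric(0), ncol = 2),
                       as.integer(n_trials), trial_ms, FALSE,
                       as.double(seed), opts)
  structure(list(
    rates = res$rates, rate_times = res$rate_times, spikes = res$spikes,
    pop_spike_count = res$pop_spike_count, populations = net$populations,
    seq = seq, expected_onsets = seq$elements$onset, n_trials = n_trials,
    trial_ms = trial_ms, seed = seed),
    class = "recall_result")
}

#' @export
print.recall_result <- function(x, ...) {
  cat("<recall_result>", x$n_trials, "trials,", x$trial_ms, "ms each\n")
  invisible(x)
}
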