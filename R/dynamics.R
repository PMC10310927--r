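# Bridge between the R-level network description and the C++ engine.

ROLE_ORDER <- c("T", "M", "IT", "IM")

as_engine_net <- function(net) {
  cfg <- net$config
  pops <- net$populations
  kind <- ifelse(pops$role %in% c("T", "M"), "exc", "inh")
  keys <- c("C_m", "g_L", "V_rest", "V_th", "V_reset", "t_ref", "E_exc", "E_inh")
  neuron <- lapply(keys, function(k)
    vapply(kind, function(r) cfg$neuron[[r]][[k]], 0, USE.NAMES = FALSE))
  names(neuron) <- keys
  neuron$sigma_pA <- rep(cfg$noise$scale * cfg$noise$sigma_xi, nrow(pops))
  gs <- cfg$synapse$g_sat
  list(
    n_neurons = sum(pops$size),
    pop_offset = as.integer(pops$offset),
    pop_size = as.integer(pops$size),
    neuron = neuron,
    classes = unname(lapply(net$classes, function(cl)
      list(pre = cl$pre, post = cl$post, w = cl$w,
           channel = as.integer(cl$channel),
           trace_set = as.integer(cl$trace_set), eta_lr = cl$eta_lr))),
    syn = list(tau = c(cfg$synapse$tau_exc, cfg$synapse$tau_inh,
                       cfg$synapse$tau_input),
               g_sat = unname(gs[c("exc", "inh", "input")]),
               dt = cfg$dt, delay = cfg$delay),
    plast = list(
      tau_r = cfg$plasticity$tau_r,
      tau_r_hebb = cfg$plasticity$tau_r_hebb %||% cfg$plasticity$tau_r,
      plast_dt = cfg$plasticity$plast_dt,
      hebbian_mode = if (identical(cfg$plasticity$hebbian_mode, "product")) 1L else 0L,
      trace_refractory = cfg$reward$trace_refractory,
      rec = cfg$plasticity$rec, ff = cfg$plasticity$ff)
  )
}

empty_events <- function() {
  matrix(numeric(0), ncol = 5,
         dimnames = list(NULL, c("trial", "neuron", "time", "weight", "channel")))
}

engine_opts <- function(net, n_trials, record_spikes = integer(0),
                        record_rates = integer(0), log_trials = integer(0),
                        log_edges = NULL, learning_params = NULL,
                        I_const = NULL, noise_dt = NULL, runaway_limit = NULL,
                        probe_neuron = NULL) {
  cfg <- net$config
  list(record_spikes = as.integer(record_spikes),
       record_rates = as.integer(record_rates),
       log_trials = as.integer(log_trials),
       log_edges = log_edges,
       learning_params = learning_params,
       I_const = I_const,
       noise_dt = noise_dt %||% cfg$noise$noise_dt,
       runaway_limit = runaway_limit %||% cfg$protocol$runaway_limit,
       probe_neuron = probe_neuron)
}

#' Advance a network for a fixed window
#'
#' Runs the clock-driven integration (forward Euler, spike registration one
#' step after threshold crossing, conductance decay and saturating
#' increments) for `duration` ms from the reset state, without plasticity.
#' Used for spontaneous-activity measurements and single-window probes; the
#' training/recall protocol is in [run_training()] and [run_recall()].
#'
#' @param net a `col_network`.
#' @param duration window length in ms (must be a multiple of `dt`).
#' @param input optional event data.frame/matrix with columns `neuron`
#'   (1-based id), `time` (ms), `weight` (nS) and `channel` (0 = recurrent
#'   excitatory, 1 = inhibitory, 2 = input); arrival times are used as given.
#' @param I_const constant injected current, a scalar or one value per
#'   neuron (pA).
#' @param sigma_xi optional override of the noise amplitude (0 disables
#'   noise).
#' @param seed integer seed for the simulation noise stream.
#' @param record_spikes,record_rates logical.
#' @param probe_neuron optional neuron id whose membrane potential and
#'   conductances are recorded at every integration step (returned as
#'   `probe`, columns V, g_exc, g_inh, g_input).
#' @param dt optional integration-step override (ms).
#' @return list with `spikes` (data.frame `neuron`, `time`), `rates`
#'   (matrix time-bin x population, exponential-filter estimate), `rate_times`,
#'   `pop_spike_count`, and `populations`.
#' @examples
#' net <- build_network(n_columns = 2, seed = 1)
#' quiet <- run_window(net, 200, sigma_xi = 0, seed = 1)
#' nrow(quiet$spikes)  # no noise, no input: silent
#' @export
run_window <- function(net, duration, input = NULL, I_const = NULL,
                       sigma_xi = NULL, seed = 1, record_spikes = TRUE,
                       record_rates = TRUE, probe_neuron = NULL,
                       dt = NULL) {
  if (!is.null(dt)) net$config$dt <- dt
  stopifnot(inherits(net, "col_network"), duration >= 0)
  if (duration == 0)
    return(list(spikes = data.frame(neuron = integer(0), time = numeric(0)),
                rates = NULL, rate_times = numeric(0),
                pop_spike_count = NULL, populations = net$populations))
  if (!is.null(sigma_xi)) net$config$noise$sigma_xi <- sigma_xi
  enet <- as_engine_net(net)
  ev <- if (is.null(input)) empty_events() else {
    input <- as.data.frame(input)
    cbind(trial = 1, neuron = input$neuron, time = input$time,
          weight = input$weight, channel = input$channel)
  }
  opts <- engine_opts(net, 1L,
                      record_spikes = if (record_spikes) 1L else integer(0),
                      record_rates = if (record_rates) 1L else integer(0),
                      I_const = I_const, probe_neuron = probe_neuron)
  res <- cpp_run_phase(enet, ev, matrix(numeric(0), ncol = 2), 1L, duration,
                       FALSE, as.double(seed), opts)
  sp <- res$spikes[[1]]
  spikes <- if (is.null(sp)) data.frame(neuron = integer(0), time = numeric(0))
            else data.frame(neuron = as.integer(sp[, 1]), time = sp[, 2])
  list(spikes = spikes, rates = res$rates[[1]], rate_times = res$rate_times,
       pop_spike_count = drop(res$pop_spike_count),
       probe = res$probe, dt = net$config$dt,
       populations = net$populations)
}

#' Exponential-filter firing-rate estimate
#'
#' Causal exponential filter with unit-integral kernel
#' `(1/tau_r) exp(-t/tau_r)`, evaluated on a regular grid: a nu-regular
#' spike train converges to nu.  Each spike adds `1000/tau_r` spks/sec.
#'
#' @param spike_times numeric vector of spike times (ms).
#' @param tau_r filter time constant (ms).
#' @param dt grid resolution (ms).
#' @param duration end of the grid (ms); defaults to the last spike.
#' @return data.frame with `time` (bin ends) and `rate` (spks/sec).
#' @export
estimate_rate <- function(spike_times, tau_r = 40, dt = 1, duration = NULL) {
  stopifnot(tau_r > 0, dt > 0)
  duration <- duration %||% if (length(spike_times)) max(spike_times) else 0
  n <- ceiling(duration / dt)
  if (n == 0) return(data.frame(time = numeric(0), rate = numeric(0)))
  counts <- tabulate(pmin(pmax(ceiling(spike_times / dt), 1L), n), nbins = n)
  dec <- exp(-dt / tau_r)
  jump <- 1000 / tau_r
  r <- numeric(n)
  acc <- 0
  for (k in seq_len(n)) {
    acc <- acc * dec + counts[k] * jump
    r[k] <- acc
  }
  data.frame(time = seq_len(n) * dt, rate = r)
}

#' Mean filtered rate of one population
#'
#' @param result a list with `rates` and `rate_times` as returned by
#'   [run_window()], or one element of a recall result.
#' @param net the network the result came from.
#' @param role,column population selector.
#' @return data.frame `time`, `rate`.
#' @export
population_rate <- function(result, net, role, column) {
  p <- pop_index(net, role, column)
  data.frame(time = result$rate_times, rate = result$rates[, p])
}

#' Write a spike record as gdf-style text
#'
#' Two whitespace-separated columns (neuron id, spike time in ms), one file
#' per population when `split = TRUE`.
#'
#' @param spikes data.frame with `neuron` and `time`.
#' @param path output file (or directory stem when splitting).
#' @param net optional network, required for `split = TRUE`.
#' @param split write one file per population (`<path>_<pop>.gdf`).
#' @return the path(s), invisibly.
#' @export
write_spikes <- function(spikes, path, net = NULL, split = FALSE) {
  if (!split) {
    write.table(spikes[, c("neuron", "time")], path, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  stopifnot(!is.null(net))
  paths <- character(0)
  for (i in seq_len(nrow(net$populations))) {
    p <- net$populations[i, ]
    ids <- seq.int(p$offset + 1L, p$offset + p$size)
    f <- paste0(path, "_", p$name, ".gdf")
    write.table(spikes[spikes$neuron %in% ids, c("neuron", "time")], f,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
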