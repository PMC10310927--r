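# Measurement procedures: recall times, outlier statistics, spike-train
# statistics, weight trajectories.

#' Recall time of a rate trace
#'
#' The recall time of a Timer population is the time at which its filtered
#' rate drops below `threshold` (10 spks/sec), after the population has been
#' active: the rate must first stay above threshold for at least
#' `onset_guard` ms, which skips spurious pre-activation crossings.
#'
#' @param rate numeric rate trace (spks/sec).
#' @param time matching time grid (ms).
#' @param threshold rate threshold (spks/sec).
#' @param onset_guard minimum supra-threshold run to count as activation (ms).
#' @return list with `offset` (the recall time, ms; `NA` if the population
#'   never activates or never falls back below threshold) and `onset` (first
#'   time of sustained activation).
#' @export
recall_time <- function(rate, time, threshold = 10, onset_guard = 20) {
  stopifnot(length(rate) == length(time), length(rate) > 1)
  dt <- time[2] - time[1]
  need <- max(1L, ceiling(onset_guard / dt))
  above <- rate > threshold
  run <- 0L
  onset_idx <- NA_integer_
  for (k in seq_along(above)) {
    run <- if (above[k]) run + 1L else 0L
    if (run >= need) { onset_idx <- k - need + 1L; break }
  }
  if (is.na(onset_idx)) {
    warning("population never activates above threshold")
    return(list(offset = NA_real_, onset = NA_real_))
  }
  below <- which(!above & seq_along(above) > onset_idx + need - 1L)
  off <- if (length(below)) time[below[1]] else NA_real_
  if (is.na(off)) warning("rate never falls back below threshold")
  list(offset = off, onset = time[onset_idx])
}

#' Recall times of all columns over recall trials
#'
#' Applies [recall_time()] to the Timer rate of every column in every recall
#' trial.  The *absolute* recall time is measured from the cue (t = 0); the
#' *relative* recall time subtracts the column's expected onset on the
#' training grid, so it estimates the reported duration of that element.
#'
#' @param recall a `recall_result`.
#' @param threshold,onset_guard see [recall_time()].
#' @return data.frame with one row per trial x column: `trial`, `column`,
#'   `expected_onset`, `onset`, `absolute`, `relative`.
#' @export
recall_times <- function(recall, threshold = 10, onset_guard = 20) {
  stopifnot(inherits(recall, "recall_result"))
  els <- recall$seq$elements
  out <- vector("list", recall$n_trials * nrow(els))
  k <- 0
  for (tr in seq_len(recall$n_trials)) {
    rates <- recall$rates[[tr]]
    for (e in seq_len(nrow(els))) {
      p <- which(recall$populations$role == "T" &
                 recall$populations$column == els$column[e])
      rt <- suppressWarnings(
        recall_time(rates[, p], recall$rate_times, threshold, onset_guard))
      k <- k + 1
      out[[k]] <- data.frame(
        trial = tr, column = els$column[e], expected_onset = els$onset[e],
        onset = rt$onset, absolute = rt$offset,
        relative = rt$offset - els$onset[e])
    }
  }
  do.call(rbind, out)
}

#' Count large deviations from the expected recall grid
#'
#' @param times measured (relative) recall times (ms).
#' @param expected expected values, recycled to the length of `times`.
#' @param tol tolerance (ms); 140 ms is 20 percent of a 700 ms interval.
#' @return number of `|times - expected| > tol` (NA times count as outliers:
#'   a failed recall is an outlier trial).
#' @export
count_deviation_outliers <- function(times, expected, tol = 140) {
  dev <- abs(times - expected)
  sum(dev > tol | is.na(dev))
}

#' Modified z-score (median absolute deviation form)
#'
#' `z_i = 0.6745 (x_i - median(x)) / MAD` with the unscaled MAD
#' (`median(|x - median(x)|)`); values with `|z| > threshold` are flagged.
#' When the MAD is zero all scores are defined as zero.
#'
#' @param x numeric values (at least 2).
#' @param threshold outlier threshold on `|z|`.
#' @return list with `z` and logical `outlier`.
#' @examples
#' modified_zscore(c(1, 2, 3, 4, 100))$outlier
#' @export
modified_zscore <- function(x, threshold = 3) {
  stopifnot(length(x) >= 2)
  med <- median(x, na.rm = TRUE)
  mad0 <- median(abs(x - med), na.rm = TRUE)
  z <- if (is.na(mad0) || mad0 == 0) rep(0, length(x))
       else 0.6745 * (x - med) / mad0
  z[is.na(x)] <- Inf  # failed recalls flag as outliers
  list(z = z, outlier = abs(z) > threshold)
}

#' Coefficient of variation of inter-spike intervals
#'
#' ISIs are computed per neuron, pooled across the neurons of the
#' population, and summarized as `sd/mean`.  Restrict `window` to the
#' population's active epoch to measure in-recall statistics.
#'
#' @param spikes data.frame/matrix with `neuron` and `time` columns.
#' @param neurons neuron ids forming the population.
#' @param window optional `c(t0, t1)` (ms).
#' @param min_isi minimum number of pooled intervals required.
#' @return the CV (dimensionless), or `NA` if fewer than `min_isi` intervals.
#' @export
isi_cv <- function(spikes, neurons = NULL, window = NULL, min_isi = 2) {
  spikes <- as.data.frame(spikes)
  if (!is.null(neurons)) spikes <- spikes[spikes$neuron %in% neurons, ]
  if (!is.null(window))
    spikes <- spikes[spikes$time >= window[1] & spikes$time <= window[2], ]
  if (nrow(spikes) < 2) return(NA_real_)
  isis <- unlist(lapply(split(spikes$time, spikes$neuron),
                        function(t) if (length(t) > 1) diff(sort(t))), use.names = FALSE)
  if (length(isis) < min_isi) return(NA_real_)
  sd(isis) / mean(isis)
}

#' Pooled in-recall ISI CV for one role
#'
#' Pools per-neuron ISIs of all columns' populations of the given role
#' across recall trials, restricting each column to its active epoch
#' (activation onset to recall time) in each trial.
#'
#' @param recall a `recall_result`.
#' @param role `"T"` or `"M"`.
#' @param threshold rate threshold defining the active epoch of the
#'   column's Timer population.
#' @return the pooled CV.
#' @export
recall_isi_cv <- function(recall, role = "T", threshold = 10) {
  stopifnot(inherits(recall, "recall_result"))
  els <- recall$seq$elements
  pops <- recall$populations
  all_isis <- list()
  for (tr in seq_len(recall$n_trials)) {
    sp <- recall$spikes[[tr]]
    if (is.null(sp)) next
    sp <- data.frame(neuron = sp[, 1], time = sp[, 2])
    rates <- recall$rates[[tr]]
    for (e in seq_len(nrow(els))) {
      cl <- els$column[e]
      # active epoch of the measured population itself (Messenger bursts are
      # much shorter than the Timer span; pooling over the Timer epoch would
      # inflate Messenger ISIs with silent gaps)
      pE <- which(pops$role == role & pops$column == cl)
      rt <- suppressWarnings(
        recall_time(rates[, pE], recall$rate_times, threshold))
      if (is.na(rt$onset) || is.na(rt$offset)) next
      p <- pops[pops$role == role & pops$column == cl, ]
      ids <- seq.int(p$offset + 1L, p$offset + p$size)
      sub <- sp[sp$neuron %in% ids & sp$time >= rt$onset & sp$time <= rt$offset, ]
      if (nrow(sub) < 2) next
      all_isis[[length(all_isis) + 1L]] <-
        unlist(lapply(split(sub$time, sub$neuron),
                      function(t) if (length(t) > 1) diff(sort(t))),
               use.names = FALSE)
    }
  }
  isis <- unlist(all_isis, use.names = FALSE)
  if (length(isis) < 2) return(NA_real_)
  sd(isis) / mean(isis)
}

#' Per-trial mean weight of a connection class
#'
#' Averages the per-group mean weights of all connection groups belonging to
#' `class`, weighted by group size.
#'
#' @param training a `training_result`.
#' @param class class label, e.g. `"T_T"` or `"M_T"`.
#' @return numeric vector, one mean weight (nS) per training trial.
#' @export
weight_trajectory <- function(training, class) {
  stopifnot(inherits(training, "training_result"))
  sel <- training$classes$class == class
  if (!any(sel)) stop("no such class: ", class)
  w <- training$class_w[, sel, drop = FALSE]
  n <- training$classes$n_edges[sel]
  drop(w %*% n) / sum(n)
}

#' First trial at which a weight series stabilizes
#'
#' The convergence trial is the first trial after which the per-trial
#' relative change of the series stays below `rel_tol` for `patience`
#' consecutive trials (use `patience = Inf` to require stability until the
#' end of the series).
#'
#' @param series per-trial values (e.g. from [weight_trajectory()]).
#' @param rel_tol relative-change tolerance.
#' @param patience number of consecutive stable trials required.
#' @return the trial index, or `NA` if the series never stabilizes.
#' @export
convergence_trial <- function(series, rel_tol = 0.02, patience = 20) {
  n <- length(series)
  if (n < 2) return(NA_integer_)
  rel <- abs(diff(series)) / pmax(abs(series[-n]), .Machine$double.eps)
  ok <- rel < rel_tol   # ok[k]: change from trial k to k+1 is small
  for (cand in seq_len(n - 1)) {
    horizon <- min(cand + patience - 1, n - 1)
    if (all(ok[cand:horizon])) return(cand)
  }
  NA_integer_
}

#' Column activation order during recall
#'
#' The activation order is the ranking of the columns' Timer activation
#' onsets within a recall trial.  A trial counts as *ordered* when every
#' column activates and the onsets are strictly increasing in stimulation
#' order.
#'
#' @param recall a `recall_result`.
#' @param threshold,onset_guard see [recall_time()].
#' @return data.frame with `trial`, `ordered` (logical) and the onset of
#'   each column (`onset.1`, `onset.2`, ...).
#' @export
activation_order <- function(recall, threshold = 10, onset_guard = 20) {
  rt <- recall_times(recall, threshold, onset_guard)
  cols <- sort(unique(rt$column))
  out <- data.frame(trial = seq_len(recall$n_trials))
  on <- matrix(NA_real_, recall$n_trials, length(cols))
  for (k in seq_along(cols)) on[, k] <- rt$onset[rt$column == cols[k]]
  out$ordered <- apply(on, 1, function(x) !any(is.na(x)) && all(diff(x) > 0))
  colnames(on) <- paste0("onset.", cols)
  cbind(out, on)
}

#' @rdname activation_order
#' @return `ordered_fraction()`: the fraction of recall trials with the
#'   correct activation order.
#' @export
ordered_fraction <- function(recall, threshold = 10, onset_guard = 20) {
  mean(activation_order(recall, threshold, onset_guard)$ordered)
}
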