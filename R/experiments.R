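# Named experiments: one per results theme, config-driven, desk-scale
# instance counts by default.

#' Specification of a named experiment
#'
#' Maps an experiment name to its architecture variant, task sequence,
#' parameter overrides and default instance counts.  Instance counts are
#' deliberately desk-scale (e.g. 3 instead of 20); pass larger values to
#' [run_experiment()] for full-scale runs.
#'
#' @param name one of `"four_interval_sequence"`, `"robustness_weights"`,
#'   `"robustness_learning"`, `"inhibition_sweep"`, `"scaling"`,
#'   `"all_to_all"`, `"all_to_all_low_noise"`,
#'   `"all_to_all_high_threshold"`, `"local_inhibition"`.
#' @return a list with `name`, `variant`, `seq`, `config`, `n_instances`,
#'   `n_train`, `n_recall`, `randomize`, and `sweep` (for sweep
#'   experiments).
#' @export
experiment_spec <- function(name = c("four_interval_sequence", "robustness_weights",
                                     "robustness_learning", "inhibition_sweep",
                                     "scaling", "all_to_all",
                                     "all_to_all_low_noise",
                                     "all_to_all_high_threshold",
                                     "local_inhibition")) {
  name <- match.arg(name)
  spec <- list(name = name, variant = "baseline",
               seq = fixture_sequence("robustness"),
               config = default_config(), n_instances = 1L,
               n_train = 100L, n_recall = 50L, randomize = "none",
               sweep = NULL)
  switch(name,
    four_interval_sequence = {
      spec$seq <- fixture_sequence("four_interval")
      spec$n_recall <- 30L
    },
    robustness_weights = {
      spec$n_instances <- 3L
      spec$sweep <- list(classes = c("T_M", "IT_M"),
                         grid = c(-20, 0, 20))
    },
    robustness_learning = {
      spec$n_instances <- 3L
      spec$randomize <- "per_trial"
    },
    inhibition_sweep = {
      spec$seq <- fixture_sequence("scaling")   # three 700 ms elements
      spec$n_instances <- 2L
      spec$sweep <- list(classes = "T_IT", grid = c(-30, -25, 0, 40))
    },
    scaling = {
      spec$variant <- "scaled"
      spec$config <- default_config("scaled")
      spec$seq <- fixture_sequence("scaling")
      spec$n_recall <- 10L
    },
    all_to_all = {
      spec$variant <- "all_to_all"
      spec$config <- default_config("all_to_all")
      spec$n_recall <- 15L
    },
    all_to_all_low_noise = {
      spec$variant <- "all_to_all"
      cfg <- default_config("all_to_all")
      cfg$noise$sigma_xi <- 50           # half the baseline amplitude
      cfg$weights$T_IT <- cfg$weights$T_IT * 0.92
      cfg$weights$M_IM <- cfg$weights$M_IM * 1.05
      cfg$weights$w_in <- 110
      spec$config <- cfg
      spec$n_recall <- 15L
    },
    all_to_all_high_threshold = {
      spec$variant <- "all_to_all"
      cfg <- default_config("all_to_all")
      cfg$plasticity$ff$r_th <- 30       # raised from the baseline 20 spks/sec
      spec$config <- cfg
      spec$n_recall <- 15L
    },
    local_inhibition = {
      spec$variant <- "local_inhibition"
      spec$config <- default_config("local_inhibition")
      spec$seq <- fixture_sequence("two_element")
      spec$n_recall <- 15L
    })
  spec
}

# train + recall one instance and compute the standard metric block
run_instance <- function(spec, instance, seed, deltas = NULL) {
  net <- build_network(spec$variant, n_columns = max(spec$seq$elements$column),
                       config = spec$config, seed = seed + instance)
  if (!is.null(deltas)) net <- apply_weight_overrides(net, deltas = deltas)
  tr <- run_training(net, spec$seq, n_trials = spec$n_train,
                     seed = seed + 1000L + instance,
                     randomize = spec$randomize)
  rc <- run_recall(tr$net, spec$seq, n_trials = spec$n_recall,
                   seed = seed + 2000L + instance)
  rt <- recall_times(rc)
  cols <- sort(unique(rt$column))
  per_col <- do.call(rbind, lapply(cols, function(cc) {
    r <- rt$relative[rt$column == cc]
    a <- rt$absolute[rt$column == cc]
    data.frame(
      instance = instance, column = cc,
      median_relative = median(r, na.rm = TRUE),
      sd_relative = sd(r, na.rm = TRUE),
      n_failed = sum(is.na(r)),
      outliers_140 = count_deviation_outliers(
        r, spec$seq$elements$duration[match(cc, spec$seq$elements$column)]),
      z_outliers = sum(modified_zscore(a)$outlier))
  }))
  list(training = tr, recall = rc, recall_times = rt, per_column = per_col,
       ordered_fraction = ordered_fraction(rc),
       cv_timer = recall_isi_cv(rc, "T"),
       cv_messenger = recall_isi_cv(rc, "M"),
       convergence = convergence_trial(weight_trajectory(tr, "T_T"),
                                       patience = Inf))
}

#' Run a named experiment
#'
#' Builds `n_instances` networks, trains each on the experiment's sequence,
#' runs cued recall, and computes the standard analysis metrics (per-column
#' recall-time statistics, outlier counts, activation-order fraction, ISI
#' CVs, weight-convergence trial).  Sweep-type experiments delegate to
#' [sweep()].
#'
#' @param name experiment name, see [experiment_spec()].
#' @param seed master integer seed; instance seeds are derived from it.
#' @param n_instances override the experiment's default instance count.
#' @param n_train,n_recall override trial counts.
#' @param out_dir if non-`NULL`, write a results bundle (config.yaml,
#'   metrics CSV, per-instance spike files, weight trajectories).
#' @param keep_raw keep the full training/recall objects of every instance
#'   in the returned bundle (memory-hungry; the first instance is always
#'   kept).
#' @return a list of class `experiment_result`.
#' @export
run_experiment <- function(name, seed = 1, n_instances = NULL, n_train = NULL,
                           n_recall = NULL, out_dir = NULL, keep_raw = FALSE) {
  spec <- experiment_spec(name)
  if (!is.null(n_instances)) spec$n_instances <- n_instances
  if (!is.null(n_train)) spec$n_train <- n_train
  if (!is.null(n_recall)) spec$n_recall <- n_recall
  if (!is.null(spec$sweep))
    return(sweep(spec, spec$sweep$classes, spec$sweep$grid,
                 n_instances = spec$n_instances, seed = seed,
                 out_dir = out_dir))
  inst <- vector("list", spec$n_instances)
  for (i in seq_len(spec$n_instances)) {
    inst[[i]] <- run_instance(spec, i, seed)
    if (!keep_raw && i > 1) inst[[i]]$training <- inst[[i]]$recall <- NULL
  }
  per_col <- do.call(rbind, lapply(inst, `[[`, "per_column"))
  res <- structure(list(
    name = name, seed = seed, spec = spec,
    per_column = per_col,
    summary = data.frame(
      instance = seq_len(spec$n_instances),
      ordered_fraction = vapply(inst, `[[`, 0, "ordered_fraction"),
      cv_timer = vapply(inst, `[[`, 0, "cv_timer"),
      cv_messenger = vapply(inst, `[[`, 0, "cv_messenger"),
      convergence = vapply(inst, function(x) as.numeric(x$convergence), 0)),
    instances = inst), class = "experiment_result")
  if (!is.null(out_dir)) write_bundle(res, out_dir)
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", x$name, "| instances:",
      nrow(x$summary), "\n")
  agg <- aggregate(cbind(median_relative, outliers_140, z_outliers) ~ column,
                   x$per_column, mean)
  print(agg, row.names = FALSE)
  cat("mean ordered fraction:", round(mean(x$summary$ordered_fraction), 2),
      "| CV (T/M):", round(mean(x$summary$cv_timer), 2), "/",
      round(mean(x$summary$cv_messenger), 2), "\n")
  invisible(x)
}

#' Sweep class weights over a percentage grid
#'
#' Cartesian sweep over mean-weight deltas for the given connection classes;
#' each cell trains `n_instances` fresh networks and reports per-column
#' outlier counts and median recall-time deviation, averaged over instances.
#' Cells whose simulation aborts (runaway excitation) or whose recall fails
#' are flagged `unstable` rather than raising an error.
#'
#' @param spec an [experiment_spec()] (or any spec-like list with `seq`,
#'   `config`, `variant`, `n_train`, `n_recall`).
#' @param classes character vector of class names to vary.
#' @param grid numeric vector of percentage deltas (one axis, applied as the
#'   Cartesian product over `classes`).
#' @param n_instances networks per cell.
#' @param seed master seed.
#' @param out_dir optional bundle directory.
#' @return data.frame of class `sweep_result`: one row per cell x column.
#' @export
sweep <- function(spec, classes, grid, n_instances = 2, seed = 1,
                  out_dir = NULL) {
  cells <- expand.grid(rep(list(grid), length(classes)))
  names(cells) <- classes
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    deltas <- as.list(cells[ci, , drop = FALSE])
    cell_res <- list()
    for (i in seq_len(n_instances)) {
      r <- tryCatch(
        run_instance(spec, i, seed + 10000L * ci, deltas = deltas),
        error = function(e) NULL)
      if (!is.null(r)) cell_res[[length(cell_res) + 1L]] <- r$per_column
    }
    unstable <- length(cell_res) < n_instances
    pc <- if (length(cell_res)) {
      agg <- do.call(rbind, cell_res)
      aggregate(cbind(median_relative, sd_relative, outliers_140, z_outliers,
                      n_failed) ~ column, agg, mean)
    } else data.frame(column = NA, median_relative = NA, sd_relative = NA,
                      outliers_140 = NA, z_outliers = NA, n_failed = NA)
    # a cell is also unstable when recall routinely fails
    if (any(!is.na(pc$n_failed) & pc$n_failed > spec$n_recall / 2))
      unstable <- TRUE
    for (k in seq_len(nrow(pc)))
      rows[[length(rows) + 1L]] <- cbind(cells[ci, , drop = FALSE],
                                         pc[k, ], unstable = unstable,
                                         row.names = NULL)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "sweep_metrics.csv"),
                     row.names = FALSE)
  }
  out
}

#' Canonical task fixtures and per-experiment configurations
#'
#' Emits the standard sequences and the configuration of each named
#' experiment, optionally writing them as YAML/CSV under `out_dir`.
#'
#' @param kind `"sequences"` for the canonical task set, or an experiment
#'   name for its configuration.
#' @param out_dir optional output directory.
#' @return a named list of `stim_sequence`s, or an experiment spec.
#' @export
generate_fixtures <- function(kind = "sequences", out_dir = NULL) {
  if (kind == "sequences") {
    out <- list(four_interval = fixture_sequence("four_interval"),
                robustness = fixture_sequence("robustness"),
                scaling = fixture_sequence("scaling"),
                two_element = fixture_sequence("two_element"),
                half_second = fixture_sequence("half_second"))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (nm in names(out))
        utils::write.csv(out[[nm]]$elements,
                         file.path(out_dir, paste0("sequence_", nm, ".csv")),
                         row.names = FALSE)
    }
    return(out)
  }
  spec <- experiment_spec(kind)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(spec$config, file.path(out_dir, paste0(kind, "_config.yaml")))
    utils::write.csv(spec$seq$elements,
                     file.path(out_dir, paste0(kind, "_sequence.csv")),
                     row.names = FALSE)
  }
  spec
}

# results bundle: config, metrics, spikes (gdf), weight trajectories, log
write_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(res$spec$config, file.path(out_dir, "config.yaml"))
  utils::write.csv(res$per_column, file.path(out_dir, "metrics_per_column.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summary, file.path(out_dir, "metrics_summary.csv"),
                   row.names = FALSE)
  first <- res$instances[[1]]
  if (!is.null(first$training)) {
    utils::write.csv(
      data.frame(trial = seq_len(nrow(first$training$class_w)),
                 first$training$class_w, check.names = FALSE),
      file.path(out_dir, "weights_per_trial.csv"), row.names = FALSE)
  }
  if (!is.null(first$recall)) {
    dir.create(file.path(out_dir, "spikes"), showWarnings = FALSE)
    sp <- first$recall$spikes[[1]]
    if (!is.null(sp))
      write_spikes(data.frame(neuron = sp[, 1], time = sp[, 2]),
                   file.path(out_dir, "spikes", "recall_trial1.gdf"))
  }
  writeLines(c(paste("experiment:", res$name),
               paste("seed:", res$seed),
               paste("generated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}
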