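# Shared helpers: small probe networks for mechanics tests, and a cache of
# trained baseline instances reused by the slower behavioural tests (training
# a 4-column instance takes about a minute; several tests measure different
# statistics of the same protocol).

tiny_net <- function(n_columns = 1, n_neurons = 20, seed = 1, ...) {
  cfg <- default_config(...)
  cfg$n_neurons <- as.integer(n_neurons)
  build_network(n_columns = n_columns, config = cfg, seed = seed)
}

.colseq_cache <- new.env(parent = emptyenv())

# one trained + recalled baseline instance on four 700 ms elements
baseline_instance <- function(i, n_train = 100, n_recall = 50) {
  key <- sprintf("base_%d_%d_%d", i, n_train, n_recall)
  if (!is.null(.colseq_cache[[key]])) return(.colseq_cache[[key]])
  seq4 <- fixture_sequence("robustness")
  net <- build_network(n_columns = 4, seed = 100 + i)
  tr <- run_training(net, seq4, n_trials = n_train, seed = 200 + i)
  rc <- run_recall(tr$net, seq4, n_trials = n_recall, seed = 300 + i)
  out <- list(training = tr, recall = rc, recall_times = recall_times(rc))
  .colseq_cache[[key]] <- out
  out
}

expect_no_autapse <- function(net) {
  for (cl in net$classes)
    if (identical(cl$src, cl$tgt))
      expect_false(any(cl$pre == cl$post), info = cl$name)
}
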