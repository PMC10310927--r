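#' Sample a random connection matrix
#'
#' Each ordered (pre, post) pair is connected independently with probability
#' `phi`; self-pairs are excluded for recurrent connections within one
#' population.
#'
#' @param n_pre,n_post population sizes.
#' @param phi connection probability in `[0, 1]`.
#' @param allow_autapse keep `pre == post` pairs (only meaningful when the
#'   source and target population are the same).
#' @return integer matrix with columns `pre`, `post` (1-based local indices).
#' @export
sample_connections <- function(n_pre, n_post, phi, allow_autapse = TRUE) {
  stopifnot(phi >= 0, phi <= 1)
  if (phi == 0 || n_pre == 0 || n_post == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("pre", "post"))))
  hit <- which(runif(n_pre * n_post) < phi) - 1L
  pre <- hit %% n_pre + 1L
  post <- hit %/% n_pre + 1L
  if (!allow_autapse) {
    keep <- pre != post
    pre <- pre[keep]; post <- post[keep]
  }
  cbind(pre = pre, post = post)
}

# population table: one row per (column, role), fixed role order
make_populations <- function(n_columns, n_neurons) {
  roles <- c("T", "M", "IT", "IM")
  df <- expand.grid(role = roles, column = seq_len(n_columns),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[order(df$column, match(df$role, roles)), ]
  df$name <- paste0(df$role, df$column)
  df$size <- n_neurons
  df$offset <- cumsum(c(0L, df$size[-nrow(df)]))  # 0-based global start
  rownames(df) <- df$name
  df[, c("name", "role", "column", "size", "offset")]
}

pop_index <- function(net, role, column) {
  which(net$populations$role == role & net$populations$column == column)
}

#' Neuron ids of one population
#'
#' @param net a `col_network`.
#' @param role one of `"T"`, `"M"`, `"IT"`, `"IM"`.
#' @param column column index.
#' @return 1-based global neuron ids.
#' @export
neuron_ids <- function(net, role, column) {
  p <- net$populations[pop_index(net, role, column), ]
  seq.int(p$offset + 1L, p$offset + p$size)
}

# one connection-class instance between two concrete populations
make_class <- function(pops, class, src, tgt, mean_w, sd_w, phi, channel,
                       plastic, trace_set, eta_lr, plastic_init) {
  edges <- sample_connections(pops$size[src], pops$size[tgt], phi,
                              allow_autapse = !identical(src, tgt))
  n <- nrow(edges)
  w <- if (plastic) runif(n, 0, plastic_init)
       else pmax(rnorm(n, mean_w, min(sd_w, mean_w)), 0)
  list(name = sprintf("%s.%s_%s", class, pops$name[src], pops$name[tgt]),
       class = class, src = pops$name[src], tgt = pops$name[tgt],
       src_col = pops$column[src], tgt_col = pops$column[tgt],
       pre = as.integer(pops$offset[src] + edges[, "pre"] - 1L),
       post = as.integer(pops$offset[tgt] + edges[, "post"] - 1L),
       w = w, mean_w = mean_w, channel = channel,
       plastic = plastic, trace_set = trace_set, eta_lr = eta_lr)
}

# wiring plan per variant: src/tgt roles, scope, weight key, channel, plasticity
wiring_plan <- function(variant) {
  row <- function(class, src, tgt, scope, channel, plastic = FALSE,
                  trace_set = -1L)
    list(class = class, src = src, tgt = tgt, scope = scope,
         channel = channel, plastic = plastic, trace_set = trace_set)
  switch(variant,
    baseline = ,
    scaled = list(
      row("T_T",  "T",  "T",  "intra", 0L, TRUE, 0L),
      row("T_IT", "T",  "IT", "intra", 0L),
      row("T_M",  "T",  "M",  "intra", 0L),
      row("M_IM", "M",  "IM", "intra", 0L),
      row("IT_M", "IT", "M",  "intra", 1L),
      row("IT_T", "IT", "T",  "cross", 1L),
      row("IM_M", "IM", "M",  "cross", 1L),
      row("M_T",  "M",  "T",  "next",  0L, TRUE, 1L)),
    all_to_all = list(
      row("T_T",  "T",  "T",  "intra", 0L, TRUE, 0L),
      row("T_IT", "T",  "IT", "intra", 0L),
      row("T_M",  "T",  "M",  "intra", 0L),
      row("M_IM", "M",  "IM", "intra", 0L),
      row("IT_M", "IT", "M",  "intra", 1L),
      row("IT_T", "IT", "T",  "cross", 1L),
      row("IM_M", "IM", "M",  "cross", 1L),
      row("M_T",  "M",  "T",  "cross", 0L, TRUE, 1L)),
    local_inhibition = list(
      row("T_T",    "T",  "T",  "intra", 0L, TRUE, 0L),
      row("T_M",    "T",  "M",  "intra", 0L),
      row("T_IM",   "T",  "IM", "intra", 0L),
      row("T_IT_x", "T",  "IT", "cross", 0L),
      row("M_T",    "M",  "T",  "next",  0L, TRUE, 1L),
      row("M_IM_x", "M",  "IM", "cross", 0L),
      row("IT_T",   "IT", "T",  "intra", 1L),
      row("IM_M",   "IM", "M",  "intra", 1L)),
    stop("unknown variant: ", variant)
  )
}

#' Construct a columnar network
#'
#' Builds the populations, connectivity and initial weights for one network
#' instance of the requested architecture variant.
#'
#' Baseline wiring, per column i: plastic recurrent `T^i -> T^i`; static
#' `T^i -> I_T^i`, `T^i -> M^i`, `M^i -> I_M^i`, `I_T^i -> M^i`;
#' cross-columnar inhibition `I_T^i -> T^j` and `I_M^i -> M^j` (i != j); and
#' plastic feedforward `M^i -> T^(i+1)` between consecutive columns only.
#' The all-to-all variant instead instantiates plastic `M^i -> T^j` for every
#' i != j.  The local-inhibition variant keeps all inhibition within the
#' column and routes feedforward inhibition through excitatory cross-columnar
#' projections onto the inhibitory populations.  The scaled variant uses
#' baseline wiring at N = 400 with statics rescaled by `sqrt(N/N')` (see
#' [scale_static_weights()]) plus the configured override set.
#'
#' Static weights are drawn from N(mean, sd) and clipped at zero; plastic
#' weights start uniform in `[0, plastic_init]`.  Uses R's RNG: seed it (or
#' pass `seed`) for a reproducible instance.
#'
#' @param variant architecture variant; defaults taken from `config`.
#' @param n_columns number of columns (one per sequence element).
#' @param config a [default_config()] list.
#' @param seed optional integer seed applied before sampling.
#' @return an object of class `col_network`.
#' @examples
#' net <- build_network(n_columns = 2, seed = 1)
#' net
#' @export
build_network <- function(variant = NULL, n_columns = NULL,
                          config = default_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  variant <- variant %||% config$variant
  config$variant <- variant
  n_columns <- as.integer(n_columns %||% config$n_columns)
  stopifnot(n_columns >= 1)
  config$n_columns <- n_columns
  n_neurons <- as.integer(if (variant == "scaled") 400L else config$n_neurons)
  config$n_neurons <- n_neurons

  pops <- make_populations(n_columns, n_neurons)
  plan <- wiring_plan(variant)
  wcfg <- config$weights
  classes <- list()
  for (pl in plan) {
    eta_lr <- if (!pl$plastic) 0
              else if (pl$trace_set == 0L) config$plasticity$eta
              else config$plasticity$eta_ff
    mean_w <- wcfg[[pl$class]]
    if (is.null(mean_w)) stop("no weight configured for class ", pl$class)
    pairs <- switch(pl$scope,
      intra = cbind(seq_len(n_columns), seq_len(n_columns)),
      cross = { g <- expand.grid(i = seq_len(n_columns), j = seq_len(n_columns))
                as.matrix(g[g$i != g$j, , drop = FALSE]) },
      next_ = NULL,
      "next" = if (n_columns > 1)
                 cbind(seq_len(n_columns - 1), seq.int(2, n_columns))
               else matrix(integer(0), ncol = 2))
    if (is.null(pairs) || nrow(pairs) == 0) next
    for (r in seq_len(nrow(pairs))) {
      src <- pop_index(list(populations = pops), pl$src, pairs[r, 1])
      tgt <- pop_index(list(populations = pops), pl$tgt, pairs[r, 2])
      classes[[length(classes) + 1L]] <- make_class(
        pops, pl$class, src, tgt, mean_w, wcfg$sd, config$phi, pl$channel,
        pl$plastic, pl$trace_set, eta_lr, wcfg$plastic_init)
    }
  }
  names(classes) <- vapply(classes, `[[`, "", "name")
  net <- structure(
    list(populations = pops, classes = classes, config = config,
         variant = variant, n_columns = n_columns, n_neurons = n_neurons),
    class = "col_network")
  if (variant == "scaled") {
    net <- scale_static_weights(net, 100L, n_neurons)
    ov <- config$scaled_overrides
    if (length(ov)) net <- apply_weight_overrides(net, deltas = ov)
  }
  net
}

#' @export
print.col_network <- function(x, ...) {
  n_edges <- sum(vapply(x$classes, function(cl) length(cl$pre), 0))
  n_plast <- sum(vapply(x$classes,
                        function(cl) if (cl$plastic) length(cl$pre) else 0, 0))
  cat(sprintf("<col_network> %s: %d columns, %d populations, %d neurons\n",
              x$variant, x$n_columns, nrow(x$populations),
              sum(x$populations$size)))
  cat(sprintf("  %d synapses in %d connection groups (%d plastic synapses)\n",
              n_edges, length(x$classes), n_plast))
  invisible(x)
}

#' Rescale static weights for a larger network
#'
#' Multiplies every non-plastic weight by `sqrt(N / N_prime)`, the standard
#' size scaling that keeps the input variance of balanced networks constant,
#' and halves the noise amplitude when the population size is quadrupled.
#' Plastic weights are untouched.
#'
#' @param net a `col_network`.
#' @param N,N_prime original and new population sizes (`N_prime >= N`).
#' @return the rescaled network.
#' @export
scale_static_weights <- function(net, N, N_prime) {
  stopifnot(inherits(net, "col_network"), N_prime >= N)
  f <- sqrt(N / N_prime)
  for (i in seq_along(net$classes)) {
    if (!net$classes[[i]]$plastic) {
      net$classes[[i]]$w <- net$classes[[i]]$w * f
      net$classes[[i]]$mean_w <- net$classes[[i]]$mean_w * f
    }
  }
  if (N_prime / N == 4) net$config$noise$scale <- net$config$noise$scale / 2
  net
}

#' Override class mean weights
#'
#' Shifts the mean weight of whole connection classes, either to an absolute
#' value (`values`, in nS) or by a percentage (`deltas`).  By default the
#' existing draws are rescaled multiplicatively, which preserves the sampled
#' topology and weight pattern across sweep points; `mode = "redraw"` draws
#' fresh `N(mean, sd)` weights instead (clipped at zero).
#'
#' @param net a `col_network`.
#' @param values named list/vector: class -> new mean (nS).
#' @param deltas named list/vector: class -> percent change (e.g. `-20`).
#' @param mode `"rescale"` or `"redraw"`.
#' @return the modified network.
#' @examples
#' net <- build_network(n_columns = 2, seed = 1)
#' net2 <- apply_weight_overrides(net, deltas = list(T_IT = 40))
#' @export
apply_weight_overrides <- function(net, values = list(), deltas = list(),
                                   mode = c("rescale", "redraw")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "col_network"))
  targets <- c(lapply(values, function(v) list(value = v)),
               lapply(deltas, function(d) list(delta = d)))
  known <- unique(vapply(net$classes, `[[`, "", "class"))
  bad <- setdiff(names(targets), known)
  if (length(bad)) stop("unknown connection class: ", paste(bad, collapse = ", "))
  for (i in seq_along(net$classes)) {
    cl <- net$classes[[i]]
    tg <- targets[[cl$class]]
    if (is.null(tg)) next
    new_mean <- if (!is.null(tg$value)) tg$value
                else cl$mean_w * (1 + tg$delta / 100)
    if (mode == "rescale") {
      if (cl$mean_w == 0 && new_mean != 0)
        stop("cannot rescale class with zero mean: ", cl$class)
      f <- if (cl$mean_w == 0) 1 else new_mean / cl$mean_w
      net$classes[[i]]$w <- cl$w * f
    } else {
      net$classes[[i]]$w <- pmax(
        rnorm(length(cl$w), new_mean,
              min(net$config$weights$sd, new_mean)), 0)
    }
    net$classes[[i]]$mean_w <- new_mean
  }
  net
}

#' Export the network as an edge list
#'
#' @param net a `col_network`.
#' @return data.frame with columns `source`, `target` (1-based global neuron
#'   ids), `weight` (nS), `delay` (ms), `plastic`, `class`.
#' @export
export_edges <- function(net) {
  stopifnot(inherits(net, "col_network"))
  do.call(rbind, lapply(net$classes, function(cl) {
    data.frame(source = cl$pre + 1L, target = cl$post + 1L, weight = cl$w,
               delay = net$config$delay, plastic = cl$plastic,
               class = cl$class, row.names = NULL)
  }))
}

#' @rdname export_edges
#' @param path CSV output path.
#' @export
write_edges <- function(net, path) {
  utils::write.csv(export_edges(net), path, row.names = FALSE)
  invisible(path)
}
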