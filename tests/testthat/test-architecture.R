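test_that("connection sampling follows the independent-pair model", {
  set.seed(1)
  expect_equal(nrow(sample_connections(50, 50, 0)), 0)
  full <- sample_connections(100, 100, 1, allow_autapse = FALSE)
  expect_equal(nrow(full), 100 * 99)          # complete digraph minus diagonal
  expect_false(any(full[, "pre"] == full[, "post"]))
  # binomial check at the published density
  n <- replicate(5, nrow(sample_connections(100, 100, 0.26)))
  expect_true(all(abs(n - 2600) < 4 * sqrt(10000 * 0.26 * 0.74)))
})

test_that("baseline network has the documented populations and plastic classes", {
  net <- build_network(n_columns = 4, seed = 1)
  expect_equal(nrow(net$populations), 16)     # 4 columns x 4 populations
  expect_equal(sum(net$populations$size), 1600)
  meta <- vapply(net$classes, `[[`, "", "class")
  plastic <- vapply(net$classes, `[[`, FALSE, "plastic")
  expect_setequal(unique(meta[plastic]), c("T_T", "M_T"))
  # feedforward projections exist only between consecutive columns
  ff <- net$classes[meta == "M_T"]
  expect_equal(vapply(ff, `[[`, 0, "tgt_col"),
               vapply(ff, `[[`, 0, "src_col") + 1)
  expect_equal(length(ff), 3)
  expect_no_autapse(net)
  expect_true(all(unlist(lapply(net$classes, `[[`, "w")) >= 0))
})

test_that("all-to-all variant wires plastic M->T between every column pair", {
  net <- build_network("all_to_all", n_columns = 4, seed = 1)
  meta <- vapply(net$classes, `[[`, "", "class")
  ff <- net$classes[meta == "M_T"]
  expect_equal(length(ff), 12)                # ordered pairs i != j
  pairs <- t(vapply(ff, function(cl) c(cl$src_col, cl$tgt_col), numeric(2)))
  expect_false(any(pairs[, 1] == pairs[, 2]))
})

test_that("local-inhibition variant has no cross-columnar inhibitory edges", {
  net <- build_network("local_inhibition", n_columns = 2, seed = 1)
  inh <- net$classes[vapply(net$classes, `[[`, 0L, "channel") == 1L]
  for (cl in inh) expect_equal(cl$src_col, cl$tgt_col)
  # stimulus in this variant targets only the Timer cells
  set.seed(2)
  ev <- make_stimulus(net, 1)
  expect_true(all(ev[, "neuron"] %in% neuron_ids(net, "T", 1)))
})

test_that("static weight scaling uses the inverse square-root size ratio", {
  net <- build_network(n_columns = 2, seed = 1)
  w0 <- lapply(net$classes, `[[`, "w")
  s0 <- net$config$noise$scale
  same <- scale_static_weights(net, 100, 100)
  expect_equal(lapply(same$classes, `[[`, "w"), w0)  # N' = N is the identity
  scaled <- scale_static_weights(net, 100, 400)
  for (i in seq_along(net$classes)) {
    if (net$classes[[i]]$plastic)
      expect_equal(scaled$classes[[i]]$w, w0[[i]])   # plastic untouched
    else
      expect_equal(scaled$classes[[i]]$w, w0[[i]] * 0.5)
  }
  expect_equal(scaled$config$noise$scale, s0 / 2)    # noise halved at 4N
  # a second application with an unchanged size is idempotent
  again <- scale_static_weights(scaled, 400, 400)
  expect_equal(lapply(again$classes, `[[`, "w"),
               lapply(scaled$classes, `[[`, "w"))
})

test_that("weight overrides shift class means and preserve topology", {
  net <- build_network(n_columns = 2, seed = 1)
  unchanged <- apply_weight_overrides(net, deltas = list(T_M = 0))
  expect_equal(lapply(unchanged$classes, `[[`, "w"),
               lapply(net$classes, `[[`, "w"))
  down <- apply_weight_overrides(net, deltas = list(T_M = -20))
  for (i in seq_along(net$classes)) {
    cl <- net$classes[[i]]
    if (cl$class == "T_M") {
      expect_equal(down$classes[[i]]$w, cl$w * 0.8)
      expect_equal(down$classes[[i]]$mean_w, cl$mean_w * 0.8)
      expect_equal(down$classes[[i]]$pre, cl$pre)    # same topology
    }
  }
  abs_set <- apply_weight_overrides(net, values = list(T_IT = 0.23))
  i <- which(vapply(abs_set$classes, `[[`, "", "class") == "T_IT")[1]
  expect_equal(abs_set$classes[[i]]$mean_w, 0.23)
  expect_error(apply_weight_overrides(net, deltas = list(nope = 10)),
               "unknown connection class")
})

test_that("network construction is reproducible under a fixed seed", {
  a <- build_network(n_columns = 2, seed = 42)
  b <- build_network(n_columns = 2, seed = 42)
  expect_equal(lapply(a$classes, `[[`, "w"), lapply(b$classes, `[[`, "w"))
  expect_equal(lapply(a$classes, `[[`, "pre"), lapply(b$classes, `[[`, "pre"))
})

test_that("edge export is consistent with the class structure", {
  net <- tiny_net(n_columns = 2, n_neurons = 10)
  edges <- export_edges(net)
  expect_equal(nrow(edges), sum(vapply(net$classes, function(cl) length(cl$pre), 0)))
  expect_true(all(edges$weight >= 0))
  expect_true(all(edges$delay == net$config$delay))
  path <- tempfile(fileext = ".csv")
  write_edges(net, path)
  expect_equal(nrow(utils::read.csv(path)), nrow(edges))
})
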