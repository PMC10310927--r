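test_that("recall time finds the downward threshold crossing after activation", {
  t <- seq(1, 1200)
  rate <- ifelse(t <= 700, 50, 0)
  rt <- recall_time(rate, t)
  expect_equal(rt$offset, 701)   # first sample below threshold after the step
  expect_equal(rt$onset, 1)
  # filtered version: the exponential tail delays the crossing by ~tau ln(r/th)
  filt <- estimate_rate(seq(0, 700, by = 20), tau_r = 40, duration = 1200)
  rt2 <- recall_time(filt$rate, filt$time)
  expect_gt(rt2$offset, 700)
  expect_lt(rt2$offset, 700 + 40 * log(50 / 10) + 25)
  # never-active trace yields a sentinel with a warning
  expect_warning(none <- recall_time(rep(0, 100), seq_len(100)))
  expect_true(is.na(none$offset))
})

test_that("recall time is translation-equivariant", {
  t <- seq(1, 2000)
  base <- pmax(0, 60 * exp(-(t - 100) / 300)) * (t > 100)
  r0 <- recall_time(base, t)
  for (shift in c(50, 137, 400)) {
    shifted <- c(rep(0, shift), base)[seq_along(t)]
    rs <- recall_time(shifted, t)
    expect_equal(rs$offset, r0$offset + shift)
  }
})

test_that("an onset guard skips brief pre-activation crossings", {
  t <- seq(1, 1000)
  rate <- numeric(1000)
  rate[50:55] <- 30            # 6 ms blip, shorter than the 20 ms guard
  rate[200:700] <- 40
  rt <- recall_time(rate, t)
  expect_equal(rt$onset, 200)
  expect_equal(rt$offset, 701)
})

test_that("deviation outliers count large misses and failed recalls", {
  expect_equal(count_deviation_outliers(rep(700, 10), 700), 0)
  expect_equal(count_deviation_outliers(c(700, 850, 540), 700), 2)
  expect_equal(count_deviation_outliers(c(700, NA), 700), 1)
  # monotone non-increasing in the tolerance
  set.seed(50)
  times <- 700 + rnorm(200, 0, 120)
  tols <- seq(20, 300, by = 20)
  counts <- vapply(tols, function(tl)
    count_deviation_outliers(times, 700, tl), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("modified z-scores match the direct median/MAD computation", {
  expect_equal(modified_zscore(rep(5, 10))$z, rep(0, 10))  # MAD = 0 convention
  x <- c(1, 2, 3, 4, 100)
  z <- modified_zscore(x)
  med <- median(x); mad0 <- median(abs(x - med))
  expect_equal(z$z, 0.6745 * (x - med) / mad0)
  expect_equal(which(z$outlier), 5L)                       # only the extreme
})

test_that("modified z-score outlier flags are affine invariant", {
  set.seed(51)
  for (i in 1:10) {
    x <- rnorm(40)
    x[sample(40, 2)] <- x[sample(40, 2)] + 10
    base <- modified_zscore(x)$outlier
    a <- runif(1, 0.1, 5); b <- runif(1, -100, 100)
    expect_equal(modified_zscore(a * x + b)$outlier, base)
  }
})

test_that("ISI CV is zero for regular trains and near one for Poisson", {
  regular <- data.frame(neuron = 1, time = seq(0, 10000, by = 100))
  expect_equal(isi_cv(regular), 0)
  set.seed(52)
  pois <- data.frame(neuron = 1, time = cumsum(rexp(3000, rate = 0.01)))
  expect_equal(isi_cv(pois), 1, tolerance = 0.05)
  # too few spikes yields the sentinel
  expect_true(is.na(isi_cv(data.frame(neuron = 1, time = 5))))
  # window restriction
  expect_true(is.na(isi_cv(regular, window = c(0, 50))))
})

test_that("convergence detection matches a brute-force scan of its definition", {
  expect_equal(convergence_trial(rep(1, 30)), 1)
  expect_true(is.na(convergence_trial(2^(1:30))))
  series <- 1 - exp(-(1:100) / 20)
  brute <- function(s, tol = 0.02, patience = 20) {
    rel <- abs(diff(s)) / pmax(abs(s[-length(s)]), .Machine$double.eps)
    for (cand in seq_along(rel))
      if (all(rel[cand:min(cand + patience - 1, length(rel))] < tol))
        return(cand)
    NA_integer_
  }
  expect_equal(convergence_trial(series), brute(series))
  set.seed(53)
  for (i in 1:10) {
    s <- cumsum(rnorm(60, 0.1, 0.3))
    expect_equal(convergence_trial(s), brute(s))
    expect_equal(convergence_trial(s, patience = Inf),
                 brute(s, patience = length(s)))
  }
})

test_that("activation order summarises recall trials", {
  # synthetic recall result: two columns, one ordered and one scrambled trial
  mk_rates <- function(on1, on2) {
    t <- seq_len(1800)
    m <- matrix(0, 1800, 8)
    m[, 1] <- ifelse(t > on1 & t < on1 + 600, 50, 0)
    m[, 5] <- ifelse(t > on2 & t < on2 + 600, 50, 0)
    m
  }
  net <- tiny_net(n_columns = 2)
  fake <- structure(list(
    rates = list(mk_rates(10, 700), mk_rates(700, 10)),
    rate_times = seq_len(1800), spikes = list(NULL, NULL),
    populations = net$populations, seq = fixture_sequence("two_element"),
    expected_onsets = c(0, 700), n_trials = 2, trial_ms = 1800, seed = 1),
    class = "recall_result")
  ord <- activation_order(fake)
  expect_equal(ord$ordered, c(TRUE, FALSE))
  expect_equal(ordered_fraction(fake), 0.5)
})
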