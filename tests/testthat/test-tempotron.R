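test_that("the PSP kernel is causal, unimodal and normalized to 1", {
  prm <- psp_params(tau_m = 0.1)
  expect_equal(prm$tau_s, 0.025)
  expect_equal(psp_kernel(0, prm), 0)
  expect_equal(psp_kernel(-0.3, prm), 0)

  grid <- seq(0, 1, length.out = 20001)
  kv <- psp_kernel(grid, prm)
  expect_true(all(kv >= 0))
  expect_lt(abs(max(kv) - 1), 1e-6)
  # analytic argmax agrees with the dense-grid maximizer
  t_star <- 0.1 * 0.025 / (0.1 - 0.025) * log(0.1 / 0.025)
  expect_lt(abs(grid[which.max(kv)] - t_star), 1e-4)
  expect_equal(prm$t_peak, t_star)
  expect_equal(prm$v0, 2.1165, tolerance = 1e-4)
  # single interior maximum: increasing then decreasing
  i_max <- which.max(kv)
  expect_true(all(diff(kv[1:i_max]) >= 0))
  expect_true(all(diff(kv[i_max:length(kv)]) <= 0))
})

test_that("time-to-first-spike conversion maps strength to latency", {
  pk <- peak_set(data.frame(s = 3L, theta = 0, x = 0:1, y = 0L,
                            value = c(1.0, 0.5)), 40, 40)
  sp <- peaks_to_spikes(pk, t_win = 1)
  expect_equal(sort(sp$time), c(0, 0.5))
  expect_equal(length(unique(sp$afferent)), 2L)

  single <- peaks_to_spikes(peak_set(data.frame(s = 3L, theta = 0, x = 0L,
                                                y = 0L, value = 0.3),
                                     40, 40))
  expect_equal(single$time, 0)

  none <- peaks_to_spikes(peak_set(NULL, 40, 40))
  expect_equal(length(none$afferent), 0L)
  expect_equal(none$n_afferents, 16L * 40L * 40L)
})

test_that("membrane potential is the weighted PSP sum plus rest", {
  cfg <- tempotron_config()
  n_aff <- 16L * 40L * 40L
  pat0 <- peaks_to_spikes(peak_set(NULL, 40, 40))
  w <- rep(0, n_aff)
  expect_equal(membrane_potential(w, pat0, c(0, 0.5, 1), cfg), rep(0, 3))

  pk <- peak_set(data.frame(s = 3L, theta = 0, x = 3L, y = 4L, value = 1),
                 40, 40)
  pat <- peaks_to_spikes(pk)
  w[pat$afferent] <- 0.7
  ts <- seq(0, 1, by = 0.05)
  expect_equal(membrane_potential(w, pat, ts, cfg),
               0.7 * psp_kernel(ts, cfg$psp))

  # additivity over afferents
  pk2 <- peak_set(data.frame(s = 3L, theta = 0, x = c(3L, 8L), y = 4L,
                             value = c(1, 0.6)), 40, 40)
  pat2 <- peaks_to_spikes(pk2)
  set.seed(61)
  w2 <- runif(n_aff)
  sep <- sapply(seq_along(pat2$afferent), function(i) {
    p1 <- pat2; p1$afferent <- pat2$afferent[i]; p1$time <- pat2$time[i]
    membrane_potential(w2, p1, ts, cfg)
  })
  expect_equal(membrane_potential(w2, pat2, ts, cfg), rowSums(sep))
})

test_that("simulation fires at the first threshold crossing and shunts", {
  cfg <- tempotron_config()
  n_aff <- 16L * 40L * 40L
  pat <- peaks_to_spikes(peak_set(data.frame(s = 3L, theta = 0, x = 0L,
                                             y = 0L, value = 1), 40, 40))
  res0 <- tempotron_simulate(rep(0, n_aff), pat, cfg)
  expect_false(res0$fired)
  expect_equal(res0$t_event, 0)   # flat potential, first grid point

  w <- rep(0, n_aff); w[pat$afferent] <- 2
  res <- tempotron_simulate(w, pat, cfg)
  expect_true(res$fired)
  grid <- seq(0, 1, length.out = cfg$n_steps + 1)
  first <- grid[which(2 * psp_kernel(grid, cfg$psp) > cfg$v_thr)[1]]
  expect_equal(res$t_event, first)

  # doubling weights never delays firing
  set.seed(62)
  for (i in 1:20) {
    pk <- peak_set(data.frame(s = 3L, theta = 0, x = sample(0:39, 5),
                              y = sample(0:39, 5), value = runif(5)), 40, 40)
    p <- peaks_to_spikes(pk)
    ww <- rep(0, n_aff); ww[p$afferent] <- runif(5, 0.3, 1)
    r1 <- tempotron_simulate(ww, p, cfg)
    r2 <- tempotron_simulate(2 * ww, p, cfg)
    if (r1$fired) {
      expect_true(r2$fired)
      expect_lte(r2$t_event, r1$t_event)
    }
  }
})

# small linearly separable corpus: two classes on disjoint afferent sets
separable_patterns <- function(n_per_class = 20, seed = 71) {
  set.seed(seed)
  mk <- function(x_range, n) lapply(seq_len(n), function(i) {
    xs <- sample(x_range, 8)
    peaks_to_spikes(peak_set(data.frame(s = 3L, theta = 0, x = xs, y = 2L,
                                        value = runif(8, 0.5, 1)), 40, 40))
  })
  list(patterns = c(mk(0:15, n_per_class), mk(24:39, n_per_class)),
       labels = rep(c("a", "b"), each = n_per_class))
}

test_that("training is inert at lambda 0 and reproducible under a seed", {
  corp <- separable_patterns(5)
  cfg0 <- tempotron_config(lambda = 0, max_epochs = 2, seed = 3,
                           n_neurons = 2)
  w0 <- tempotron_train(corp$patterns, corp$labels, cfg0)
  init <- aerorient:::with_seed(3, lapply(1:4, function(i)
    runif(16 * 40 * 40, 0, 0.01)))
  expect_identical(w0$weights, init)

  cfg <- tempotron_config(seed = 5, n_neurons = 3)
  w1 <- tempotron_train(corp$patterns, corp$labels, cfg)
  w2 <- tempotron_train(corp$patterns, corp$labels, cfg)
  expect_identical(w1$weights, w2$weights)
})

test_that("a lone miss with a spike at time zero is corrected by lambda", {
  # one pattern, one spike at t = 0: the subthreshold potential is
  # proportional to the kernel, so its peak sits at the kernel peak where
  # K = 1, and the miss update on that afferent is lambda * K(t*) = lambda
  pk <- peak_set(data.frame(s = 3L, theta = 0, x = 0L, y = 0L, value = 1),
                 40, 40)
  pat <- peaks_to_spikes(pk)
  cfg <- tempotron_config(lambda = 3e-3, max_epochs = 1, seed = 9,
                          n_neurons = 1)
  fit <- tempotron_train(list(pat), factor("a"), cfg)
  init <- aerorient:::with_seed(9, lapply(1, function(i)
    runif(16 * 40 * 40, 0, 0.01)))[[1]]
  d <- fit$weights[[1]] - init
  expect_equal(d[pat$afferent], 3e-3, tolerance = 1e-3)
  expect_equal(sum(d != 0), 1L)
})

test_that("separable spike classes reach perfect accuracy within 10 epochs", {
  corp <- separable_patterns(20)
  cfg <- tempotron_config(seed = 13)
  fit <- tempotron_train(corp$patterns, corp$labels, cfg)
  expect_lte(fit$epochs_run, 10L)
  preds <- vapply(corp$patterns,
                  function(p) tempotron_classify(p, fit)$category,
                  character(1))
  expect_equal(mean(preds == corp$labels), 1)
})

test_that("voting counts fires and falls back to peak potentials", {
  corp <- separable_patterns(10)
  cfg <- tempotron_config(seed = 17)
  fit <- tempotron_train(corp$patterns, corp$labels, cfg)
  dec <- tempotron_classify(corp$patterns[[1]], fit)
  expect_equal(dec$category, "a")
  expect_equal(sum(dec$votes), sum(dec$fired))

  # zero-fire fallback: empty pattern fires nothing, falls back to the
  # category with the larger summed (flat) peak potential - deterministic
  empty <- peaks_to_spikes(peak_set(NULL, 40, 40))
  d0 <- tempotron_classify(empty, fit)
  expect_equal(sum(d0$fired), 0L)
  expect_equal(d0$category,
               names(which.max(tapply(d0$peak_potential,
                                      fit$neuron_category, sum))))
  expect_identical(d0$category, tempotron_classify(empty, fit)$category)

  expect_error(tempotron_train(list(), factor(character(0))), "empty")
})

test_that("jittered template patterns are recognized out of sample", {
  # two synthetic peak templates + address jitter; train on half, test held out
  set.seed(81)
  template <- list(
    a = data.frame(s = 3L, theta = 0, x = c(5, 10, 15, 20, 25),
                   y = c(5, 8, 11, 14, 17), value = c(1, .9, .8, .7, .6)),
    b = data.frame(s = 5L, theta = 90, x = c(30, 32, 34, 36, 38),
                   y = c(30, 27, 24, 21, 18), value = c(1, .9, .8, .7, .6)))
  jitter_pat <- function(tpl) {
    d <- tpl
    d$x <- pmin(pmax(d$x + sample(-1:1, nrow(d), TRUE), 0), 39)
    d$y <- pmin(pmax(d$y + sample(-1:1, nrow(d), TRUE), 0), 39)
    d$value <- pmax(d$value + rnorm(nrow(d), 0, 0.05), 0.1)
    peaks_to_spikes(peak_set(d, 40, 40))
  }
  pats <- c(replicate(30, jitter_pat(template$a), simplify = FALSE),
            replicate(30, jitter_pat(template$b), simplify = FALSE))
  labs <- rep(c("a", "b"), each = 30)
  tr_idx <- c(1:20, 31:50)
  fit <- tempotron_train(pats[tr_idx], labs[tr_idx],
                         tempotron_config(seed = 23))
  held <- setdiff(seq_along(pats), tr_idx)
  preds <- vapply(pats[held], function(p) tempotron_classify(p, fit)$category,
                  character(1))
  expect_gt(mean(preds == labs[held]), 0.9)
})
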