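test_that("forced alphabet-size scenarios give closed-form entropies", {
  # rank-1 distance exactly 30 + identity calibration -> M_hat = 30
  toks <- make_fixed_distance_sequence(D = 30)
  ident <- make_power_calibration(1, 1, 0)
  eq <- estimate_entropy_equiprobable(symbol_sequence(toks), calib = ident,
                                      r = 1)
  expect_equal(eq$value, log2(30), tolerance = 1e-9)
  expect_equal(eq$M_hat, 30, tolerance = 1e-9)
  expect_equal(eq$rank_used, 1)
  expect_equal(eq$perplexity, 30, tolerance = 1e-6)

  # distance 4 -> M_hat = 4 -> 2 bits under the equiprobable model
  toks4 <- make_fixed_distance_sequence(D = 4)
  eq4 <- estimate_entropy_equiprobable(symbol_sequence(toks4), calib = ident,
                                       r = 1)
  expect_equal(eq4$value, 2, tolerance = 1e-9)

  # under a zml synthesis the same M_hat reproduces the model entropy
  zm <- estimate_entropy_model(symbol_sequence(toks), calib = ident,
                               family = "zml")
  expect_equal(zm$M_hat, 30, tolerance = 1e-9)
  expect_equal(zm$value, model_entropy(zml_model(30)), tolerance = 1e-9)
  expect_equal(zm$method, "zml_coincidence")
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(estimate_entropy_model("ab"), class = "zml_no_coincidence")
  # distance 2 -> M_hat = 1 under a shifted calibration: rejected
  shifted <- make_power_calibration(1, 1, -1)
  expect_error(estimate_entropy_equiprobable("aaaa", calib = shifted),
               class = "zml_estimate_error")
})

test_that("plug-in and Miller-Madow match hand-computed values", {
  expect_equal(plugin_entropy(c(1, 1, 1, 1))$value, 2)
  expect_equal(plugin_entropy(c(5))$value, 0)
  expect_equal(plugin_entropy(c(2, 1, 1))$value, 1.5)
  expect_error(plugin_entropy(c(0, 0)), class = "zml_estimate_error")

  expect_equal(miller_madow_entropy(c(1, 1))$value, 1 + 1 / (4 * log(2)),
               tolerance = 1e-12)
  expect_equal(miller_madow_entropy(c(7))$value, plugin_entropy(c(7))$value)
  # counts can come straight from a sequence
  expect_equal(plugin_entropy("aabb")$value, 1)
})

test_that("the bias correction shrinks the plug-in gap on uniform data", {
  # undersampled uniform source: plugin underestimates log2(M); the
  # Miller-Madow correction moves the mean estimate toward the truth
  M <- 30; N <- 1000; truth <- log2(M)
  d <- zml_model(M, "equiprobable")
  pl <- mm <- numeric(100)
  for (i in 1:100) {
    x <- sample_iid_sequence(d, N, seed = 500 + i)
    counts <- tabulate(x$tokens, M)
    pl[i] <- plugin_entropy(counts)$value
    mm[i] <- miller_madow_entropy(counts)$value
  }
  expect_lt(mean(pl), truth)                     # negative plug-in bias
  expect_lt(abs(mean(mm) - truth), abs(mean(pl) - truth))
})

test_that("perplexity is two to the entropy", {
  expect_equal(perplexity(0), 1)
  expect_equal(perplexity(1), 2)
  expect_equal(perplexity(log2(30)), 30, tolerance = 1e-12)
  est <- plugin_entropy(c(1, 1))
  expect_equal(est$perplexity, 2)
  expect_equal(perplexity(est), 2)
  expect_error(perplexity(-1), class = "zml_estimate_error")
})

test_that("equiprobable estimation recovers log2(M) from uniform streams", {
  d <- zml_model(20, "equiprobable")
  vals <- vapply(1:50, function(i) {
    x <- sample_iid_sequence(d, 1e4, seed = 700 + i)
    estimate_entropy_equiprobable(x)$value
  }, numeric(1))
  expect_lt(abs(mean(vals) - log2(20)), 0.05)

  # long-stream limit, single run
  x <- sample_iid_sequence(d, 1e6, seed = 42)
  expect_lt(abs(estimate_entropy_equiprobable(x)$value - log2(20)), 0.01)
})

test_that("model-based estimation converges on zml data", {
  d <- zml_model(30)
  x <- sample_iid_sequence(d, 1e6, seed = 11)
  est <- estimate_entropy_model(x)
  expect_lt(abs(est$value - model_entropy(d)), 0.005)
  expect_lt(abs(est$M_hat - 30), 0.6)
  expect_equal(est$rank_used, 1L)
  # entropy cannot exceed the log of the rounded support
  expect_lte(est$value, log2(round(est$M_hat)) + 1e-9)
})

test_that("multi-rank mode pools alphabet-size estimates by weight", {
  d <- zml_model(30)
  x <- sample_iid_sequence(d, 2e5, seed = 13)
  est <- estimate_entropy_model(x, ranks = 1:5)
  expect_equal(est$rank_used, 1:5)
  expect_lt(abs(est$M_hat - 30), 1.5)
  # ranks whose symbol never repeats are skipped, not fatal
  short <- symbol_sequence(c("a", "a", "a", "b", "a", "c"))
  est2 <- estimate_entropy_model(short, ranks = 1:3,
                                 calib = make_power_calibration(1, 1, 2,
                                                                family = "zml"))
  expect_true(any(grepl("skipped", est2$warnings)))
})

test_that("the combinatorial cap bounds the alphabet estimate", {
  d <- zml_model(30)
  x <- sample_iid_sequence(d, 5e4, seed = 17)
  est <- estimate_entropy_model(x, M_max = 10)
  expect_equal(est$M_hat, 10)
  expect_true(any(grepl("capped", est$warnings)))
  expect_equal(est$value, model_entropy(zml_model(10)))
})
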