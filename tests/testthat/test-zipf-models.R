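test_that("unconstrained model parameters follow the closed forms", {
  m2 <- zml_model(2)
  expect_equal(m2$alpha, log(3) / log(2), tolerance = 1e-12)
  expect_equal(m2$beta, 2 / 3, tolerance = 1e-12)

  # alpha decreases monotonically toward 1 as M grows
  alphas <- vapply(c(2, 5, 10, 100, 1e4, 1e6), function(M) zml_model(M)$alpha,
                   numeric(1))
  expect_true(all(diff(alphas) < 0))
  expect_gt(min(alphas), 1)
  expect_lt(alphas[length(alphas)] - 1, 1e-4)

  expect_error(zml_model(1), class = "zml_model_error")
})

test_that("all families normalize to one and decrease strictly in rank", {
  for (M in c(2, 3, 5, 10, 30, 100, 500)) {
    fams <- if (M >= 3) c("zml", "czml1", "czml2") else "zml"
    for (fam in fams) {
      d <- zml_model(M, fam)
      expect_lt(abs(sum(d$p) - 1), 1e-9)
      expect_true(all(diff(d$p) < 0))
      expect_true(all(d$p > 0))
    }
  }
})

test_that("constrained model I reflects branching M-1", {
  expect_equal(zml_model(3, "czml1")$alpha, 2, tolerance = 1e-12)  # log4/log2
  expect_equal(zml_model(3, "czml1")$beta, 2 / 3)
  expect_error(zml_model(2.9, "czml1"), class = "zml_model_error")
})

test_that("constraint ratio is >1, largest at small M, tending to 1", {
  curve <- alpha_ratio_curve(3:12)
  expect_equal(curve$ratio[1], log(3) / log(2), tolerance = 1e-12)
  expect_equal(curve$ratio[10], log(12) / log(11), tolerance = 1e-12)
  expect_true(all(curve$ratio > 1))
  expect_true(all(diff(curve$ratio) < 0))
  expect_lt(alpha_ratio_curve(1000)$ratio - 1, 1e-2)
  expect_error(alpha_ratio_curve(2), class = "zml_model_error")
})

test_that("continuation-branching family reduces to family I at B = M-1", {
  d1 <- zml_model(10, "czml1")
  d2 <- zml_model(10, "czml2", B = 9)
  expect_lt(max(abs(d1$p - d2$p)), 1e-12)

  # default branching is ceiling((M-1)/2)
  d <- zml_model(10, "czml2")
  expect_equal(d$B, 5)
  expect_equal(d$alpha, log(11) / log(5), tolerance = 1e-12)
  # the reduced lexicon steepens the rank decay relative to czml1
  expect_gt(d$alpha, d1$alpha)

  expect_error(zml_model(10, "czml2", B = 1), class = "zml_model_error")
  expect_error(zml_model(10, "czml2", B = 10), class = "zml_model_error")
})

test_that("word-space counts and normalization match the closed forms", {
  ws <- word_space(26, 5)
  expect_identical(ws$N_w, 26^5)          # 11,881,376 five-letter words
  expect_equal(ws$N_w, 11881376)
  expect_equal(ws$gamma_w, 27^2 / 26, tolerance = 1e-12)
  expect_identical(word_space(26, 2)$N_w, 676)   # the bigram table size

  expect_equal(word_space(3, 2, "czml1")$N_w, 6)
})

test_that("constrained word counts agree with exhaustive enumeration", {
  for (M in 2:5) for (L in 1:5) {
    expect_equal(word_space(M, L, if (M >= 3) "czml1" else "zml")$N_w,
                 if (M >= 3) oracle_count_no_adjacent(M, L) else M^L,
                 info = sprintf("M=%d L=%d", M, L))
  }
})

test_that("word-space probability series conserve total mass", {
  for (M in c(2, 5, 26, 50)) {
    expect_lt(abs(word_space_series(M) - 1), 1e-9)
    if (M >= 3) {
      expect_lt(abs(word_space_series(M, "czml1") - 1), 1e-9)
      expect_lt(abs(word_space_series(M, "czml2") - 1), 1e-9)
    }
  }
})

test_that("model entropy matches independent direct-summation oracles", {
  expect_equal(model_entropy(zml_model(30, "equiprobable")), log2(30),
               tolerance = 1e-12)
  expect_equal(model_entropy(c(1)), 0)
  expect_equal(model_entropy(zml_model(30)),
               oracle_entropy_bits(oracle_zml_pmf(30)), tolerance = 1e-12)
  expect_equal(model_entropy(zml_model(12, "czml1")),
               oracle_entropy_bits(oracle_zml_pmf(12, branching = 11)),
               tolerance = 1e-12)
})

test_that("large alphabets approach the pure Zipf 1/r tail", {
  d <- zml_model(1e5)
  # deep in the rank tail the offset beta is negligible: p(r)/p(2r) -> 2^alpha
  expect_equal(d$p[1000] / d$p[2000], 2^d$alpha, tolerance = 1e-3)
  expect_lt(d$alpha - 1, 1e-4)
})

test_that("large-support rank sums agree with dense summation", {
  d <- zml_model(2.9e5)  # dense path
  s <- zmlentropy:::zml_rank_sums(d$support, d$alpha, d$beta)
  H_analytic <- (d$alpha * s$T / s$kappa + log(s$kappa)) / log(2)
  expect_equal(H_analytic, model_entropy(d), tolerance = 1e-9)

  # forced approximate path at a support just above the dense cutoff
  S <- 4e5; al <- 1.02; be <- 0.95
  u <- seq_len(S) + be; w <- u^(-al)
  appr <- zmlentropy:::zml_rank_sums(S, al, be)
  expect_equal(appr$kappa, sum(w), tolerance = 1e-7)
  expect_equal(appr$T, sum(w * log(u)), tolerance = 1e-7)

  # very large models still yield finite, ordered quantities
  big <- zml_model(1e12)
  expect_true(is.finite(model_entropy(big)))
  expect_gt(model_entropy(big), model_entropy(zml_model(1e6)))
})

test_that("non-integer alphabet sizes use a rounded support", {
  d <- zml_model(29.4)
  expect_equal(d$support, 29L)
  expect_equal(zml_model(29.6)$support, 30L)
  expect_lt(abs(sum(d$p) - 1), 1e-9)
})
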