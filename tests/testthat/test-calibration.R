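test_that("distance ensembles match the coincidence expectation", {
  ens <- simulate_distance_ensemble("equiprobable", m_grid = 2, trials = 30,
                                    samples = 2000, seed = 1)
  # mean gap of either symbol in a fair binary stream: 1 + 1/0.5 = 3; the
  # *empirical rank-1* symbol is the majority one, slightly more frequent
  expect_lt(abs(ens$D_bar - 3), 3 * ens$sd / sqrt(ens$trials) + 0.1)
})

test_that("ensembles are deterministic given the seed and monotone in M", {
  a <- simulate_distance_ensemble("zml", m_grid = c(5, 10, 20), trials = 5,
                                  samples = 5000, seed = 9)
  b <- simulate_distance_ensemble("zml", m_grid = c(5, 10, 20), trials = 5,
                                  samples = 5000, seed = 9)
  expect_identical(a, b)
  expect_true(all(diff(a$D_bar) > 0))
})

test_that("noiseless power-law data is recovered to 1e-6", {
  D <- seq(2, 12, length.out = 15)
  ens <- data.frame(M = 2 * D^1.5 + 10, rank = 1L, D_bar = D, sd = 0,
                    trials = 1L)
  fit <- fit_forward_model(ens, fit = "power")
  m <- fit$models[["1"]]
  expect_equal(m$a, 2, tolerance = 1e-6)
  expect_equal(m$b, 1.5, tolerance = 1e-6)
  expect_equal(m$c, 10, tolerance = 1e-5)

  ident <- data.frame(M = D, rank = 1L, D_bar = D, sd = 0, trials = 1L)
  fid <- fit_forward_model(ident, fit = "power")$models[["1"]]
  expect_equal(fid$a, 1, tolerance = 1e-4)
  expect_equal(fid$b, 1, tolerance = 1e-4)
  expect_equal(abs(fid$c), 0, tolerance = 1e-4)
})

test_that("non-monotone ensembles are rejected with a diagnostic", {
  bad <- data.frame(M = c(5, 10, 20), rank = 1L, D_bar = c(3, 5, 4.5),
                    sd = 0, trials = 1L)
  expect_error(fit_forward_model(bad), class = "zml_nonmonotone_ensemble")
  few <- data.frame(M = c(5, 10), rank = 1L, D_bar = c(3, 5), sd = 0,
                    trials = 1L)
  expect_error(fit_forward_model(few), class = "zml_calibration_error")
})

test_that("forward and inverse predictions agree in closed form", {
  cal <- make_power_calibration(1, 1, 0)
  expect_equal(as.numeric(predict_M(cal, 30)), 30)
  expect_equal(predict_D(cal, 30), 30)

  cal2 <- make_power_calibration(2, 2, 1)
  expect_equal(predict_D(cal2, 9), 2)      # ((9-1)/2)^(1/2)
  for (D in c(2, 5, 20, 100))
    expect_equal(predict_D(cal2, as.numeric(predict_M(cal2, D))), D,
                 tolerance = 1e-6)
  expect_error(predict_D(cal2, 0.5), class = "zml_calibration_error")
  expect_error(predict_M(cal2, -1), class = "zml_calibration_error")
  expect_error(predict_M(cal2, 5, r = 2), class = "zml_calibration_error")
})

test_that("out-of-range distances are flagged as extrapolation", {
  cal <- make_power_calibration(1, 1, 0, valid = c(5, 50))
  expect_warning(m <- predict_M(cal, 2), "extrapolating")
  expect_true(attr(m, "extrapolated"))
  expect_equal(as.numeric(m), 2)
  expect_false(attr(suppressWarnings(predict_M(cal, 10)), "extrapolated"))
})

test_that("simulation-fitted calibration is self-consistent on its grid", {
  grid <- c(8, 12, 18, 27, 40, 60, 90)
  cal <- zml_calibrate("zml", m_grid = grid, trials = 20, samples = 4e4,
                       seed = 2)
  ens <- simulate_distance_ensemble("zml", m_grid = grid, trials = 20,
                                    samples = 4e4, seed = 2)
  mh <- vapply(seq_len(nrow(ens)), function(i)
    as.numeric(suppressWarnings(predict_M(cal, ens$D_bar[i], ens$rank[i]))),
    numeric(1))
  expect_lt(max(abs(mh - ens$M) / ens$M), 0.05)
})

test_that("calibration objects are reproducible byte for byte", {
  cfg <- list(m_grid = c(6, 12, 24), trials = 5, samples = 5000, seed = 31)
  a <- zml_calibrate("zml", m_grid = cfg$m_grid, trials = cfg$trials,
                     samples = cfg$samples, seed = cfg$seed)
  b <- zml_calibrate("zml", m_grid = cfg$m_grid, trials = cfg$trials,
                     samples = cfg$samples, seed = cfg$seed)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("polynomial fits invert numerically to the fitted curve", {
  grid <- c(6, 10, 16, 26, 42, 68)
  ens <- simulate_distance_ensemble("zml", m_grid = grid, trials = 10,
                                    samples = 2e4, seed = 4)
  cal <- fit_forward_model(ens, fit = "polynomial", degree = 3)
  expect_equal(cal$fit, "polynomial")
  for (D in range(ens$D_bar)) {
    M <- as.numeric(suppressWarnings(predict_M(cal, D)))
    expect_equal(suppressWarnings(predict_D(cal, M)), D, tolerance = 1e-5)
  }
})

test_that("analytic calibration inverts the exact distance curve", {
  cal <- analytic_calibration("zml")
  for (M in c(4, 30, 200, 5000)) {
    D <- predict_D(cal, M, 1)
    expect_equal(D, 1 + 1 / zmlentropy:::prob_of_rank(zml_model(M), 1),
                 tolerance = 1e-12)
    expect_equal(as.numeric(predict_M(cal, D, 1)), M, tolerance = 1e-6)
  }
  # equiprobable closed form
  eq <- analytic_calibration("equiprobable")
  expect_equal(predict_D(eq, 30), 31)
  expect_equal(as.numeric(predict_M(eq, 31)), 30)
  # higher ranks work without a refit
  expect_equal(as.numeric(predict_M(cal, predict_D(cal, 50, 3), 3)), 50,
               tolerance = 1e-6)
})

test_that("calibrations survive a JSON round trip", {
  f <- withr::local_tempfile(fileext = ".json")
  cal <- zml_calibrate("zml", m_grid = c(6, 12, 24), trials = 4,
                       samples = 4000, seed = 5)
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(back$fit, cal$fit)
  m0 <- cal$models[["1"]]; m1 <- back$models[["1"]]
  expect_equal(m1$a, m0$a, tolerance = 1e-12)
  expect_equal(m1$b, m0$b, tolerance = 1e-12)
  expect_equal(m1$c, m0$c, tolerance = 1e-12)
  expect_equal(as.numeric(predict_M(back, 6)), as.numeric(predict_M(cal, 6)),
               tolerance = 1e-10)
})

test_that("fan of per-rank curves: one increasing model per rank", {
  ens <- simulate_distance_ensemble("zml", m_grid = c(12, 20, 34, 56, 90),
                                    ranks = 1:3, trials = 10, samples = 4e4,
                                    seed = 6)
  cal <- fit_forward_model(ens)
  expect_setequal(names(cal$models), c("1", "2", "3"))
  for (r in 1:3) {
    m <- cal$models[[as.character(r)]]
    expect_gt(m$a, 0); expect_gt(m$b, 0)   # strictly increasing forward map
    D <- seq(m$valid_range[1], m$valid_range[2], length.out = 20)
    expect_true(all(diff(suppressWarnings(predict_M(cal, D, r))) > 0))
  }
})
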