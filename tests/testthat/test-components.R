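test_that("Gaussian peak: mode, half-maximum and integral identities", {
  x <- seq(1, 400)
  expect_identical(eval_gauss(100, 150, 4, 150), 100)
  expect_equal(sum(eval_gauss(100, 150, 4, x)), 100 * 4 * sqrt(2 * pi),
               tolerance = 1e-6)
  hwhm <- 4 * sqrt(2 * log(2))
  expect_equal(eval_gauss(100, 150, 4, 150 + hwhm), 50, tolerance = 1e-10)
  expect_equal(eval_gauss(100, 150, 4, 150 - hwhm), 50, tolerance = 1e-10)
})

test_that("single-cut debris: delta histogram, zero histogram, tail behavior", {
  h <- numeric(256); h[100] <- 500
  hist <- make_hist(h)
  x <- 1:256
  sc <- eval_single_cut(0.01, hist, x)
  expect_equal(sc[x < 100], rep(0.01 * sqrt(100) * 500, sum(x < 100)))
  expect_equal(sc[x >= 100], rep(0, sum(x >= 100)))
  expect_equal(eval_single_cut(0.01, make_hist(numeric(256)), x), rep(0, 256))
})

test_that("multi-cut debris: k = 0 limit and damped single-term value", {
  h <- numeric(256); h[100] <- 500
  hist <- make_hist(h)
  x <- 1:256
  mc0 <- eval_multi_cut(0.02, 0, hist, x)
  tail_sum <- vapply(x, function(xx) sum(h[seq_along(h) > xx]), numeric(1))
  expect_equal(mc0, 0.02 * tail_sum)
  expect_equal(eval_multi_cut(0.01, 0.02, hist, 50), 0.01 * exp(-1) * 500)
  expect_equal(round(eval_multi_cut(0.01, 0.02, hist, 50), 4), 1.8394)
})

test_that("broadened rectangle: plateau, mirror symmetry and area", {
  x <- 1:1024
  br <- eval_broadened_rect(50, 200, 400, 10, x)
  expect_equal(br[300], 50, tolerance = 1e-10)
  d <- seq(0, 150, by = 0.5)
  expect_equal(eval_broadened_rect(50, 200, 400, 10, 200 + d),
               eval_broadened_rect(50, 200, 400, 10, 400 - d),
               tolerance = 1e-12)
  expect_equal(sum(br), 50 * (400 - 200), tolerance = 1e-3)
})

test_that("aggregate component: delta pair, impossible bins, non-negativity", {
  h <- numeric(256); h[100] <- 500
  hist <- make_hist(h)
  agg <- eval_aggregate(1e-6, hist, 1:256)
  expect_equal(agg[200], 1e-6 * sqrt(100 * 100) * 500 * 500)  # = 25
  expect_equal(agg[-200], rep(0, 255))
  expect_equal(eval_aggregate(5, random_hist(seed = 2), 1)[1], 0)
})

test_that("debris and aggregate curves match brute-force enumeration on random histograms", {
  for (s in 1:100) {
    hist <- random_hist(n_bins = 64, lambda = 30, seed = s)
    h <- hist$counts
    x <- 1:64
    expect_lt(max(abs(eval_single_cut(0.013, hist, x) - sc_brute(0.013, h, x))), 1e-9)
    expect_lt(max(abs(eval_multi_cut(0.02, 0.03, hist, x) - mc_brute(0.02, 0.03, h, x))), 1e-9)
    expect_lt(max(abs(eval_aggregate(1e-5, hist, x) - agg_brute(1e-5, h, x))), 1e-9)
  }
})

test_that("debris curves are non-increasing and all components non-negative", {
  for (s in 1:20) {
    hist <- random_hist(seed = s)
    x <- 1:64
    sc <- eval_single_cut(0.1, hist, x)
    mc <- eval_multi_cut(0.1, 0.05, hist, x)
    expect_true(all(diff(sc) <= 1e-12))
    expect_true(all(diff(mc) <= 1e-12))
    expect_true(all(sc >= 0) && all(mc >= 0))
    expect_true(all(eval_aggregate(2, hist, x) >= 0))
  }
  expect_true(all(eval_broadened_rect(10, 5, 40, 3, 1:64) >= -1e-12))
})

test_that("composite model is the exact sum of its components, with linkages applied", {
  p <- std_pipeline()
  hist <- p$hist; model <- p$model
  x <- seq_len(hist$n_bins)

  # degenerate composite: a single Gaussian model equals eval_gauss
  solo <- build_model(hist, list(sample = p$roles$sample, standard = NULL),
                      model_options(debris_kind = "none",
                                    include_g2_sample = FALSE,
                                    include_s_phase = FALSE,
                                    include_aggregates = FALSE))
  th <- c(A_sample = 500, mu_sample = 200, sigma_sample = 6)
  expect_equal(eval_model(solo, th, hist), eval_gauss(500, 200, 6, x))

  # full six-component model vs an independently coded sum
  set.seed(99)
  lo <- model$lower_bounds; hi <- model$upper_bounds
  hi_f <- pmin(hi, 2 * pmax(model$init_values, 1))
  theta <- lo + runif(length(lo)) * (hi_f - lo)
  names(theta) <- model$param_names
  theta["a_debris"] <- 0.012   # realistic amplitudes keep the comparison
  theta["a_agg"] <- 2.3e-6     # inside floating-point summation noise
  manual <- eval_gauss(theta["A_standard"], theta["mu_standard"], theta["sigma_standard"], x) +
    eval_gauss(theta["A_sample"], theta["mu_sample"], theta["sigma_sample"], x) +
    eval_gauss(theta["A_g2_sample"], 2 * theta["mu_sample"], 2 * theta["sigma_sample"], x) +
    sc_brute(theta["a_debris"], hist$counts, x) +
    eval_broadened_rect(theta["A_s"], theta["mu_sample"], 2 * theta["mu_sample"],
                        theta["sigma_s"], x) +
    agg_brute(theta["a_agg"], hist$counts, x)
  expect_lt(max(abs(eval_model(model, theta, hist) - manual)), 1e-8)

  # additivity against the package's own component evaluators is tighter
  own <- eval_gauss(theta["A_standard"], theta["mu_standard"], theta["sigma_standard"], x) +
    eval_gauss(theta["A_sample"], theta["mu_sample"], theta["sigma_sample"], x) +
    eval_gauss(theta["A_g2_sample"], 2 * theta["mu_sample"], 2 * theta["sigma_sample"], x) +
    eval_single_cut(theta["a_debris"], hist, x) +
    eval_broadened_rect(theta["A_s"], theta["mu_sample"], 2 * theta["mu_sample"],
                        theta["sigma_s"], x) +
    eval_aggregate(theta["a_agg"], hist, x)
  expect_lt(max(abs(eval_model(model, theta, hist) - own)), 1e-9)

  expect_error(eval_model(model, theta[-1], hist), class = "pf_contract_error")
})
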