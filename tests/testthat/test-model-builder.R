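two_peak_hist <- function() {
  x <- 1:256
  make_hist(round(eval_gauss(1000, 100, 3, x) + eval_gauss(500, 200, 3, x)))
}

test_that("peak detection finds two Gaussian peaks near their true positions", {
  pk <- detect_peaks(two_peak_hist())
  expect_equal(nrow(pk), 2L)
  pos <- sort(pk$position)
  expect_lte(abs(pos[1] - 100), 2)
  expect_lte(abs(pos[2] - 200), 2)
  # sorted by descending prominence: the taller peak first
  expect_equal(pk$position[1], pos[1])
})

test_that("pure debris shapes and flat histograms yield no peaks; a narrow spike yields one", {
  mono <- make_hist(round(3000 * exp(-0.05 * (1:256))))
  expect_equal(nrow(detect_peaks(mono)), 0L)

  spike <- numeric(256); spike[148:152] <- c(50, 400, 900, 400, 50)
  pk <- detect_peaks(make_hist(spike))
  expect_equal(nrow(pk), 1L)
  expect_lte(abs(pk$position - 150), 1)

  thin <- numeric(256); thin[100] <- 10  # fewer non-zero bins than the window
  expect_error(detect_peaks(make_hist(thin)), class = "pf_detection_error")
  expect_error(detect_peaks(make_hist(thin)), "insufficient signal")
})

test_that("maxima below the debris-exclusion floor are ignored", {
  h <- round(eval_gauss(5000, 5, 2, 1:256) + eval_gauss(300, 150, 4, 1:256))
  pk <- detect_peaks(make_hist(h))
  expect_true(all(pk$position > 10))
  expect_lte(abs(pk$position[1] - 150), 2)
})

test_that("role assignment honors position hints, labels, and candidate shortages", {
  pk <- detect_peaks(two_peak_hist())
  r <- assign_roles(pk, standard_selector = 100)
  expect_lte(abs(r$standard$position - 100), 2)
  expect_lte(abs(r$sample$position - 200), 2)

  # label rule: standard defaults to the lower-position peak
  r2 <- assign_roles(pk)
  expect_lt(r2$standard$position, r2$sample$position)
  r3 <- assign_roles(pk, standard_label = "B")
  expect_gt(r3$standard$position, r3$sample$position)

  one <- pk[1, , drop = FALSE]
  expect_error(assign_roles(one), class = "pf_assignment_error")
  expect_equal(assign_roles(one, has_standard = FALSE)$sample$position,
               one$position)
  expect_error(assign_roles(pk[0, , drop = FALSE]), class = "pf_assignment_error")
})

test_that("a shoulder close to a stronger peak is suppressed, leaving two assignable roles", {
  x <- 1:256
  h <- round(eval_gauss(1000, 100, 3, x) + eval_gauss(600, 200, 3, x) +
             eval_gauss(350, 207, 2, x))
  pk <- detect_peaks(make_hist(h))
  expect_equal(nrow(pk), 2L)
  r <- assign_roles(pk)
  expect_lte(abs(r$standard$position - 100), 2)
  expect_lte(abs(r$sample$position - 200), 3)
})

test_that("model assembly emits the requested components with consistent parameters", {
  hist <- two_peak_hist()
  roles <- assign_roles(detect_peaks(hist))

  # minimal model: one role, no optional components -> one Gaussian, 3 params
  m1 <- build_model(hist, list(sample = roles$sample, standard = NULL),
                    model_options(debris_kind = "none",
                                  include_g2_sample = FALSE,
                                  include_s_phase = FALSE,
                                  include_aggregates = FALSE))
  expect_equal(length(m1$components), 1L)
  expect_equal(m1$param_names, c("A_sample", "mu_sample", "sigma_sample"))

  # everything on (both G2 peaks): 7 components, 12 parameters
  m2 <- build_model(hist, roles,
                    model_options(include_g2_standard = TRUE))
  expect_equal(length(m2$components), 7L)
  expect_equal(length(m2$param_names), 12L)
  expect_setequal(m2$param_names,
                  c("A_standard", "mu_standard", "sigma_standard",
                    "A_sample", "mu_sample", "sigma_sample",
                    "A_g2_sample", "A_g2_standard",
                    "a_debris", "A_s", "sigma_s", "a_agg"))

  # S-phase without a sample G2 is a configuration error
  expect_error(build_model(hist, roles,
                           model_options(include_g2_sample = FALSE,
                                         include_s_phase = TRUE)),
               class = "pf_configuration_error")

  # variable linearity adds the bounded linearity parameter
  m3 <- build_model(hist, roles, model_options(linearity_mode = "variable"))
  expect_true("linearity" %in% m3$param_names)
  expect_equal(unname(m3$lower_bounds["linearity"]), 1.90)
  expect_equal(unname(m3$upper_bounds["linearity"]), 2.10)
})

test_that("initial values sit within bounds for randomized synthetic inputs, and building is deterministic", {
  n_ok <- 0
  for (s in 1:60) {
    set.seed(1000 + s)
    spec <- sim_spec(n_events = 4000,
                     mu_standard = runif(1, 250, 450),
                     mu_sample = runif(1, 700, 1100),
                     cv_sample = runif(1, 0.02, 0.06),
                     cv_standard = runif(1, 0.02, 0.06),
                     frac_standard = runif(1, 0.3, 0.6),
                     frac_debris = runif(1, 0.05, 0.25),
                     seed = 1000 + s)
    tab <- simulate_events(spec)
    hist <- bin_events(tab, "FL1", n_bins = 1024, range_max = 4096)
    pk <- tryCatch(detect_peaks(hist), error = function(e) NULL)
    if (is.null(pk) || nrow(pk) < 2) next
    roles <- assign_roles(pk)
    m <- build_model(hist, roles)
    expect_true(all(m$init_values >= m$lower_bounds - 1e-12))
    expect_true(all(m$init_values <= m$upper_bounds + 1e-12))
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 50)

  hist <- std_hist()
  roles <- assign_roles(detect_peaks(hist))
  m_a <- build_model(hist, roles)
  m_b <- build_model(hist, roles)
  expect_identical(m_a, m_b)
})
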