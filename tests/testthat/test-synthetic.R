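test_that("a pure two-population mixture reproduces its means and CVs (CLT oracle)", {
  spec <- sim_spec(n_events = 20000, frac_debris = 0, frac_aggregate = 0,
                   frac_g2 = 0, frac_s = 0, frac_standard = 0.5, seed = 1)
  tab <- simulate_events(spec)
  v <- tab$events[, "FL1"]
  truth <- attr(tab, "truth")
  expect_equal(sum(truth$class_counts), 20000L)
  expect_equal(sum(truth$class_counts[c("standard_g1", "sample_g1")]), 20000L)

  # split at the valley between the two G1 peaks
  std <- v[v < 600]; smp <- v[v >= 600]
  se_std <- sd(std) / sqrt(length(std))
  se_smp <- sd(smp) / sqrt(length(smp))
  expect_lt(abs(mean(std) - 400), 3 * se_std)
  expect_lt(abs(mean(smp) - 800), 3 * se_smp)

  # empirical CV converges to the spec CV
  cv_se <- 0.03 / sqrt(2 * (length(smp) - 1))
  expect_lt(abs(sd(smp) / mean(smp) - 0.03), 3 * cv_se)
})

test_that("simulation edge cases: empty run, exact class-count conservation, invariants", {
  empty <- simulate_events(sim_spec(n_events = 0, seed = 9))
  expect_equal(empty$n_events, 0L)
  expect_equal(sum(attr(empty, "truth")$class_counts), 0L)

  tab <- simulate_events(sim_spec(n_events = 5000, seed = 4))
  expect_equal(sum(attr(tab, "truth")$class_counts), 5000L)
  expect_true(all(is.finite(tab$events)))
  expect_true(all(tab$events >= 0))

  expect_error(sim_spec(frac_debris = 0.4, frac_aggregate = 0.2),
               class = "pf_parameter_error")
  expect_error(sim_spec(cv_sample = 0.5), class = "pf_parameter_error")
})

test_that("simulation is bitwise deterministic for a fixed seed and leaves the caller's RNG alone", {
  a <- standard_fixture()
  b <- standard_fixture()
  expect_identical(a$events, b$events)
  expect_identical(attr(a, "truth")$class_counts, attr(b, "truth")$class_counts)

  set.seed(77)
  before <- runif(5)
  set.seed(77)
  invisible(simulate_events(sim_spec(n_events = 100, seed = 1)))
  expect_identical(runif(5), before)
})

test_that("the frozen reference simulation matches its declared spec", {
  tab <- get_std_fixture()
  truth <- attr(tab, "truth")
  expect_equal(truth$spec$n_events, 20000L)
  expect_equal(truth$mu_sample, 800)
  expect_equal(truth$mu_standard, 400)
  expect_equal(truth$ratio, 2.0)
  expect_equal(truth$spec$cv_sample, 0.03)
  expect_equal(truth$spec$frac_debris, 0.15)
  expect_equal(truth$spec$seed, 1L)
  # class frequencies agree with the generative fractions
  cc <- truth$class_counts
  expect_equal(cc[["debris"]] / 20000, 0.15, tolerance = 0.05)
  expect_equal(cc[["aggregate"]] / 20000, 0.02, tolerance = 0.2)
})

test_that("the scatter channel is emitted and correlated with fluorescence", {
  tab <- standard_fixture(scatter_channel = TRUE)
  expect_equal(list_channels(tab), c("FL1", "SSC"))
  expect_gt(cor(tab$events[, "FL1"], tab$events[, "SSC"]), 0.8)
})

test_that("FCS fixtures round-trip and are readable by an independent parser", {
  tab <- simulate_events(sim_spec(n_events = 1000, seed = 6,
                                  scatter_channel = TRUE))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs_fixture(tab, path)
  back <- read_fcs(path)
  expect_equal(unname(back$events), unname(tab$events), tolerance = 1e-6)
  expect_equal(back$channel_names, tab$channel_names)

  # independent minimal FCS reader written against the published layout
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import struct, sys, re",
    "raw = open(sys.argv[1], 'rb').read()",
    "assert raw[:6] == b'FCS3.0'",
    "tb, te = int(raw[10:18]), int(raw[18:26])",
    "txt = raw[tb:te + 1].decode()",
    "d = txt[0]",
    "parts = txt[1:].split(d)",
    "kw = dict(zip(parts[0::2], parts[1::2]))",
    "par, tot = int(kw['$PAR']), int(kw['$TOT'])",
    "db, de = int(kw['$BEGINDATA']), int(kw['$ENDDATA'])",
    "vals = struct.unpack('<%df' % (par * tot), raw[db:de + 1])",
    "print(par, tot, ' '.join('%.4f' % v for v in vals[:4]))"
  ), script)
  out <- tryCatch(
    system2("python", c(script, path), stdout = TRUE, stderr = TRUE),
    warning = function(w) NULL, error = function(e) NULL)
  if (!is.null(out) && length(out) == 1) {
    got <- strsplit(trimws(out), " +")[[1]]
    expect_equal(as.integer(got[1]), 2L)
    expect_equal(as.integer(got[2]), 1000L)
    expect_equal(as.numeric(got[3:6]),
                 as.numeric(t(tab$events)[1:4]), tolerance = 1e-3)
  } else {
    succeed("independent parser unavailable; round-trip already verified above")
  }
})
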