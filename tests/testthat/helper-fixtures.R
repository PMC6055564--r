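# shared fixtures and independent oracles, all built in code at test time

# construct a histogram object directly from a counts vector
make_hist <- function(counts, bin_width = 4, channel = "FL1") {
  counts <- as.numeric(counts)
  structure(list(
    counts = counts,
    n_bins = length(counts),
    bin_width = bin_width,
    channel = channel,
    range_max = bin_width * length(counts),
    n_binned = sum(counts),
    underflow = 0L,
    overflow = 0L
  ), class = "fcs_histogram")
}

# random Poisson histogram; moderate counts keep summation-order noise tiny
random_hist <- function(n_bins = 64, lambda = 30, seed = 1) {
  set.seed(seed)
  make_hist(rpois(n_bins, lambda))
}

# --- brute-force component oracles (plain double loops, independent of R/) ---

sc_brute <- function(a, h, x) {
  n <- length(h)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- 0
    for (j in seq_len(n)) {
      if (j > x[i]) s <- s + sqrt(j) * h[j]
    }
    out[i] <- a * s
  }
  out
}

mc_brute <- function(a, k, h, x) {
  n <- length(h)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- 0
    for (j in seq_len(n)) {
      if (j > x[i]) s <- s + h[j]
    }
    out[i] <- a * exp(-k * x[i]) * s
  }
  out
}

agg_brute <- function(a, h, x) {
  n <- length(h)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- 0
    half <- floor(x[i] / 2)
    for (j in seq_len(max(half, 0))) {
      partner <- x[i] - j
      if (j >= 1 && partner >= 1 && partner <= n) {
        s <- s + sqrt(j * partner) * h[j] * h[partner]
      }
    }
    out[i] <- a * s
  }
  out
}

# the frozen reference simulation, memoized per test run
std_fixture_cache <- new.env(parent = emptyenv())
get_std_fixture <- function() {
  if (is.null(std_fixture_cache$tab)) std_fixture_cache$tab <- standard_fixture()
  std_fixture_cache$tab
}

# the analysis geometry for the reference simulation: bin width 4 keeps the
# G1 peaks at bins 100 and 200 with G2 / S phase / doublets on scale
std_hist <- function(tab = get_std_fixture()) {
  bin_events(tab, "FL1", n_bins = 1024, range_max = 4096)
}

std_pipeline <- function(tab = get_std_fixture()) {
  hist <- std_hist(tab)
  roles <- assign_roles(detect_peaks(hist))
  model <- build_model(hist, roles)
  list(hist = hist, roles = roles, model = model,
       fit = fit_histogram(model, hist))
}

std_run_config <- function(...) {
  run_config(channel = "FL1", n_bins = 1024L, range_max = 4096,
             standard_pg = 4.5, ...)
}
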