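# Model component families, all evaluated on the histogram's 1-based
# bin-index axis. Debris and aggregate components are histogram-dependent:
# they are computed from the observed counts H(j), not from the fitted curve,
# which makes each a fixed shape vector scaled linearly by its amplitude.

#' Gaussian nuclei peak
#'
#' \code{A * exp(-(x - mu)^2 / (2 * sigma^2))}: the model for a G1 or G2
#' population of nuclei.
#'
#' @param A Peak height (counts), \code{A >= 0}.
#' @param mu Peak mean (bin index, real-valued), \code{mu > 0}.
#' @param sigma Peak standard deviation (bins), \code{sigma > 0}.
#' @param x Bin-index vector to evaluate at.
#' @return Numeric vector of counts per bin.
#' @export
eval_gauss <- function(A, mu, sigma, x) {
  stopifnot(A >= 0, mu > 0, sigma > 0)
  A * exp(-(x - mu)^2 / (2 * sigma^2))
}

#' Single-cut debris component
#'
#' Models fragments of cut nuclei: every bin j of the observed histogram
#' contributes debris below it, weighted by \code{sqrt(j)}:
#' \code{SC(x) = a * sum_{j > x} sqrt(j) * H(j)}. \code{SC(N) = 0}.
#'
#' @param a Debris amplitude (dimensionless, \code{>= 0}).
#' @param hist An \code{fcs_histogram} supplying the observed counts H(j).
#' @param x Integer bin-index vector.
#' @return Numeric vector of counts per bin.
#' @export
eval_single_cut <- function(a, hist, x) {
  stopifnot(a >= 0, inherits(hist, "fcs_histogram"))
  h <- hist$counts
  n <- hist$n_bins
  w <- sqrt(seq_len(n)) * h
  # tail[j] = sum_{k >= j} w_k; SC(x) = a * tail[x + 1]
  tail_sum <- rev(cumsum(rev(w)))
  tail_sum <- c(tail_sum, 0)
  xi <- pmin(pmax(as.integer(round(x)), 0L), n)
  a * tail_sum[xi + 1L]
}

#' Multi-cut debris component
#'
#' Models repeatedly cut nuclei as an exponentially damped tail sum:
#' \code{MC(x) = a * exp(-k * x) * sum_{j > x} H(j)}. With \code{k = 0} it
#' reduces to the plain tail cumulative count.
#'
#' @param a Debris amplitude (\code{>= 0}).
#' @param k Decay rate per bin (\code{>= 0}).
#' @inheritParams eval_single_cut
#' @return Numeric vector of counts per bin.
#' @export
eval_multi_cut <- function(a, k, hist, x) {
  stopifnot(a >= 0, k >= 0, inherits(hist, "fcs_histogram"))
  h <- hist$counts
  n <- hist$n_bins
  tail_sum <- c(rev(cumsum(rev(h))), 0)
  xi <- pmin(pmax(as.integer(round(x)), 0L), n)
  a * exp(-k * x) * tail_sum[xi + 1L]
}

#' Broadened-rectangle S-phase component
#'
#' A rectangle spanning the interval between the G1 and G2 means with
#' error-function-smoothed edges:
#' \code{BR(x) = (A_s / 2) * (erf((x - x1) / (sqrt(2) sigma_s)) -
#' erf((x - x2) / (sqrt(2) sigma_s)))}. The plateau height is \code{A_s}.
#'
#' @param A_s Plateau height (counts, \code{>= 0}).
#' @param x1,x2 Left and right edges (bin index, \code{0 < x1 < x2}); in a
#'   full model they are tied to the sample G1 and G2 means.
#' @param sigma_s Edge-broadening standard deviation (bins, \code{> 0}).
#' @param x Bin-index vector.
#' @return Numeric vector of counts per bin.
#' @export
eval_broadened_rect <- function(A_s, x1, x2, sigma_s, x) {
  stopifnot(A_s >= 0, x1 > 0, x2 > x1, sigma_s > 0)
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  (A_s / 2) * (erf((x - x1) / (sqrt(2) * sigma_s)) -
               erf((x - x2) / (sqrt(2) * sigma_s)))
}

#' Continuous (doublet) aggregate component
#'
#' Models two nuclei passing the laser together: the signal at bin x is the
#' weighted sum over unordered bin pairs (j, x - j) of the observed histogram,
#' \code{Agg(x) = a * sum_{j = 1}^{floor(x/2)} sqrt(j (x - j)) H(j) H(x - j)},
#' each unordered pair counted once.
#'
#' @param a Aggregate amplitude (\code{>= 0}).
#' @inheritParams eval_single_cut
#' @return Numeric vector of counts per bin.
#' @export
eval_aggregate <- function(a, hist, x) {
  stopifnot(a >= 0, inherits(hist, "fcs_histogram"))
  h <- hist$counts
  n <- hist$n_bins
  g <- sqrt(seq_len(n)) * h  # sqrt(j (x-j)) factors as sqrt(j) * sqrt(x-j)
  xi <- as.integer(round(x))
  vapply(xi, function(xx) {
    half <- xx %/% 2L
    if (half < 1L) return(0)
    j <- seq_len(half)
    partner <- xx - j
    keep <- partner >= 1L & partner <= n & j <= n
    sum(g[j[keep]] * g[partner[keep]])
  }, numeric(1)) * a
}

#' Evaluate a composite histogram model
#'
#' Sums all active component curves at one parameter vector, applying the
#' linkage constraints first: each G2 mean is \code{L} times its G1 mean, the
#' G2 standard deviation is \code{L} times the G1 standard deviation, and the
#' S-phase edges are the sample G1 and G2 means. \code{L} is the linearity
#' (2.0 when fixed, a bounded free parameter in variable-linearity mode).
#'
#' @param model A \code{histogram_model} from [build_model()].
#' @param params Named or ordered numeric vector matching
#'   \code{model$param_names}.
#' @param hist The \code{fcs_histogram} the model was built for.
#' @param bases Optional precomputed unit-amplitude debris/aggregate shape
#'   vectors from [model_bases()]. These depend only on the observed
#'   histogram, so the fitting loop computes them once; the default recomputes
#'   them on every call with identical results.
#' @return Numeric vector of fitted counts per bin (length \code{hist$n_bins}).
#' @export
eval_model <- function(model, params, hist, bases = NULL) {
  stopifnot(inherits(model, "histogram_model"), inherits(hist, "fcs_histogram"))
  if (length(params) != length(model$param_names)) {
    pf_error(sprintf("parameter vector has length %d, model declares %d (%s)",
                     length(params), length(model$param_names),
                     paste(model$param_names, collapse = ", ")),
             "pf_contract_error")
  }
  bases <- bases %||% model_bases(model, hist)
  p <- stats::setNames(as.numeric(params), model$param_names)
  x <- seq_len(hist$n_bins)
  L <- if ("linearity" %in% model$param_names) p[["linearity"]] else model$linearity
  total <- numeric(hist$n_bins)
  for (comp in model$components) {
    total <- total + switch(comp$kind,
      g1 = eval_gauss(p[[comp$A]], p[[comp$mu]], p[[comp$sigma]], x),
      g2 = eval_gauss(p[[comp$A]], L * p[[comp$mu]], L * p[[comp$sigma]], x),
      single_cut = p[["a_debris"]] * bases$single_cut,
      multi_cut = p[["a_debris"]] * exp(-p[["k_decay"]] * x) * bases$mc_tail,
      s_phase = eval_broadened_rect(p[["A_s"]], p[[comp$mu]], L * p[[comp$mu]],
                                    p[["sigma_s"]], x),
      aggregate = p[["a_agg"]] * bases$aggregate,
      pf_error(sprintf("unknown component kind '%s'", comp$kind),
               "pf_contract_error")
    )
  }
  total
}

#' Precompute the histogram-dependent component shapes of a model
#'
#' The debris and aggregate components are fixed linear operators in their
#' amplitudes: their shape depends only on the observed histogram. This
#' returns those unit-amplitude shapes so repeated model evaluations (the
#' fitting loop) need not recompute them.
#'
#' @inheritParams eval_model
#' @return List with the unit shapes the model's components need:
#'   \code{single_cut}, \code{mc_tail} (multi-cut tail sum at \code{k = 0}),
#'   \code{aggregate}; absent components yield \code{NULL} entries.
#' @export
model_bases <- function(model, hist) {
  x <- seq_len(hist$n_bins)
  kinds <- vapply(model$components, `[[`, character(1), "kind")
  list(
    single_cut = if ("single_cut" %in% kinds) eval_single_cut(1, hist, x),
    mc_tail = if ("multi_cut" %in% kinds) eval_multi_cut(1, 0, hist, x),
    aggregate = if ("aggregate" %in% kinds) eval_aggregate(1, hist, x)
  )
}
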