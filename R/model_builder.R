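#' Detect candidate G1 peaks in a histogram
#'
#' Smooths the counts with a centered moving average, finds local maxima at
#' least \code{min_height_frac} of the global smoothed maximum, drops maxima
#' at or below the debris-exclusion floor (the lowest bins, where cut-fragment
#' debris dominates), and suppresses candidates within \code{2 * window} bins
#' of a stronger candidate. Candidates are returned sorted by descending
#' prominence.
#'
#' @param hist An \code{fcs_histogram}.
#' @param min_height_frac Minimum smoothed height as a fraction of the global
#'   smoothed maximum, in (0, 1). Default 0.10.
#' @param window Moving-average window (odd, >= 3). Default 5 bins.
#' @param floor_bins Debris-exclusion floor: candidates at or below this bin
#'   are ignored. Default scales the committed 10-of-256 floor to the
#'   histogram's resolution.
#' @return A data frame with columns \code{position} (bin index),
#'   \code{height} (smoothed counts), and \code{prominence}.
#' @export
detect_peaks <- function(hist, min_height_frac = 0.10, window = 5L,
                         floor_bins = NULL) {
  stopifnot(inherits(hist, "fcs_histogram"))
  if (min_height_frac <= 0 || min_height_frac >= 1) {
    pf_error("min_height_frac must be in (0, 1)", "pf_parameter_error")
  }
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    pf_error("window must be odd and >= 3", "pf_parameter_error")
  }
  if (sum(hist$counts > 0) < window) {
    pf_error("insufficient signal: fewer non-zero bins than the smoothing window",
             "pf_detection_error")
  }
  floor_bins <- floor_bins %||% round(10 * hist$n_bins / 256)
  n <- hist$n_bins
  sm <- as.numeric(stats::filter(hist$counts, rep(1 / window, window),
                                 sides = 2))
  # shrink the window at the edges instead of dropping to NA
  half <- window %/% 2L
  for (i in which(is.na(sm))) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sm[i] <- mean(hist$counts[lo:hi])
  }
  # the detection threshold is set by the signal region, not the debris floor
  gmax <- max(sm[seq.int(min(floor_bins + 1, n), n)])
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (sm[i] > sm[i - 1] && sm[i] >= sm[i + 1] &&
        sm[i] >= min_height_frac * gmax && i > floor_bins) {
      cand <- c(cand, i)
    }
  }
  if (!length(cand)) {
    return(data.frame(position = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  prominence <- vapply(cand, peak_prominence, numeric(1), sm = sm)
  ord <- order(-prominence, cand)
  cand <- cand[ord]; prominence <- prominence[ord]
  # non-maximum suppression: drop candidates close to a stronger one
  keep <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) {
    if (!keep[i]) next
    close_by <- abs(cand - cand[i]) <= 2L * window & seq_along(cand) > i
    keep[close_by] <- FALSE
  }
  data.frame(position = cand[keep], height = sm[cand[keep]],
             prominence = prominence[keep])
}

# topographic prominence of a local maximum of the smoothed curve:
# height above the higher of the two key saddles toward higher ground
peak_prominence <- function(i, sm) {
  n <- length(sm)
  left_min <- right_min <- 0
  j <- i
  lo <- sm[i]
  while (j > 1) {
    j <- j - 1
    lo <- min(lo, sm[j])
    if (sm[j] > sm[i]) break
  }
  left_min <- if (sm[j] > sm[i]) lo else min(sm[1:i])
  j <- i
  lo <- sm[i]
  while (j < n) {
    j <- j + 1
    lo <- min(lo, sm[j])
    if (sm[j] > sm[i]) break
  }
  right_min <- if (sm[j] > sm[i]) lo else min(sm[i:n])
  sm[i] - max(left_min, right_min)
}

#' Assign sample and internal-standard roles to detected peaks
#'
#' With no selector, the two most prominent candidates are taken; the
#' lower-position one is label A and the higher label B, and
#' \code{standard_label} says which label is the internal standard. With a
#' numeric position hint, the candidate nearest the hint becomes the standard
#' and the most prominent remaining candidate the sample. With
#' \code{has_standard = FALSE} only the most prominent candidate is used, as
#' the sample.
#'
#' @param peaks Data frame from [detect_peaks()].
#' @param standard_selector \code{NULL}, or a numeric expected bin position of
#'   the standard G1 peak.
#' @param standard_label \code{"A"} (standard is the lower-position peak, the
#'   default) or \code{"B"} (the higher), used when no position hint is given.
#' @param has_standard Is an internal standard present? Default \code{TRUE}.
#' @return List with \code{sample} and \code{standard} (each a one-row peak
#'   candidate, or \code{NULL} for a missing standard).
#' @export
assign_roles <- function(peaks, standard_selector = NULL,
                         standard_label = c("A", "B"), has_standard = TRUE) {
  standard_label <- match.arg(standard_label)
  if (nrow(peaks) < 1) {
    pf_error("no peaks detected; supply manual parameter overrides",
             "pf_assignment_error")
  }
  if (!has_standard) {
    return(list(sample = peaks[1, ], standard = NULL))
  }
  if (nrow(peaks) < 2) {
    pf_error(paste("fewer peak candidates than roles (sample + standard);",
                   "supply manual parameter overrides"),
             "pf_assignment_error")
  }
  if (is.null(standard_selector)) {
    top2 <- peaks[1:2, ]
    top2 <- top2[order(top2$position), ]  # row 1 = label A (lower), row 2 = B
    if (standard_label == "A") {
      list(sample = top2[2, ], standard = top2[1, ])
    } else {
      list(sample = top2[1, ], standard = top2[2, ])
    }
  } else {
    i_std <- which.min(abs(peaks$position - standard_selector))
    rest <- peaks[-i_std, , drop = FALSE]
    list(sample = rest[1, ], standard = peaks[i_std, ])
  }
}

#' Model-structure options
#'
#' @param debris_kind One of \code{"single_cut"}, \code{"multi_cut"},
#'   \code{"none"}.
#' @param include_g2_sample,include_g2_standard Add a linked G2 peak for the
#'   role. The standard's G2 is off by default (standards are usually
#'   G1-dominant, and in many pairings it would be collinear with the sample
#'   G1 peak).
#' @param include_s_phase Add the broadened-rectangle S-phase component
#'   (requires a sample role; spans sample G1 to sample G2 position).
#' @param include_aggregates Add the continuous doublet-aggregate component.
#' @param linearity_mode \code{"fixed"} (G2/G1 ratio pinned at 2.0) or
#'   \code{"variable"} (fitted within [1.90, 2.10] to absorb amplifier
#'   nonlinearity).
#' @return A \code{model_options} list.
#' @export
model_options <- function(debris_kind = c("single_cut", "multi_cut", "none"),
                          include_g2_sample = TRUE,
                          include_g2_standard = FALSE,
                          include_s_phase = TRUE,
                          include_aggregates = TRUE,
                          linearity_mode = c("fixed", "variable")) {
  structure(list(
    debris_kind = match.arg(debris_kind),
    include_g2_sample = isTRUE(include_g2_sample),
    include_g2_standard = isTRUE(include_g2_standard),
    include_s_phase = isTRUE(include_s_phase),
    include_aggregates = isTRUE(include_aggregates),
    linearity_mode = match.arg(linearity_mode)
  ), class = "model_options")
}

#' Assemble a histogram model with initial estimates and bounds
#'
#' Builds the composite model for one histogram: a Gaussian G1 peak per role,
#' optional linked G2 peaks, a debris component, an optional S phase tied to
#' the sample G1/G2 means, and an optional aggregate component. Initial
#' estimates come from the detected peak positions and heights (starting CV
#' 5\%); bounds keep the optimizer away from label switching and degenerate
#' collapses. The fit mask excludes the debris-floor bins and the top bin.
#'
#' @param hist An \code{fcs_histogram}.
#' @param roles Role assignment from [assign_roles()].
#' @param opts A [model_options()] list.
#' @param floor_bins Debris floor used for the fit mask; same default as
#'   [detect_peaks()].
#' @return A \code{histogram_model}: list with \code{components},
#'   \code{param_names}, \code{init_values}, \code{lower_bounds},
#'   \code{upper_bounds}, \code{linkages}, \code{fit_mask}, \code{linearity},
#'   \code{opts}.
#' @export
build_model <- function(hist, roles, opts = model_options(),
                        floor_bins = NULL) {
  stopifnot(inherits(hist, "fcs_histogram"))
  if (is.null(roles$sample)) {
    pf_error("a sample role is required", "pf_configuration_error")
  }
  if (opts$include_s_phase && !opts$include_g2_sample) {
    pf_error("S-phase requires a G2-capable sample role (include_g2_sample)",
             "pf_configuration_error")
  }
  floor_bins <- floor_bins %||% round(10 * hist$n_bins / 256)
  n <- hist$n_bins

  comps <- list()
  nm <- c(); init <- c(); lo <- c(); hi <- c()
  linkages <- list()
  add <- function(names, inits, lows, highs) {
    nm <<- c(nm, names); init <<- c(init, inits)
    lo <<- c(lo, lows); hi <<- c(hi, highs)
  }
  gauss_par <- function(role, peak) {
    mu0 <- as.numeric(peak$position)
    A0 <- as.numeric(peak$height)
    s0 <- 0.05 * mu0
    add(paste0(c("A_", "mu_", "sigma_"), role),
        c(A0, mu0, s0),
        c(0, 0.9 * mu0, 0.005 * mu0),
        c(Inf, 1.1 * mu0, 0.15 * mu0))
  }

  for (role in c("standard", "sample")) {
    peak <- roles[[role]]
    if (is.null(peak)) next
    comps[[length(comps) + 1]] <- list(kind = "g1", role = role,
                                       A = paste0("A_", role),
                                       mu = paste0("mu_", role),
                                       sigma = paste0("sigma_", role))
    gauss_par(role, peak)
    g2_on <- if (role == "sample") opts$include_g2_sample else opts$include_g2_standard
    if (g2_on) {
      comps[[length(comps) + 1]] <- list(kind = "g2", role = role,
                                         A = paste0("A_g2_", role),
                                         mu = paste0("mu_", role),
                                         sigma = paste0("sigma_", role))
      g2_pos <- min(round(2 * peak$position), n)
      sm_h <- hist$counts[g2_pos]
      add(paste0("A_g2_", role), max(0.05 * peak$height, sm_h * 0.5), 0, Inf)
      linkages[[length(linkages) + 1]] <-
        sprintf("mu_g2_%s = linearity * mu_%s; sigma_g2_%s = linearity * sigma_%s",
                role, role, role, role)
    }
  }

  included <- setdiff(seq_len(n), c(seq_len(floor_bins), n))
  if (opts$debris_kind != "none") {
    comps[[length(comps) + 1]] <- list(kind = opts$debris_kind)
    # amplitude init: mean observed counts over the lowest quartile of
    # included bins, divided by the unit-amplitude debris curve there
    low_q <- included[seq_len(max(1L, length(included) %/% 4L))]
    unit <- if (opts$debris_kind == "single_cut") {
      eval_single_cut(1, hist, low_q)
    } else {
      eval_multi_cut(1, 0.01, hist, low_q)
    }
    a0 <- mean(hist$counts[low_q]) / max(mean(unit), .Machine$double.eps)
    add("a_debris", min(max(a0, 0), 1e6), 0, 1e6)
    if (opts$debris_kind == "multi_cut") add("k_decay", 0.01, 0, 1)
  }
  if (opts$include_s_phase) {
    A_s0 <- 0.01 * as.numeric(roles$sample$height)
    s_mu <- as.numeric(roles$sample$position)
    add(c("A_s", "sigma_s"),
        c(A_s0, 0.05 * s_mu),
        c(0, 0.005 * s_mu),
        c(Inf, 0.15 * s_mu))
    comps[[length(comps) + 1]] <- list(kind = "s_phase", mu = "mu_sample")
    linkages[[length(linkages) + 1]] <-
      "s_phase: x1 = mu_sample; x2 = linearity * mu_sample"
  }
  if (opts$include_aggregates) {
    comps[[length(comps) + 1]] <- list(kind = "aggregate")
    add("a_agg", 1e-7, 0, 1e6)
  }
  if (opts$linearity_mode == "variable") {
    add("linearity", 2.0, 1.90, 2.10)
    linkages[[length(linkages) + 1]] <- "linearity fitted within [1.90, 2.10]"
  }

  fit_mask <- rep(FALSE, n)
  fit_mask[included] <- TRUE

  structure(list(
    components = comps,
    param_names = nm,
    init_values = stats::setNames(init, nm),
    lower_bounds = stats::setNames(lo, nm),
    upper_bounds = stats::setNames(hi, nm),
    linkages = linkages,
    fit_mask = fit_mask,
    linearity = 2.0,
    floor_bins = floor_bins,
    opts = opts
  ), class = "histogram_model")
}

#' @export
print.histogram_model <- function(x, ...) {
  kinds <- vapply(x$components, function(c) {
    if (!is.null(c$role)) paste(c$kind, c$role) else c$kind
  }, character(1))
  cat(sprintf("<histogram_model> %d components (%s), %d parameters\n",
              length(x$components), paste(kinds, collapse = ", "),
              length(x$param_names)))
  invisible(x)
}
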