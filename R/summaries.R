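#' Modeled nuclei count of a Gaussian peak
#'
#' The area under a Gaussian peak, \code{A * sigma * sqrt(2 * pi)}: the number
#' of nuclei the fitted component accounts for.
#'
#' @param A Peak height (counts).
#' @param sigma Peak standard deviation (bins).
#' @return Modeled nuclei count.
#' @export
peak_count <- function(A, sigma) {
  stopifnot(A >= 0, sigma > 0)
  A * sigma * sqrt(2 * pi)
}

#' Coefficient of variation of a peak, in percent
#'
#' \code{100 * sigma / mu}, the standard flow-cytometry peak-quality metric.
#'
#' @param mu Peak mean (bin index).
#' @param sigma Peak standard deviation (bins).
#' @return CV in percent.
#' @export
peak_cv <- function(mu, sigma) {
  stopifnot(mu > 0, sigma >= 0)
  100 * sigma / mu
}

#' Genome size from the peak ratio and the internal standard
#'
#' \code{ratio * standard_pg}: the sample G1 / standard G1 fluorescence ratio
#' times the standard's known DNA content gives the sample genome size in
#' pg/2C.
#'
#' @param ratio Sample G1 mean / standard G1 mean (dimensionless, > 0).
#' @param standard_pg DNA content of the internal standard (pg/2C, > 0).
#' @return Sample genome size (pg/2C).
#' @export
genome_size <- function(ratio, standard_pg) {
  stopifnot(ratio > 0, standard_pg > 0)
  ratio * standard_pg
}

#' Summarize a fitted histogram model
#'
#' Extracts the reported quantities from a converged fit: per-peak positions,
#' CVs and modeled nuclei counts, the total modeled nuclei (all Gaussian G1
#' and G2 components; debris, S phase, and aggregates are excluded), the
#' sample/standard G1 peak ratio, the residual chi-square, and the genome size
#' when the standard's DNA content is supplied.
#'
#' @param result A \code{fit_result}.
#' @param standard_pg DNA content of the internal standard (pg/2C), or
#'   \code{NA} when absent.
#' @param file Source file label for the summary row.
#' @return A \code{sample_summary}: list with \code{file}, \code{converged},
#'   \code{rcs}, \code{peaks} (data frame: component, role, mean, cv, count),
#'   \code{total_nuclei}, \code{ratio}, \code{genome_pg}, \code{gate_report},
#'   \code{message}.
#' @export
summarize_fit <- function(result, standard_pg = NA_real_, file = NA_character_) {
  stopifnot(inherits(result, "fit_result"))
  model <- result$model
  p <- result$params
  L <- if ("linearity" %in% model$param_names) p[["linearity"]] else model$linearity

  rows <- list()
  for (comp in model$components) {
    if (!comp$kind %in% c("g1", "g2")) next
    mu <- p[[comp$mu]]; sg <- p[[comp$sigma]]
    if (comp$kind == "g2") { mu <- L * mu; sg <- L * sg }
    rows[[length(rows) + 1]] <- data.frame(
      component = comp$kind, role = comp$role,
      mean = mu, cv = peak_cv(mu, sg), count = peak_count(p[[comp$A]], sg))
  }
  peaks <- do.call(rbind, rows)
  total_nuclei <- sum(peaks$count)

  has_sample <- any(peaks$component == "g1" & peaks$role == "sample")
  has_standard <- any(peaks$component == "g1" & peaks$role == "standard")
  if (!is.na(standard_pg) && !has_standard) {
    pf_error("standard_pg given but the model has no standard role",
             "pf_configuration_error")
  }
  ratio <- NA_real_
  if (has_sample && has_standard) {
    mu_s <- peaks$mean[peaks$component == "g1" & peaks$role == "sample"]
    mu_r <- peaks$mean[peaks$component == "g1" & peaks$role == "standard"]
    ratio <- mu_s / mu_r
  }
  genome_pg <- if (!is.na(ratio) && !is.na(standard_pg)) {
    genome_size(ratio, standard_pg)
  } else {
    NA_real_
  }

  structure(list(
    file = file,
    converged = result$converged,
    rcs = result$rcs,
    peaks = peaks,
    total_nuclei = total_nuclei,
    ratio = ratio,
    genome_pg = genome_pg,
    gate_report = attr(result$hist, "gate_report"),
    message = result$message %||% ""
  ), class = "sample_summary")
}

summary_row <- function(s) {
  g1 <- function(role, what) {
    i <- which(s$peaks$component == "g1" & s$peaks$role == role)
    if (length(i) == 1) s$peaks[[what]][i] else NA_real_
  }
  gate <- s$gate_report %||% list(retained = NA_integer_, excluded = NA_integer_)
  data.frame(
    file = s$file,
    converged = s$converged,
    rcs = s$rcs,
    sample_mean = g1("sample", "mean"),
    sample_cv = g1("sample", "cv"),
    sample_count = g1("sample", "count"),
    standard_mean = g1("standard", "mean"),
    standard_cv = g1("standard", "cv"),
    standard_count = g1("standard", "count"),
    total_nuclei = s$total_nuclei,
    ratio = s$ratio,
    genome_pg = s$genome_pg,
    gate_retained = gate$retained,
    gate_excluded = gate$excluded,
    message = s$message,
    stringsAsFactors = FALSE
  )
}

#' Write sample summaries to a CSV results table
#'
#' One row per input file, fixed column order, header always present.
#' Numeric fields are written with enough digits to round-trip to 6
#' significant figures.
#'
#' @param summaries List of \code{sample_summary} objects (at least one).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_results_csv <- function(summaries, path) {
  if (inherits(summaries, "sample_summary")) summaries <- list(summaries)
  if (!length(summaries)) {
    pf_error("at least one summary required", "pf_parameter_error")
  }
  df <- do.call(rbind, lapply(summaries, summary_row))
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "converged"
  for (j in which(num)) df[[j]] <- signif(df[[j]], 6)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> %s: %s, RCS %.3f\n", x$file,
              if (isTRUE(x$converged)) "converged" else "NOT converged", x$rcs))
  print(transform(x$peaks, mean = round(mean, 2), cv = round(cv, 2),
                  count = round(count, 1)))
  if (!is.na(x$ratio)) {
    cat(sprintf("  peak ratio (sample/standard): %.4f\n", x$ratio))
  }
  if (!is.na(x$genome_pg)) {
    cat(sprintf("  genome size: %.3f pg/2C\n", x$genome_pg))
  }
  invisible(x)
}

#' Plot a fitted histogram with its components
#'
#' Renders the observed histogram, the total fitted curve, and each component
#' curve in distinguishable styles, annotated with the RCS and the fitted peak
#' positions/CVs. A non-converged fit is still rendered, with a warning
#' banner.
#'
#' @param result A \code{fit_result}.
#' @param path Output PNG path.
#' @return \code{path}, invisibly.
#' @export
plot_fit <- function(result, path) {
  stopifnot(inherits(result, "fit_result"))
  model <- result$model
  hist <- result$hist
  x <- seq_len(hist$n_bins)
  p <- result$params
  L <- if ("linearity" %in% model$param_names) p[["linearity"]] else model$linearity

  comp_curves <- lapply(model$components, function(comp) {
    switch(comp$kind,
      g1 = eval_gauss(p[[comp$A]], p[[comp$mu]], p[[comp$sigma]], x),
      g2 = eval_gauss(p[[comp$A]], L * p[[comp$mu]], L * p[[comp$sigma]], x),
      single_cut = eval_single_cut(p[["a_debris"]], hist, x),
      multi_cut = eval_multi_cut(p[["a_debris"]], p[["k_decay"]], hist, x),
      s_phase = eval_broadened_rect(p[["A_s"]], p[[comp$mu]], L * p[[comp$mu]],
                                    p[["sigma_s"]], x),
      aggregate = eval_aggregate(p[["a_agg"]], hist, x))
  })
  labels <- vapply(model$components, function(comp) {
    if (!is.null(comp$role)) paste(comp$kind, comp$role) else comp$kind
  }, character(1))
  cols <- grDevices::hcl.colors(max(length(labels), 3), "Dark 3")

  grDevices::png(path, width = 1000, height = 700)
  on.exit(grDevices::dev.off())
  graphics::plot(x, hist$counts, type = "h", col = "grey70",
                 xlab = sprintf("%s (bin)", hist$channel), ylab = "Nuclei",
                 main = sprintf("RCS = %.3f", result$rcs))
  graphics::lines(x, result$fitted_curve, lwd = 2)
  for (i in seq_along(comp_curves)) {
    graphics::lines(x, comp_curves[[i]], col = cols[i], lty = 2)
  }
  for (comp in model$components) {
    if (comp$kind != "g1") next
    mu <- p[[comp$mu]]
    graphics::text(mu, max(hist$counts) * 0.95,
                   sprintf("%s\n%.1f (CV %.2f%%)", comp$role, mu,
                           peak_cv(mu, p[[comp$sigma]])), cex = 0.8)
  }
  graphics::legend("topright", legend = c("total fit", labels),
                   col = c("black", cols[seq_along(labels)]),
                   lty = c(1, rep(2, length(labels))), lwd = c(2, rep(1, length(labels))))
  if (!isTRUE(result$converged)) {
    graphics::mtext("WARNING: fit did not converge", col = "red", line = 0.5)
  }
  invisible(path)
}
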