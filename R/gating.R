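#' Define a polygon gate on two channels
#'
#' @param x_channel,y_channel Channel labels for the scatterplot axes.
#' @param vertices Two-column numeric matrix (or data frame) of at least three
#'   polygon vertices in order; the polygon is closed implicitly. A rectangle
#'   is the 4-vertex special case.
#' @return A \code{gate_spec} object.
#' @export
gate_spec <- function(x_channel, y_channel, vertices) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (nrow(vertices) < 3 || ncol(vertices) != 2) {
    pf_error("gate vertices must be >= 3 (x, y) pairs", "pf_parameter_error")
  }
  if (abs(polygon_area(vertices)) < .Machine$double.eps * max(abs(vertices), 1)^2) {
    pf_error("degenerate gate polygon (zero area)", "pf_parameter_error")
  }
  structure(list(x_channel = x_channel, y_channel = y_channel,
                 vertices = vertices), class = "gate_spec")
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2]) / 2
}

# even-odd point-in-polygon; points on the boundary count as inside
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  scale <- max(abs(v), 1)
  eps <- 1e-9 * scale
  j <- n
  for (i in seq_len(n)) {
    x1 <- v[j, 1]; y1 <- v[j, 2]
    x2 <- v[i, 1]; y2 <- v[i, 2]
    # boundary: zero cross product and inside the segment bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on_seg <- abs(cross) <= eps * sqrt(seg_len2 + 1) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | on_seg
    # even-odd crossing of the horizontal ray toward +x
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Gate an event table to a polygon region of a two-channel scatterplot
#'
#' Keeps exactly the events whose (x, y) intensities fall inside or on the
#' boundary of the gate polygon (even-odd rule; boundary points are retained
#' so the rule is deterministic). The input table is not modified.
#'
#' @param table An \code{event_table}.
#' @param gate A [gate_spec()].
#' @return The gated \code{event_table}, with a \code{gate_report} attribute:
#'   list with \code{retained} and \code{excluded} event counts.
#' @export
apply_gate <- function(table, gate) {
  stopifnot(inherits(table, "event_table"), inherits(gate, "gate_spec"))
  for (ch in c(gate$x_channel, gate$y_channel)) {
    if (!ch %in% table$channel_names) {
      pf_error(sprintf("unknown gate channel '%s'; available: %s", ch,
                       paste(table$channel_names, collapse = ", ")),
               "pf_lookup_error")
    }
  }
  px <- table$events[, match(gate$x_channel, table$channel_names)]
  py <- table$events[, match(gate$y_channel, table$channel_names)]
  keep <- points_in_polygon(px, py, gate$vertices)
  out <- table
  out$events <- table$events[keep, , drop = FALSE]
  out$n_events <- sum(keep)
  attr(out, "gate_report") <- list(retained = sum(keep),
                                   excluded = sum(!keep))
  out
}

#' Render a two-channel scatterplot with an optional gate overlay
#'
#' @param table An \code{event_table}.
#' @param gate A [gate_spec()], or \code{NULL} for no overlay.
#' @param path Output PNG path.
#' @param x_channel,y_channel Channels to plot; default to the gate's channels,
#'   or the first two channels when no gate is given.
#' @return \code{path}, invisibly.
#' @export
gate_scatter_plot <- function(table, gate = NULL, path,
                              x_channel = NULL, y_channel = NULL) {
  stopifnot(inherits(table, "event_table"))
  x_channel <- x_channel %||% (if (!is.null(gate)) gate$x_channel else table$channel_names[1])
  y_channel <- y_channel %||% (if (!is.null(gate)) gate$y_channel else table$channel_names[2])
  for (ch in c(x_channel, y_channel)) {
    if (!ch %in% table$channel_names) {
      pf_error(sprintf("unknown channel '%s'", ch), "pf_lookup_error")
    }
  }
  px <- table$events[, match(x_channel, table$channel_names)]
  py <- table$events[, match(y_channel, table$channel_names)]
  grDevices::png(path, width = 800, height = 800)
  on.exit(grDevices::dev.off())
  graphics::smoothScatter(px, py, xlab = x_channel, ylab = y_channel,
                          main = basename(table$source_path %||% ""))
  if (!is.null(gate)) {
    graphics::polygon(gate$vertices, border = "red", lwd = 2)
  }
  invisible(path)
}
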