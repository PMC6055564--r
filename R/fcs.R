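#' Read an FCS list-mode file into an event table
#'
#' Parses FCS 2.0, 3.0, and 3.1 files (list-mode, integer / float / double
#' data) and returns the raw per-event channel intensities with no
#' transformation applied. Only standard single-analysis list-mode layouts are
#' supported; compensation and log amplification are out of scope.
#'
#' @param path Path to an FCS file.
#' @param dataset_index Which dataset segment to read when the file holds
#'   several (chained via the \code{$NEXTDATA} keyword). Default 1, the first.
#' @return An object of class \code{event_table}: a list with \code{events}
#'   (numeric matrix, events x channels), \code{channel_names},
#'   \code{source_path}, \code{n_events}, and \code{keywords} (named character
#'   vector of the TEXT segment).
#' @seealso [write_fcs_fixture()] for the matching writer, [bin_events()].
#' @export
read_fcs <- function(path, dataset_index = 1L) {
  if (!file.exists(path)) {
    pf_error(sprintf("FCS file not found: '%s'", path), "pf_format_error")
  }
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 58) {
    pf_error(sprintf(
      "'%s' is not a valid FCS file: HEADER segment truncated (version keyword missing)",
      path), "pf_format_error")
  }
  if (dataset_index < 1) {
    pf_error("dataset_index must be >= 1", "pf_range_error")
  }

  offset <- 0L
  for (ds in seq_len(dataset_index)) {
    seg <- parse_fcs_dataset(raw, offset, path)
    if (ds == dataset_index) break
    nxt <- suppressWarnings(as.integer(seg$keywords["$NEXTDATA"]))
    if (is.na(nxt) || nxt == 0L) {
      pf_error(sprintf(
        "dataset_index %d out of range: '%s' holds %d dataset(s)",
        dataset_index, path, ds), "pf_range_error")
    }
    offset <- offset + nxt
  }

  events <- seg$events
  kw <- seg$keywords
  n_par <- ncol(events)
  ch <- character(n_par)
  for (i in seq_len(n_par)) {
    nm <- kw[sprintf("$P%dN", i)]
    if (is.na(nm) || !nzchar(nm)) nm <- kw[sprintf("$P%dS", i)]
    if (is.na(nm) || !nzchar(nm)) nm <- sprintf("P%d", i)
    ch[i] <- nm
  }
  colnames(events) <- ch
  structure(list(
    events = events,
    channel_names = ch,
    source_path = path,
    n_events = nrow(events),
    keywords = kw
  ), class = "event_table")
}

# parse one dataset segment starting at byte `offset` (0-based)
parse_fcs_dataset <- function(raw, offset, path) {
  hdr_raw <- raw[(offset + 1):(offset + 58)]
  if (any(hdr_raw > as.raw(0x7F)) || any(hdr_raw == as.raw(0))) {
    pf_error(sprintf("'%s': HEADER segment is not ASCII (version keyword)", path),
             "pf_format_error")
  }
  hdr <- rawToChar(hdr_raw)
  version <- substr(hdr, 1, 6)
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1")) {
    pf_error(sprintf(
      "'%s' is not a supported FCS file: header version keyword is '%s' (need FCS2.0/FCS3.0/FCS3.1)",
      path, version), "pf_format_error")
  }
  field <- function(k) {
    s <- substr(hdr, 11 + (k - 1) * 8, 10 + k * 8)
    v <- suppressWarnings(as.integer(trimws(s)))
    if (is.na(v)) 0L else v
  }
  text_beg <- field(1); text_end <- field(2)
  data_beg <- field(3); data_end <- field(4)
  if (text_beg <= 0 || text_end <= text_beg) {
    pf_error(sprintf(
      "'%s': invalid TEXT segment offsets in header (keyword TEXT begin/end)",
      path), "pf_format_error")
  }

  txt_raw <- raw[(offset + text_beg + 1):(offset + text_end + 1)]
  delim <- rawToChar(txt_raw[1])
  body <- tryCatch(rawToChar(txt_raw[-1]), error = function(e) {
    pf_error(sprintf("'%s': unreadable TEXT segment", path), "pf_format_error")
  })
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  parts <- parts[seq_len(length(parts) - length(parts) %% 2)]
  if (length(parts) < 2) {
    pf_error(sprintf("'%s': empty TEXT segment (no keywords)", path),
             "pf_format_error")
  }
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- trimws(parts[seq(2, length(parts), by = 2)])
  kw <- stats::setNames(vals, keys)

  kwi <- function(name) suppressWarnings(as.integer(kw[name]))
  if (data_beg == 0 || data_end == 0) {
    data_beg <- kwi("$BEGINDATA")
    data_end <- kwi("$ENDDATA")
  }
  if (is.na(data_beg) || is.na(data_end) || data_end < data_beg) {
    pf_error(sprintf("'%s': DATA segment offsets missing ($BEGINDATA/$ENDDATA)",
                     path), "pf_format_error")
  }

  n_par <- kwi("$PAR")
  n_tot <- kwi("$TOT")
  dtype <- kw["$DATATYPE"]
  mode <- kw["$MODE"]
  if (is.na(n_par) || n_par < 1) {
    pf_error(sprintf("'%s': missing or invalid $PAR keyword", path),
             "pf_format_error")
  }
  if (is.na(n_tot) || n_tot < 0) {
    pf_error(sprintf("'%s': missing or invalid $TOT keyword", path),
             "pf_format_error")
  }
  if (!is.na(mode) && mode != "L") {
    pf_error(sprintf("'%s': only list-mode data supported ($MODE = '%s')",
                     path, mode), "pf_format_error")
  }
  byteord <- kw["$BYTEORD"]
  endian <- if (!is.na(byteord) && substr(byteord, 1, 1) != "1") "big" else "little"

  data_raw <- raw[(offset + data_beg + 1):(offset + data_end + 1)]
  n_values <- n_par * n_tot
  if (n_tot == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = n_par)
    return(list(events = m, keywords = kw))
  }
  if (is.na(dtype)) {
    pf_error(sprintf("'%s': missing $DATATYPE keyword", path), "pf_format_error")
  }
  vals <- switch(dtype,
    "F" = readBin(data_raw, "numeric", n = n_values, size = 4, endian = endian),
    "D" = readBin(data_raw, "numeric", n = n_values, size = 8, endian = endian),
    "I" = {
      bits <- suppressWarnings(as.integer(kw["$P1B"]))
      if (is.na(bits)) {
        pf_error(sprintf("'%s': integer data but missing $P1B keyword", path),
                 "pf_format_error")
      }
      allb <- suppressWarnings(as.integer(kw[sprintf("$P%dB", seq_len(n_par))]))
      if (any(allb != bits, na.rm = TRUE)) {
        pf_error(sprintf("'%s': mixed $PnB widths not supported", path),
                 "pf_format_error")
      }
      v <- readBin(data_raw, "integer", n = n_values, size = bits / 8,
                   signed = bits > 16, endian = endian)
      # stored values are unsigned; undo two's-complement wrap for 8/16-bit
      if (bits <= 16) v[v < 0] <- v[v < 0] + 2^bits
      as.numeric(v)
    },
    pf_error(sprintf("'%s': unsupported $DATATYPE '%s'", path, dtype),
             "pf_format_error")
  )
  if (length(vals) < n_values || anyNA(vals)) {
    pf_error(sprintf("'%s': DATA segment shorter than $TOT x $PAR values", path),
             "pf_format_error")
  }
  m <- matrix(vals[seq_len(n_values)], nrow = n_tot, ncol = n_par, byrow = TRUE)
  if (any(!is.finite(m))) {
    pf_error(sprintf("'%s': non-finite intensities in DATA segment", path),
             "pf_format_error")
  }
  list(events = m, keywords = kw)
}

#' List the channels of an event table
#'
#' @param table An \code{event_table} from [read_fcs()] or [simulate_events()].
#' @return Character vector of channel labels in FCS parameter order.
#' @export
list_channels <- function(table) {
  stopifnot(inherits(table, "event_table"))
  table$channel_names
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events x %d channels (%s)\n", x$n_events,
              length(x$channel_names), paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  source: %s\n", x$source_path %||% "<in memory>"))
  invisible(x)
}

#' Write an event table as a minimal FCS 3.0 file
#'
#' Produces a standard-conforming single-dataset FCS 3.0 file (list mode,
#' 32-bit float data, little-endian) that [read_fcs()] and other FCS readers
#' parse back to an equal table. Intended for building test fixtures and for
#' exporting simulated data.
#'
#' @param table An \code{event_table} (at most 16 channels).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fcs_fixture <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  m <- table$events
  n_par <- ncol(m)
  if (n_par > 16) pf_error("at most 16 channels supported", "pf_parameter_error")
  n_tot <- nrow(m)

  rng <- function(j) {
    mx <- if (n_tot > 0) max(m[, j]) else 0
    max(2^ceiling(log2(max(mx, 1) + 1e-9)), 1024)
  }
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$NEXTDATA" = "0",
    "$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot)
  )
  for (j in seq_len(n_par)) {
    kw[sprintf("$P%dN", j)] <- table$channel_names[j]
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- format(rng(j), scientific = FALSE)
  }
  # fixed-width data offsets so TEXT length does not depend on their value
  kw["$BEGINDATA"] <- strrep("0", 10)
  kw["$ENDDATA"] <- strrep("0", 10)

  delim <- "/"
  build_text <- function(kw) paste0(delim, paste0(names(kw), delim, kw, delim, collapse = ""))
  text <- build_text(kw)
  text_beg <- 58L
  text_end <- text_beg + nchar(text) - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * n_par * n_tot - 1L
  if (n_tot == 0) data_end <- 0L
  kw["$BEGINDATA"] <- formatC(if (n_tot > 0) data_beg else 0L, width = 10, flag = "0")
  kw["$ENDDATA"] <- formatC(data_end, width = 10, flag = "0")
  text <- build_text(kw)
  stopifnot(text_end == text_beg + nchar(text) - 1L)

  hfield <- function(v) {
    # header offset fields hold 8 chars; larger offsets go to 0 per the standard
    if (v > 99999999) v <- 0L
    formatC(v, width = 8)
  }
  header <- paste0("FCS3.0", strrep(" ", 4),
                   hfield(text_beg), hfield(text_end),
                   hfield(if (n_tot > 0) data_beg else 0L),
                   hfield(if (n_tot > 0) data_end else 0L),
                   hfield(0L), hfield(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (n_tot > 0) {
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  }
  invisible(path)
}
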