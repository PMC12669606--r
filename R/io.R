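# Text file formats: '#'-prefixed key=value metadata headers followed by
# delimited columns. Diff-able, language-agnostic, round-trip safe.

SCHEMA_VERSION <- "1"

format_meta_value <- function(v) {
  if (is.null(v)) return("NA")
  if (is.numeric(v)) {
    paste(vapply(v, function(x) format(x, digits = 17), character(1)),
          collapse = ",")
  } else {
    paste(as.character(v), collapse = ",")
  }
}

parse_meta_value <- function(s) {
  if (identical(s, "TRUE")) return(TRUE)
  if (identical(s, "FALSE")) return(FALSE)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (length(parts) == 0) return(s)
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) {
    if (length(num) == 1) num else num
  } else if (identical(s, "NA")) {
    NULL
  } else {
    if (length(parts) == 1) parts else parts
  }
}

write_meta_header <- function(meta, con) {
  meta <- c(list(schema_version = SCHEMA_VERSION), meta)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  writeLines(sprintf("# %s=%s", names(meta),
                     vapply(meta, format_meta_value, character(1))), con)
}

read_meta_header <- function(path) {
  lines <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1)
    if (length(l) == 0 || !startsWith(l, "#")) break
    lines <- c(lines, l)
  }
  kv <- sub("^#\\s*", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- lapply(vals, parse_meta_value)
  names(meta) <- keys
  meta
}

#' Write a recording trace to a delimited text file
#'
#' Format: '#' key=value metadata lines, then tab-separated columns
#' `time_s`, `current_pA`.
#'
#' @param trace A [recording_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "recording_trace"))
  con <- file(path, "w")
  meta <- c(trace$meta, list(dt_s = trace$dt))
  write_meta_header(meta, con)
  close(con)
  n <- length(trace$current_pA)
  dt_tab <- data.table::data.table(
    time_s = (seq_len(n) - 1L) * trace$dt,
    current_pA = trace$current_pA
  )
  data.table::fwrite(dt_tab, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a recording trace written by [write_trace()]
#'
#' @param path Input file path; must carry a `voltage_mV` metadata line and
#'   monotone time stamps. Unknown metadata keys are preserved verbatim.
#' @return A [recording_trace()].
#' @export
read_trace <- function(path) {
  meta <- read_meta_header(path)
  if (is.null(meta$voltage_mV)) {
    err_format(sprintf("%s: missing mandatory metadata key voltage_mV", path))
  }
  d <- data.table::fread(path, sep = "\t", skip = "time_s")
  if (nrow(d) < 2) err_format("trace file has fewer than 2 samples")
  if (is.unsorted(d$time_s, strictly = TRUE)) {
    err_format("non-monotone time column")
  }
  dt <- meta$dt_s %||% (d$time_s[2] - d$time_s[1])
  meta$dt_s <- NULL
  meta$schema_version <- NULL
  recording_trace(d$current_pA, dt, meta)
}

#' Write an idealized event table as TSV
#'
#' @param events An `event_table` from [idealize_half_amplitude()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  meta <- c(attr(events, "meta"),
            list(dead_time_s = attr(events, "dead_time_s")))
  write_meta_header(meta, con)
  close(con)
  data.table::fwrite(as.data.frame(events), path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#' @param path Input file path.
#' @return An `event_table`.
#' @export
read_events <- function(path) {
  meta <- read_meta_header(path)
  d <- as.data.frame(data.table::fread(path, sep = "\t", skip = "state"))
  dead <- meta$dead_time_s
  meta$dead_time_s <- NULL
  meta$schema_version <- NULL
  structure(d, meta = meta, dead_time_s = dead,
            class = c("event_table", "data.frame"))
}

#' Write a crossing-event set as TSV
#' @param x A `crossing_events` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_crossings <- function(x, path) {
  stopifnot(inherits(x, "crossing_events"))
  con <- file(path, "w")
  write_meta_header(list(voltage_mV = x$voltage_mV,
                         duration_ns = x$duration_ns), con)
  close(con)
  data.table::fwrite(x$events, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a crossing-event set written by [write_crossings()]
#' @param path Input file path.
#' @return A `crossing_events` object.
#' @export
read_crossings <- function(path) {
  meta <- read_meta_header(path)
  d <- as.data.frame(data.table::fread(path, sep = "\t", skip = "time_ns"))
  if (nrow(d) == 0) {
    d <- data.frame(time_ns = numeric(0), species = character(0),
                    valence = integer(0), direction = integer(0))
  }
  crossing_events(d, meta$voltage_mV, meta$duration_ns)
}

#' Read a key=value run configuration file
#'
#' Lines of `key = value`; '#' comments and blank lines ignored. Values are
#' parsed as numbers where possible; comma-separated values become vectors.
#'
#' @param path Config file path.
#' @param known Character vector of accepted keys; unknown keys are an
#'   error (catches typos).
#' @return Named list.
#' @export
read_config <- function(path, known = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  cfg <- lapply(vals, parse_meta_value)
  names(cfg) <- keys
  if (!is.null(known)) {
    bad <- setdiff(keys, known)
    if (length(bad)) {
      err_config(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
    }
  }
  cfg
}
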