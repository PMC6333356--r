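#' Load sensor event or vitals records
#'
#' Reads a CSV or JSON-lines file of timestamped records, validates every row
#' against the documented schema, sorts valid records by home and timestamp
#' and collects malformed rows into a rejection report instead of silently
#' dropping them.
#'
#' Event files carry columns `home_id,timestamp,viewpoint,state,value`; vitals
#' files carry `home_id,timestamp,parameter,value`. JSON-lines files mirror
#' the same field names, one object per line. The format is inferred from the
#' file extension (`.jsonl`/`.json` vs anything else) unless given explicitly.
#'
#' @param path Path to the input file.
#' @param kind `"events"` or `"vitals"`.
#' @param format `"auto"` (default), `"csv"` or `"jsonl"`.
#' @return A list of class `dws_stream` with elements
#'   `records` (tibble of valid rows, time-sorted within home),
#'   `report` (tibble of rejected rows: `line`, `reason`),
#'   `kind`, and `empty` (TRUE when the file held no data rows, in which case
#'   a warning is also raised).
#' @export
load_records <- function(path, kind = c("events", "vitals"),
                         format = c("auto", "csv", "jsonl")) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  raw <- switch(format,
    csv = read_raw_csv(path, kind),
    jsonl = read_raw_jsonl(path, kind)
  )
  if (nrow(raw) == 0L) {
    warning("no data rows in ", path)
    return(new_stream(empty_records(kind), empty_report(), kind, empty = TRUE))
  }
  validate_records(raw, kind)
}

read_raw_csv <- function(path, kind) {
  cols <- if (kind == "events") {
    readr::cols(
      home_id = readr::col_character(),
      timestamp = readr::col_character(),
      viewpoint = readr::col_character(),
      state = readr::col_character(),
      value = readr::col_double()
    )
  } else {
    readr::cols(
      home_id = readr::col_character(),
      timestamp = readr::col_character(),
      parameter = readr::col_character(),
      value = readr::col_double()
    )
  }
  out <- readr::read_csv(path, col_types = cols, progress = FALSE)
  out$.line <- seq_len(nrow(out)) + 1L  # header is line 1
  out
}

read_raw_jsonl <- function(path, kind) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- if (kind == "events") {
    c("home_id", "timestamp", "viewpoint", "state", "value")
  } else {
    c("home_id", "timestamp", "parameter", "value")
  }
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
    out <- stats::setNames(as.list(rep(NA, length(fields))), fields)
    if (!is.null(rec)) {
      for (f in fields) if (!is.null(rec[[f]])) out[[f]] <- rec[[f]]
    }
    out$.line <- i
    out
  })
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

empty_records <- function(kind) {
  if (kind == "events") {
    tibble::tibble(
      home_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      viewpoint = character(), state = character(), value = numeric()
    )
  } else {
    tibble::tibble(
      home_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      parameter = character(), value = numeric()
    )
  }
}

empty_report <- function() tibble::tibble(line = integer(), reason = character())

new_stream <- function(records, report, kind, empty = FALSE) {
  structure(
    list(records = records, report = report, kind = kind, empty = empty),
    class = "dws_stream"
  )
}

#' @export
print.dws_stream <- function(x, ...) {
  cat(
    "<dws_stream> ", x$kind, ": ", nrow(x$records), " records, ",
    nrow(x$report), " rejected",
    if (x$empty) " (empty input)" else "", "\n",
    sep = ""
  )
  invisible(x)
}

# Parse timestamps without erroring on malformed strings: returns NA where
# the value matches neither "YYYY-MM-DD HH:MM:SS" nor ISO-T form.
parse_timestamp <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"), tz = "UTC")
  iso <- is.na(out)
  if (any(iso)) {
    out[iso] <- as.POSIXct(strptime(x[iso], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                           tz = "UTC")
  }
  out
}

validate_records <- function(raw, kind) {
  ts <- parse_timestamp(raw$timestamp)
  reasons <- rep(NA_character_, nrow(raw))
  bad <- function(cond, why) {
    ifelse(is.na(reasons) & cond, why, reasons)
  }
  reasons <- bad(is.na(raw$home_id) | !nzchar(as.character(raw$home_id)),
                 "missing home_id")
  reasons <- bad(is.na(ts), "unparseable timestamp")
  if (kind == "events") {
    reasons <- bad(!(raw$viewpoint %in% all_viewpoints()),
                   paste0("unknown viewpoint '", raw$viewpoint, "'"))
    reasons <- bad(!is.na(raw$state) & !(raw$state %in% c("on", "off")),
                   "state must be 'on' or 'off'")
    is_energy <- !is.na(raw$viewpoint) & raw$viewpoint == "energy_monitor"
    reasons <- bad(is_energy & (is.na(suppressWarnings(as.numeric(raw$value))) |
                                  suppressWarnings(as.numeric(raw$value)) < 0),
                   "energy_monitor requires a non-negative value")
  } else {
    val <- suppressWarnings(as.numeric(raw$value))
    reasons <- bad(!(raw$parameter %in% vital_parameters()),
                   paste0("unknown parameter '", raw$parameter, "'"))
    reasons <- bad(is.na(val) | !is.finite(val) | val < 0,
                   "value must be finite and non-negative")
  }
  keep <- is.na(reasons)
  report <- tibble::tibble(line = raw$.line[!keep], reason = reasons[!keep])
  ok <- raw[keep, , drop = FALSE]
  records <- if (kind == "events") {
    tibble::tibble(
      home_id = as.character(ok$home_id),
      timestamp = ts[keep],
      viewpoint = as.character(ok$viewpoint),
      state = ifelse(is.na(ok$state), "on", as.character(ok$state)),
      value = suppressWarnings(as.numeric(ok$value))
    )
  } else {
    tibble::tibble(
      home_id = as.character(ok$home_id),
      timestamp = ts[keep],
      parameter = as.character(ok$parameter),
      value = as.numeric(ok$value)
    )
  }
  records <- dplyr::arrange(records, .data$home_id, .data$timestamp)
  new_stream(records, report, kind, empty = FALSE)
}

#' Write event or vitals records
#'
#' Inverse of [load_records()]: writes a record tibble (or `dws_stream`) to
#' CSV or JSON-lines with the documented column set, timestamps formatted as
#' `YYYY-MM-DD HH:MM:SS`. A written file loads back to identical records.
#'
#' @param records Tibble of records, or a `dws_stream`.
#' @param path Output path; extension `.jsonl` selects JSON-lines.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  if (inherits(records, "dws_stream")) records <- records$records
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      row <- as.list(out[i, , drop = FALSE])
      row <- row[!vapply(row, function(v) is.na(v), logical(1))]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
    }
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' @importFrom dplyr .data
NULL
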