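# Plain-text file formats: map rasters, release schedules, time series.

#' Write a map to the plain-text raster dialect
#'
#' Header lines carry the cell geometry and capacities as `# key=value`
#' comments (`dx`, `dy`, `k_house`, `k_street`), followed by one map row per
#' line of whitespace-separated 0/1 tokens (row 1 = top).
#'
#' @param map An `aedes_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map_file <- function(map, path) {
  stopifnot(inherits(map, "aedes_map"))
  header <- sprintf("# %s=%.17g", c("dx", "dy", "k_house", "k_street"),
                    c(map$dx, map$dy, map$k_house, map$k_street))
  rows <- apply(map$cells, 1L, paste, collapse = " ")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a map from the plain-text raster dialect
#'
#' Accepts the format of [write_map_file()] (LF or CRLF line endings).
#' Header `# key=value` lines override the corresponding arguments; keys
#' absent from both are an error for geometry and default to the arguments
#' for capacities.
#'
#' @param path Input file path.
#' @param dx,dy,k_house,k_street Fallback values when the file header does
#'   not provide them.
#' @return An `aedes_map`.
#' @export
read_map_file <- function(path, dx = 5, dy = 5, k_house = 0.1475,
                          k_street = 0.0295) {
  if (!file.exists(path)) stop("map file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  vals <- list(dx = dx, dy = dy, k_house = k_house, k_street = k_street)
  data_lines <- character(0)
  data_lineno <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#", "", ln))
      if (grepl("=", body, fixed = TRUE)) {
        kv <- strsplit(body, "=", fixed = TRUE)[[1]]
        key <- trimws(kv[1])
        if (key %in% names(vals)) {
          v <- suppressWarnings(as.numeric(trimws(kv[2])))
          if (is.na(v)) stop("bad header value at line ", i, " of ", path)
          vals[[key]] <- v
        }
      }
      next
    }
    data_lines <- c(data_lines, ln)
    data_lineno <- c(data_lineno, i)
  }
  if (!length(data_lines)) stop("no map rows found in ", path)
  rows <- lapply(seq_along(data_lines), function(k) {
    toks <- strsplit(data_lines[[k]], "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(toks))
    if (any(is.na(v)) || !all(v %in% c(0, 1))) {
      stop("non-binary map token at line ", data_lineno[k], " of ", path)
    }
    v
  })
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop("ragged map row at line ", data_lineno[bad], " of ", path,
         " (expected ", widths[1], " tokens, found ", widths[bad], ")")
  }
  mat <- do.call(rbind, rows)
  map_from_matrix(mat, vals$dx, vals$dy, vals$k_house, vals$k_street)
}

#' Path of the committed synthetic city raster
#'
#' The 40 x 40 synthetic stand-in for the city neighborhood map (1072 house /
#' 528 street cells of 5 m x 5 m), shipped under `extdata`. Its capacities
#' are the defaults calibrated to a domain female equilibrium of 10000.
#'
#' @return File path.
#' @export
city_map_path <- function() {
  system.file("extdata", "city_map_synthetic.txt", package = "aedesgm",
              mustWork = TRUE)
}

#' Write a simulated time series as CSV
#'
#' Deterministic fixed-precision CSV with header
#' `day,E_total,A_total,F_total,M_total,G_total`.
#'
#' @param run An `aedes_run` or its `totals` data frame.
#' @param path Output path.
#' @param digits Significant digits kept (fixed formatting).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(run, path, digits = 6) {
  tt <- if (inherits(run, "aedes_run")) run$totals else run
  cols <- c("day", "E_total", "A_total", "F_total", "M_total", "G_total")
  if (!all(cols %in% names(tt))) stop("trajectory is missing required columns")
  body <- vapply(seq_len(nrow(tt)), function(i) {
    paste(c(format(tt$day[i], trim = TRUE),
            vapply(cols[-1], function(cn) {
              sprintf("%.*g", digits, tt[[cn]][i])
            }, character(1))), collapse = ",")
  }, character(1))
  writeLines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' Read a time-series CSV written by [write_timeseries()]
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Read a release schedule from a key-value text file
#'
#' Recognized keys: `kind` (localized/homogeneous), `period`, `start_day`,
#' and either `multiple` (of the domain female equilibrium) or `amount`
#' (absolute per event); optional `cells_file` with one `col row` pair per
#' line overrides the footprint.
#'
#' @param path Schedule file.
#' @param map Calibrated map the schedule applies to.
#' @param params Parameters (needed to resolve `multiple`).
#' @return An `aedes_schedule`.
#' @export
read_schedule_file <- function(path, map, params = default_parameters()) {
  kv <- read_keyvalue_file(path)
  kind <- kv$kind %||% "localized"
  period <- as.integer(kv$period %||% "1")
  start_day <- as.integer(kv$start_day %||% "0")
  footprint <- NULL
  if (!is.null(kv$cells_file)) {
    cf <- file.path(dirname(path), kv$cells_file)
    pairs <- utils::read.table(cf, col.names = c("col", "row"))
    footprint <- (pairs$col - 1L) * map$ny + pairs$row
  }
  if (!is.null(kv$amount)) {
    cells <- if (kind == "homogeneous") "all" else
      footprint %||% central_release_cells(map)
    release_schedule(cells, period = period,
                     amount_per_period = as.numeric(kv$amount),
                     start_day = start_day)
  } else {
    multiple <- as.numeric(kv$multiple %||% "11")
    make_release_schedule(kind, map, params, multiple = multiple,
                          period = period, start_day = start_day,
                          footprint = footprint)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
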