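# Record tables, station effort, detection histories and survey summaries.

#' Construct a camera-trap record table
#'
#' A record table holds one row per photographic event: the station where it
#' occurred, the species photographed, and the timestamp (minute resolution).
#'
#' @param station character vector of station labels.
#' @param species character vector of species labels.
#' @param timestamp `POSIXct` vector (or strings parseable as ISO 8601).
#' @return A `data.frame` of class `record_table` with columns
#'   `station`, `species`, `timestamp`, sorted by station, species, time.
#' @export
record_table <- function(station, species, timestamp) {
  if (!inherits(timestamp, "POSIXct")) {
    ts <- tryCatch(
      as.POSIXct(timestamp, tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                "%Y-%m-%d")),
      error = function(e) rep(as.POSIXct(NA), length(timestamp)))
  } else ts <- timestamp
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop("unparseable timestamp(s) at row(s): ", paste(utils::head(bad, 10), collapse = ", "))
  }
  out <- data.frame(station = as.character(station),
                    species = as.character(species),
                    timestamp = ts, stringsAsFactors = FALSE)
  out <- out[order(out$station, out$species, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("record_table", "data.frame")
  out
}

#' Construct a station effort table
#'
#' @param station station labels (unique).
#' @param deploy,retrieve deployment and retrieval dates (`Date` or string).
#' @param gaps optional list (one element per station) of two-column
#'   data.frames `start`,`end` giving inactive date ranges (camera failure,
#'   damage). Ranges are inclusive and must lie within the window.
#' @return `data.frame` of class `station_effort`.
#' @export
station_effort <- function(station, deploy, retrieve, gaps = NULL) {
  deploy <- as.Date(deploy); retrieve <- as.Date(retrieve)
  station <- as.character(station)
  if (anyDuplicated(station)) stop("duplicate station ids in effort table")
  if (any(deploy >= retrieve)) stop("deploy_date must precede retrieve_date")
  if (is.null(gaps)) gaps <- rep(list(NULL), length(station))
  stopifnot(length(gaps) == length(station))
  gaps <- lapply(seq_along(gaps), function(i) {
    g <- gaps[[i]]
    if (is.null(g) || nrow(g) == 0)
      return(data.frame(start = as.Date(character()), end = as.Date(character())))
    g <- data.frame(start = as.Date(g$start), end = as.Date(g$end))
    g <- g[order(g$start), , drop = FALSE]
    if (any(g$start > g$end)) stop("gap start after gap end (station ", station[i], ")")
    if (any(g$start < deploy[i]) || any(g$end > retrieve[i]))
      stop("inactive interval outside operational window (station ", station[i], ")")
    if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)]))
      stop("overlapping inactive intervals (station ", station[i], ")")
    g
  })
  out <- data.frame(station = station, deploy = deploy, retrieve = retrieve,
                    stringsAsFactors = FALSE)
  out$gaps <- I(gaps)
  class(out) <- c("station_effort", "data.frame")
  out
}

# Active calendar days for one effort row (inclusive window minus gap days).
.active_days <- function(efforts, i) {
  days <- seq(efforts$deploy[i], efforts$retrieve[i], by = "day")
  g <- efforts$gaps[[i]]
  if (!is.null(g) && nrow(g) > 0) {
    inactive <- unlist(lapply(seq_len(nrow(g)),
                              function(j) as.integer(seq(g$start[j], g$end[j], by = "day"))))
    days <- days[!(as.integer(days) %in% inactive)]
  }
  days
}

#' Total effective trap nights (active station-days)
#' @param efforts a `station_effort` table.
#' @return integer count of active station-days summed over stations.
#' @export
trap_nights <- function(efforts) {
  sum(vapply(seq_len(nrow(efforts)), function(i) length(.active_days(efforts, i)), 1L))
}

#' Read a camera-trap record table from delimited text
#'
#' Expects a header naming the station, species and timestamp columns
#' (ISO 8601 timestamps by default). When an effort table is supplied, rows
#' timestamped outside their station's operational window (or at unknown
#' stations) are rejected and reported.
#'
#' @param path file path.
#' @param efforts optional `station_effort` table used for validation.
#' @param station_col,species_col,timestamp_col column names in the file.
#' @param sep field separator.
#' @return a validated `record_table`; rejected rows (if any) are attached as
#'   attribute `"rejected"` and reported via warning.
#' @export
read_records <- function(path, efforts = NULL, station_col = "station",
                         species_col = "species", timestamp_col = "timestamp",
                         sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty record file: ", path)
  for (cc in c(station_col, species_col, timestamp_col))
    if (!cc %in% names(df)) stop("missing column '", cc, "' in ", path)
  rec <- record_table(df[[station_col]], df[[species_col]], df[[timestamp_col]])
  if (!is.null(efforts)) rec <- validate_records(rec, efforts)
  rec
}

#' Validate records against a station effort table
#'
#' @inheritParams read_records
#' @param records a `record_table`.
#' @return the accepted records; rejected rows in attribute `"rejected"`.
#' @export
validate_records <- function(records, efforts) {
  idx <- match(records$station, efforts$station)
  if (anyNA(idx)) {
    bad <- unique(records$station[is.na(idx)])
    stop("unknown station id(s): ", paste(bad, collapse = ", "))
  }
  day <- as.Date(records$timestamp)
  ok <- day >= efforts$deploy[idx] & day <= efforts$retrieve[idx]
  for (i in which(ok)) {           # drop records falling inside failure gaps
    g <- efforts$gaps[[idx[i]]]
    if (!is.null(g) && nrow(g) > 0 && any(day[i] >= g$start & day[i] <= g$end))
      ok[i] <- FALSE
  }
  if (any(!ok)) {
    warning(sum(!ok), " record(s) outside station operational windows rejected ",
            "(rows: ", paste(utils::head(which(!ok), 10), collapse = ", "), ")")
    rej <- records[!ok, , drop = FALSE]
    records <- records[ok, , drop = FALSE]
    rownames(records) <- NULL
    attr(records, "rejected") <- rej
  }
  records
}

#' Write a record table to CSV
#' @param records a `record_table`.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  out <- data.frame(station = records$station, species = records$species,
                    timestamp = format(records$timestamp, "%Y-%m-%dT%H:%M:%S"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a station effort table
#'
#' Format: `station,deploy,retrieve[,gap_start,gap_end]*` — each row may carry
#' zero or more trailing pairs of inactive-interval dates (ragged rows allowed).
#' @param path file path.
#' @return a `station_effort` table.
#' @export
read_efforts <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("empty effort file: ", path)
  rows <- strsplit(lines[-1], ",")
  st <- vapply(rows, `[`, "", 1)
  dep <- vapply(rows, `[`, "", 2)
  ret <- vapply(rows, `[`, "", 3)
  gaps <- lapply(rows, function(r) {
    extra <- r[-(1:3)]
    extra <- extra[nzchar(trimws(extra))]
    if (length(extra) == 0) return(NULL)
    if (length(extra) %% 2 != 0) stop("unpaired gap columns in effort file")
    data.frame(start = extra[seq(1, length(extra), 2)],
               end = extra[seq(2, length(extra), 2)])
  })
  station_effort(st, dep, ret, gaps)
}

#' Write a station effort table
#' @param efforts a `station_effort` table.
#' @param path output path.
#' @export
write_efforts <- function(efforts, path) {
  lines <- "station,deploy,retrieve"
  for (i in seq_len(nrow(efforts))) {
    g <- efforts$gaps[[i]]
    tail <- if (!is.null(g) && nrow(g) > 0)
      paste0(",", paste(t(cbind(format(g$start), format(g$end))), collapse = ","))
    else ""
    lines <- c(lines, paste0(efforts$station[i], ",", format(efforts$deploy[i]),
                             ",", format(efforts$retrieve[i]), tail))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Temporal independence filter
#'
#' Keeps, per station and species, only events at least `window_hours` after
#' the last *retained* event (greedy forward scan; the first event is always
#' kept, and a spacing of exactly `window_hours` is kept — "at least").
#'
#' @param records a `record_table`.
#' @param window_hours minimum gap in hours (default 1).
#' @return filtered `record_table`. Idempotent.
#' @export
independence_filter <- function(records, window_hours = 1) {
  if (window_hours < 0) stop("window_hours must be non-negative")
  if (nrow(records) == 0) return(records)
  key <- paste(records$station, records$species, sep = "\r")
  keep <- logical(nrow(records))
  for (k in unique(key)) {
    ii <- which(key == k)                # already time-sorted by construction
    last <- -Inf
    for (i in ii) {
      t <- as.numeric(records$timestamp[i])
      if (t - last >= window_hours * 3600) {
        keep[i] <- TRUE
        last <- t
      }
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("record_table", "data.frame")
  out
}

#' Build a detection history for one species
#'
#' Detections are collapsed into occasions of `occasion_length_days` days,
#' anchored per station at its deployment date. An entry is 1 if the species
#' was detected at least once in the occasion, 0 if the station was active
#' (for at least part of the occasion) with no detection, and `NA` if the
#' station was inactive for the entire occasion (including occasions past the
#' station's retrieval).
#'
#' @param records an independence-filtered `record_table`.
#' @param efforts a `station_effort` table.
#' @param species species label (absent species yields an all-zero history).
#' @param occasion_length_days occasion length in days (default 6).
#' @return object of class `detection_history`: list with `species`,
#'   `stations`, `occasion_length`, `n_occasions` and `matrix`
#'   (stations x occasions, values 0/1/NA).
#' @export
build_history <- function(records, efforts, species, occasion_length_days = 6) {
  stopifnot(occasion_length_days >= 1)
  n <- nrow(efforts)
  dur <- as.integer(efforts$retrieve - efforts$deploy) + 1L
  K <- as.integer(ceiling(max(dur) / occasion_length_days))
  Y <- matrix(NA_integer_, n, K,
              dimnames = list(efforts$station, paste0("occ_", seq_len(K))))
  for (i in seq_len(n)) {
    act <- as.integer(.active_days(efforts, i) - efforts$deploy[i]) + 1L
    if (length(act) == 0) {
      warning("station ", efforts$station[i], " has zero active days")
      next
    }
    occ_active <- unique((act - 1L) %/% occasion_length_days + 1L)
    Y[i, occ_active] <- 0L
  }
  rec <- records[records$species == species, , drop = FALSE]
  if (nrow(rec) > 0) {
    idx <- match(rec$station, efforts$station)
    if (anyNA(idx)) stop("record at unknown station")
    day <- as.integer(as.Date(rec$timestamp) - efforts$deploy[idx]) + 1L
    occ <- (day - 1L) %/% occasion_length_days + 1L
    ok <- day >= 1L & occ <= K
    for (j in which(ok)) Y[idx[j], occ[j]] <- 1L
  }
  structure(list(species = species, stations = efforts$station,
                 occasion_length = occasion_length_days,
                 n_occasions = K, matrix = Y),
            class = "detection_history")
}

#' Write / read a detection history as CSV
#'
#' One row per station, columns `occ_1..occ_K`, `NA` for missing occasions.
#' @param history a `detection_history`.
#' @param path file path.
#' @export
write_history <- function(history, path) {
  df <- data.frame(station = history$stations, history$matrix,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_history
#' @param species species label to attach on read.
#' @param occasion_length occasion length (days) to attach on read.
#' @export
read_history <- function(path, species = NA_character_, occasion_length = 6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  Y <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(Y) <- "integer"
  rownames(Y) <- df$station
  structure(list(species = species, stations = df$station,
                 occasion_length = occasion_length,
                 n_occasions = ncol(Y), matrix = Y),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  cat("Detection history:", x$species, "-", length(x$stations), "stations x",
      x$n_occasions, "occasions of", x$occasion_length, "days\n")
  cat("  detections:", sum(x$matrix == 1, na.rm = TRUE),
      " missing cells:", sum(is.na(x$matrix)), "\n")
  invisible(x)
}

#' Capture rate per 100 trap nights
#' @param n_events number of independent events.
#' @param trap_nights effective trap nights.
#' @return events per 100 trap nights.
#' @export
capture_rate <- function(n_events, trap_nights) {
  if (any(trap_nights <= 0)) stop("trap_nights must be positive")
  100 * n_events / trap_nights
}

#' Survey summary statistics
#'
#' Per species: number of independent events, capture rate (events per 100
#' effective trap nights) and naive occupancy (proportion of stations with at
#' least one detection). Records should already be independence-filtered.
#'
#' @param records a `record_table`.
#' @param efforts a `station_effort` table.
#' @param species optional species subset (default: all present).
#' @return data.frame of class `survey_summary` with one row per species.
#' @export
survey_summary <- function(records, efforts, species = NULL) {
  if (is.null(species)) species <- sort(unique(records$species))
  tn <- trap_nights(efforts)
  rows <- lapply(species, function(sp) {
    rec <- records[records$species == sp, , drop = FALSE]
    data.frame(species = sp, n_events = nrow(rec),
               trap_nights = tn,
               capture_rate = capture_rate(nrow(rec), tn),
               naive_occupancy = length(unique(rec$station)) / nrow(efforts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("survey_summary", "data.frame")
  out
}
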