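#' @importFrom stats aggregate
NULL

#' The closed species vocabulary
#'
#' The five species handled by the pipeline: two predators (jaguar, puma)
#' and three prey (white-tailed deer, collared peccary, calves). Any other
#' species label in an input file is rejected at load time.
#'
#' @export
SPECIES <- c("jaguar", "puma", "deer", "peccary", "calf")

## Row-tolerant ISO-8601 parser: unmatched rows stay NA so callers can
## report line numbers instead of aborting on the first bad row.
parse_datetime <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M")) {
    na <- is.na(out)
    if (!any(na)) break
    out[na] <- as.POSIXct(strptime(x[na], fmt, tz = "UTC"))
  }
  out
}

#' Read the camera-station table
#'
#' One row per station-year: station id, decimal-degree coordinates, a
#' road flag (1 = camera on a road, 0 = stream/trail) and the active
#' interval (`active_from`, `active_to`, ISO dates) for that year.
#' Paired cameras must already be merged under one station id.
#'
#' @param path CSV file with columns
#'   `station, lat, lon, road, year, active_from, active_to`.
#' @return a `camera_stations` data frame.
#' @export
read_station_table <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("station", "lat", "lon", "road", "year", "active_from", "active_to")
  miss <- setdiff(need, names(st))
  if (length(miss))
    stop("station table is missing columns: ", paste(miss, collapse = ", "))
  if (any(abs(st$lat) > 90) || any(abs(st$lon) > 180))
    stop("station coordinates out of range (|lat| <= 90, |lon| <= 180)")
  if (!all(st$road %in% c(0L, 1L)))
    stop("road flag must be 0 or 1")
  st$station <- as.character(st$station)
  st$active_from <- as.Date(st$active_from)
  st$active_to <- as.Date(st$active_to)
  if (any(is.na(st$active_from)) || any(is.na(st$active_to)))
    stop("unparseable active_from/active_to dates in station table")
  if (any(st$active_to < st$active_from))
    stop("active_to precedes active_from for some station-year")
  class(st) <- c("camera_stations", "data.frame")
  st
}

#' @export
print.camera_stations <- function(x, ...) {
  cat("<camera_stations> ", length(unique(x$station)), " stations, years ",
      paste(sort(unique(x$year)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

## Calendar dates a station was active in a given year (possibly several
## intervals); empty Date vector if none recorded.
active_days <- function(stations, station, year) {
  rows <- stations[stations$station == station & stations$year == year, ,
                   drop = FALSE]
  if (!nrow(rows)) return(as.Date(character(0)))
  days <- unlist(lapply(seq_len(nrow(rows)), function(i)
    seq(rows$active_from[i], rows$active_to[i], by = "day")))
  sort(unique(as.Date(days, origin = "1970-01-01")))
}

#' Load camera-trap photo records
#'
#' Reads a photo-record CSV (`station, species, datetime`), validates it
#' against the closed species vocabulary and the station table, and
#' returns a time-sorted record set. Unparseable datetimes are reported
#' with their line numbers; unknown stations and species are errors.
#'
#' @param path photo CSV with header columns `station, species, datetime`
#'   (ISO-8601 datetimes, minute resolution or finer).
#' @param station_table a `camera_stations` object from
#'   [read_station_table()], or a path to the station CSV.
#' @return a `photo_records` data frame with columns
#'   `station, species, datetime, year`; the station table is attached as
#'   attribute `"stations"`.
#' @export
load_photo_records <- function(path, station_table) {
  if (is.character(station_table))
    station_table <- read_station_table(station_table)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("station", "species", "datetime")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("photo CSV is missing columns: ", paste(miss, collapse = ", "))
  rec$station <- as.character(rec$station)
  bad_sp <- setdiff(unique(rec$species), SPECIES)
  if (length(bad_sp))
    stop("unknown species label(s): ", paste(bad_sp, collapse = ", "),
         " (vocabulary: ", paste(SPECIES, collapse = ", "), ")")
  dt <- suppressWarnings(parse_datetime(rec$datetime))
  if (any(is.na(dt))) {
    lines <- which(is.na(dt)) + 1L   # +1 for the header row
    stop("unparseable datetime on line(s): ",
         paste(utils::head(lines, 10L), collapse = ", "),
         if (length(lines) > 10L) " ..." else "")
  }
  rec$datetime <- dt
  bad_st <- setdiff(unique(rec$station), unique(station_table$station))
  if (length(bad_st))
    stop("station(s) absent from station table: ",
         paste(bad_st, collapse = ", "))
  rec$year <- as.integer(format(dt, "%Y"))
  rec <- rec[order(rec$station, rec$datetime), c("station", "species",
                                                 "datetime", "year")]
  rownames(rec) <- NULL
  attr(rec, "stations") <- station_table
  class(rec) <- c("photo_records", "data.frame")
  rec
}

#' @export
print.photo_records <- function(x, ...) {
  cat("<photo_records> ", nrow(x), " photos, ",
      length(unique(x$station)), " stations, species: ",
      paste(sort(unique(x$species)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

stations_of <- function(records) {
  st <- attr(records, "stations")
  if (is.null(st)) stop("photo records carry no station table")
  st
}

#' Pick the focal survey month
#'
#' Returns the calendar month with the most records of a species in a
#' year (the survey convention: the month with the most jaguar records
#' defines the single-season window). Ties are broken towards the
#' earliest month, deterministically.
#'
#' @param records a `photo_records` object.
#' @param species species label.
#' @param year survey year.
#' @return integer month (1-12).
#' @export
select_focal_month <- function(records, species, year) {
  sub <- records[records$species == species & records$year == year, ]
  if (!nrow(sub))
    stop("no ", species, " records in ", year, ": cannot pick a focal month")
  mo <- as.integer(format(sub$datetime, "%m"))
  counts <- tabulate(mo, nbins = 12L)
  which.max(counts)          # which.max takes the first (earliest) maximum
}

#' Collapse photos to daily detection/non-detection
#'
#' One photo or many on the same surveyed day count as a single
#' detection. Days outside a station's active calendar are masked `NA`
#' (not zero). Rows are all stations with at least one active day in the
#' month; columns are the calendar days of the focal month.
#'
#' @param records a `photo_records` object.
#' @param species species label.
#' @param year survey year.
#' @param month focal calendar month (1-12).
#' @return binary station x day matrix with `NA` for masked days.
#' @export
collapse_daily <- function(records, species, year, month) {
  stations <- stations_of(records)
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  last <- seq(first, by = "month", length.out = 2L)[2L] - 1L
  days <- seq(first, last, by = "day")
  ids <- sort(unique(stations$station[stations$year == year]))
  act <- lapply(ids, function(s) active_days(stations, s, year))
  keep <- vapply(act, function(d) any(d >= first & d <= last), logical(1))
  ids <- ids[keep]; act <- act[keep]
  m <- matrix(NA_integer_, length(ids), length(days),
              dimnames = list(ids, format(days, "%Y-%m-%d")))
  for (i in seq_along(ids)) m[i, days %in% act[[i]]] <- 0L
  sub <- records[records$species == species & records$year == year, ]
  if (nrow(sub)) {
    d <- as.Date(sub$datetime)
    inm <- d >= first & d <= last & sub$station %in% ids
    for (k in which(inm)) {
      i <- match(sub$station[k], ids); j <- match(d[k], days)
      if (!is.na(m[i, j])) m[i, j] <- 1L    # photos on masked days ignored
    }
  }
  m
}

#' Filter photos to independent activity events
#'
#' Applies the 1-h (by default) independence rule by a greedy forward
#' scan, separately within each station and species: a photo is kept iff
#' it falls at least `gap_hours` after the previously kept photo of the
#' same species at the same station. Idempotent.
#'
#' @param records a `photo_records` object.
#' @param species species label (or `NULL` for all species at once).
#' @param gap_hours independence gap in hours (default 1).
#' @return an `event_set` data frame (`species, station, datetime, year`),
#'   station table attached.
#' @export
filter_independent_events <- function(records, species = NULL, gap_hours = 1) {
  sub <- if (is.null(species)) records else
    records[records$species %in% species, ]
  sub <- sub[order(sub$species, sub$station, sub$datetime), ]
  keep <- logical(nrow(sub))
  if (nrow(sub)) {
    key <- paste(sub$species, sub$station, sep = "\r")
    last <- -Inf; lastkey <- ""
    tt <- as.numeric(sub$datetime)
    for (k in seq_len(nrow(sub))) {
      if (key[k] != lastkey || tt[k] - last >= gap_hours * 3600) {
        keep[k] <- TRUE; last <- tt[k]; lastkey <- key[k]
      }
    }
  }
  out <- sub[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stations") <- attr(records, "stations")
  attr(out, "gap_hours") <- gap_hours
  class(out) <- c("event_set", "data.frame")
  out
}

#' @export
print.event_set <- function(x, ...) {
  cat("<event_set> ", nrow(x), " independent events (gap ",
      attr(x, "gap_hours") %||% NA, " h), species: ",
      paste(sort(unique(x$species)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Prey-presence covariate
#'
#' Proportion of surveyed days on which a prey species was photographed
#' at a station in the focal month: the number of distinct active days
#' with at least one photo, divided by the number of surveyed days.
#'
#' @param records a `photo_records` object.
#' @param prey prey species label.
#' @param station station id.
#' @param year survey year.
#' @param month focal month.
#' @param survey_days number of surveyed (active) days; must be >= 1.
#' @return proportion in `[0, 1]`.
#' @export
prey_covariate <- function(records, prey, station, year, month, survey_days) {
  if (survey_days < 1) stop("survey_days must be >= 1")
  stations <- stations_of(records)
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  last <- seq(first, by = "month", length.out = 2L)[2L] - 1L
  act <- active_days(stations, station, year)
  act <- act[act >= first & act <= last]
  sub <- records[records$species == prey & records$station == station &
                   records$year == year, ]
  d <- unique(as.Date(sub$datetime))
  n_days <- sum(d %in% act)
  n_days / survey_days
}

#' Write photo records / station tables back to CSV
#'
#' Inverse of [load_photo_records()] / [read_station_table()]; the
#' round trip is lossless at minute resolution.
#'
#' @param records a `photo_records` object.
#' @param stations a `camera_stations` object.
#' @param path output CSV path.
#' @export
write_photo_csv <- function(records, path) {
  out <- data.frame(station = records$station, species = records$species,
                    datetime = format(records$datetime, "%Y-%m-%d %H:%M:%S"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_photo_csv
#' @export
write_station_csv <- function(stations, path) {
  out <- as.data.frame(stations)
  out$active_from <- format(out$active_from)
  out$active_to <- format(out$active_to)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
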