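#' Sunrise and sunset times
#'
#' Computes local sunrise and sunset (decimal hours) from the standard
#' solar-position equations (fractional year, equation of time, solar
#' declination, hour angle at zenith 90.833 degrees — i.e. including
#' atmospheric refraction and the solar disc radius). Accuracy is within
#' about two minutes of published ephemerides at mid latitudes.
#'
#' @param date `Date` (vectorised).
#' @param lat,lon decimal degrees (positive north / east).
#' @param utc_offset local clock offset from UTC in hours (e.g. -7 for
#'   the Sonora study region, fixed local standard time).
#' @return data frame with `sunrise`, `sunset`, `day_hours` (decimal
#'   local hours; day length in hours).
#' @examples
#' sun_events(as.Date("2009-03-20"), 0, 0, 0)   # ~ 06:00 / 18:00
#' @export
sun_events <- function(date, lat, lon, utc_offset = -7) {
  if (any(abs(lat) >= 66))
    stop("latitudes within the polar circles are not supported")
  doy <- as.integer(format(date, "%j"))
  g <- 2 * pi / 365 * (doy - 1 + 0.5)             # fractional year, solar noon
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  latr <- lat * pi / 180
  cos_ha <- cos(90.833 * pi / 180) / (cos(latr) * cos(decl)) -
    tan(latr) * tan(decl)
  if (any(abs(cos_ha) > 1))
    stop("polar day or night at this latitude/date")
  ha <- acos(cos_ha) * 180 / pi                    # degrees
  sunrise_utc <- 720 - 4 * (lon + ha) - eqtime     # minutes UTC
  sunset_utc <- 720 - 4 * (lon - ha) - eqtime
  sr <- (sunrise_utc / 60 + utc_offset) %% 24
  ss <- (sunset_utc / 60 + utc_offset) %% 24
  data.frame(sunrise = sr, sunset = ss, day_hours = (ss - sr) %% 24)
}

#' Clock time to sun time
#'
#' Double-anchored circular transformation: sunrise maps to `pi/2`,
#' sunset to `3*pi/2`, with linear interpolation inside the day and
#' night segments. Solar midnight (the midpoint of the night segment)
#' is 0, solar noon is `pi`. This removes seasonal shifts in day length
#' before circular density estimation, and makes the +-1 h crepuscular
#' bands fixed angular windows.
#'
#' @param hour decimal clock hour in `[0, 24)` (vectorised).
#' @param sunrise,sunset decimal clock hours of the anchors.
#' @return radians in `[0, 2*pi)`.
#' @export
to_sun_time <- function(hour, sunrise, sunset) {
  day_len <- (sunset - sunrise) %% 24
  night_len <- 24 - day_len
  since_rise <- (hour - sunrise) %% 24
  ifelse(since_rise <= day_len,
         pi / 2 + pi * since_rise / day_len,
         (3 * pi / 2 + pi * (since_rise - day_len) / night_len) %% (2 * pi))
}

#' @rdname to_sun_time
#' @param theta sun-time radians in `[0, 2*pi)`.
#' @return `from_sun_time()` returns decimal clock hours.
#' @export
from_sun_time <- function(theta, sunrise, sunset) {
  theta <- theta %% (2 * pi)
  day_len <- (sunset - sunrise) %% 24
  night_len <- 24 - day_len
  ifelse(theta >= pi / 2 & theta <= 3 * pi / 2,
         (sunrise + (theta - pi / 2) / pi * day_len) %% 24,
         (sunset + ((theta - 3 * pi / 2) %% (2 * pi)) / pi * night_len) %% 24)
}

#' Attach sun times to an event set
#'
#' Computes sunrise/sunset for every event from its date and station
#' coordinates, averages the anchors within each survey year (yearly
#' mean anchoring), and transforms each event's clock time to sun-time
#' radians with its year's mean anchors.
#'
#' @param events an `event_set` (needs the station table attached) or a
#'   data frame with `station, datetime, year` plus an attached
#'   `camera_stations` table.
#' @param utc_offset local clock offset from UTC in hours.
#' @return the events with a `sun_time` column; per-year mean anchors as
#'   attribute `"anchors"` (data frame `year, sunrise, sunset,
#'   day_hours`).
#' @export
event_sun_times <- function(events, utc_offset = -7) {
  stations <- attr(events, "stations")
  if (is.null(stations)) stop("events carry no station table")
  key <- paste(stations$station, stations$year)
  idx <- match(paste(events$station, events$year), key)
  if (any(is.na(idx)))
    idx[is.na(idx)] <- match(events$station[is.na(idx)], stations$station)
  se <- sun_events(as.Date(events$datetime), stations$lat[idx],
                   stations$lon[idx], utc_offset)
  anchors <- do.call(rbind, lapply(split(se, events$year), function(z)
    data.frame(sunrise = mean(z$sunrise), sunset = mean(z$sunset))))
  anchors$year <- as.integer(rownames(anchors))
  anchors$day_hours <- (anchors$sunset - anchors$sunrise) %% 24
  a <- anchors[match(events$year, anchors$year), ]
  hr <- as.numeric(format(events$datetime, "%H")) +
    as.numeric(format(events$datetime, "%M")) / 60 +
    as.numeric(format(events$datetime, "%S")) / 3600
  events$sun_time <- to_sun_time(hr, a$sunrise, a$sunset)
  attr(events, "anchors") <- anchors[c("year", "sunrise", "sunset",
                                       "day_hours")]
  events
}
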