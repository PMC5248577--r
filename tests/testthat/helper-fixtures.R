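## Fixture builders and independent oracles shared across test files.

## A two-station table active through June of one year.
tiny_stations <- function(year = 2009, road = c(0L, 1L)) {
  st <- data.frame(station = c("s1", "s2"), lat = c(29.3, 29.5),
                   lon = c(-109.1, -109.0), road = road, year = year,
                   active_from = as.Date(sprintf("%d-06-01", year)),
                   active_to = as.Date(sprintf("%d-06-30", year)))
  class(st) <- c("camera_stations", "data.frame")
  st
}

tiny_photo_csv <- function(rows, stations = tiny_stations()) {
  pp <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".csv")
  utils::write.csv(rows, pp, row.names = FALSE, quote = FALSE)
  write_station_csv(stations, sp)
  list(photos = pp, stations = sp)
}

## Independent brute-force oracle for the two-species site likelihood:
## explicit enumeration of the four latent states with per-occasion
## probability products written from the model's defining conditionals
## (kept free of any package likelihood code).
oracle_site_lik <- function(yA, yB, p) {
  occ <- function(state, a, b) {
    if (is.na(a)) return(1)
    switch(state,
      AB = (if (a) p$rA else 1 - p$rA) *
        (if (a) (if (b) p$rBA else 1 - p$rBA)
         else (if (b) p$rBa else 1 - p$rBa)),
      A = if (b) 0 else (if (a) p$pA else 1 - p$pA),
      B = if (a) 0 else (if (b) p$pB else 1 - p$pB),
      none = if (!a && !b) 1 else 0)
  }
  w <- c(AB = p$psiA * p$psiBA,
         A = p$psiA * (1 - p$psiBA),
         B = (1 - p$psiA) * p$psiBa,
         none = (1 - p$psiA) * (1 - p$psiBa))
  tot <- 0
  for (s in names(w)) {
    prod <- 1
    for (j in seq_along(yA)) prod <- prod * occ(s, yA[j], yB[j])
    tot <- tot + w[[s]] * prod
  }
  tot
}

random_params <- function() {
  p <- as.list(stats::runif(8, 0.05, 0.95))
  names(p) <- c("psiA", "psiBA", "psiBa", "pA", "pB", "rA", "rBA", "rBa")
  p
}

## Random small paired history with a shared mask.
random_history <- function(J) {
  yA <- stats::rbinom(J, 1, 0.4)
  yB <- stats::rbinom(J, 1, 0.4)
  mask <- stats::runif(J) < 0.2
  yA[mask] <- NA; yB[mask] <- NA
  if (all(is.na(yA))) { yA[1] <- 1L; yB[1] <- 0L }
  list(yA = yA, yB = yB)
}
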