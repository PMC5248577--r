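test_that("photo ingestion validates species, stations and datetimes", {
  rows <- data.frame(
    station = c("s1", "s1", "s2"),
    species = c("jaguar", "puma", "deer"),
    datetime = c("2009-06-03 10:00:00", "2009-06-03 11:30:00",
                 "2009-06-10 14:05:00"))
  fx <- tiny_photo_csv(rows)
  rec <- load_photo_records(fx$photos, fx$stations)
  expect_s3_class(rec, "photo_records")
  expect_equal(nrow(rec), 3L)
  expect_true(!is.unsorted(as.numeric(rec$datetime[rec$station == "s1"])))

  bad_sp <- rows; bad_sp$species[2] <- "ocelot"
  fx2 <- tiny_photo_csv(bad_sp)
  expect_error(load_photo_records(fx2$photos, fx2$stations), "ocelot")

  bad_st <- rows; bad_st$station[3] <- "s9"
  fx3 <- tiny_photo_csv(bad_st)
  expect_error(load_photo_records(fx3$photos, fx3$stations), "s9")

  bad_dt <- rows; bad_dt$datetime[3] <- "not-a-time"
  fx4 <- tiny_photo_csv(bad_dt)
  expect_error(load_photo_records(fx4$photos, fx4$stations), "line")
})

test_that("focal month is the argmax with earliest-month tie-break", {
  rows <- data.frame(
    station = "s1", species = "jaguar",
    datetime = c(sprintf("2009-03-%02d 10:00:00", 1:2),
                 sprintf("2009-06-%02d 10:00:00", 1:9),
                 sprintf("2009-11-%02d 10:00:00", 1:4)))
  st <- tiny_stations()
  st$active_from <- as.Date("2009-01-01"); st$active_to <- as.Date("2009-12-31")
  fx <- tiny_photo_csv(rows, st)
  rec <- load_photo_records(fx$photos, fx$stations)
  expect_equal(select_focal_month(rec, "jaguar", 2009), 6L)
  expect_error(select_focal_month(rec, "puma", 2009), "no puma")

  tie <- data.frame(station = "s1", species = "jaguar",
                    datetime = c("2009-04-01 08:00:00", "2009-09-01 08:00:00"))
  fx2 <- tiny_photo_csv(tie, st)
  rec2 <- load_photo_records(fx2$photos, fx2$stations)
  expect_equal(select_focal_month(rec2, "jaguar", 2009), 4L)
})

test_that("daily collapse is duplicate-invariant and masks inactive days", {
  rows <- data.frame(
    station = "s1", species = "jaguar",
    datetime = sprintf("2009-06-05 %02d:00:00", c(1, 5, 9, 14, 22)))
  st <- tiny_stations()
  st$active_from[1] <- as.Date("2009-06-04")   # s1 starts on June 4
  fx <- tiny_photo_csv(rows, st)
  rec <- load_photo_records(fx$photos, fx$stations)
  m <- collapse_daily(rec, "jaguar", 2009, 6L)
  expect_equal(sum(m == 1L, na.rm = TRUE), 1L)       # 5 photos -> one detection
  expect_equal(unname(m["s1", "2009-06-05"]), 1L)
  expect_true(all(is.na(m["s1", 1:3])))              # masked before activation

  ## a photo on a masked day is ignored, not counted
  rows2 <- rbind(rows, data.frame(station = "s1", species = "jaguar",
                                  datetime = "2009-06-02 10:00:00"))
  fx2 <- tiny_photo_csv(rows2, st)
  rec2 <- load_photo_records(fx2$photos, fx2$stations)
  m2 <- collapse_daily(rec2, "jaguar", 2009, 6L)
  expect_identical(m2, m)
})

test_that("independence filter applies the 1-h gap greedily and idempotently", {
  rows <- data.frame(
    station = "s1", species = "puma",
    datetime = c("2009-06-03 10:00:00", "2009-06-03 10:30:00",
                 "2009-06-03 11:30:00"))
  fx <- tiny_photo_csv(rows)
  rec <- load_photo_records(fx$photos, fx$stations)
  ev <- filter_independent_events(rec, "puma")
  expect_equal(nrow(ev), 2L)                     # 10:00 and 11:30 survive

  one <- load_photo_records(tiny_photo_csv(rows[1, ])$photos, fx$stations)
  expect_equal(nrow(filter_independent_events(one, "puma")), 1L)

  ## idempotence on a random record set (fixed seed)
  set.seed(11)
  many <- data.frame(
    station = sample(c("s1", "s2"), 120, replace = TRUE),
    species = sample(c("jaguar", "puma"), 120, replace = TRUE),
    datetime = format(as.POSIXct("2009-06-01", tz = "UTC") +
                        sort(round(runif(120, 0, 20 * 86400))),
                      "%Y-%m-%d %H:%M:%S"))
  fx2 <- tiny_photo_csv(many)
  rec2 <- load_photo_records(fx2$photos, fx2$stations)
  ev1 <- filter_independent_events(rec2)
  ev2 <- filter_independent_events(ev1)
  expect_equal(nrow(ev2), nrow(ev1))
  expect_equal(ev2$datetime, ev1$datetime)
  ## successive kept events at one station are >= 1 h apart
  for (s in unique(ev1$station)) for (sp in unique(ev1$species)) {
    tt <- sort(as.numeric(ev1$datetime[ev1$station == s &
                                         ev1$species == sp]))
    if (length(tt) > 1) expect_true(all(diff(tt) >= 3600))
  }
})

test_that("prey covariate is the proportion of surveyed days with photos", {
  rows <- data.frame(
    station = "s1", species = "deer",
    datetime = c("2009-06-02 10:00:00", "2009-06-02 15:00:00",
                 "2009-06-11 10:00:00", "2009-06-20 10:00:00"))
  fx <- tiny_photo_csv(rows)
  rec <- load_photo_records(fx$photos, fx$stations)
  expect_equal(prey_covariate(rec, "deer", "s1", 2009, 6L, 30), 0.1)
  expect_equal(prey_covariate(rec, "peccary", "s1", 2009, 6L, 30), 0)
  expect_error(prey_covariate(rec, "deer", "s1", 2009, 6L, 0), "survey_days")
})

test_that("generator -> writer -> loader -> builder round-trips exactly", {
  sim <- simulate_occupancy(sim_design(S = 25), seed = 31)
  pp <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".csv")
  write_photo_csv(sim$records, pp)
  write_station_csv(sim$stations, sp)
  rec <- load_photo_records(pp, sp)
  expect_equal(nrow(rec), nrow(sim$records))
  expect_equal(format(rec$datetime, "%Y-%m-%d %H:%M:%S"),
               format(sim$records$datetime, "%Y-%m-%d %H:%M:%S"))
  hist <- build_two_species_histories(rec, sim$truth$focal_months)
  expect_identical(unname(hist$yA), unname(sim$data$yA))
  expect_identical(unname(hist$yB), unname(sim$data$yB))
  expect_equal(hist$covariates$deer, sim$data$covariates$deer)
  expect_equal(hist$covariates$peccary, sim$data$covariates$peccary)
  ## structural invariants
  expect_true(all(hist$yA %in% c(0L, 1L, NA)))
  covs <- hist$covariates[c("deer", "peccary", "calf")]
  expect_true(all(unlist(covs) >= 0 & unlist(covs) <= 1))
  ## history CSV round trip
  hp <- tempfile(fileext = ".csv")
  write_history_csv(hist, hp)
  h2 <- read_history_csv(hp)
  expect_identical(unname(h2$yA), unname(hist$yA))
  expect_identical(unname(h2$yB), unname(hist$yB))
  expect_equal(h2$covariates$calf, hist$covariates$calf)
})
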