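#' Pipeline configuration
#'
#' Bundles every knob of the two analysis branches into one declarative
#' object: input paths, focal species, independence gap, solar offset,
#' the model list for the occupancy branch, bootstrap settings, seed and
#' output directory. All pipeline outputs embed the seed and a hash of
#' this configuration, so identical configurations give identical files.
#'
#' @param photos,stations input CSV paths (must exist).
#' @param outdir output directory (created if needed).
#' @param species_a,species_b focal predator labels (dominant A,
#'   subordinate B).
#' @param prey prey species used as covariates and in overlap pairs.
#' @param gap_hours independence gap for activity events.
#' @param utc_offset local clock offset from UTC (hours).
#' @param models list of model strings or [occu2_model()] objects.
#' @param reps bootstrap replicates for overlap CIs.
#' @param adjust bandwidth adjustment for Delta-1.
#' @param seed RNG seed recorded in all outputs.
#' @return a `run_config` list.
#' @export
run_config <- function(photos, stations, outdir = tempfile("occoverlap_run"),
                       species_a = "jaguar", species_b = "puma",
                       prey = c("deer", "peccary", "calf"),
                       gap_hours = 1, utc_offset = -7,
                       models = list("psiA(.) psiBA(.) psiBa(.) pA=rA(.) pB=rBA=rBa(.)"),
                       reps = 10000L, adjust = 0.8, seed = 1L) {
  for (p in c(photos, stations))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  cfg <- list(photos = photos, stations = stations, outdir = outdir,
              species_a = species_a, species_b = species_b, prey = prey,
              gap_hours = gap_hours, utc_offset = utc_offset,
              models = models, reps = as.integer(reps), adjust = adjust,
              seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

## Small deterministic content hash (polynomial rolling hash of the
## deparsed configuration); identifies a configuration in output files.
config_hash <- function(cfg) {
  cfg$hash <- NULL
  cfg$outdir <- NULL      # where results land does not change what they are
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

stamp_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  writeLines(sprintf("# occoverlap seed=%d config=%s", cfg$seed, cfg$hash),
             con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Build detection histories and event sets from photo records
#'
#' Runs the ingestion branch end to end: loads and validates the photo
#' and station CSVs, picks each year's focal month (most records of
#' species A), builds the paired detection histories with covariates,
#' and applies the independence filter for the activity branch. Writes
#' the wide history CSV and the event CSV to the configured output
#' directory and logs the record-count funnel at each step.
#'
#' @param config a [run_config()].
#' @return list with `data` (an `occu2_data`), `events` (an
#'   `event_set`), `focal_months`, and the output paths.
#' @export
run_build <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  rec <- load_photo_records(config$photos, config$stations)
  if (!nrow(rec)) stop("no records in input: ", config$photos)
  message(sprintf("[build] %d photos, %d stations", nrow(rec),
                  length(unique(rec$station))))
  yrs <- sort(unique(rec$year[rec$species == config$species_a]))
  fm <- vapply(yrs, function(y)
    select_focal_month(rec, config$species_a, y), integer(1))
  names(fm) <- yrs
  data <- build_two_species_histories(rec, fm, config$species_a,
                                      config$species_b, config$prey)
  message(sprintf("[build] focal months: %s",
                  paste(yrs, fm, sep = "-", collapse = ", ")))
  message(sprintf("[build] %d site-year units, %d daily detections (A: %d, B: %d)",
                  nrow(data$yA), sum(data$yA, na.rm = TRUE) +
                    sum(data$yB, na.rm = TRUE),
                  sum(data$yA, na.rm = TRUE), sum(data$yB, na.rm = TRUE)))
  ev <- filter_independent_events(rec, gap_hours = config$gap_hours)
  message(sprintf("[build] %d photos -> %d independent events (gap %g h)",
                  nrow(rec), nrow(ev), config$gap_hours))
  hist_path <- file.path(config$outdir, "detection_history.csv")
  write_history_csv(data, hist_path)
  txt <- readLines(hist_path)
  writeLines(c(sprintf("# occoverlap seed=%d config=%s", config$seed,
                       config$hash), txt), hist_path)
  ev_path <- file.path(config$outdir, "events.csv")
  stamp_csv(data.frame(species = ev$species, station = ev$station,
                       datetime = format(ev$datetime, "%Y-%m-%d %H:%M:%S"),
                       year = ev$year),
            ev_path, config)
  list(data = data, events = ev, focal_months = fm,
       history_path = hist_path, events_path = ev_path)
}

#' Fit the configured model list and write selection tables
#'
#' Fits every model in `config$models` to the detection histories
#' (failures are logged and skipped), writes the AICc model-selection
#' table, the per-year derived estimates (reals, joint occupancy, SIF)
#' of the best model, and a JSON bundle of coefficients, covariance and
#' convergence diagnostics.
#'
#' @param config a [run_config()].
#' @param data an `occu2_data` (e.g. from [run_build()]).
#' @return list with `fits`, `selection` (data frame), `derived`
#'   (data frame for the best model) and output paths.
#' @export
run_fit <- function(config, data) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  fits <- list()
  for (i in seq_along(config$models)) {
    m <- config$models[[i]]
    lab <- if (is.character(m)) m else m$label
    f <- tryCatch(fit_occu2(m, data, seed = config$seed),
                  error = function(e) {
                    message("[fit] model failed, skipped: ", lab,
                            " (", conditionMessage(e), ")")
                    NULL
                  })
    if (!is.null(f)) fits[[lab]] <- f
  }
  if (!length(fits)) stop("no model could be fitted")
  sel <- model_selection_table(fits)
  best <- fits[[which.max(vapply(names(fits), function(nm)
    nm == sel$model[1], logical(1)))]]
  der <- derived_estimates(best)
  sel_path <- file.path(config$outdir, "model_selection.csv")
  der_path <- file.path(config$outdir, "derived_estimates.csv")
  stamp_csv(sel, sel_path, config)
  stamp_csv(der, der_path, config)
  bundle <- list(seed = config$seed, config = config$hash,
                 best_model = best$model$label,
                 coefficients = as.list(coef(best)),
                 vcov = unname(as.matrix(best$vcov)),
                 loglik = best$loglik, K = best$K, n = best$n,
                 converged = best$converged, boundary = best$boundary)
  json_path <- file.path(config$outdir, "fit_bundle.json")
  jsonlite::write_json(bundle, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  message(sprintf("[fit] %d model(s); best: %s (AICc %.2f)", length(fits),
                  sel$model[1], sel$AICc[1]))
  list(fits = fits, selection = sel, derived = der,
       selection_path = sel_path, derived_path = der_path,
       bundle_path = json_path)
}

#' Activity-pattern analysis: densities, overlap and classification
#'
#' Transforms independent events to sun time (yearly mean anchors),
#' estimates each species-year activity density, computes all pairwise
#' Delta-1 overlaps with smoothed-bootstrap confidence intervals,
#' classifies each species-year as diurnal/nocturnal/crepuscular, and
#' averages overlap across years per species pair. Species with fewer
#' than 2 events in a year are skipped with a warning.
#'
#' @param config a [run_config()].
#' @param events an `event_set` (e.g. from [run_build()]).
#' @return list with `overlap`, `classification`, `means` data frames
#'   and output paths.
#' @export
run_activity <- function(config, events) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ev <- event_sun_times(events, utc_offset = config$utc_offset)
  anchors <- attr(ev, "anchors")
  dens_rows <- list(); ov_rows <- list(); cls_rows <- list()
  for (yr in sort(unique(ev$year))) {
    sub <- ev[ev$year == yr, ]
    day_h <- anchors$day_hours[anchors$year == yr]
    by_sp <- split(sub$sun_time, sub$species)
    small <- names(by_sp)[vapply(by_sp, length, integer(1)) < 2]
    if (length(small)) {
      warning("skipping species with < 2 events in ", yr, ": ",
              paste(small, collapse = ", "))
      by_sp <- by_sp[setdiff(names(by_sp), small)]
    }
    for (s in names(by_sp)) {
      d <- vm_kernel_density(by_sp[[s]], adjust = config$adjust)
      dens_rows[[paste(yr, s)]] <- data.frame(
        year = yr, species = s, angle = d$grid, density = d$values)
      cl <- classify_activity(d, day_hours = day_h)
      cls_rows[[paste(yr, s)]] <- data.frame(
        year = yr, species = s, n = d$n,
        diurnal = cl$proportions[["diurnal"]],
        nocturnal = cl$proportions[["nocturnal"]],
        crepuscular = cl$proportions[["crepuscular"]], label = cl$label)
    }
    sp <- names(by_sp)
    if (length(sp) >= 2) {
      for (i in seq_len(length(sp) - 1)) for (j in seq.int(i + 1, length(sp))) {
        ci <- bootstrap_ci(by_sp[[sp[i]]], by_sp[[sp[j]]],
                           reps = config$reps, adjust = config$adjust,
                           seed = config$seed + yr)
        ov_rows[[paste(yr, sp[i], sp[j])]] <- data.frame(
          year = yr, species1 = sp[i], species2 = sp[j],
          delta1 = ci$delta1, ci_low = ci$ci_low, ci_high = ci$ci_high,
          n1 = ci$n1, n2 = ci$n2)
      }
    }
  }
  overlap <- do.call(rbind, ov_rows)
  classification <- do.call(rbind, cls_rows)
  means <- NULL
  if (!is.null(overlap)) {
    key <- paste(overlap$species1, overlap$species2, sep = "-")
    means <- aggregate(list(mean_delta1 = overlap$delta1), list(pair = key),
                       mean)
  }
  paths <- list(density = file.path(config$outdir, "activity_density.csv"),
                overlap = file.path(config$outdir, "overlap.csv"),
                classification = file.path(config$outdir,
                                           "classification.csv"),
                means = file.path(config$outdir, "overlap_means.csv"))
  stamp_csv(do.call(rbind, dens_rows), paths$density, config)
  if (!is.null(overlap)) stamp_csv(overlap, paths$overlap, config)
  stamp_csv(classification, paths$classification, config)
  if (!is.null(means)) stamp_csv(means, paths$means, config)
  message(sprintf("[activity] %d species-year densities, %d overlap pairs",
                  length(dens_rows), length(ov_rows)))
  list(overlap = overlap, classification = classification, means = means,
       anchors = anchors, paths = paths)
}
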