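#' Construct a paired two-species detection-history object
#'
#' Container for the conditional two-species occupancy model: paired
#' daily detection matrices for the dominant species A and subordinate
#' species B over site-year units, a shared missing-occasion mask
#' (`NA` cells), and per-unit covariates. Units are station-years; the
#' survey year enters the model as a group factor.
#'
#' @param yA,yB integer site x occasion matrices in `{0, 1, NA}` with an
#'   identical `NA` pattern (a station inactive on a day is masked for
#'   both species jointly).
#' @param covariates data frame with one row per site-year unit; must
#'   contain a `year` column; proportions must lie in `[0, 1]`.
#' @param species labels for (A, B), cosmetic.
#' @return an `occu2_data` object.
#' @export
occu2_data <- function(yA, yB, covariates, species = c("jaguar", "puma")) {
  yA <- as.matrix(yA); yB <- as.matrix(yB)
  stopifnot(identical(dim(yA), dim(yB)), nrow(yA) == nrow(covariates))
  if (!identical(is.na(yA), is.na(yB)))
    stop("yA and yB must share one missing-occasion mask")
  if (!all(yA %in% c(0L, 1L, NA)) || !all(yB %in% c(0L, 1L, NA)))
    stop("unmasked history cells must be 0 or 1")
  if (!"year" %in% names(covariates)) stop("covariates must contain 'year'")
  covariates$year <- factor(covariates$year)
  num <- vapply(covariates, is.numeric, logical(1))
  prop <- intersect(names(covariates)[num], c("deer", "peccary", "calf"))
  for (v in prop)
    if (any(covariates[[v]] < 0 | covariates[[v]] > 1))
      stop("covariate '", v, "' outside [0, 1]")
  if (any(rowSums(!is.na(yA)) == 0))
    warning("some site-year units have all occasions masked; ",
            "they contribute nothing to the likelihood")
  structure(list(yA = yA, yB = yB, covariates = covariates,
                 species = species),
            class = "occu2_data")
}

#' @export
print.occu2_data <- function(x, ...) {
  cat("<occu2_data> ", nrow(x$yA), " site-year units x ", ncol(x$yA),
      " occasions (", x$species[1], " = A, ", x$species[2], " = B)\n",
      sep = "")
  cat("  detections A: ", sum(x$yA, na.rm = TRUE),
      ", B: ", sum(x$yB, na.rm = TRUE),
      ", masked cells: ", sum(is.na(x$yA)), "\n", sep = "")
  cat("  years: ", paste(levels(x$covariates$year), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Build paired detection histories and covariates
#'
#' Runs the full ingestion for the occupancy branch: for each year's
#' focal month, collapses photos of the two focal species to daily
#' detections (shared mask from the station activity calendar), attaches
#' the prey-presence proportions and the road flag per site-year, and
#' stacks years into one `occu2_data` object. Stations with zero active
#' days in a focal month are dropped with a warning.
#'
#' @param records a `photo_records` object.
#' @param focal_months named integer vector, one month per year
#'   (names are years), e.g. from [select_focal_month()].
#' @param species_a,species_b focal species labels (dominant A,
#'   subordinate B).
#' @param prey prey species to turn into proportion covariates.
#' @return an `occu2_data` object.
#' @export
build_two_species_histories <- function(records, focal_months,
                                        species_a = "jaguar",
                                        species_b = "puma",
                                        prey = c("deer", "peccary", "calf")) {
  stations <- stations_of(records)
  years <- as.integer(names(focal_months))
  if (any(is.na(years))) stop("focal_months must be named by year")
  per_year <- lapply(seq_along(years), function(k) {
    yr <- years[k]; mo <- as.integer(focal_months[k])
    mA <- collapse_daily(records, species_a, yr, mo)
    mB <- collapse_daily(records, species_b, yr, mo)
    surveyed <- rowSums(!is.na(mA))
    if (any(surveyed == 0)) {
      warning(sum(surveyed == 0), " station(s) with zero active days in ",
              yr, "-", mo, " dropped")
      mA <- mA[surveyed > 0, , drop = FALSE]
      mB <- mB[surveyed > 0, , drop = FALSE]
      surveyed <- surveyed[surveyed > 0]
    }
    ids <- rownames(mA)
    cov <- data.frame(site = ids, year = yr, row.names = NULL)
    for (p in prey)
      cov[[p]] <- vapply(seq_along(ids), function(i)
        prey_covariate(records, p, ids[i], yr, mo, surveyed[i]), numeric(1))
    cov$road <- vapply(ids, function(s)
      stations$road[match(paste(s, yr), paste(stations$station,
                                              stations$year))], numeric(1))
    list(yA = mA, yB = mB, cov = cov)
  })
  J <- max(vapply(per_year, function(z) ncol(z$yA), integer(1)))
  pad <- function(m) {
    if (ncol(m) < J)
      m <- cbind(m, matrix(NA_integer_, nrow(m), J - ncol(m)))
    colnames(m) <- paste0("occ", seq_len(J)); m
  }
  yA <- do.call(rbind, lapply(per_year, function(z) pad(z$yA)))
  yB <- do.call(rbind, lapply(per_year, function(z) pad(z$yB)))
  cov <- do.call(rbind, lapply(per_year, function(z) z$cov))
  rownames(yA) <- rownames(yB) <- paste(cov$site, cov$year, sep = ":")
  occu2_data(yA, yB, cov, species = c(species_a, species_b))
}

#' Write / read a detection-history CSV
#'
#' Wide plain-text form, one row per site-year unit: paired daily
#' detection columns `dA_1..dA_J` and `dB_1..dB_J` with `"."` marking
#' masked occasions, followed by the covariate columns.
#'
#' @param data an `occu2_data` object.
#' @param path CSV path.
#' @return `read_history_csv()` returns an `occu2_data` object.
#' @export
write_history_csv <- function(data, path) {
  J <- ncol(data$yA)
  fmt <- function(m) {
    m2 <- matrix(as.character(m), nrow(m)); m2[is.na(m2)] <- "."; m2
  }
  out <- data.frame(site = data$covariates$site,
                    year = as.character(data$covariates$year),
                    fmt(data$yA), fmt(data$yB),
                    data$covariates[setdiff(names(data$covariates),
                                            c("site", "year"))],
                    check.names = FALSE)
  names(out)[2 + seq_len(J)] <- paste0("dA_", seq_len(J))
  names(out)[2 + J + seq_len(J)] <- paste0("dB_", seq_len(J))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_history_csv
#' @param species labels passed through to [occu2_data()].
#' @export
read_history_csv <- function(path, species = c("jaguar", "puma")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE, colClasses = "character")
  ja <- grep("^dA_", names(df)); jb <- grep("^dB_", names(df))
  if (!length(ja) || length(ja) != length(jb))
    stop("history CSV must contain paired dA_*/dB_* columns")
  tomat <- function(cols) {
    m <- as.matrix(df[cols]); m[m == "."] <- NA
    matrix(as.integer(m), nrow(df), dimnames = list(NULL, NULL))
  }
  covcols <- setdiff(names(df), c("site", "year", names(df)[c(ja, jb)]))
  cov <- data.frame(site = df$site, year = df$year)
  for (v in covcols) cov[[v]] <- as.numeric(df[[v]])
  occu2_data(tomat(ja), tomat(jb), cov, species = species)
}
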