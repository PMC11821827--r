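#' Classify mortality severity
#'
#' Percent mortality is recorded in 10% steps. Classes: low below 30%,
#' moderate between 30% and 60% inclusive, severe above 60%. The interval
#' endpoints 30 and 60 belong to the moderate class, since low is "below 30%"
#' and severe "exceeding 60%".
#'
#' @param percent_mortality Numeric vector of percentages, each a multiple of
#'   10 in \[10, 100\].
#' @return Character vector: `"low"`, `"moderate"` or `"severe"`.
#' @export
classify_severity <- function(percent_mortality) {
  p <- percent_mortality
  bad <- !is.finite(p) | p < 10 | p > 100 | (p %% 10 != 0)
  if (any(bad)) {
    stop("percent_mortality must be a multiple of 10 in [10, 100]; got: ",
         paste(unique(p[bad]), collapse = ", "), call. = FALSE)
  }
  ifelse(p < 30, "low", ifelse(p <= 60, "moderate", "severe"))
}

parse_drivers <- function(s) {
  out <- strsplit(s, ";", fixed = TRUE)
  lapply(out, function(x) trimws(x[nzchar(trimws(x))]))
}

#' Assign a record to one of the twelve driver classes
#'
#' @param drivers A list of character vectors (one per record) of driver
#'   labels from [driver_vocabulary()].
#' @return Character vector of class labels from [driver_classes()].
#' @export
classify_driver <- function(drivers) {
  vocab <- driver_vocabulary()
  vapply(drivers, function(d) {
    cls <- vocab$class[match(d, vocab$driver)]
    if (anyNA(cls)) {
      stop("unknown driver label: ",
           paste(d[is.na(cls)], collapse = ", "), call. = FALSE)
    }
    if (all(cls == "abiotic")) {
      if (length(unique(d)) > 1L) "abiotic combination" else d[[1L]]
    } else if (all(cls == "biotic")) {
      if (length(unique(d)) > 1L) "biotic combination" else d[[1L]]
    } else {
      "abiotic-biotic combination"
    }
  }, character(1))
}

#' Read mortality records from CSV
#'
#' Expects columns `species`, `phylum`, `year`, `longitude`, `latitude`,
#' `depth_range`, `habitat`, `drivers` (semicolon-separated labels from
#' [driver_vocabulary()]) and `percent_mortality` (blank for events observed
#' but not quantified). Quantified rows are validated (driver vocabulary,
#' 10% steps) and returned; unquantified rows are counted and excluded from
#' analysis.
#'
#' @param csv_source Path to a CSV file, or a connection.
#' @return A list with `records` (a `mortality_records` data.frame carrying
#'   `severity`, `driver_class` and a `drivers` list-column) and
#'   `unquantified_count`.
#' @export
read_mortality_records <- function(csv_source) {
  df <- utils::read.csv(csv_source, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("species", "phylum", "year", "longitude", "latitude",
            "depth_range", "habitat", "drivers", "percent_mortality")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("mortality table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pm_raw <- trimws(df$percent_mortality)
  unquantified <- !nzchar(pm_raw) | is.na(pm_raw)
  rec <- df[!unquantified, , drop = FALSE]
  pm <- suppressWarnings(as.numeric(pm_raw[!unquantified]))
  if (anyNA(pm)) {
    stop("non-numeric percent_mortality for species: ",
         paste(rec$species[is.na(pm)], collapse = ", "), call. = FALSE)
  }
  records <- data.frame(
    species = rec$species,
    phylum = rec$phylum,
    year = as.integer(rec$year),
    longitude = as.numeric(rec$longitude),
    latitude = as.numeric(rec$latitude),
    depth_range = rec$depth_range,
    habitat = rec$habitat,
    percent_mortality = pm,
    stringsAsFactors = FALSE
  )
  records$severity <- classify_severity(pm)
  dl <- parse_drivers(rec$drivers)
  if (any(lengths(dl) == 0L)) {
    stop("records with an empty driver set: ",
         paste(rec$species[lengths(dl) == 0L], collapse = ", "),
         call. = FALSE)
  }
  records$driver_class <- classify_driver(dl)
  records$drivers <- I(dl)
  rownames(records) <- NULL
  class(records) <- c("mortality_records", "data.frame")
  list(records = records, unquantified_count = sum(unquantified))
}

#' Write mortality records back to the CSV interchange format
#'
#' @param records A `mortality_records` data.frame.
#' @param path Output CSV path.
#' @keywords internal
write_mortality_records <- function(records, path) {
  out <- data.frame(
    species = records$species, phylum = records$phylum,
    year = records$year, longitude = records$longitude,
    latitude = records$latitude, depth_range = records$depth_range,
    habitat = records$habitat,
    drivers = vapply(records$drivers, paste, character(1), collapse = ";"),
    percent_mortality = records$percent_mortality,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Assign Mediterranean sub-basin by longitude
#'
#' Default boundaries follow the conventional western/central/eastern split
#' (Sicily Channel about 11.5 degrees E; about 22 degrees E for the eastern
#' basin).
#'
#' @param longitude Numeric vector, decimal degrees east.
#' @param boundaries Two increasing longitudes splitting the basin.
#' @return Character vector: `"western"`, `"central"` or `"eastern"`.
#' @export
assign_region <- function(longitude, boundaries = c(11.5, 22.0)) {
  stopifnot(length(boundaries) == 2L, boundaries[1] < boundaries[2])
  if (any(!is.finite(longitude))) stop("non-finite longitude", call. = FALSE)
  ifelse(longitude < boundaries[1], "western",
         ifelse(longitude <= boundaries[2], "central", "eastern"))
}

#' Filter mortality records
#'
#' All supplied filters are combined with AND. The minimum-percent filter is
#' inclusive (`>=`) for thresholds 10..90; a threshold of 100 selects the
#' ">90%" top bin, i.e. records at exactly 100%.
#'
#' @param records A `mortality_records` data.frame.
#' @param severity Optional severity class(es): low/moderate/severe.
#' @param min_percent Optional threshold in 10..100.
#' @param driver_class Optional driver class(es) from [driver_classes()].
#' @param region Optional region(s): western/central/eastern.
#' @param years Optional length-2 inclusive year window.
#' @param region_boundaries Longitude boundaries passed to [assign_region()].
#' @return The filtered records (same class).
#' @export
subset_records <- function(records, severity = NULL, min_percent = NULL,
                           driver_class = NULL, region = NULL, years = NULL,
                           region_boundaries = c(11.5, 22.0)) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(severity)) keep <- keep & records$severity %in% severity
  if (!is.null(min_percent)) {
    stopifnot(length(min_percent) == 1L, min_percent %in% seq(10, 100, 10))
    keep <- keep & if (min_percent == 100) records$percent_mortality == 100
                   else records$percent_mortality >= min_percent
  }
  if (!is.null(driver_class)) keep <- keep & records$driver_class %in% driver_class
  if (!is.null(region)) {
    keep <- keep & assign_region(records$longitude, region_boundaries) %in% region
  }
  if (!is.null(years)) {
    stopifnot(length(years) == 2L)
    if (years[1] > years[2]) stop("contradictory year window", call. = FALSE)
    keep <- keep & records$year >= years[1] & records$year <= years[2]
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
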