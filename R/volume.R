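space_coords <- function(space, m = NULL) {
  if (is.null(m)) m <- space$m_selected
  if (is.null(m)) {
    stop("no dimension selected; run select_dimension() or pass m",
         call. = FALSE)
  }
  navail <- ncol(space$coordinates)
  if (m > navail) stop("m exceeds available axes", call. = FALSE)
  space$coordinates[, seq_len(m), drop = FALSE]
}

#' Impacted trait-volume fractions for sets of functional entities
#'
#' For each impacted FE set, computes the ratio of the convex-hull volume of
#' the impacted FE coordinates to the hull volume of all FEs, in the
#' m-dimensional selected trait space. Sets with fewer than m+1 FEs, or
#' affinely dependent ones, are degenerate and score fraction 0 (flagged).
#'
#' @param space A `trait_space` with `m_selected` set (or pass `m`).
#' @param impacted_sets A list of character vectors of fe_ids (labels of
#'   `space`), or a single character vector for one set.
#' @param m Dimension override; default `space$m_selected`.
#' @return A data.frame with one row per set: `n_fes_impacted`,
#'   `n_fes_total`, `hull_volume_global`, `hull_volume_impacted`, `fraction`,
#'   `degenerate`.
#' @export
impacted_fractions <- function(space, impacted_sets, m = NULL) {
  if (is.character(impacted_sets)) impacted_sets <- list(impacted_sets)
  coords <- space_coords(space, m)
  m <- ncol(coords)
  labels <- space$labels
  for (s in impacted_sets) {
    bad <- setdiff(s, labels)
    if (length(bad)) {
      stop("unknown fe_id(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  global <- hull_volumes(list(coords))
  if (global$degenerate[1] || global$volume[1] <= 0) {
    stop("global hull is degenerate; cannot normalize fractions",
         call. = FALSE)
  }
  vg <- global$volume[1]
  nset <- length(impacted_sets)
  vol <- numeric(nset)
  degen <- logical(nset)
  sizes <- lengths(impacted_sets)
  todo <- which(sizes >= m + 1)
  degen[sizes < m + 1] <- TRUE
  if (length(todo)) {
    res <- hull_volumes(lapply(impacted_sets[todo], function(s) {
      coords[match(unique(s), labels), , drop = FALSE]
    }))
    vol[todo] <- res$volume
    degen[todo] <- res$degenerate
  }
  vol[degen] <- 0
  data.frame(
    n_fes_impacted = sizes,
    n_fes_total = length(labels),
    hull_volume_global = vg,
    hull_volume_impacted = vol,
    fraction = vol / vg,
    degenerate = degen
  )
}

#' @rdname impacted_fractions
#' @param impacted A single character vector of fe_ids.
#' @export
impacted_fraction <- function(space, impacted, m = NULL) {
  res <- impacted_fractions(space, list(impacted), m = m)
  as.list(res[1, ])
}

#' Balanced resampling of the impacted trait volume
#'
#' Draws `n` records without replacement from the supplied group `R` times;
#' each repetition maps the drawn records to impacted FEs and computes the
#' impacted volume fraction and FE count. Equalizing `n` across groups
#' (e.g. regions, decades) removes differences in survey effort.
#'
#' @param records A `mortality_records` data.frame (the group; subset before
#'   calling, e.g. with [subset_records()]).
#' @param space A `trait_space` with `m_selected`.
#' @param fes A `functional_entities` object.
#' @param group Label for reporting.
#' @param n Records per repetition (default 100). Must not exceed the group
#'   size.
#' @param R Repetitions (default 1000).
#' @param seed Integer seed; fixed seed gives identical repetition vectors.
#' @param m Dimension override.
#' @return A `resample_summary` list: `group`, `n`, `R`, `seed`, `fractions`
#'   and `n_fes` (length-R vectors), `mean_fraction`, `sd_fraction`,
#'   `mean_n_fes`, `sd_n_fes`.
#' @export
resample_volume <- function(records, space, fes, group = "all", n = 100,
                            R = 1000, seed = 1L, m = NULL) {
  if (nrow(records) < n) {
    stop(sprintf("group '%s' has %d records, fewer than n = %d", group,
                 nrow(records), n), call. = FALSE)
  }
  set.seed(seed)
  fe_of_row <- unname(fes$species_fe[records$species])
  if (anyNA(fe_of_row)) {
    stop("record species absent from trait table: ",
         paste(unique(records$species[is.na(fe_of_row)]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(seq_len(R), function(r) {
    idx <- sample.int(nrow(records), n)
    sort(unique(fe_of_row[idx]))     # sorted: identical sets give identical
  })                                 # hull volumes bit-for-bit
  res <- impacted_fractions(space, sets, m = m)
  structure(list(
    group = group, n = n, R = R, seed = seed,
    fractions = res$fraction, n_fes = res$n_fes_impacted,
    mean_fraction = mean(res$fraction), sd_fraction = stats::sd(res$fraction),
    mean_n_fes = mean(res$n_fes_impacted),
    sd_n_fes = stats::sd(res$n_fes_impacted)
  ), class = "resample_summary")
}

#' @export
print.resample_summary <- function(x, ...) {
  cat(sprintf(
    "resample_summary '%s': n=%d, R=%d | volume %.1f%% +/- %.1f%% | %.1f +/- %.1f FEs\n",
    x$group, x$n, x$R, 100 * x$mean_fraction, 100 * x$sd_fraction,
    x$mean_n_fes, x$sd_n_fes))
  invisible(x)
}

#' Impacted trait volume per driver class and year
#'
#' Builds the full driver-class-by-year grid (12 classes x the year span,
#' 420 cells for 1986-2020) and computes for each cell the impacted FE set
#' and its volume fraction. Cells without records score 0.
#'
#' @inheritParams resample_volume
#' @param years Year span (default 1986:2020).
#' @return A data.frame with columns `driver_class`, `year`, `n_records`,
#'   `n_fes_impacted`, `fraction`, `degenerate`.
#' @export
driver_year_heatmap <- function(records, space, fes, years = 1986:2020,
                                m = NULL) {
  classes <- driver_classes()
  grid <- expand.grid(driver_class = classes, year = years,
                      stringsAsFactors = FALSE)
  fe_of_row <- unname(fes$species_fe[records$species])
  key <- paste(records$driver_class, records$year)
  sets <- lapply(paste(grid$driver_class, grid$year), function(k) {
    sort(unique(fe_of_row[key == k]))
  })
  res <- impacted_fractions(space, sets, m = m)
  data.frame(
    driver_class = grid$driver_class,
    year = grid$year,
    n_records = vapply(paste(grid$driver_class, grid$year),
                       function(k) sum(key == k), integer(1),
                       USE.NAMES = FALSE),
    n_fes_impacted = res$n_fes_impacted,
    fraction = res$fraction,
    degenerate = res$degenerate
  )
}

#' Annual impacted trait volume, all drivers pooled
#'
#' @inheritParams driver_year_heatmap
#' @return A data.frame with columns `year`, `n_records`, `n_fes_impacted`,
#'   `fraction`, `degenerate`; one row per year of `years` (zero for years
#'   without records).
#' @export
annual_impact_series <- function(records, space, fes, years = 1986:2020,
                                 m = NULL) {
  fe_of_row <- unname(fes$species_fe[records$species])
  sets <- lapply(years, function(y) sort(unique(fe_of_row[records$year == y])))
  res <- impacted_fractions(space, sets, m = m)
  data.frame(
    year = years,
    n_records = vapply(years, function(y) sum(records$year == y), integer(1)),
    n_fes_impacted = res$n_fes_impacted,
    fraction = res$fraction,
    degenerate = res$degenerate
  )
}

#' Average impacted volume over calendar windows
#'
#' Windows of `window` years aligned to `start_year` (default decades
#' 1986-1995, 1996-2005, ...). Means are arithmetic over all years of the
#' window present in the input (including zero years). If the input carries
#' a `driver_class` column (heatmap cells), summaries are per class.
#'
#' @param annual A data.frame with columns `year`, `fraction`,
#'   `n_fes_impacted` and optionally `driver_class`.
#' @param window Window length in years: 10 (default) or 5.
#' @param start_year First year of the first window (default 1986).
#' @return A data.frame with `window_start`, `window_end` (and
#'   `driver_class` if present), `n_years`, `mean_fraction`,
#'   `mean_n_fes`, `sd_n_fes`.
#' @export
decade_summary <- function(annual, window = 10, start_year = 1986) {
  stopifnot(window >= 1, all(c("year", "fraction") %in% names(annual)))
  if (nrow(annual) == 0L) stop("empty input", call. = FALSE)
  w0 <- start_year + window * ((annual$year - start_year) %/% window)
  by_cols <- list(window_start = w0)
  if ("driver_class" %in% names(annual)) {
    by_cols$driver_class <- annual$driver_class
  }
  agg <- function(v, f) {
    out <- aggregate(v, by = by_cols, FUN = f)
    out$x
  }
  base <- aggregate(annual$fraction, by = by_cols, FUN = mean)
  names(base)[names(base) == "x"] <- "mean_fraction"
  base$n_years <- agg(annual$year, function(y) length(unique(y)))
  if ("n_fes_impacted" %in% names(annual)) {
    base$mean_n_fes <- agg(annual$n_fes_impacted, mean)
    base$sd_n_fes <- agg(annual$n_fes_impacted, stats::sd)
  }
  base$window_end <- base$window_start + window - 1
  ord <- c("window_start", "window_end",
           intersect("driver_class", names(base)),
           "n_years", "mean_fraction",
           intersect(c("mean_n_fes", "sd_n_fes"), names(base)))
  base <- base[order(base$window_start), ord, drop = FALSE]
  rownames(base) <- NULL
  base
}
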