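#' Configuration for a full analysis run
#'
#' Either point `traits_csv`/`mortality_csv` at input files, or supply
#' `simulate` (a [synthetic_config()]) to generate the inputs in-memory.
#'
#' @param traits_csv,mortality_csv Input CSV paths (ignored when `simulate`
#'   is given).
#' @param simulate Optional [synthetic_config()].
#' @param schema A [trait_schema()].
#' @param dimension_candidates Candidate PCoA dimensionalities.
#' @param region_bounds Longitude boundaries for [assign_region()].
#' @param resample_n,resample_R Balanced-resampling plan per region.
#' @param chains_severity,iter_severity,warmup_severity Chain plan for the
#'   per-trait severity models.
#' @param chains_volume,iter_volume,warmup_volume Chain plan for the volume
#'   model.
#' @param severity_traits Trait codes to model (default all ten).
#' @param out_dir Output directory, or NULL to skip writing files.
#' @param seed Master seed for resampling and model fits.
#' @return A `run_config` list.
#' @export
run_config <- function(traits_csv = NULL, mortality_csv = NULL,
                       simulate = NULL, schema = default_trait_schema(),
                       dimension_candidates = 2:10,
                       region_bounds = c(11.5, 22.0),
                       resample_n = 100, resample_R = 1000,
                       chains_severity = 2, iter_severity = 2000,
                       warmup_severity = 1000,
                       chains_volume = 2, iter_volume = 3000,
                       warmup_volume = 1000,
                       severity_traits = NULL,
                       out_dir = NULL, seed = 1L) {
  if (is.null(simulate) &&
      (is.null(traits_csv) || is.null(mortality_csv))) {
    stop("either supply traits_csv and mortality_csv, or a simulate config",
         call. = FALSE)
  }
  if (is.null(severity_traits)) severity_traits <- trait_codes(schema)
  structure(list(
    traits_csv = traits_csv, mortality_csv = mortality_csv,
    simulate = simulate, schema = schema,
    dimension_candidates = dimension_candidates,
    region_bounds = region_bounds,
    resample_n = resample_n, resample_R = resample_R,
    chains_severity = chains_severity, iter_severity = iter_severity,
    warmup_severity = warmup_severity,
    chains_volume = chains_volume, iter_volume = iter_volume,
    warmup_volume = warmup_volume,
    severity_traits = severity_traits,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "run_config")
}

load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    table <- generate_trait_table(config$simulate)
    gen <- generate_mortality_records(table, config$simulate)
    list(table = table, records = gen$records,
         unquantified_count = nrow(gen$unquantified), truth = gen$truth)
  } else {
    table <- read_trait_table(config$traits_csv, config$schema)
    mr <- read_mortality_records(config$mortality_csv)
    list(table = table, records = mr$records,
         unquantified_count = mr$unquantified_count, truth = NULL)
  }
}

#' Validate run inputs without running the analysis
#'
#' @param config A [run_config()].
#' @return A data.frame of violations (`stage`, `message`); zero rows when
#'   the inputs are clean.
#' @export
validate_inputs <- function(config) {
  violations <- data.frame(stage = character(0), message = character(0),
                           stringsAsFactors = FALSE)
  note <- function(stage, msg) {
    rbind(violations, data.frame(stage = stage, message = msg,
                                 stringsAsFactors = FALSE))
  }
  if (!is.null(config$simulate)) {
    return(tryCatch({
      validate_synthetic_config(config$simulate)
      violations
    }, error = function(e) note("simulate", conditionMessage(e))))
  }
  for (p in c(config$traits_csv, config$mortality_csv)) {
    if (!file.exists(p)) violations <- note("paths", paste("missing file:", p))
  }
  if (nrow(violations)) return(violations)
  table <- tryCatch(read_trait_table(config$traits_csv, config$schema),
                    error = function(e) e)
  if (inherits(table, "error")) {
    return(note("trait_table", conditionMessage(table)))
  }
  mr <- tryCatch(read_mortality_records(config$mortality_csv),
                 error = function(e) e)
  if (inherits(mr, "error")) {
    return(note("mortality_records", conditionMessage(mr)))
  }
  unknown <- setdiff(unique(mr$records$species), table$species)
  for (sp in unknown) {
    violations <- note("cross_reference",
                       paste("record species absent from trait table:", sp))
  }
  violations
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("stage %-18s %6.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full trait-vulnerability analysis
#'
#' Composes the pipeline: ingest (or simulate) -> functional entities ->
#' Gower/PCoA trait space with mAD dimension selection -> impacted trait
#' volumes by severity bin, driver class and year, decade/5-year summaries,
#' regional balanced resampling -> per-trait severity ZOIB models and the
#' annual volume ZOIB model. Deterministic given the config seeds. When
#' `config$out_dir` is set, all report tables are written there as TSV/JSON
#' plus a `manifest.json` (package version, seeds, config hash).
#'
#' @param config A [run_config()].
#' @return A `run_report` list with elements `redundancy`, `trait_space`
#'   (mAD profile, `m_selected`), `severity_bins`, `heatmap`, `annual`,
#'   `decades`, `five_year`, `regional` (list of `resample_summary`),
#'   `severity_models` (per trait: `severity_by_category`, `r2`, max R-hat,
#'   or a skip note), `volume_model`, `counts`, `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- stage("ingest", load_inputs(config))
  table <- inputs$table
  records <- inputs$records
  message(sprintf("  %d species, %d quantified records (%d unquantified)",
                  nrow(table), nrow(records), inputs$unquantified_count))

  fes <- stage("entities", build_functional_entities(table))
  redundancy <- summarize_redundancy(fes)

  space <- stage("trait_space", {
    D <- gower_distance(fes)
    select_dimension(D, config$dimension_candidates)
  })
  m <- space$m_selected

  severity_bins <- stage("severity_bins", {
    thresholds <- seq(10, 100, 10)
    sets <- lapply(thresholds, function(th) {
      impacted_fe_ids(subset_records(records, min_percent = th), fes)
    })
    res <- impacted_fractions(space, sets)
    cbind(data.frame(min_percent = thresholds), res)
  })

  heatmap <- stage("heatmap", {
    years <- config$simulate$year_range %||% range(records$year)
    driver_year_heatmap(records, space, fes,
                        years = seq(years[1], years[2]))
  })
  annual <- stage("annual", {
    years <- range(heatmap$year)
    annual_impact_series(records, space, fes,
                         years = seq(years[1], years[2]))
  })
  decades <- decade_summary(annual, window = 10, start_year = min(annual$year))
  five_year <- decade_summary(annual, window = 5, start_year = min(annual$year))

  regional <- stage("resampling", {
    out <- list()
    for (reg in c("western", "central", "eastern")) {
      sub <- subset_records(records, region = reg,
                            region_boundaries = config$region_bounds)
      if (nrow(sub) < config$resample_n) {
        out[[reg]] <- sprintf("skipped: %d records < n = %d", nrow(sub),
                              config$resample_n)
      } else {
        out[[reg]] <- resample_volume(sub, space, fes, group = reg,
                                      n = config$resample_n,
                                      R = config$resample_R,
                                      seed = config$seed + match(
                                        reg, c("western", "central",
                                               "eastern")))
      }
    }
    out
  })

  severity_models <- stage("severity_models", {
    out <- list()
    for (trait in config$severity_traits) {
      out[[trait]] <- tryCatch(
        fit_severity_model(records, trait, table,
                           chains = config$chains_severity,
                           iter = config$iter_severity,
                           warmup = config$warmup_severity,
                           seed = config$seed + 100L +
                             match(trait, trait_codes(config$schema))),
        benthovuln_single_category = function(e) {
          list(skipped = conditionMessage(e))
        })
    }
    out
  })

  volume_model <- stage("volume_model", {
    counts <- stats::xtabs(n_fes_impacted ~ year + driver_class,
                           data = heatmap)
    counts <- matrix(counts, nrow(counts), ncol(counts),
                     dimnames = dimnames(counts))
    n_pred <- sum(apply(counts, 2, function(col) {
      stats::var(col) > 0 && sum(col != 0) >= 3
    }))
    if (all(annual$fraction == 0)) {
      list(skipped = "all-zero annual impacted volume")
    } else if (nrow(annual) < n_pred + 10) {
      list(skipped = sprintf(
        "too few annual observations (%d) for %d driver predictors",
        nrow(annual), n_pred))
    } else {
      fit_volume_model(annual$fraction,
                       counts[as.character(annual$year), , drop = FALSE],
                       chains = config$chains_volume,
                       iter = config$iter_volume,
                       warmup = config$warmup_volume,
                       seed = config$seed + 200L)
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("benthovuln")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    simulate_seed = config$simulate$seed %||% NA,
    config_hash = config_hash(config),
    n_species = nrow(table), n_records = nrow(records),
    unquantified_count = inputs$unquantified_count,
    m_selected = m
  )

  report <- structure(list(
    redundancy = redundancy, trait_space = space,
    severity_bins = severity_bins, heatmap = heatmap, annual = annual,
    decades = decades, five_year = five_year, regional = regional,
    severity_models = severity_models, volume_model = volume_model,
    counts = list(n_records = nrow(records),
                  unquantified = inputs$unquantified_count,
                  severity_mix = prop.table(table(records$severity))),
    truth = inputs$truth,
    manifest = manifest
  ), class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, compress = FALSE)
  unname(tools::md5sum(f))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Write a run report to disk
#'
#' @param report A `run_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report$redundancy, file.path(dir, "redundancy.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(mad_profile = as.list(report$trait_space$mad_profile),
         m_selected = report$trait_space$m_selected,
         eigenvalues = report$trait_space$eigenvalues),
    file.path(dir, "trait_space.json"), auto_unbox = TRUE, digits = NA)
  coords <- report$trait_space$coordinates
  write_tsv(cbind(data.frame(fe_id = rownames(coords)), as.data.frame(coords)),
            file.path(dir, "fe_coordinates.tsv"))
  write_tsv(report$severity_bins, file.path(dir, "severity_bins.tsv"))
  write_tsv(report$heatmap, file.path(dir, "driver_year_heatmap.tsv"))
  write_tsv(report$annual, file.path(dir, "annual_impact.tsv"))
  write_tsv(report$decades, file.path(dir, "decade_summary.tsv"))
  write_tsv(report$five_year, file.path(dir, "five_year_summary.tsv"))
  reg <- report$regional
  jsonlite::write_json(
    lapply(reg, function(r) if (is.character(r)) r else unclass(r)),
    file.path(dir, "regional_resampling.json"), auto_unbox = TRUE,
    digits = NA)
  sev <- do.call(rbind, lapply(report$severity_models, function(mfit) {
    if (!is.null(mfit$skipped)) NULL else mfit$severity_by_category
  }))
  if (!is.null(sev)) write_tsv(sev, file.path(dir, "severity_by_category.tsv"))
  pars <- do.call(rbind, lapply(names(report$severity_models), function(tr) {
    mfit <- report$severity_models[[tr]]
    if (!is.null(mfit$skipped)) return(NULL)
    cbind(data.frame(model = tr), mfit$summary)
  }))
  if (!is.null(pars)) {
    write_tsv(pars, file.path(dir, "severity_model_summaries.tsv"))
  }
  diag <- do.call(rbind, lapply(names(report$severity_models), function(tr) {
    mfit <- report$severity_models[[tr]]
    if (!is.null(mfit$skipped)) {
      data.frame(model = tr, status = mfit$skipped, max_rhat = NA,
                 r2_median = NA)
    } else {
      data.frame(model = tr, status = "ok", max_rhat = max(mfit$fit$rhat),
                 r2_median = mfit$r2$median)
    }
  }))
  if (!is.null(report$volume_model$skipped)) {
    diag <- rbind(diag, data.frame(model = "volume",
                                   status = report$volume_model$skipped,
                                   max_rhat = NA, r2_median = NA))
  } else {
    diag <- rbind(diag, data.frame(
      model = "volume", status = "ok",
      max_rhat = max(report$volume_model$fit$rhat),
      r2_median = report$volume_model$r2$median))
    write_tsv(report$volume_model$summary,
              file.path(dir, "volume_model_summary.tsv"))
  }
  write_tsv(diag, file.path(dir, "model_diagnostics.tsv"))
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
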