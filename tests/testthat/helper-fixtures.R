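# Small in-code fixtures shared across tests.

# A valid species row under the default schema; override single traits.
base_signature <- function() {
  c(A = "a", B = "1", C = "a", D = "a", E = "a", F = "a", G = "1", H = "1",
    I = "a", J = "a")
}

make_table <- function(signatures, phylum = "Porifera") {
  # signatures: list of named character vectors (partial overrides of the base)
  rows <- lapply(seq_along(signatures), function(i) {
    sig <- base_signature()
    sig[names(signatures[[i]])] <- signatures[[i]]
    c(species = sprintf("sp_%02d", i), phylum = phylum, sig)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  as_trait_table(df)
}

random_table <- function(n, seed = 1) {
  cfg <- synthetic_config(n_species = n, seed = seed)
  generate_trait_table(cfg)
}

make_records <- function(species, percent, year = 2000,
                         longitude = 5, drivers = "temperature anomaly") {
  n <- length(species)
  percent <- rep_len(percent, n)
  dl <- lapply(rep_len(drivers, n), function(d) {
    strsplit(d, ";", fixed = TRUE)[[1]]
  })
  out <- data.frame(
    species = species, phylum = rep_len("Porifera", n),
    year = rep_len(year, n),
    longitude = rep_len(longitude, n), latitude = rep_len(40, n),
    depth_range = rep_len("0-10 m", n), habitat = rep_len("rocky reef", n),
    percent_mortality = percent, stringsAsFactors = FALSE
  )
  out$severity <- classify_severity(percent)
  out$driver_class <- classify_driver(dl)
  out$drivers <- I(dl)
  class(out) <- c("mortality_records", "data.frame")
  out
}

records_csv <- function(rows) {
  # rows: data.frame in the CSV interchange layout; returns a temp file path
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

fixture_run_config <- function(seed = 3, ...) {
  sim <- synthetic_config(
    n_species = 40, n_impacted_species = 12,
    events_per_period = c(60, 90, 150),
    year_range = c(1986L, 2000L),
    seed = seed
  )
  run_config(simulate = sim, dimension_candidates = 2:4,
             resample_n = 40, resample_R = 30,
             iter_severity = 2500, warmup_severity = 500,
             iter_volume = 2500, warmup_volume = 500,
             seed = seed, ...)
}
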