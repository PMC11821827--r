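#' Read and validate a species-by-trait table
#'
#' Expects a CSV with columns `species`, `phylum` and one column per trait
#' code of `schema` (A-J for the default schema). Every trait value must
#' belong to its trait's vocabulary; species names must be unique; missing
#' values are a validation error, never imputed.
#'
#' @param csv_source Path to a CSV file, or a connection.
#' @param schema A [trait_schema()]; defaults to [default_trait_schema()].
#' @return A `trait_table`: a data.frame with columns `species`, `phylum`
#'   and the trait columns (character), row order preserved, with the schema
#'   attached as attribute `schema`.
#' @export
read_trait_table <- function(csv_source, schema = default_trait_schema()) {
  df <- utils::read.csv(csv_source, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_trait_table(df, schema)
}

#' Validate a data.frame as a trait table
#'
#' @param df A data.frame with `species`, `phylum` and trait columns.
#' @inheritParams read_trait_table
#' @return A validated `trait_table`.
#' @export
as_trait_table <- function(df, schema = default_trait_schema()) {
  codes <- trait_codes(schema)
  need <- c("species", "phylum", codes)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, need, drop = FALSE]
  for (col in need) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$species)) {
    dup <- unique(df$species[duplicated(df$species)])
    stop("duplicate species: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_missing <- character(0)
  bad_value <- character(0)
  for (tr in schema$traits) {
    v <- df[[tr$code]]
    miss <- is.na(v) | !nzchar(trimws(v))
    if (any(miss)) {
      bad_missing <- c(bad_missing,
                       sprintf("%s (trait %s)", df$species[miss], tr$code))
    }
    unknown <- !miss & !(v %in% tr$categories)
    if (any(unknown)) {
      bad_value <- c(bad_value,
                     sprintf("%s: trait %s value '%s'",
                             df$species[unknown], tr$code, v[unknown]))
    }
  }
  if (length(bad_missing)) {
    stop("missing trait values for: ", paste(bad_missing, collapse = "; "),
         call. = FALSE)
  }
  if (length(bad_value)) {
    stop("unknown trait categories: ", paste(bad_value, collapse = "; "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, schema = schema, class = c("trait_table", "data.frame"))
}

#' @rdname read_trait_table
#' @param table A `trait_table`.
#' @param path Output CSV path.
#' @export
write_trait_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fe_signature_strings <- function(table, schema = attr(table, "schema")) {
  codes <- trait_codes(schema)
  do.call(paste, c(unname(as.list(as.data.frame(table)[codes])), sep = "|"))
}

#' Group species into functional entities
#'
#' A functional entity (FE) is the set of species sharing one exact
#' combination of the ten trait values. FE ids are assigned in lexicographic
#' order of the signature (trait values concatenated A..J), so the labelling
#' is deterministic and invariant to row order.
#'
#' @param table A validated `trait_table`.
#' @return An object of class `functional_entities`: a list with
#'   `fe` (data.frame: `fe_id`, one column per trait, `n_species`),
#'   `members` (named list fe_id -> character vector of species),
#'   `species_fe` (named character: species -> fe_id) and the schema.
#' @export
build_functional_entities <- function(table) {
  schema <- attr(table, "schema")
  stopifnot(inherits(table, "trait_table"))
  codes <- trait_codes(schema)
  sig <- fe_signature_strings(table, schema)
  usig <- sort(unique(sig))
  fe_id <- sprintf("FE_%03d", seq_along(usig))
  names(fe_id) <- usig
  species_fe <- fe_id[sig]
  names(species_fe) <- table$species
  members <- split(table$species, factor(species_fe, levels = fe_id))
  sigdf <- as.data.frame(do.call(rbind, strsplit(usig, "|", fixed = TRUE)),
                         stringsAsFactors = FALSE)
  names(sigdf) <- codes
  fe <- cbind(data.frame(fe_id = fe_id, stringsAsFactors = FALSE), sigdf)
  fe$n_species <- lengths(members)[fe$fe_id]
  rownames(fe) <- NULL
  structure(list(fe = fe, members = members, species_fe = species_fe,
                 schema = schema),
            class = "functional_entities")
}

#' @export
print.functional_entities <- function(x, ...) {
  cat(sprintf("functional_entities: %d FEs from %d species (max %d species/FE)\n",
              nrow(x$fe), length(x$species_fe), max(x$fe$n_species)))
  invisible(x)
}

#' Summarize functional redundancy
#'
#' @param fes A `functional_entities` object.
#' @return A list with `n_species`, `n_fes`, `n_singletons`,
#'   `singleton_share` (fraction of FEs holding a single species),
#'   `mean_species_per_fe`, `max_species_per_fe`. Means are kept at full
#'   precision; round only at presentation.
#' @export
summarize_redundancy <- function(fes) {
  stopifnot(inherits(fes, "functional_entities"))
  sizes <- fes$fe$n_species
  if (length(sizes) == 0L) stop("no functional entities", call. = FALSE)
  list(
    n_species = sum(sizes),
    n_fes = length(sizes),
    n_singletons = sum(sizes == 1L),
    singleton_share = sum(sizes == 1L) / length(sizes),
    mean_species_per_fe = sum(sizes) / length(sizes),
    max_species_per_fe = max(sizes)
  )
}

#' Map mortality records to impacted functional entities
#'
#' An FE counts as impacted as soon as any one of its member species appears
#' in any record of the subset: vulnerability of a single member marks the
#' whole entity as vulnerable.
#'
#' @param records A `mortality_records` data.frame (see
#'   [read_mortality_records()]) or any data.frame with a `species` column.
#' @param fes A `functional_entities` object.
#' @return Character vector of impacted fe_ids (sorted, no duplicates).
#' @export
impacted_fe_ids <- function(records, fes) {
  stopifnot(inherits(fes, "functional_entities"))
  sp <- unique(records$species)
  unknown <- setdiff(sp, names(fes$species_fe))
  if (length(unknown)) {
    stop("record species absent from trait table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sort(unique(unname(fes$species_fe[sp])))
}
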