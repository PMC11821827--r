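#' Trait schema: the typed vocabulary of the ten ecological traits
#'
#' A `trait_schema` is an ordered list of ten trait definitions. Each trait
#' carries a one-letter code (A-J), a human-readable name, a kind
#' (`"nominal"` or `"ordinal"`) and an ordered, duplicate-free category
#' vocabulary. Ordinal categories are totally ordered by their listed rank;
#' nominal categories have no order. The schema is the single source of truth
#' for validation of trait tables and for Gower dissimilarities.
#'
#' @param traits A list of trait definitions; each element is a list with
#'   fields `code`, `name`, `kind` and `categories`.
#' @return An object of class `trait_schema`.
#' @seealso [default_trait_schema()], [read_trait_schema()]
#' @export
trait_schema <- function(traits) {
  if (!is.list(traits) || length(traits) != 10L) {
    stop("a trait schema must define exactly 10 traits", call. = FALSE)
  }
  for (tr in traits) {
    if (!all(c("code", "name", "kind", "categories") %in% names(tr))) {
      stop("each trait needs fields code, name, kind, categories", call. = FALSE)
    }
    if (!tr$kind %in% c("nominal", "ordinal")) {
      stop(sprintf("trait %s: kind must be 'nominal' or 'ordinal'", tr$code),
           call. = FALSE)
    }
    cats <- as.character(tr$categories)
    if (length(cats) == 0L || anyDuplicated(cats)) {
      stop(sprintf("trait %s: category vocabulary must be non-empty and duplicate-free",
                   tr$code), call. = FALSE)
    }
  }
  codes <- vapply(traits, `[[`, character(1), "code")
  if (anyDuplicated(codes)) stop("duplicate trait codes", call. = FALSE)
  structure(list(traits = traits), class = "trait_schema")
}

#' Default ten-trait schema for Mediterranean benthic species
#'
#' Encodes the standard trait set used for benthic invertebrates and
#' macrophytes: feeding mode, maximum longevity, coloniality, morphological
#' form, carbon storage, energetic resource, height, growth rate,
#' calcification and motility. Nominal traits use lower-case letter labels;
#' ordinal (semi-quantitative) traits use digit labels whose listed order is
#' their rank. The same schema ships as machine-readable JSON in
#' `system.file("extdata", "trait_schema.json", package = "benthovuln")`.
#'
#' @return A `trait_schema`.
#' @export
default_trait_schema <- function() {
  trait_schema(list(
    list(code = "A", name = "feeding", kind = "nominal",
         categories = letters[1:7]),
    # a autotroph (none), b active filter feeder (cilia), c active filter
    # feeder (pumping), d passive filter feeder, e herbivore/grazer,
    # f carnivore, g detritivore
    list(code = "B", name = "maximum_longevity", kind = "ordinal",
         categories = as.character(1:5)),
    # 1 <=1y, 2 2-5y, 3 5-10y, 4 10-20y, 5 >20y
    list(code = "C", name = "coloniality", kind = "nominal",
         categories = c("a", "b")),          # a colonial/modular, b solitary
    list(code = "D", name = "morphological_form", kind = "nominal",
         categories = letters[1:12]),
    # a boring, b encrusting, c filamentous, d stolonial, e foliose-erect,
    # f articulated, g coarse-branched, h cup-like, i massive-encrusting,
    # j massive-hemispheric, k massive-erect, l tree-like
    list(code = "E", name = "carbon_storage", kind = "nominal",
         categories = c("a", "b", "c")),     # a yes, b potentially, c no
    list(code = "F", name = "energetic_resource", kind = "nominal",
         categories = c("a", "b", "c")),
    # a photosynthetic autotroph, b photo-heterotroph, c heterotroph
    list(code = "G", name = "height", kind = "ordinal",
         categories = as.character(1:5)),
    # 1 <2cm ... 5 >50cm
    list(code = "H", name = "growth_rate", kind = "ordinal",
         categories = as.character(1:5)),
    # 1 <1cm/y ... 5 >10cm/y
    list(code = "I", name = "calcification", kind = "nominal",
         categories = c("a", "b")),          # a calcareous, b non-calcareous
    list(code = "J", name = "motility", kind = "nominal",
         categories = c("a", "b"))           # a sessile, b vagile
  ))
}

#' @export
print.trait_schema <- function(x, ...) {
  cat("trait_schema with", length(x$traits), "traits\n")
  for (tr in x$traits) {
    cat(sprintf("  %s %-20s %-7s {%s}\n", tr$code, tr$name, tr$kind,
                paste(tr$categories, collapse = ",")))
  }
  invisible(x)
}

trait_codes <- function(schema) vapply(schema$traits, `[[`, character(1), "code")

schema_trait <- function(schema, code) {
  i <- match(code, trait_codes(schema))
  if (is.na(i)) stop(sprintf("unknown trait code '%s'", code), call. = FALSE)
  schema$traits[[i]]
}

#' Read or write a trait schema as JSON
#'
#' @param path Path to a JSON file with a top-level `traits` array.
#' @return `read_trait_schema()` returns a `trait_schema`;
#'   `write_trait_schema()` returns `path` invisibly.
#' @export
read_trait_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  traits <- lapply(obj$traits, function(tr) {
    list(code = tr$code, name = tr$name, kind = tr$kind,
         categories = unlist(tr$categories, use.names = FALSE))
  })
  trait_schema(traits)
}

#' @rdname read_trait_schema
#' @param schema A `trait_schema`.
#' @export
write_trait_schema <- function(schema, path) {
  jsonlite::write_json(list(traits = schema$traits), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Controlled mortality-driver vocabulary. "other" is disambiguated per class
# so that a flat label list remains unambiguous in CSV interchange.
abiotic_drivers <- function() {
  c("temperature anomaly", "storm", "pollution", "turbidity increase",
    "other abiotic")
}

biotic_drivers <- function() {
  c("disease", "mucilage coverage", "predator outbreak", "other biotic")
}

#' Controlled vocabulary of mortality drivers
#'
#' Nine driver labels, each tagged abiotic or biotic.
#'
#' @return A data.frame with columns `driver` and `class`.
#' @export
driver_vocabulary <- function() {
  data.frame(
    driver = c(abiotic_drivers(), biotic_drivers()),
    class = rep(c("abiotic", "biotic"),
                c(length(abiotic_drivers()), length(biotic_drivers()))),
    stringsAsFactors = FALSE
  )
}

#' The twelve driver classes used for driver-by-year summaries
#'
#' Single-driver records fall in their driver's own class; records with
#' several drivers of one class fall in that class's "combination"; records
#' mixing abiotic and biotic drivers fall in the combined class.
#'
#' @return Character vector of the 12 class labels.
#' @export
driver_classes <- function() {
  c(abiotic_drivers(), "abiotic combination",
    biotic_drivers(), "biotic combination",
    "abiotic-biotic combination")
}
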