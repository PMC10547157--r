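#' Registry of compounds handled by the artificial phosphoketolase pathway
#'
#' Returns the bundled registry of every compound the APK route touches:
#' the C1--C6 sugars and sugar phosphates, the C2 products (acetyl-phosphate,
#' acetate, acetyl-CoA), and the feeder alcohols that enter through a single
#' dehydrogenase/oxidase step. Phosphate positions are one-based indices on
#' the carbon backbone; `carbon_weight_role` marks how a compound is treated
#' in yield accounting.
#'
#' @return A tibble with columns `id`, `name`, `n_carbons`, `sugar_class`
#'   (`"aldose"`, `"ketose"` or `"nonsugar"`), `phospho_position` (integer or
#'   `NA`), and `carbon_weight_role` (`"source"`, `"intermediate"` or
#'   `"terminal"`).
#' @examples
#' apk_species()
#' @export
apk_species <- function() {
  tibble::tribble(
    ~id,               ~name,                             ~n_carbons, ~sugar_class, ~phospho_position, ~carbon_weight_role,
    "HCHO",            "formaldehyde",                    1L,  "aldose",   NA_integer_, "intermediate",
    "GALD",            "glycolaldehyde",                  2L,  "aldose",   NA_integer_, "intermediate",
    "GCD",             "D-glyceraldehyde",                3L,  "aldose",   NA_integer_, "intermediate",
    "DHA",             "dihydroxyacetone",                3L,  "ketose",   NA_integer_, "intermediate",
    "G3P",             "D-glyceraldehyde 3-phosphate",    3L,  "aldose",   3L,          "intermediate",
    "DHAP",            "dihydroxyacetone phosphate",      3L,  "ketose",   1L,          "intermediate",
    "D-ETS",           "D-erythrose",                     4L,  "aldose",   NA_integer_, "intermediate",
    "D-EUS",           "D-erythrulose",                   4L,  "ketose",   NA_integer_, "intermediate",
    "L-EUS",           "L-erythrulose",                   4L,  "ketose",   NA_integer_, "intermediate",
    "E4P",             "D-erythrose 4-phosphate",         4L,  "aldose",   4L,          "intermediate",
    "Eu4P",            "D-erythrulose 4-phosphate",       4L,  "ketose",   4L,          "intermediate",
    "Xu5P",            "D-xylulose 5-phosphate",          5L,  "ketose",   5L,          "source",
    "F6P",             "D-fructose 6-phosphate",          6L,  "ketose",   6L,          "source",
    "AcP",             "acetyl-phosphate",                2L,  "nonsugar", NA_integer_, "terminal",
    "acetate",         "acetate",                         2L,  "nonsugar", NA_integer_, "terminal",
    "AcCoA",           "acetyl-CoA",                      2L,  "nonsugar", NA_integer_, "terminal",
    "methanol",        "methanol",                        1L,  "nonsugar", NA_integer_, "source",
    "ethylene_glycol", "ethylene glycol",                 2L,  "nonsugar", NA_integer_, "source",
    "ethanolamine",    "ethanolamine",                    2L,  "nonsugar", NA_integer_, "source",
    "glycerol",        "glycerol",                        3L,  "nonsugar", NA_integer_, "source",
    "erythritol",      "erythritol",                      4L,  "nonsugar", NA_integer_, "source"
  )
}

#' Enzyme capability tables of the APK toolbox
#'
#' The empirical whitelists that the network generator consults: which
#' compounds phosphoketolase accepts (phosphate anchoring excludes DHAP and
#' Eu4P), which aldose/ketose pairs an isomerase interconverts, which sugar
#' phosphates a selective phosphatase hydrolyzes, the formose carboligation
#' variants that recycle formaldehyde, and the one-step feeder oxidations of
#' C1--C4 alcohols. These are curated sets, not structural predicates: the
#' substrate scope of phosphoketolase is an experimental finding. There is
#' deliberately no isomerase entry for free glyceraldehyde, which forces the
#' G3P branch to isomerize at the phosphate level before dephosphorylation.
#'
#' @return A list with elements `pk_substrates` (character), `cleavage`
#'   (named character: substrate id -> remainder id, `NA` for the C2 case),
#'   `isomerase_pairs`, `phosphatase_pairs`, `formose_variants` and `feeders`
#'   (tibbles).
#' @examples
#' apk_capabilities()$pk_substrates
#' @export
apk_capabilities <- function() {
  list(
    pk_substrates = c("F6P", "Xu5P", "D-EUS", "L-EUS", "DHA", "GALD"),
    cleavage = c(
      "F6P" = "E4P", "Xu5P" = "G3P", "D-EUS" = "GALD",
      "L-EUS" = "GALD", "DHA" = "HCHO", "GALD" = NA_character_
    ),
    isomerase_pairs = tibble::tribble(
      ~from,    ~to,     ~enzyme,
      "D-ETS",  "D-EUS", "Ps-LRhI",
      "G3P",    "DHAP",  "EcTIM"
    ),
    phosphatase_pairs = tibble::tribble(
      ~from,   ~to,     ~enzyme,
      "E4P",   "D-ETS", "EcHAD",
      "DHAP",  "DHA",   "CpHAD"
    ),
    formose_variants = tibble::tribble(
      ~variant, ~n_hcho, ~product, ~enzyme,
      "fls",    3L,      "DHA",    "FLS",
      "gals",   2L,      "GALD",   "GALS"
    ),
    feeders = tibble::tribble(
      ~from,             ~to,     ~enzyme, ~untested,
      "methanol",        "HCHO",  "MDH",   TRUE,
      "ethylene_glycol", "GALD",  "EGDH",  TRUE,
      "ethanolamine",    "GALD",  "EOX",   TRUE,
      "glycerol",        "DHA",   "GDH",   TRUE,
      "erythritol",      "D-EUS", "ERDH",  TRUE
    )
  )
}

species_lookup <- function(id, registry = apk_species()) {
  hit <- registry[registry$id == id, ]
  if (nrow(hit) != 1) {
    stop("unknown species id: '", id, "'", call. = FALSE)
  }
  hit
}

n_carbons_of <- function(ids, registry = apk_species()) {
  idx <- match(ids, registry$id)
  if (anyNA(idx)) {
    stop("unknown species id: '", ids[which(is.na(idx))[1]], "'", call. = FALSE)
  }
  registry$n_carbons[idx]
}

#' Is a compound a phosphoketolase substrate?
#'
#' @param id Species id (see [apk_species()]).
#' @param capabilities Capability tables, default [apk_capabilities()].
#' @param registry Species registry, default [apk_species()].
#' @return Logical scalar.
#' @examples
#' is_pk_substrate("F6P")   # TRUE
#' is_pk_substrate("DHAP")  # FALSE: phosphate anchoring blocks cleavage
#' @export
is_pk_substrate <- function(id, capabilities = apk_capabilities(),
                            registry = apk_species()) {
  species_lookup(id, registry)
  id %in% capabilities$pk_substrates
}

#' Products of a single phosphoketolase cleavage
#'
#' Phosphoketolase breaks the C2--C3 bond of an accepted ketose (or, for
#' glycolaldehyde, consumes the whole C2 unit), releasing acetyl-phosphate
#' plus the two-carbon-shorter aldose remainder. Carbon is conserved exactly:
#' the substrate's carbon count equals 2 plus the remainder's.
#'
#' @inheritParams is_pk_substrate
#' @return A tibble with one row: `substrate`, `acp` (always `"AcP"`), and
#'   `remainder` (species id or `NA` for the C2 substrate).
#' @examples
#' pk_cleavage_products("Xu5P")  # AcP + G3P
#' pk_cleavage_products("GALD")  # AcP, no remainder
#' @export
pk_cleavage_products <- function(id, capabilities = apk_capabilities(),
                                 registry = apk_species()) {
  species_lookup(id, registry)
  if (!id %in% capabilities$pk_substrates) {
    stop("'", id, "' is not a phosphoketolase substrate", call. = FALSE)
  }
  tibble::tibble(
    substrate = id,
    acp = "AcP",
    remainder = unname(capabilities$cleavage[[id]])
  )
}

#' Serialize or load the species registry as versioned JSON
#'
#' The bundled registry and capability tables can be written to, and
#' overridden from, a plain JSON document so that alternative substrate
#' whitelists (e.g. widened phosphoketolase scope) can be supplied as config.
#'
#' @param path File path.
#' @param registry Species registry tibble.
#' @param capabilities Capability tables list.
#' @return `write_registry_json()` returns `path` invisibly;
#'   `read_registry_json()` returns a list with elements `registry` and
#'   `capabilities`.
#' @export
write_registry_json <- function(path, registry = apk_species(),
                                capabilities = apk_capabilities()) {
  capabilities$cleavage <- as.list(capabilities$cleavage)  # keep names in JSON
  doc <- list(
    format = "apk-registry",
    version = 1L,
    species = registry,
    capabilities = capabilities
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_registry_json
#' @export
read_registry_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "apk-registry")) {
    stop("not an apk registry document: ", path, call. = FALSE)
  }
  reg <- tibble::as_tibble(doc$species)
  reg$n_carbons <- as.integer(reg$n_carbons)
  reg$phospho_position <- as.integer(reg$phospho_position)
  caps <- doc$capabilities
  caps$cleavage <- unlist(lapply(caps$cleavage, function(x) {
    if (is.null(x)) NA_character_ else x
  }))
  for (nm in c("isomerase_pairs", "phosphatase_pairs", "formose_variants", "feeders")) {
    caps[[nm]] <- tibble::as_tibble(caps[[nm]])
  }
  list(registry = reg, capabilities = caps)
}
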