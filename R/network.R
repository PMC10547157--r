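#' Generate the APK reaction network for a carbon source
#'
#' Expands the pathway breadth-first from `source`, applying a fixed routing
#' policy to each newly discovered compound:
#'
#' 1. cleave with phosphoketolase whenever the compound is an accepted
#'    substrate;
#' 2. for a sugar phosphate, dephosphorylate first and isomerize the free
#'    sugar when a free-sugar isomerase exists for the product (the E4P
#'    branch); otherwise isomerize at the phosphate level and then
#'    dephosphorylate (the G3P branch, forced because no free glyceraldehyde
#'    isomerase is available);
#' 3. condense formaldehyde via the chosen formose variant (`"fls"`: 3 HCHO
#'    -> dihydroxyacetone by formolase; `"gals"`: 2 HCHO -> glycolaldehyde by
#'    glycolaldehyde synthase), or leave it as a terminal loss when
#'    `recycle = "none"`.
#'
#' Feeder alcohols (methanol, ethylene glycol, ethanolamine, glycerol,
#' erythritol) first enter through their one-step oxidation (see
#' [feeder_entry()]) and then follow the same policy. Expansion terminates
#' because the species universe is finite; reaction order is discovery order
#' and regeneration is deterministic.
#'
#' @param source Species id of the carbon source.
#' @param recycle One of `"fls"` (default), `"gals"`, `"none"` -- the
#'   formaldehyde recycle variant. Formolase is the default because
#'   phosphoketolase has the higher affinity for dihydroxyacetone.
#' @param registry,capabilities Registry and capability tables; override to
#'   explore alternative substrate scopes.
#' @param routing_overrides Optional named character vector mapping a species
#'   id to a forced action (`"cleave"`, `"dephosphorylate"`, `"isomerize"`),
#'   honored before the default priority.
#' @return An object of class `apk_design`: a list with `source`,
#'   `recycle_mode`, `reactions` (a tibble with columns `id`, `rtype`,
#'   `enzyme`, `reversible`, `equation` and a `stoich` list-column of named
#'   signed coefficients) and `species` (all ids touched).
#' @examples
#' apk_design("F6P")
#' apk_design("Xu5P", recycle = "fls")
#' tidy(apk_design("GALD", recycle = "none"))
#' @export
apk_design <- function(source, recycle = c("fls", "gals", "none"),
                       registry = apk_species(),
                       capabilities = apk_capabilities(),
                       routing_overrides = NULL) {
  recycle <- match.arg(recycle)
  species_lookup(source, registry)
  caps <- capabilities

  reactions <- list()
  add_reaction <- function(rtype, enzyme, stoich, reversible = FALSE) {
    check_reaction_carbon(stoich, registry)
    reactions[[length(reactions) + 1]] <<- list(
      rtype = rtype, enzyme = enzyme, stoich = stoich, reversible = reversible
    )
  }

  terminal_ids <- c("AcP", "acetate", "AcCoA")
  queue <- source
  visited <- character(0)

  while (length(queue) > 0) {
    s <- queue[[1]]
    queue <- queue[-1]
    if (s %in% visited || s %in% terminal_ids) next
    visited <- c(visited, s)
    info <- species_lookup(s, registry)

    feeders <- caps$feeders
    iso <- caps$isomerase_pairs
    phos <- caps$phosphatase_pairs

    forced <- if (!is.null(routing_overrides) && s %in% names(routing_overrides)) {
      routing_overrides[[s]]
    } else NA_character_

    act <- NA_character_
    if (!is.na(forced)) {
      act <- forced
    } else if (s %in% caps$pk_substrates) {
      act <- "cleave"
    } else if (s %in% feeders$from) {
      act <- "feed"
    } else if (!is.na(info$phospho_position)) {
      free_to <- phos$to[match(s, phos$from)]
      # dephosphorylate-then-isomerize when the free sugar has an isomerase
      if (!is.na(free_to) && (free_to %in% iso$from || free_to %in% caps$pk_substrates)) {
        act <- "dephosphorylate"
      } else if (s %in% iso$from) {
        act <- "isomerize"
      } else if (!is.na(free_to)) {
        act <- "dephosphorylate"
      }
    } else if (s %in% iso$from) {
      act <- "isomerize"
    } else if (s == "HCHO") {
      act <- if (recycle == "none") "terminal" else "condense"
    }

    if (is.na(act)) {
      stop("dead-end species '", s, "': no applicable rule (recycle = ",
           recycle, ")", call. = FALSE)
    }

    if (act == "cleave") {
      if (!s %in% caps$pk_substrates) {
        stop("'", s, "' is not a phosphoketolase substrate", call. = FALSE)
      }
      rem <- unname(caps$cleavage[[s]])
      stoich <- c(-1, 1)
      names(stoich) <- c(s, "AcP")
      if (!is.na(rem)) {
        stoich <- c(stoich, stats::setNames(1, rem))
        queue <- c(queue, rem)
      }
      add_reaction("pk_cleavage", "BbPK", stoich)
    } else if (act == "feed") {
      row <- feeders[feeders$from == s, ]
      add_reaction("feeder_oxidation", row$enzyme,
                   stats::setNames(c(-1, 1), c(s, row$to)))
      queue <- c(queue, row$to)
    } else if (act == "dephosphorylate") {
      row <- phos[phos$from == s, ]
      if (nrow(row) != 1) stop("no phosphatase for '", s, "'", call. = FALSE)
      add_reaction("dephosphorylation", row$enzyme,
                   stats::setNames(c(-1, 1), c(s, row$to)))
      queue <- c(queue, row$to)
    } else if (act == "isomerize") {
      row <- iso[iso$from == s, ]
      if (nrow(row) != 1) stop("no isomerase for '", s, "'", call. = FALSE)
      add_reaction("isomerization", row$enzyme,
                   stats::setNames(c(-1, 1), c(s, row$to)), reversible = TRUE)
      queue <- c(queue, row$to)
    } else if (act == "condense") {
      var <- caps$formose_variants[caps$formose_variants$variant == recycle, ]
      add_reaction("formose_condensation", var$enzyme,
                   stats::setNames(c(-var$n_hcho, 1), c("HCHO", var$product)))
      queue <- c(queue, var$product)
    } # "terminal": nothing to add

  }

  rx <- tibble::tibble(
    id = paste0("R", seq_along(reactions)),
    rtype = vapply(reactions, `[[`, character(1), "rtype"),
    enzyme = vapply(reactions, `[[`, character(1), "enzyme"),
    reversible = vapply(reactions, `[[`, logical(1), "reversible"),
    stoich = lapply(reactions, `[[`, "stoich")
  )
  rx$equation <- vapply(rx$stoich, format_equation, character(1))

  all_species <- unique(c(source, unlist(lapply(rx$stoich, names))))
  structure(
    list(source = source, recycle_mode = recycle, reactions = rx,
         species = all_species, registry = registry),
    class = "apk_design"
  )
}

check_reaction_carbon <- function(stoich, registry) {
  carbons <- sum(stoich * n_carbons_of(names(stoich), registry))
  if (carbons != 0) {
    stop("reaction does not conserve carbon: ", format_equation(stoich),
         call. = FALSE)
  }
  invisible(TRUE)
}

format_equation <- function(stoich) {
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  fmt <- function(x) {
    paste(ifelse(abs(x) == 1, names(x), paste(abs(x), names(x))), collapse = " + ")
  }
  paste(fmt(lhs), "->", fmt(rhs))
}

#' One-step feeder oxidation entering the APK pathway
#'
#' Maps a feeder alcohol to its dehydrogenase/oxidase entry reaction:
#' methanol -> formaldehyde (MDH), ethylene glycol -> glycolaldehyde (EGDH),
#' ethanolamine -> glycolaldehyde (EOX), glycerol -> dihydroxyacetone (GDH),
#' erythritol -> D-erythrulose (ERDH). Entries drawn with dashed arrows in
#' the source figure (not experimentally verified) carry `untested = TRUE`.
#'
#' @param alcohol Feeder species id.
#' @param capabilities Capability tables.
#' @return One-row tibble with `from`, `to`, `enzyme`, `untested`, `equation`.
#' @examples
#' feeder_entry("glycerol")
#' @export
feeder_entry <- function(alcohol, capabilities = apk_capabilities()) {
  feeders <- capabilities$feeders
  if (!alcohol %in% feeders$from) {
    stop("'", alcohol, "' is not a feeder alcohol", call. = FALSE)
  }
  row <- feeders[feeders$from == alcohol, ]
  row$equation <- paste(row$from, "->", row$to)
  row
}

#' Count distinct core reaction types in a design
#'
#' The core categories are phosphoketolase cleavage, isomerization,
#' dephosphorylation and (when recycling is active) formose condensation;
#' feeder oxidations and terminal transfers are auxiliary and not counted.
#'
#' @param design An [apk_design()] object.
#' @return Integer count.
#' @examples
#' count_reaction_types(apk_design("F6P"))   # 3
#' count_reaction_types(apk_design("Xu5P"))  # 4
#' @export
count_reaction_types <- function(design) {
  stopifnot(inherits(design, "apk_design"))
  core <- c("pk_cleavage", "isomerization", "dephosphorylation")
  if (design$recycle_mode != "none") core <- c(core, "formose_condensation")
  length(intersect(unique(design$reactions$rtype), core))
}

#' Terminal transfer of acetyl-phosphate
#'
#' Acetyl-phosphate is converted downstream either to acetyl-CoA by phosphate
#' acetyltransferase (PTA) or to acetate (plus ATP) by acetate kinase (AckA).
#' This auxiliary step is not part of the generated designs, whose terminal
#' product is acetyl-phosphate itself.
#'
#' @param product `"AcCoA"` or `"acetate"`.
#' @return One-row tibble describing the transfer reaction.
#' @export
acp_transfer <- function(product = c("AcCoA", "acetate")) {
  product <- match.arg(product)
  tibble::tibble(
    rtype = "terminal_transfer",
    enzyme = if (product == "AcCoA") "PTA" else "AckA",
    stoich = list(stats::setNames(c(-1, 1), c("AcP", product))),
    equation = paste("AcP ->", product)
  )
}

#' Serialize a pathway design to JSON
#'
#' @param design An [apk_design()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "apk_design"))
  rx <- design$reactions
  doc <- list(
    format = "apk-design",
    version = 1L,
    source = design$source,
    recycle_mode = design$recycle_mode,
    reactions = lapply(seq_len(nrow(rx)), function(i) {
      list(id = rx$id[i], rtype = rx$rtype[i], enzyme = rx$enzyme[i],
           reversible = rx$reversible[i], stoich = as.list(rx$stoich[[i]]))
    }),
    species = design$species
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.apk_design <- function(x, ...) {
  cat("APK pathway design\n")
  cat("  source:  ", x$source, "\n", sep = "")
  cat("  recycle: ", x$recycle_mode, "\n", sep = "")
  cat("  reactions (discovery order):\n")
  for (i in seq_len(nrow(x$reactions))) {
    cat(sprintf("    %-3s %-22s %-8s %s\n", x$reactions$id[i],
                x$reactions$rtype[i], x$reactions$enzyme[i],
                x$reactions$equation[i]))
  }
  invisible(x)
}
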