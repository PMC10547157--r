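#' Stoichiometric matrix of a pathway design
#'
#' @param design An [apk_design()] object.
#' @return Integer matrix, species (rows) by reactions (columns); negative
#'   entries are consumed, positive produced.
#' @examples
#' stoich_matrix(apk_design("F6P"))
#' @export
stoich_matrix <- function(design) {
  stopifnot(inherits(design, "apk_design"))
  sp <- design$species
  rx <- design$reactions
  S <- matrix(0L, nrow = length(sp), ncol = nrow(rx),
              dimnames = list(sp, rx$id))
  for (j in seq_len(nrow(rx))) {
    st <- rx$stoich[[j]]
    S[names(st), j] <- as.integer(st)
  }
  S
}

# species never consumed by any reaction are terminal outputs
terminal_species <- function(design) {
  S <- stoich_matrix(design)
  rownames(S)[apply(S, 1, function(r) all(r >= 0))]
}

#' Exact overall reaction and carbon yield of a design
#'
#' Solves for the nonnegative rational flux vector that consumes exactly one
#' mole of the source while every internal intermediate has zero net
#' production, using exact rational Gaussian elimination (recycle-loop
#' stoichiometries such as 5/2 acetyl-phosphate per xylulose-5-phosphate come
#' out exact). Free flux directions that do not change the net overall
#' reaction (e.g. a duplicated reaction) are resolved to the minimal-support
#' solution; free directions that do change it raise an ambiguity error.
#' With recycling off, the stranded formaldehyde simply appears as a terminal
#' product of the overall reaction.
#'
#' Carbon yield is `2 * AcP per source / n_carbons(source)`, the carbon-mole
#' fraction ending in the two-carbon product.
#'
#' @param design An [apk_design()] object.
#' @return An object of class `apk_yield`: list with `source`, `recycle_mode`,
#'   `acp_per_source` and `carbon_yield` (numeric, with exact fraction strings
#'   in `acp_exact` / `yield_exact`), `overall` (tibble of net coefficients
#'   over non-internal species), and `flux` (tibble of reaction fluxes).
#' @examples
#' overall_reaction(apk_design("F6P"))          # 3 AcP per F6P, yield 1
#' overall_reaction(apk_design("Xu5P"))         # 5/2 AcP per Xu5P, yield 1
#' overall_reaction(apk_design("DHA", recycle = "none"))  # 1 AcP + 1 HCHO
#' @export
overall_reaction <- function(design) {
  stopifnot(inherits(design, "apk_design"))
  S <- stoich_matrix(design)
  registry <- design$registry %||% apk_species()
  sp <- rownames(S)
  term <- terminal_species(design)
  internal <- setdiff(sp, c(design$source, term))

  # constraint rows: source row = -1, internal rows = 0
  A <- S[c(design$source, internal), , drop = FALSE]
  b <- c(-1, rep(0, length(internal)))
  aug_num <- cbind(A, b)
  aug_den <- matrix(1, nrow(aug_num), ncol(aug_num))
  rr <- rat_rref(aug_num, aug_den)

  nvar <- ncol(A)
  pivots <- setdiff(rr$pivots, nvar + 1L)
  if ((nvar + 1L) %in% rr$pivots) {
    stop("infeasible flux system for source '", design$source, "'",
         call. = FALSE)
  }
  free <- setdiff(seq_len(nvar), pivots)

  # minimal-support particular solution: free fluxes at zero
  v_num <- rep(0, nvar); v_den <- rep(1, nvar)
  for (k in seq_along(pivots)) {
    v_num[pivots[k]] <- rr$num[k, nvar + 1L]
    v_den[pivots[k]] <- rr$den[k, nvar + 1L]
  }

  if (length(free) > 0) {
    # nullspace direction for free column j: z_j = 1, z_piv = -rref coeff
    for (j in free) {
      z_num <- rep(0, nvar); z_den <- rep(1, nvar)
      z_num[j] <- 1
      for (k in seq_along(pivots)) {
        z_num[pivots[k]] <- -rr$num[k, j]
        z_den[pivots[k]] <- rr$den[k, j]
      }
      net <- S %*% (z_num / z_den)
      keep <- setdiff(sp, internal)
      if (any(abs(net[keep, 1]) > 1e-9)) {
        stop("underdetermined network: free flux direction through ",
             design$reactions$id[j], " changes the overall reaction",
             call. = FALSE)
      }
    }
  }

  if (any(v_num / v_den < 0)) {
    stop("no nonnegative flux solution for source '", design$source, "'",
         call. = FALSE)
  }

  # net production of non-internal species, exactly
  ext <- setdiff(sp, internal)
  net <- lapply(ext, function(s) {
    acc <- rat(0)
    for (j in seq_len(nvar)) {
      if (S[s, j] != 0) {
        acc <- rat_add(acc, rat_mul(rat(S[s, j]), rat(v_num[j], v_den[j])))
      }
    }
    acc
  })
  names(net) <- ext

  acp <- net[["AcP"]] %||% rat(0)
  ncarb <- n_carbons_of(design$source, registry)
  yield <- rat_div(rat_mul(rat(2), acp), rat(ncarb))

  overall <- tibble::tibble(
    species = ext,
    coefficient = unname(vapply(net, rat_value, numeric(1))),
    exact = unname(vapply(net, rat_format, character(1)))
  )
  overall <- overall[overall$coefficient != 0 | overall$species == design$source, ]

  structure(
    list(
      source = design$source,
      recycle_mode = design$recycle_mode,
      acp_per_source = rat_value(acp),
      acp_exact = rat_format(acp),
      carbon_yield = rat_value(yield),
      yield_exact = rat_format(yield),
      overall = overall,
      flux = tibble::tibble(
        reaction = design$reactions$id,
        equation = design$reactions$equation,
        flux = v_num / v_den,
        exact = rat_format(list(num = v_num, den = v_den))
      )
    ),
    class = "apk_yield"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Theoretical carbon yield of the APK pathway for a source
#'
#' Generates the design and solves its exact overall reaction. With
#' formaldehyde recycling on, every C1--C6 source reaches yield 1; with
#' recycling off, odd-carbon sources strand one formaldehyde, giving
#' (n-1)/n for a Cn free ketose.
#'
#' @inheritParams apk_design
#' @return Numeric yield in `[0, 1]` (exact-rational value).
#' @examples
#' theoretical_yield("Xu5P")                    # 1
#' theoretical_yield("DHA", recycle = "none")   # 2/3
#' @export
theoretical_yield <- function(source, recycle = c("fls", "gals", "none"),
                              registry = apk_species(),
                              capabilities = apk_capabilities()) {
  recycle <- match.arg(recycle)
  design <- apk_design(source, recycle = recycle, registry = registry,
                       capabilities = capabilities)
  overall_reaction(design)$carbon_yield
}

#' The canonical glycolytic route as a yield reference
#'
#' The bundled benchmark: glucose through the ten Embden--Meyerhof--Parnas
#' steps to two pyruvate, then pyruvate dehydrogenase to acetyl-CoA -- eleven
#' reactions in all, two acetyl-CoA per glucose, and a carbon yield of 4/6
#' (two CO2 lost), reported as a whole percent (67%).
#'
#' @return List with `reactions` (tibble of the 11 steps), `n_reactions`,
#'   `accoa_per_glucose`, `carbon_yield` (fraction) and
#'   `carbon_yield_percent` (rounded half-up).
#' @examples
#' glycolysis_reference()$carbon_yield_percent  # 67
#' @export
glycolysis_reference <- function() {
  steps <- tibble::tribble(
    ~step, ~enzyme,                                ~per_glucose, ~co2_out, ~accoa_out,
    1L,  "hexokinase",                             1L, 0L, 0L,
    2L,  "phosphoglucose isomerase",               1L, 0L, 0L,
    3L,  "phosphofructokinase",                    1L, 0L, 0L,
    4L,  "fructose-bisphosphate aldolase",         1L, 0L, 0L,
    5L,  "triose-phosphate isomerase",             1L, 0L, 0L,
    6L,  "glyceraldehyde-3-phosphate dehydrogenase", 2L, 0L, 0L,
    7L,  "phosphoglycerate kinase",                2L, 0L, 0L,
    8L,  "phosphoglycerate mutase",                2L, 0L, 0L,
    9L,  "enolase",                                2L, 0L, 0L,
    10L, "pyruvate kinase",                        2L, 0L, 0L,
    11L, "pyruvate dehydrogenase",                 2L, 1L, 1L
  )
  accoa <- sum(steps$per_glucose * steps$accoa_out)
  co2 <- sum(steps$per_glucose * steps$co2_out)
  yield <- rat(2 * accoa, 6)  # acetyl carbons over glucose carbons
  stopifnot(2 * accoa + co2 == 6)  # carbon closes over the route
  list(
    reactions = steps,
    n_reactions = nrow(steps),
    accoa_per_glucose = accoa,
    carbon_yield = rat_value(yield),
    carbon_yield_percent = round_half_up(100 * rat_value(yield))
  )
}

round_half_up <- function(x) floor(x + 0.5)

#' @export
print.apk_yield <- function(x, ...) {
  cat("APK yield report --", x$source, "(recycle:", x$recycle_mode, ")\n")
  cat("  AcP per source: ", x$acp_exact, "\n", sep = "")
  cat("  carbon yield:   ", x$yield_exact,
      sprintf(" (%.4g)", x$carbon_yield), "\n", sep = "")
  lhs <- x$overall[x$overall$coefficient < 0, ]
  rhs <- x$overall[x$overall$coefficient > 0, ]
  fmt <- function(d) paste(ifelse(abs(d$coefficient) == 1, d$species,
                                  paste(sub("^-", "", d$exact), d$species)),
                           collapse = " + ")
  cat("  overall: ", fmt(lhs), " -> ", fmt(rhs), "\n", sep = "")
  invisible(x)
}
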