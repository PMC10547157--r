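#' Default kinetic parameter set for the in vitro cascades
#'
#' Per (enzyme, substrate) catalytic constants plus per-enzyme loadings and
#' molar masses for the shipped cascade scenarios. The loadings are the
#' printed in vitro recipe (phosphoketolase 2, EcHAD 0.5, Ps-LRhI 1, CpHAD 1,
#' EcTIM 0.1, FLS 2 mg/mL, 10 mM substrate). The kcat/Km values are
#' **plausible placeholders, not measured ground truth** -- the underlying
#' kinetic table is not printed in the source text. They are constrained to
#' respect the printed orderings: fast cleavage of the phosphorylated ketoses
#' (consumed within ~2 h), a slow short-chain tail (glycolaldehyde,
#' dihydroxyacetone, D-erythrulose), and a higher phosphoketolase affinity
#' for dihydroxyacetone than for glycolaldehyde (the reason formolase is the
#' default recycle variant). The EcTIM turnover number is deliberately far
#' below the diffusion-limited literature value so the explicit integrator is
#' not stability-limited; only its net flux matters at this resolution.
#'
#' @param rate_law `"competitive"` (default): substrates of one enzyme share
#'   a single active site and compete; `"independent"`: independent
#'   Michaelis-Menten terms per substrate.
#' @return Object of class `apk_parameters`: list with tibbles `kinetics`
#'   (`enzyme`, `substrate`, `kcat` /s, `km` mM, `keq` for reversible steps)
#'   and `enzymes` (`enzyme`, `loading` mg/mL, `mass_kda`), plus `rate_law`.
#' @examples
#' apk_parameters()
#' @export
apk_parameters <- function(rate_law = c("competitive", "independent")) {
  rate_law <- match.arg(rate_law)
  kinetics <- tibble::tribble(
    ~enzyme,   ~substrate, ~kcat, ~km,  ~keq,
    "BbPK",    "F6P",      0.6,   3,    NA,
    "BbPK",    "Xu5P",     0.8,   2,    NA,
    "BbPK",    "D-EUS",    0.25,  30,   NA,
    "BbPK",    "L-EUS",    0.15,  40,   NA,
    "BbPK",    "GALD",     0.18,  50,   NA,
    "BbPK",    "DHA",      0.18,  20,   NA,
    "EcHAD",   "E4P",      5,     2,    NA,
    "CpHAD",   "DHAP",     5,     2,    NA,
    "Ps-LRhI", "D-ETS",    10,    10,   3,
    "EcTIM",   "G3P",      5,     0.5,  20,
    "FLS",     "HCHO",     0.5,   30,   NA,
    "GALS",    "HCHO",     0.5,   30,   NA,
    "MDH",     "methanol",        1, 10, NA,
    "EGDH",    "ethylene_glycol", 1, 10, NA,
    "EOX",     "ethanolamine",    1, 10, NA,
    "GDH",     "glycerol",        1, 10, NA,
    "ERDH",    "erythritol",      1, 10, NA
  )
  enzymes <- tibble::tribble(
    ~enzyme,   ~loading, ~mass_kda,
    "BbPK",    2,    92,
    "EcHAD",   0.5,  30,
    "Ps-LRhI", 1,    47,
    "CpHAD",   1,    28,
    "EcTIM",   0.1,  27,
    "FLS",     2,    60,
    "GALS",    2,    60,
    "MDH",     1,    40,
    "EGDH",    1,    40,
    "EOX",     1,    40,
    "GDH",     1,    40,
    "ERDH",    1,    40
  )
  structure(list(kinetics = kinetics, enzymes = enzymes, rate_law = rate_law),
            class = "apk_parameters")
}

#' Phosphoketolase point mutants and their catalytic-efficiency gains
#'
#' The engineered single-point mutants and the fold-improvements of kcat/Km
#' over wild type that the defaults encode: E520I and Q321A improve
#' dihydroxyacetone turnover 2.3- and 5-fold; H142N improves glycolaldehyde
#' 8.5-fold and D-erythrulose 3.6-fold.
#'
#' @return Tibble with columns `mutant`, `substrate`, `fold`.
#' @export
bbpk_mutants <- function() {
  tibble::tribble(
    ~mutant,  ~substrate, ~fold,
    "E520I",  "DHA",      2.3,
    "Q321A",  "DHA",      5,
    "H142N",  "GALD",     8.5,
    "H142N",  "D-EUS",    3.6
  )
}

#' Parameter set with a phosphoketolase mutant substituted
#'
#' Scales the wild-type kcat on the affected substrates by the mutant's
#' catalytic-efficiency fold-change (Km held fixed), so the mutant set's
#' kcat/Km ratios reproduce the encoded folds exactly.
#'
#' @param mutant One of `"E520I"`, `"Q321A"`, `"H142N"`.
#' @param params Base parameter set.
#' @return Modified `apk_parameters` object.
#' @export
mutant_parameters <- function(mutant, params = apk_parameters()) {
  tab <- bbpk_mutants()
  tab <- tab[tab$mutant == mutant, ]
  if (nrow(tab) == 0) stop("unknown mutant '", mutant, "'", call. = FALSE)
  k <- params$kinetics
  for (i in seq_len(nrow(tab))) {
    sel <- k$enzyme == "BbPK" & k$substrate == tab$substrate[i]
    k$kcat[sel] <- k$kcat[sel] * tab$fold[i]
  }
  params$kinetics <- k
  params
}

param_entry <- function(params, enzyme, substrate) {
  k <- params$kinetics
  hit <- k[k$enzyme == enzyme & k$substrate == substrate, ]
  if (nrow(hit) != 1) {
    stop("no kinetic parameters for (", enzyme, ", ", substrate, ")",
         call. = FALSE)
  }
  hit
}

enzyme_conc_mM <- function(params, enzyme) {
  e <- params$enzymes[params$enzymes$enzyme == enzyme, ]
  if (nrow(e) != 1) stop("no loading for enzyme '", enzyme, "'", call. = FALSE)
  e$loading / e$mass_kda  # (mg/mL) / (mg/umol) = umol/mL = mM
}

# Precompile the rate model of a design: one row per reaction with enzyme
# concentration, kcat, Km, reversibility, substrate/product indices, and the
# competitive grouping by enzyme.
build_rate_model <- function(design, params) {
  rx <- design$reactions
  sp <- design$species
  n <- nrow(rx)
  sub_idx <- integer(n); prod_idx <- integer(n)
  kcat <- numeric(n); km <- numeric(n); keq <- rep(NA_real_, n)
  e_mM <- numeric(n); turnover_sub <- numeric(n)
  for (j in seq_len(n)) {
    st <- rx$stoich[[j]]
    subs <- names(st)[st < 0]
    if (length(subs) != 1) stop("multi-substrate reaction unsupported", call. = FALSE)
    p <- param_entry(params, rx$enzyme[j], subs)
    sub_idx[j] <- match(subs, sp)
    kcat[j] <- p$kcat; km[j] <- p$km; keq[j] <- p$keq
    e_mM[j] <- enzyme_conc_mM(params, rx$enzyme[j])
    turnover_sub[j] <- abs(st[[subs]])
    if (rx$reversible[j]) {
      prod_id <- names(st)[st > 0]
      prod_idx[j] <- match(prod_id, sp)
      if (is.na(keq[j])) {
        stop("reversible reaction (", rx$enzyme[j], ", ", subs,
             ") needs an equilibrium constant", call. = FALSE)
      }
    }
  }
  S <- stoich_matrix(design)
  list(
    S = S, n = n, species = sp,
    sub_idx = sub_idx, prod_idx = prod_idx,
    kcat = kcat, km = km, keq = keq, e_mM = e_mM,
    reversible = rx$reversible,
    enzyme = rx$enzyme,
    competitive = identical(params$rate_law, "competitive")
  )
}

# Per-reaction rates in mM/h for a concentration vector (mM, design order).
model_rates <- function(m, y) {
  s_over_km <- y[m$sub_idx] / m$km
  # binding terms per reaction: substrate always; product too when reversible
  p_over_km <- ifelse(m$reversible, y[pmax(m$prod_idx, 1)] / m$km, 0)
  if (m$competitive) {
    occ <- s_over_km + p_over_km
    denom_by_enz <- tapply(occ, m$enzyme, sum)
    denom <- 1 + as.numeric(denom_by_enz[m$enzyme])
  } else {
    denom <- 1 + s_over_km + p_over_km
  }
  fwd <- s_over_km
  rev <- ifelse(m$reversible, p_over_km / m$keq, 0)
  3600 * m$kcat * m$e_mM * (fwd - rev) / denom
}

#' Per-reaction rates of a cascade at given concentrations
#'
#' Evaluates the rate law of every reaction in a design. Substrates of a
#' shared enzyme compete for a single active site by default:
#' `v_i = kcat_i E (S_i/Km_i) / (1 + sum_j S_j/Km_j)`; reversible isomerases
#' use the net reversible form constrained by the equilibrium constant (with
#' product Km taken equal to substrate Km); the formose step is a single
#' saturating turnover consuming 3 (formolase) or 2 (glycolaldehyde synthase)
#' formaldehyde.
#'
#' @param design An [apk_design()] object.
#' @param params An [apk_parameters()] object.
#' @param concentrations Named numeric vector of concentrations (mM);
#'   species missing from the design raise an error, species missing from
#'   the vector default to 0.
#' @return Tibble with `reaction`, `enzyme`, `equation`, `rate` (mM/h,
#'   turnover units: multiply by the stoichiometric coefficient for a
#'   species' production rate).
#' @examples
#' d <- apk_design("F6P")
#' apk_rates(d, apk_parameters(), c(F6P = 10))
#' @export
apk_rates <- function(design, params, concentrations) {
  unknown <- setdiff(names(concentrations), design$species)
  if (length(unknown) > 0) {
    stop("species not in design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  y <- stats::setNames(rep(0, length(design$species)), design$species)
  y[names(concentrations)] <- concentrations
  m <- build_rate_model(design, params)
  tibble::tibble(
    reaction = design$reactions$id,
    enzyme = design$reactions$enzyme,
    equation = design$reactions$equation,
    rate = unname(model_rates(m, y))
  )
}

#' Simulate an in vitro cascade time course
#'
#' Integrates the Michaelis-Menten ODE system of a design with an adaptive
#' Runge-Kutta scheme and samples the solution on the requested grid
#' (default: every 2 h over a 10 h run, the sampling scheme of the in vitro
#' process analyses). Phosphate buffer is treated as a constant excess and is
#' not a state variable. Acetyl-phosphate is reported as such; downstream the
#' assay hydrolyzes it to acetate, so pool accounting merges both into a
#' single "Ac" pool (see [carbon_abundance()]).
#'
#' @param design An [apk_design()] object.
#' @param params An [apk_parameters()] object.
#' @param y0 Named numeric vector of initial concentrations (mM); species not
#'   named start at 0. Default: 10 mM of the design's source.
#' @param horizon Simulation horizon in hours (default 10).
#' @param grid Output time grid (hours); default `seq(0, horizon, by = 2)`.
#' @param rtol,atol Integrator tolerances (relative 1e-8, absolute 1e-10 mM).
#' @param negtol Negative-concentration tolerance (1e-9 mM); excursions
#'   beyond it are an error, never silently clipped.
#' @param max_steps Integrator step budget before aborting.
#' @return Object of class `apk_timecourse`: a long tibble with columns
#'   `time`, `species`, `conc`, carrying the design and initial state as
#'   attributes.
#' @examples
#' tc <- apk_simulate(apk_design("F6P"))
#' head(tc)
#' @export
apk_simulate <- function(design, params = apk_parameters(), y0 = NULL,
                         horizon = 10, grid = NULL,
                         rtol = 1e-8, atol = 1e-10, negtol = 1e-9,
                         max_steps = 5e5) {
  stopifnot(inherits(design, "apk_design"))
  if (is.null(grid)) grid <- seq(0, horizon, by = 2)
  sp <- design$species
  y <- stats::setNames(rep(0, length(sp)), sp)
  if (is.null(y0)) {
    y[design$source] <- 10
  } else {
    if (any(y0 < 0)) stop("negative initial concentration", call. = FALSE)
    unknown <- setdiff(names(y0), sp)
    if (length(unknown) > 0) {
      stop("y0 names not in design: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    y[names(y0)] <- y0
  }
  m <- build_rate_model(design, params)
  rhs <- function(t, state) as.numeric(m$S %*% model_rates(m, state))
  sol <- ode_integrate(rhs, y, grid, rtol = rtol, atol = atol,
                       negtol = negtol, max_steps = max_steps)
  tc <- tibble::as_tibble(as.data.frame(sol))
  tc$time <- grid
  out <- tidyr::pivot_longer(tc, -"time", names_to = "species",
                             values_to = "conc")
  structure(out,
            class = c("apk_timecourse", class(out)),
            design_source = design$source,
            recycle_mode = design$recycle_mode,
            species = sp,
            n_carbons = stats::setNames(
              n_carbons_of(sp, design$registry %||% apk_species()), sp),
            y0 = y)
}

#' Default carbon-number pool grouping for a design
#'
#' Pools follow the in vitro metabolite analyses: the merged "Ac" pool
#' (acetyl-phosphate plus acetate/acetyl-CoA, since the assay hydrolyzes AcP
#' before quantification) and one pool per carbon number for everything else
#' (e.g. "C4" = erythrose + erythrulose + erythrose-4-phosphate in the F6P
#' system; "C3" = glyceraldehyde species + dihydroxyacetone species in the
#' Xu5P system). Pools are disjoint and cover every carbon-bearing species.
#'
#' @param design An [apk_design()] object.
#' @return Tibble with columns `pool`, `species`.
#' @export
default_pools <- function(design) {
  sp <- design$species
  ac <- intersect(sp, c("AcP", "acetate", "AcCoA"))
  rest <- setdiff(sp, ac)
  nc <- n_carbons_of(rest, design$registry %||% apk_species())
  dplyr::bind_rows(
    tibble::tibble(pool = "Ac", species = ac),
    tibble::tibble(pool = paste0("C", nc), species = rest)
  )
}

#' Carbon abundance of pools over a time course
#'
#' Carbon abundance of a pool is the ratio of its carbon moles to the total
#' carbon moles at time zero. For a conservative simulation the fractions at
#' every time sum to 1 (within integrator tolerance).
#'
#' @param dataset An [apk_simulate()] time course.
#' @param pools Pool grouping tibble (`pool`, `species`); default
#'   carbon-number pools of the dataset's species.
#' @return Tibble with `time`, `pool`, `fraction`.
#' @examples
#' tc <- apk_simulate(apk_design("F6P"))
#' carbon_abundance(tc)
#' @export
carbon_abundance <- function(dataset, pools = NULL) {
  stopifnot(inherits(dataset, "apk_timecourse"))
  nc <- attr(dataset, "n_carbons")
  if (is.null(pools)) {
    sp <- attr(dataset, "species")
    ac <- intersect(sp, c("AcP", "acetate", "AcCoA"))
    rest <- setdiff(sp, ac)
    pools <- dplyr::bind_rows(
      tibble::tibble(pool = "Ac", species = ac),
      tibble::tibble(pool = paste0("C", nc[rest]), species = rest)
    )
  }
  unknown <- setdiff(pools$species, unique(dataset$species))
  if (length(unknown) > 0) {
    stop("pool references unknown species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  y0 <- attr(dataset, "y0")
  total0 <- sum(y0 * nc[names(y0)])
  if (total0 <= 0) stop("no carbon at time zero", call. = FALSE)
  df <- dplyr::inner_join(tibble::as_tibble(dataset), pools,
                          by = "species", relationship = "many-to-many")
  df$carbon <- df$conc * nc[df$species]
  out <- dplyr::summarise(dplyr::group_by(df, .data$time, .data$pool),
                          fraction = sum(.data$carbon) / total0,
                          .groups = "drop")
  out
}

#' Final acetyl (Ac) carbon yield of a time course
#'
#' The carbon fraction of the merged Ac pool (acetyl-phosphate + acetate +
#' acetyl-CoA) at the last sampled time.
#'
#' @param dataset An [apk_simulate()] time course.
#' @return Numeric fraction in `[0, 1]`.
#' @export
final_yield <- function(dataset) {
  ab <- carbon_abundance(dataset)
  ac <- ab[ab$pool == "Ac", ]
  if (nrow(ac) == 0) return(0)
  ac$fraction[which.max(ac$time)]
}
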