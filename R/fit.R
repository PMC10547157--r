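#' Fit the Michaelis-Menten equation to an initial-rate assay
#'
#' Nonlinear least squares of `v = Vmax S / (Km + S)` on replicate initial
#' rates over a substrate concentration series (the assays cover 0--110 mM).
#' Starting values come from a Hanes-Woolf linearization; a proportional
#' error model (weights `1/v^2`) is used by default to match multiplicative
#' assay scatter. When an enzyme loading and molar mass are supplied, kcat is
#' derived from Vmax. Fits whose Km lands beyond 10x the largest assayed
#' concentration, or that fail to converge, are flagged unreliable rather
#' than silently returned.
#'
#' @param assay Tibble with columns `conc` (mM) and `rate` (mM/min), one row
#'   per replicate measurement; e.g. from [gen_mm_assay()]. Fewer than 5
#'   distinct concentrations is flagged unreliable, not fitted.
#' @param loading Enzyme loading in mg/mL (optional, for kcat).
#' @param mass_kda Enzyme molar mass in kDa (optional, for kcat).
#' @param weighting `"relative"` (default) or `"none"`.
#' @return Object of class `mm_fit`: list with `vmax`, `km`, `kcat` (or
#'   `NA`), standard errors, 95% confidence bounds, `converged`, `reliable`,
#'   `sigma`, and the data. Use [tidy()] / [glance()] to extract tables.
#' @examples
#' a <- gen_mm_assay(kcat = 10, km = 5, noise = noise_model("none"),
#'                   loading = 0.25, mass_kda = 92)
#' fit_michaelis_menten(a, loading = 0.25, mass_kda = 92)
#' @export
fit_michaelis_menten <- function(assay, loading = NULL, mass_kda = NULL,
                                 weighting = c("relative", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("conc", "rate") %in% names(assay)))
  if (is.null(loading)) loading <- attr(assay, "loading")
  if (is.null(mass_kda)) mass_kda <- attr(assay, "mass_kda")

  unreliable <- function(reason) {
    structure(list(vmax = NA_real_, km = NA_real_, kcat = NA_real_,
                   se = c(vmax = NA_real_, km = NA_real_),
                   conf = NULL, converged = FALSE, reliable = FALSE,
                   reason = reason, sigma = NA_real_, data = assay),
              class = "mm_fit")
  }
  if (length(unique(assay$conc)) < 5) {
    return(unreliable("fewer than 5 distinct concentrations"))
  }
  if (all(assay$rate <= 0) || stats::sd(assay$rate) == 0) {
    return(unreliable("no signal: rates are constant or zero"))
  }

  # Hanes-Woolf start: S/v = S/Vmax + Km/Vmax
  pos <- assay[assay$rate > 0 & assay$conc > 0, ]
  hw <- stats::coef(stats::lm(I(conc / rate) ~ conc, data = pos))
  vmax0 <- max(1 / hw[[2]], max(assay$rate))
  km0 <- max(hw[[1]] * vmax0, min(pos$conc) / 10)

  w <- if (weighting == "relative") {
    1 / pmax(assay$rate, 0.01 * max(assay$rate))^2
  } else {
    rep(1, nrow(assay))
  }
  fit <- try(stats::nls(
    rate ~ vmax * conc / (km + conc), data = assay, weights = w,
    start = list(vmax = vmax0, km = km0), algorithm = "port",
    lower = c(vmax = 1e-12, km = 1e-12),
    control = stats::nls.control(maxiter = 200, warnOnly = FALSE)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(unreliable("nonlinear least squares did not converge"))
  }
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  reliable <- est[["km"]] <= 10 * max(assay$conc)

  kcat <- NA_real_
  kcat_se <- NA_real_
  if (!is.null(loading) && !is.null(mass_kda)) {
    e_mM <- loading / mass_kda
    kcat <- est[["vmax"]] / e_mM / 60  # mM/min -> /s
    kcat_se <- se[["vmax"]] / e_mM / 60
  }

  structure(list(
    vmax = est[["vmax"]], km = est[["km"]], kcat = kcat,
    se = c(vmax = se[["vmax"]], km = se[["km"]], kcat = kcat_se),
    conf = tibble::tibble(
      term = c("vmax", "km"),
      estimate = c(est[["vmax"]], est[["km"]]),
      std.error = c(se[["vmax"]], se[["km"]]),
      conf.low = c(est[["vmax"]] - 1.96 * se[["vmax"]],
                   est[["km"]] - 1.96 * se[["km"]]),
      conf.high = c(est[["vmax"]] + 1.96 * se[["vmax"]],
                    est[["km"]] + 1.96 * se[["km"]])
    ),
    converged = TRUE, reliable = reliable,
    reason = if (reliable) NA_character_ else
      "Km estimate beyond 10x the largest assayed concentration",
    sigma = summary(fit)$sigma, data = assay
  ), class = "mm_fit")
}

#' Catalytic-efficiency fold-change between two enzymes
#'
#' `(kcat/Km)_mutant / (kcat/Km)_wildtype`. Scale-invariant in enzyme
#' loading. Accepts [fit_michaelis_menten()] results or any list carrying
#' `kcat` and `km` (falling back to `vmax` when kcat is unavailable for
#' both, in which case loadings must match). Unreliable fits propagate their
#' flag as a warning and an `NA` result.
#'
#' @param mutant,wildtype `mm_fit` objects or lists with `kcat` and `km`.
#' @return Numeric fold-change.
#' @examples
#' wt <- list(kcat = 1.0, km = 20)
#' mut <- list(kcat = 2.3, km = 20)
#' efficiency_fold_change(mut, wt)  # 2.3
#' @export
efficiency_fold_change <- function(mutant, wildtype) {
  bad <- function(x) inherits(x, "mm_fit") && !(x$converged && x$reliable)
  if (bad(mutant) || bad(wildtype)) {
    warning("unreliable fit supplied; fold-change is NA", call. = FALSE)
    return(NA_real_)
  }
  eff <- function(x) {
    num <- if (!is.null(x$kcat) && is.finite(x$kcat)) x$kcat else x$vmax
    num / x$km
  }
  eff(mutant) / eff(wildtype)
}

parse_free_params <- function(free_params) {
  parts <- strsplit(free_params, ".", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) {
    stop("free parameters must be 'enzyme.substrate.kcat|km' strings",
         call. = FALSE)
  }
  tibble::tibble(
    name = free_params,
    enzyme = vapply(parts, `[[`, character(1), 1),
    substrate = vapply(parts, `[[`, character(1), 2),
    parameter = vapply(parts, `[[`, character(1), 3)
  )
}

set_params <- function(params, spec, values) {
  k <- params$kinetics
  for (i in seq_len(nrow(spec))) {
    sel <- k$enzyme == spec$enzyme[i] & k$substrate == spec$substrate[i]
    if (!any(sel)) {
      stop("no kinetic entry (", spec$enzyme[i], ", ", spec$substrate[i], ")",
           call. = FALSE)
    }
    k[[spec$parameter[i]]][sel] <- values[i]
  }
  params$kinetics <- k
  params
}

get_params <- function(params, spec) {
  vapply(seq_len(nrow(spec)), function(i) {
    e <- param_entry(params, spec$enzyme[i], spec$substrate[i])
    e[[spec$parameter[i]]]
  }, numeric(1))
}

#' Calibrate cascade parameters against time-course data
#'
#' Least-squares fit of the ODE cascade solution to one or more time-course
#' datasets with a named subset of (enzyme, substrate) parameters free and
#' all others fixed. The objective uses relative residuals (matching the
#' multiplicative noise of the synthetic generator), optimization is on
#' log10-parameters (L-BFGS-B), and multiple starts are drawn log-uniformly
#' around the supplied values under a fixed seed. After fitting, each free
#' parameter's identifiability is probed by a +/-20% profile perturbation: a
#' flat profile flags the parameter as non-identifiable.
#'
#' @param design An [apk_design()] object.
#' @param datasets A time-course tibble (`time`, `species`, `conc`) or list
#'   of them, e.g. from [gen_timecourse()].
#' @param free_params Character vector of `"enzyme.substrate.kcat"` /
#'   `"enzyme.substrate.km"` strings naming the free parameters. Empty
#'   vector: the supplied parameters are returned unchanged.
#' @param params Starting/fixed parameter set.
#' @param y0,grid Initial state and time grid matching the datasets; defaults
#'   as in [apk_simulate()].
#' @param n_starts Number of multi-starts (default 20).
#' @param seed RNG seed for the starts (default 1729).
#' @param rtol Integrator tolerance during fitting (default 1e-6, looser
#'   than simulation for speed).
#' @return Object of class `cascade_fit`: list with `estimates` tibble
#'   (`parameter`, `estimate`, `identifiable`), `objective`, `converged`,
#'   and the refit parameter set `params`.
#' @export
fit_cascade <- function(design, datasets, free_params,
                        params = apk_parameters(), y0 = NULL, grid = NULL,
                        n_starts = 20, seed = 1729, rtol = 1e-6) {
  if (inherits(datasets, "data.frame")) datasets <- list(datasets)
  if (length(free_params) == 0) {
    return(structure(list(
      estimates = tibble::tibble(parameter = character(0),
                                 estimate = numeric(0),
                                 identifiable = logical(0)),
      objective = NA_real_, converged = TRUE, params = params
    ), class = "cascade_fit"))
  }
  spec <- parse_free_params(free_params)
  start <- get_params(params, spec)
  if (is.null(grid)) grid <- sort(unique(datasets[[1]]$time))

  obs <- lapply(datasets, function(d) {
    tidyr::pivot_wider(d[, c("time", "species", "conc")],
                       names_from = "species", values_from = "conc")
  })
  # datasets sharing a time grid share one simulation per objective call
  grid_key <- vapply(obs, function(d) paste(sort(unique(d$time)),
                                            collapse = ","), character(1))

  objective <- function(logp) {
    p <- set_params(params, spec, 10^logp)
    total <- 0
    for (key in unique(grid_key)) {
      members <- obs[grid_key == key]
      tgrid <- sort(unique(members[[1]]$time))
      sim <- try(apk_simulate(design, p, y0 = y0, grid = tgrid,
                              rtol = rtol, atol = 1e-8), silent = TRUE)
      if (inherits(sim, "try-error")) return(1e10)
      simw <- tidyr::pivot_wider(sim, names_from = "species",
                                 values_from = "conc")
      for (d in members) {
        for (s in setdiff(names(d), "time")) {
          o <- d[[s]]
          m <- simw[[s]][match(d$time, simw$time)]
          scale <- pmax(abs(o), 0.05 * max(abs(o), 1e-6))
          total <- total + sum(((m - o) / scale)^2)
        }
      }
    }
    total
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  starts <- matrix(log10(start), nrow = n_starts, ncol = length(start),
                   byrow = TRUE)
  if (n_starts > 1) {
    jitter <- matrix(stats::runif((n_starts - 1) * length(start), -1, 1),
                     nrow = n_starts - 1)
    starts[-1, ] <- starts[-1, ] + jitter
  }

  best <- NULL
  for (i in seq_len(n_starts)) {
    # Nelder-Mead: robust to the integration-tolerance noise that defeats
    # finite-difference gradients
    res <- try(stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                            control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (!inherits(res, "try-error") && length(start) == 1) {
      res <- try(stats::optim(res$par, objective, method = "Brent",
                              lower = res$par - 2, upper = res$par + 2),
                 silent = TRUE)
    }
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("cascade fit failed from every start", call. = FALSE)

  est <- 10^best$par
  # flat-profile identifiability probe
  identifiable <- vapply(seq_along(est), function(i) {
    up <- best$par; up[i] <- up[i] + log10(1.2)
    dn <- best$par; dn[i] <- dn[i] - log10(1.2)
    d <- max(objective(up), objective(dn)) - best$value
    d > max(1e-6, 1e-4 * max(best$value, 1))
  }, logical(1))

  structure(list(
    estimates = tibble::tibble(parameter = spec$name, estimate = est,
                               identifiable = identifiable),
    objective = best$value,
    converged = best$convergence == 0,
    params = set_params(params, spec, est)
  ), class = "cascade_fit")
}

#' Clones needed for NNK saturation-mutagenesis libraries
#'
#' An NNK degenerate codon encodes 32 codon variants. The number of clones
#' per single-site library is the smallest N with
#' `1 - (31/32)^N >= coverage`, rounded up to whole 96-well plates -- the
#' arithmetic behind screening 96 clones per site and 3,264 clones over 34
#' sites at 95% per-codon coverage. A per-amino-acid mode instead requires
#' every amino acid to be seen with the target probability (union bound over
#' the NNK codon multiplicities).
#'
#' @param sites Number of saturation sites (libraries), >= 1.
#' @param coverage Target coverage probability in (0, 1), default 0.95.
#' @param per `"codon"` (default) or `"amino_acid"`.
#' @param plate Plate size used for rounding (default 96).
#' @return Tibble with `sites`, `coverage`, `raw_n` (clones before plate
#'   rounding), `clones_per_library`, `total_clones`.
#' @examples
#' nnk_screen_size(34, 0.95)  # 96 per library, 3264 total
#' nnk_screen_size(40, 0.95)  # 3840 total
#' @export
nnk_screen_size <- function(sites, coverage = 0.95,
                            per = c("codon", "amino_acid"), plate = 96) {
  per <- match.arg(per)
  stopifnot(sites >= 1)
  if (coverage >= 1 || coverage <= 0) {
    stop("coverage must be in (0, 1)", call. = FALSE)
  }
  if (per == "codon") {
    raw_n <- ceiling(log(1 - coverage) / log(31 / 32))
  } else {
    # NNK amino-acid codon multiplicities: 3x Leu/Arg/Ser, 2x Ala/Gly/Pro/
    # Thr/Val, 1x the remaining twelve (stop TAG excluded from coverage)
    counts <- c(rep(3, 3), rep(2, 5), rep(1, 12))
    miss <- function(n) sum((1 - counts / 32)^n)
    raw_n <- 1
    while (miss(raw_n) > 1 - coverage) raw_n <- raw_n + 1
  }
  per_lib <- as.integer(ceiling(raw_n / plate) * plate)
  tibble::tibble(
    sites = as.integer(sites), coverage = coverage, raw_n = as.integer(raw_n),
    clones_per_library = per_lib,
    total_clones = as.integer(sites) * per_lib
  )
}
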