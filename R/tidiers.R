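#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pathway design into its reaction table
#'
#' @param x An [apk_design()] object.
#' @param ... Unused.
#' @return Tibble with one row per reaction (`id`, `rtype`, `enzyme`,
#'   `reversible`, `equation`, `stoich` list-column).
#' @method tidy apk_design
#' @export
tidy.apk_design <- function(x, ...) {
  x$reactions[, c("id", "rtype", "enzyme", "reversible", "equation", "stoich")]
}

#' One-row summary of a pathway design
#'
#' @param x An [apk_design()] object.
#' @param ... Unused.
#' @method glance apk_design
#' @export
glance.apk_design <- function(x, ...) {
  tibble::tibble(
    source = x$source,
    recycle_mode = x$recycle_mode,
    n_reactions = nrow(x$reactions),
    n_species = length(x$species),
    n_core_types = count_reaction_types(x)
  )
}

#' Tidy a yield report into its overall-reaction table
#'
#' @param x An [overall_reaction()] result.
#' @param ... Unused.
#' @method tidy apk_yield
#' @export
tidy.apk_yield <- function(x, ...) x$overall

#' One-row summary of a yield report
#'
#' @param x An [overall_reaction()] result.
#' @param ... Unused.
#' @method glance apk_yield
#' @export
glance.apk_yield <- function(x, ...) {
  tibble::tibble(
    source = x$source,
    recycle_mode = x$recycle_mode,
    acp_per_source = x$acp_per_source,
    acp_exact = x$acp_exact,
    carbon_yield = x$carbon_yield,
    yield_exact = x$yield_exact
  )
}

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return Tibble of terms with estimates, standard errors and 95% bounds.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  if (is.null(x$conf)) {
    return(tibble::tibble(term = c("vmax", "km"), estimate = NA_real_,
                          std.error = NA_real_, conf.low = NA_real_,
                          conf.high = NA_real_))
  }
  x$conf
}

#' One-row summary of a Michaelis-Menten fit
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    vmax = x$vmax, km = x$km, kcat = x$kcat, sigma = x$sigma,
    converged = x$converged, reliable = x$reliable,
    reason = x$reason %||% NA_character_
  )
}

#' Tidy a cascade calibration
#'
#' @param x A [fit_cascade()] result.
#' @param ... Unused.
#' @method tidy cascade_fit
#' @export
tidy.cascade_fit <- function(x, ...) x$estimates

#' One-row summary of a cascade calibration
#'
#' @param x A [fit_cascade()] result.
#' @param ... Unused.
#' @method glance cascade_fit
#' @export
glance.cascade_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    converged = x$converged,
    n_free = nrow(x$estimates),
    n_identifiable = sum(x$estimates$identifiable)
  )
}
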