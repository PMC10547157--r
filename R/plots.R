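#' Plot a simulated or measured cascade time course
#'
#' One line per species, concentration (mM) against time (h).
#'
#' @param object An `apk_timecourse` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(apk_simulate(apk_design("F6P")))
#' @method autoplot apk_timecourse
#' @export
autoplot.apk_timecourse <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$conc,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "time (h)", y = "concentration (mM)", colour = NULL,
      title = paste0("APK cascade from ", attr(object, "design_source"),
                     " (recycle: ", attr(object, "recycle_mode"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot carbon-pool abundances over time
#'
#' Carbon abundance (fraction of total input carbon) per pool, the view used
#' for the in vitro process analyses.
#'
#' @param dataset An `apk_timecourse` tibble.
#' @param pools Optional pool grouping (see [carbon_abundance()]).
#' @return A ggplot object.
#' @export
plot_carbon_pools <- function(dataset, pools = NULL) {
  ab <- carbon_abundance(dataset, pools)
  ggplot2::ggplot(ab, ggplot2::aes(x = .data$time, y = .data$fraction,
                                   colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (h)", y = "carbon abundance", colour = "pool") +
    ggplot2::theme_minimal()
}

#' Plot a Michaelis-Menten fit over its assay data
#'
#' @param object An `mm_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$conc, y = .data$rate)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "substrate (mM)", y = "initial rate (mM/min)") +
    ggplot2::theme_minimal()
  if (isTRUE(object$converged)) {
    grid <- tibble::tibble(conc = seq(0, max(d$conc), length.out = 200))
    grid$rate <- object$vmax * grid$conc / (object$km + grid$conc)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}
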