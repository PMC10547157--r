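#' Declare a measurement noise model
#'
#' Multiplicative Gaussian noise (a fixed coefficient of variation, default
#' 5%) is the default for rates and concentrations: assay scatter scales with
#' signal and the source experiments report only triplicate standard
#' deviations. Additive Gaussian and noise-free variants are available.
#' Identical seed and parameters give identical draws.
#'
#' @param kind One of `"multiplicative_gaussian"`, `"additive_gaussian"`,
#'   `"none"`.
#' @param cv Coefficient of variation for the multiplicative model.
#' @param sd Standard deviation (same units as the signal) for the additive
#'   model.
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative_gaussian",
                                 "additive_gaussian", "none"),
                        cv = 0.05, sd = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "multiplicative_gaussian" && cv < 0) {
    stop("cv must be >= 0", call. = FALSE)
  }
  if (kind == "additive_gaussian" && (is.null(sd) || sd < 0)) {
    stop("additive noise needs sd >= 0", call. = FALSE)
  }
  structure(list(kind = kind, cv = cv, sd = sd, seed = seed),
            class = "noise_model")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  expr
}

apply_noise <- function(x, noise) {
  switch(noise$kind,
    none = list(values = x, n_clipped = 0L),
    multiplicative_gaussian = {
      y <- x * (1 + stats::rnorm(length(x), 0, noise$cv))
      list(values = pmax(y, 0), n_clipped = sum(y < 0))
    },
    additive_gaussian = {
      y <- x + stats::rnorm(length(x), 0, noise$sd)
      list(values = pmax(y, 0), n_clipped = sum(y < 0))
    }
  )
}

#' Generate a synthetic Michaelis-Menten initial-rate assay
#'
#' Draws replicate initial rates around the true Michaelis-Menten curve on a
#' substrate concentration grid within the 0--110 mM assay range, under the
#' given noise model. The generating truth is recorded in attributes for
#' downstream recovery scoring.
#'
#' @param kcat True turnover number (/s).
#' @param km True Michaelis constant (mM).
#' @param loading Enzyme loading (mg/mL), default 0.25 (the kinetic assay
#'   recipe).
#' @param mass_kda Enzyme molar mass (kDa), default 92.
#' @param conc Concentration grid (mM), default 12 log-spaced points in
#'   1--110; must lie within `[0, 110]` with at least 5 distinct values.
#' @param replicates Replicates per concentration, default 3.
#' @param noise A [noise_model()].
#' @return Tibble with `conc`, `replicate`, `rate` (mM/min); attributes
#'   `kcat_true`, `km_true`, `loading`, `mass_kda`, `n_clipped`.
#' @examples
#' gen_mm_assay(kcat = 10, km = 5, noise = noise_model(seed = 1))
#' @export
gen_mm_assay <- function(kcat, km, loading = 0.25, mass_kda = 92,
                         conc = NULL, replicates = 3,
                         noise = noise_model()) {
  if (is.null(conc)) conc <- round(exp(seq(log(1), log(110), length.out = 12)), 2)
  if (any(conc < 0) || any(conc > 110)) {
    stop("concentration grid must lie within the 0-110 mM assay range",
         call. = FALSE)
  }
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  e_mM <- loading / mass_kda
  vmax <- kcat * e_mM * 60  # mM/min
  grid <- tidyr::expand_grid(conc = conc, replicate = seq_len(replicates))
  true_rate <- vmax * grid$conc / (km + grid$conc)
  drawn <- with_seed(noise$seed, apply_noise(true_rate, noise))
  out <- tibble::tibble(conc = grid$conc, replicate = grid$replicate,
                        rate = drawn$values)
  attr(out, "kcat_true") <- kcat
  attr(out, "km_true") <- km
  attr(out, "loading") <- loading
  attr(out, "mass_kda") <- mass_kda
  attr(out, "n_clipped") <- drawn$n_clipped
  out
}

#' Generate a noisy synthetic cascade time course
#'
#' Runs [apk_simulate()] and perturbs every sampled concentration per the
#' noise model; negative draws are clipped to zero and counted in the
#' `n_clipped` attribute, never silently. With `noise_model("none")` the
#' output equals the simulation exactly.
#'
#' @inheritParams apk_simulate
#' @param noise A [noise_model()].
#' @param ... Passed to [apk_simulate()].
#' @return An `apk_timecourse` tibble (see [apk_simulate()]) with attribute
#'   `n_clipped` and the noise model attached.
#' @examples
#' d <- apk_design("F6P")
#' gen_timecourse(d, noise = noise_model(cv = 0.05, seed = 7))
#' @export
gen_timecourse <- function(design, params = apk_parameters(), y0 = NULL,
                           noise = noise_model(), ...) {
  tc <- apk_simulate(design, params, y0 = y0, ...)
  drawn <- with_seed(noise$seed, apply_noise(tc$conc, noise))
  tc$conc <- drawn$values
  attr(tc, "n_clipped") <- drawn$n_clipped
  attr(tc, "noise") <- noise
  tc
}

#' Generate a gap-free synthetic protein family
#'
#' Mutates a random ancestor sequence independently at every position of
#' every descendant with the given per-position substitution rate (to a
#' uniformly chosen different residue). The ancestor is recorded as an
#' attribute, so consensus recovery can be scored against truth.
#'
#' @param length Alignment length (columns), >= 1.
#' @param n_sequences Number of sequences, >= 1.
#' @param mutation_rate Per-position substitution probability in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @param alphabet Residue alphabet; default the 20 amino acids.
#' @return Named character vector of aligned sequences (`seq1`...), class
#'   `protein_family`, with attribute `ancestor`.
#' @examples
#' fam <- gen_protein_family(50, 10, 0.1, seed = 1)
#' attr(fam, "ancestor")
#' @export
gen_protein_family <- function(length, n_sequences, mutation_rate, seed = NULL,
                               alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  stopifnot(length >= 1, n_sequences >= 1,
            mutation_rate >= 0, mutation_rate < 1)
  with_seed(seed, {
    ancestor <- sample(alphabet, length, replace = TRUE)
    seqs <- vapply(seq_len(n_sequences), function(i) {
      s <- ancestor
      hit <- stats::runif(length) < mutation_rate
      if (any(hit)) {
        s[hit] <- vapply(s[hit], function(res) {
          sample(setdiff(alphabet, res), 1)
        }, character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0("seq", seq_len(n_sequences))
    structure(seqs, class = "protein_family",
              ancestor = paste(ancestor, collapse = ""))
  })
}
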