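test_that("noiseless generate-then-fit recovers the truth to solver tolerance", {
  for (truth in list(c(kcat = 10, km = 5), c(kcat = 0.2, km = 30))) {
    a <- gen_mm_assay(truth[["kcat"]], truth[["km"]],
                      noise = noise_model("none"))
    fit <- fit_michaelis_menten(a)
    expect_true(fit$converged && fit$reliable)
    expect_equal(fit$kcat, truth[["kcat"]], tolerance = 1e-6)
    expect_equal(fit$km, truth[["km"]], tolerance = 1e-6)
    td <- tidy(fit)
    expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  }
})

test_that("degenerate assays are flagged unreliable, not silently fitted", {
  a <- gen_mm_assay(10, 5, noise = noise_model("none"))
  a$rate <- 0
  f <- fit_michaelis_menten(a)
  expect_false(f$reliable)
  expect_false(f$converged)

  one_conc <- gen_mm_assay(10, 5, conc = 50, replicates = 3,
                           noise = noise_model("none"))
  f1 <- fit_michaelis_menten(one_conc)
  expect_false(f1$reliable)
  expect_match(f1$reason, "distinct concentrations")

  # Km far beyond the assayed range: unreliable flag
  a2 <- gen_mm_assay(10, 5000, noise = noise_model(cv = 0.02, seed = 4))
  f2 <- fit_michaelis_menten(a2)
  expect_false(f2$reliable)
})

test_that("catalytic-efficiency fold-changes reproduce the engineered mutants", {
  wt <- list(kcat = 1.0, km = 20)
  expect_equal(efficiency_fold_change(list(kcat = 2.3, km = 20), wt), 2.3)
  expect_equal(efficiency_fold_change(list(kcat = 8.5, km = 20), wt), 8.5)
  expect_equal(efficiency_fold_change(wt, wt), 1.0)
  # fold changes encoded in the shipped mutant parameter sets
  p_wt <- apk_parameters()$kinetics
  for (i in seq_len(nrow(bbpk_mutants()))) {
    row <- bbpk_mutants()[i, ]
    p_mut <- mutant_parameters(row$mutant)$kinetics
    eff <- function(k, s) {
      k$kcat[k$enzyme == "BbPK" & k$substrate == s] /
        k$km[k$enzyme == "BbPK" & k$substrate == s]
    }
    expect_equal(eff(p_mut, row$substrate) / eff(p_wt, row$substrate),
                 row$fold)
  }
  # scale invariance: loading cancels out of kcat/Km
  a <- gen_mm_assay(5, 10, loading = 0.25, noise = noise_model("none"))
  b <- gen_mm_assay(5, 10, loading = 0.5, noise = noise_model("none"))
  fa <- fit_michaelis_menten(a)
  fb <- fit_michaelis_menten(b)
  expect_equal(efficiency_fold_change(fa, fb), 1.0, tolerance = 1e-6)
  # unreliable inputs propagate
  bad <- fit_michaelis_menten({x <- a; x$rate <- 0; x})
  expect_warning(res <- efficiency_fold_change(bad, fa), "unreliable")
  expect_true(is.na(res))
})

test_that("NNK library arithmetic matches the screening campaign", {
  res <- nnk_screen_size(34, 0.95)
  expect_identical(res$clones_per_library, 96L)
  expect_identical(res$total_clones, 3264L)
  expect_identical(res$raw_n, 95L)  # ceil(ln .05 / ln(31/32))
  expect_identical(nnk_screen_size(1, 0.95)$raw_n, 95L)
  expect_identical(nnk_screen_size(40, 0.95)$total_clones, 3840L)
  expect_error(nnk_screen_size(10, 1), "coverage")
  expect_error(nnk_screen_size(10, 1.2), "coverage")
  # monotone non-decreasing in coverage and sites
  cov <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  raw <- vapply(cov, function(cv) nnk_screen_size(1, cv)$raw_n, integer(1))
  expect_true(all(diff(raw) >= 0))
  tot <- vapply(c(1, 5, 34, 40), function(s) nnk_screen_size(s, 0.95)$total_clones,
                integer(1))
  expect_true(all(diff(tot) >= 0))
  # per-amino-acid mode needs at least as many clones as any single variant
  expect_gte(nnk_screen_size(1, 0.95, per = "amino_acid")$raw_n, 95L)
})

test_that("cascade calibration: no free parameters is the identity", {
  p <- apk_parameters()
  fit <- fit_cascade(apk_design("GALD", recycle = "none"),
                     datasets = list(), free_params = character(0), params = p)
  expect_true(fit$converged)
  expect_identical(fit$params$kinetics, p$kinetics)
})

test_that("cascade calibration recovers parameters from noiseless data", {
  d <- apk_design("GALD", recycle = "none")
  truth <- apk_parameters()
  truth$kinetics$kcat[truth$kinetics$substrate == "GALD"] <- 0.02
  truth$kinetics$km[truth$kinetics$substrate == "GALD"] <- 5
  tc <- gen_timecourse(d, truth, noise = noise_model("none"))

  start <- apk_parameters()
  start$kinetics$kcat[start$kinetics$substrate == "GALD"] <- 0.04
  start$kinetics$km[start$kinetics$substrate == "GALD"] <- 12
  fit <- fit_cascade(d, tc, c("BbPK.GALD.kcat", "BbPK.GALD.km"),
                     params = start, n_starts = 3)
  est <- fit$estimates
  expect_equal(est$estimate[est$parameter == "BbPK.GALD.kcat"], 0.02,
               tolerance = 0.01)
  expect_equal(est$estimate[est$parameter == "BbPK.GALD.km"], 5,
               tolerance = 0.01)
  expect_true(all(est$identifiable))
})

test_that("cascade calibration under 5% noise recovers identifiable parameters within 25%", {
  # simulation study: 5 independent triplicate experiments, median relative
  # error per identifiable parameter must stay within 25%
  d <- apk_design("GALD", recycle = "none")
  truth <- apk_parameters()
  truth$kinetics$kcat[truth$kinetics$substrate == "GALD"] <- 0.02
  truth$kinetics$km[truth$kinetics$substrate == "GALD"] <- 5
  start <- apk_parameters()
  start$kinetics$kcat[start$kinetics$substrate == "GALD"] <- 0.04
  start$kinetics$km[start$kinetics$substrate == "GALD"] <- 10
  truthv <- c("BbPK.GALD.kcat" = 0.02, "BbPK.GALD.km" = 5)

  rel_err <- sapply(1:5, function(study) {
    datasets <- lapply(1:3, function(i) {
      gen_timecourse(d, truth,
                     noise = noise_model(cv = 0.05, seed = 100 * study + i))
    })
    fit <- fit_cascade(d, datasets, names(truthv), params = start,
                       n_starts = 2)
    est <- fit$estimates
    expect_true(any(est$identifiable))
    ifelse(est$identifiable,
           abs(est$estimate - truthv[est$parameter]) / truthv[est$parameter],
           NA_real_)
  })
  med <- apply(rel_err, 1, stats::median, na.rm = TRUE)
  expect_true(all(med <= 0.25))
})
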