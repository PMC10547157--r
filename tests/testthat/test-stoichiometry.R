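test_that("overall reactions of the flagship designs are exact", {
  f6p <- overall_reaction(apk_design("F6P"))
  expect_identical(f6p$acp_exact, "3")       # half the even carbon number
  expect_identical(f6p$yield_exact, "1")

  xu5p <- overall_reaction(apk_design("Xu5P"))
  expect_identical(xu5p$acp_exact, "5/2")    # recycle loop gives 5/2 exactly
  expect_identical(xu5p$yield_exact, "1")

  dha <- overall_reaction(apk_design("DHA", recycle = "none"))
  expect_equal(dha$acp_per_source, 1)
  hcho <- dha$overall[dha$overall$species == "HCHO", ]
  expect_equal(hcho$coefficient, 1)          # stranded C1 reported, not an error
  expect_identical(dha$yield_exact, "2/3")
})

test_that("theoretical yields: 100% with recycling, (n-1)/n without for odd ketoses", {
  for (src in c("F6P", "Xu5P", "D-EUS", "DHA", "GALD", "HCHO")) {
    expect_identical(theoretical_yield(src, "fls"), 1,
                     label = paste("fls yield for", src))
    expect_identical(theoretical_yield(src, "gals"), 1,
                     label = paste("gals yield for", src))
  }
  expect_equal(theoretical_yield("DHA", "none"), 2 / 3)
  expect_equal(theoretical_yield("Xu5P", "none"), 4 / 5)
  # even-carbon sources lose nothing even without recycle: n/2 AcP
  expect_equal(overall_reaction(apk_design("F6P", recycle = "none"))$acp_per_source, 3)
  expect_equal(overall_reaction(apk_design("D-EUS", recycle = "none"))$acp_per_source, 2)
  expect_equal(overall_reaction(apk_design("GALD", recycle = "none"))$acp_per_source, 1)
})

test_that("glycolysis reference: 11 reactions, 2 acetyl-CoA, 67% carbon yield", {
  ref <- glycolysis_reference()
  expect_identical(ref$n_reactions, 11L)
  expect_identical(ref$accoa_per_glucose, 2L)
  expect_identical(ref$carbon_yield_percent, 67)
  expect_equal(ref$carbon_yield, 2 / 3)
})

test_that("linear solve agrees with exhaustive lattice enumeration on all bundled networks", {
  scenarios <- list(
    list("F6P", "fls"), list("F6P", "none"), list("Xu5P", "fls"),
    list("Xu5P", "gals"), list("Xu5P", "none"), list("DHA", "fls"),
    list("DHA", "none"), list("D-EUS", "fls"), list("GALD", "none"),
    list("HCHO", "fls"), list("HCHO", "gals")
  )
  for (sc in scenarios) {
    d <- apk_design(sc[[1]], recycle = sc[[2]])
    brute <- brute_force_acp(d)
    solved <- overall_reaction(d)$acp_per_source
    expect_length(brute, 1)
    expect_equal(solved, brute,
                 label = paste("AcP per", sc[[1]], "with", sc[[2]]))
  }
})

test_that("yield is invariant to reaction order and duplication", {
  d <- apk_design("Xu5P")
  base <- overall_reaction(d)$carbon_yield

  rev_d <- d
  rev_d$reactions <- d$reactions[rev(seq_len(nrow(d$reactions))), ]
  expect_equal(overall_reaction(rev_d)$carbon_yield, base)

  dup_d <- d
  dup_d$reactions <- d$reactions[c(seq_len(nrow(d$reactions)), 2), ]
  dup_d$reactions$id <- paste0("R", seq_len(nrow(dup_d$reactions)))
  expect_equal(overall_reaction(dup_d)$carbon_yield, base)
})

test_that("a genuinely underdetermined network raises an ambiguity error", {
  d <- apk_design("D-EUS")
  # add a fake second consumer of GALD producing 2 HCHO (terminal when no
  # condensation reaction follows): AcP output now depends on the flux split
  extra <- tibble::tibble(
    id = "RX", rtype = "pk_cleavage", enzyme = "BbPK", reversible = FALSE,
    stoich = list(c(GALD = -1, HCHO = 2)),
    equation = "GALD -> 2 HCHO"
  )
  d$reactions <- dplyr::bind_rows(d$reactions, extra)
  d$species <- unique(c(d$species, "HCHO"))
  expect_error(overall_reaction(d), "free flux direction")
})

test_that("stoichiometric matrix columns match the reaction stoichiometries", {
  d <- apk_design("Xu5P")
  S <- stoich_matrix(d)
  for (j in seq_len(nrow(d$reactions))) {
    st <- d$reactions$stoich[[j]]
    expect_identical(S[names(st), j], stats::setNames(as.integer(st), names(st)))
    expect_true(all(S[setdiff(rownames(S), names(st)), j] == 0))
  }
})
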