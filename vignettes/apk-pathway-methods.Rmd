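---
title: "Models and methods behind apkpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind apkpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apkpath)
```

This vignette explains the models implemented in `apkpath`, the assumptions
behind them, the tunable parameters and their defaults, what the synthetic
data do and do not emulate, and the numerical choices that were genuinely
open. It states no empirical result that the test suite or the acceptance
script does not itself compute.

## The pathway model

Phosphoketolase (PK) cleaves the C2–C3 bond of an accepted ketose,
releasing acetyl-phosphate (AcP) and the two-carbon-shorter aldose. The
artificial phosphoketolase route iterates this cleavage with two auxiliary
reaction types — aldose/ketose isomerization and selective
dephosphorylation — so that any monosaccharide funnels down to C2 units.
Odd-carbon substrates strand one formaldehyde per molecule; a formose-type
carboligation (formolase: 3 HCHO → dihydroxyacetone; glycolaldehyde
synthase: 2 HCHO → glycolaldehyde) recycles it.

Two modelling commitments follow from how the underlying biochemistry was
established, and both are deliberate:

* **The substrate scope of every enzyme is a curated whitelist, not a
  structural rule.** PK accepts F6P, Xu5P, both erythrulose enantiomers,
  dihydroxyacetone and glycolaldehyde, but not DHAP or erythrulose
  4-phosphate — the phosphate anchors those substrates away from the
  reactive center. That exclusion is an experimental finding and cannot be
  derived from a structure predicate, so `apk_capabilities()` simply states
  it. Likewise there is intentionally *no* isomerase entry for free
  glyceraldehyde: none is available, and that absence is what forces the
  G3P routing below.
* **Routing is a fixed priority policy, not a search.** Each discovered
  species is (1) cleaved if PK accepts it; (2) if phosphorylated,
  dephosphorylated first when the free sugar has an isomerase (the E4P →
  erythrose → erythrulose branch, preferred because phosphatases are
  promiscuous and phosphorylated intermediates should be minimized), and
  otherwise isomerized at the phosphate level first (G3P → DHAP → DHA);
  (3) condensed if it is formaldehyde and recycling is on. A per-species
  override table is honored for exploring alternatives. Breadth-first
  discovery order is the documented, stable output order.

L-erythrulose is registered and cleavable but not generated by default:
the published hexose cascade routes through D-erythrulose only. Formolase
is the default recycle variant because PK has the higher affinity for
dihydroxyacetone than for glycolaldehyde.

Methanol, ethylene glycol, ethanolamine, glycerol and erythritol enter via
one-step oxidations (`feeder_entry()`). All five entries are flagged
`untested`: the downstream cascades were demonstrated from the oxidation
products, not from the alcohols themselves, and the interpretation that the
methanol entry proceeds through an explicit formaldehyde intermediate
(oxidation, then formose condensation) is recorded here as a choice.

## Exact stoichiometry

Carbon yield is the acceptance surface of the whole artifact, and recycle
loops make flux values fractional (5/2 AcP per Xu5P), so
`overall_reaction()` works in exact rational arithmetic: a small
numerator/denominator fraction layer and rational Gaussian elimination.
(No arbitrary-precision package is assumed; the networks are tiny, all
intermediate integers stay far below 2^53, and doubles hold them exactly.)

The solve finds the flux vector with net consumption 1 of the source and
zero net production of every internal species. Species never consumed by
any reaction are terminal and left free — which is also how the
recycle-off case degrades gracefully: stranded formaldehyde simply appears
in the overall reaction instead of raising an error. Free flux directions
(nullspace of the constrained system) are checked against the net overall
reaction: directions that do not change it (a duplicated reaction) are
resolved to the minimal-support solution; directions that do change it
raise an ambiguity error listing the offending reaction. Percent yields
round half-up, so the glycolysis benchmark (4 of 6 carbons) prints 67.

The test suite cross-checks the solver against exhaustive enumeration of
half-integer flux lattices on every bundled network.

## Cascade kinetics

`apk_simulate()` integrates mass-action-free Michaelis–Menten ODEs for the
in vitro systems. The rate-law form is a modelling choice the source
experiments never state:

* **Shared-site competition (default).** PK is a single active site
  accepting several competing ketoses, so for substrates $S_i$ of one
  enzyme $v_i = k_{cat,i} E \frac{S_i/K_{m,i}}{1 + \sum_j S_j/K_{m,j}}$.
  An independent-sites variant is selectable
  (`apk_parameters("independent")`); the two agree in the dilute limit and
  the suite verifies the convergence as all $K_m \to \infty$ at fixed
  $k_{cat}/K_m$.
* **Reversible isomerases** use the net reversible form
  $v = \frac{(V_f/K_m)(S - P/K_{eq})}{1 + S/K_m + P/K_m}$ with the product
  $K_m$ set equal to the substrate $K_m$ — one parameter fewer, Haldane-
  consistent.
* **The formose step** is one saturating turnover consuming 3 (or 2)
  formaldehyde; no termolecular elementary kinetics, since only net flux
  matters at this resolution.
* Phosphate (50 mM buffer) is constant and untracked; AcP and acetate are
  merged into one "Ac" pool for reporting because the assay hydrolyzes AcP
  to acetate before quantification. Whether any AcP hydrolyzes earlier in
  the run is not quantified anywhere; the merged pool sidesteps the
  question and is recorded as an interpretation.

Enzyme concentrations come from loadings in mg/mL divided by molar mass in
kDa (the published recipe: PK 2, EcHAD 0.5, Ps-LRhI 1, CpHAD 1, EcTIM 0.1,
FLS 2 mg/mL; 10 mM substrate; 10 h at 37 °C sampled every 2 h).

**The shipped kcat/Km values are placeholders, not measured ground truth.**
The measured kinetic table behind the published time courses is not printed
in the available text. The defaults are therefore labelled as such and
constrained only by the printed orderings: cleavage of the phosphorylated
ketoses is fast (the source is gone within the first 2 h), the short-chain
ketoses are one to two orders slower (the 10 h tail), PK's affinity for
dihydroxyacetone exceeds that for glycolaldehyde, and the engineered-mutant
efficiency gains (2.3-, 5-, 8.5- and 3.6-fold) are encoded exactly in
`bbpk_mutants()` / `mutant_parameters()`. Two placeholder values deserve
explicit flags: the EcTIM turnover is set far below the diffusion-limited
literature value so that the explicit integrator is not stability-limited —
defensible because the recipe's TIM loading is tiny and only net
isomerization flux matters here; and the 10 h simulated yields that result
(≈ 0.93 for the hexose system, ≈ 0.99 for the pentose system) are outputs
of these placeholders, not reproductions of the measured 84%/90%.
Accordingly no test asserts a measured yield; the suite asserts
conservation, monotonicity, convergence to the exact stoichiometric yield,
and the qualitative phase ordering.

Numerical choices: adaptive Cash–Karp Runge–Kutta 4(5) (written in-package
because no ODE-solver package is available in the target environment),
relative tolerance 1e-8, absolute 1e-10 mM; negative excursions beyond
1e-9 mM are an error, never silently clipped; smaller excursions are zeroed.
Integration failures carry the failure time in the error.

## Calibration

`fit_michaelis_menten()` is nonlinear least squares of $v = V_{max}S/(K_m+S)$
(port algorithm, Hanes–Woolf starting values) with proportional weighting by
default, matching multiplicative assay noise; kcat derives from $V_{max}$,
loading and molar mass. Fits are *flagged* rather than silently returned
when there is no signal, fewer than five distinct concentrations, no
convergence, or a $K_m$ beyond 10× the largest assayed concentration.

`fit_cascade()` wraps the simulator in a relative-residual least-squares
objective with a named subset of parameters free, optimized in log10 space
by Nelder–Mead (finite-difference gradients are unreliable at integration
tolerance) from 20 log-uniform multi-starts under fixed seed 1729 (both
configurable). Identifiability is probed after the fit by ±20% profile
perturbations; flat profiles are flagged per parameter. Datasets sharing a
time grid share one simulation per objective evaluation.

`nnk_screen_size()` computes per-codon coverage by default: the smallest
$N$ with $1-(31/32)^N \ge$ the target, rounded up to whole 96-well plates —
this reproduces the 96-clones-per-site and 3,264-for-34-sites arithmetic,
which is why per-codon (rather than per-amino-acid, also offered via the
NNK codon multiplicities) is the default; the choice is an interpretation,
as the published figure does not state which convention produced it.

## Synthetic data

The generators emulate: triplicate initial-rate assays on a 0–110 mM
concentration grid with multiplicative Gaussian noise (default CV 5%, since
only triplicate standard deviations are reported); cascade time courses on
the 2 h grid, perturbed the same way with negative draws clipped at zero
and counted; and gap-free protein families mutated independently per
position from a recorded ancestor. They do **not** emulate instrument
response (HPLC/GC-MS, absorbance screens), enzyme inactivation over long
runs, pipetting covariance between time points, or alignment gaps. A green
recovery test therefore establishes that the estimators are correct and
well-calibrated *under the declared error model* — not that the published
kinetic values are recovered, which would require the unpublished raw data.

## Consensus selection

The mining steps that are genuinely bespoke are implemented: strict
(`> 40` identity, `> 600` aligned residues, literal "more than") hit
filtering, column-majority consensus (gaps excluded unless a column is all
gaps; ties to the alphabetically first residue — the procedure is silent on
ties, so the rule is fixed and recorded in the result), and selection of
the family member with the most consensus-matching columns. Whether
"closest" means column matches or percent identity is not stated; column
matches is the default and `metric = "identity"` the alternative. Upstream
hmmscan/blastp/ortholog-clustering runs are consumed as tables; they are
published tools at stated settings and are not re-implemented.

## Known limitations

* Cofactors (ATP, NAD(P)H, CoA, Pi) are untracked: the yield metric is
  carbon-only by construction.
* No thermodynamics: route feasibility and ΔG′ ranking are out of scope.
* The kinetic defaults are placeholders (above); fitting them to the real
  time courses would require data that are not bundled.
* Stereochemistry is limited to D/L labels; no structural cheminformatics.
* The explicit integrator would need smaller steps (or an implicit method)
  for genuinely stiff parameter sets, e.g. a diffusion-limited isomerase at
  high loading.
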