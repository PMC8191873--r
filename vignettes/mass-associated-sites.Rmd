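---
title: "Detecting body-mass-associated residues in myosin orthologues: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting body-mass-associated residues in myosin orthologues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`myomass` asks a comparative question: in an alignment of one myosin II
isoform across many mammals, which columns change with species body mass
rather than with phylogenetic clade? This vignette is the package's own
account of the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## The divergence regression

For a reference species `r` (by convention the smallest, mouse-like
species), every other species contributes a point
(log₁₀ mass in kg, percent identity to `r`). Identity uses the
mutually-ungapped convention — 100 × matches / columns where both
sequences carry a residue — because orthologue alignments of a single
isoform are nearly gap-free and a gap tells us nothing about substitution.
An alignment-length denominator is available for comparison
(`denominator = "alignment_length"`). Ambiguity letters (B, Z, X, J, U, O)
are accepted, logged, and never counted as matches.

The fit minimises the sum of absolute residuals (LAD) rather than squares,
so a single aberrant species (a mis-assembled sequence, an atypical mass
record) cannot lever the slope. We solve the LAD problem exactly: an
optimum always exists on a line interpolating two observations, so the fit
enumerates all candidate pair-lines and keeps the best, breaking ties
(objective within 1e-9) toward the candidate with the smallest residual
sum of squares. This is O(n³) but exact and deterministic; at the study's
n ≈ 67 it takes milliseconds, and the test suite verifies agreement with
an independent linear-programming solution to 1e-6.

Choices worth making explicit:

* **Units.** "Per log kg" is read as per *decade* of mass (log base 10),
  consistent with converting a gradient g into `|g|/100 × L` amino-acid
  changes per 10-fold mass increase over an L-residue domain.
* **R² for a robust fit** has no canonical definition. We report
  `1 − SS_res/SS_tot` computed from the LAD residuals, clamped to [0, 1]
  (an L1 line can in principle do worse than the mean on a squared-error
  scale), and also emit the ordinary least-squares R² for comparison.
* **Gradient error** comes from a nonparametric species bootstrap
  (default 1000 resamples, seeded); resamples with a degenerate regressor
  (all masses equal) are redrawn.
* **The reference species is excluded** from the fit by default: its
  identity is 100 by definition, not an observation.
* **Mass-perturbation check.** Body masses are literature compilations
  with real error; each of 1000 replicates multiplies every mass by an
  independent uniform draw in [0.8, 1.2] and refits. On a stable data set
  the replicate gradients form a narrow band around the unperturbed value.
* Gradient groups: strong (|g| > 0.5 %/decade), weak (|g| < 0.1),
  intermediate otherwise; both thresholds are arguments.

## The site scan

**Selection.** Columns are profiled (consensus amino acid, its frequency
over *all* sequences, distinct amino-acid count; gaps are tallied but can
never be consensus, and all-gap columns are flagged out). Two selection
rules are provided because they are not equivalent: keep columns with
consensus frequency strictly below a threshold (default 0.90), or keep
columns where the second amino acid reaches at least 10 % of the top
count. The consensus rule is the default.

**Encoding.** Only the two most frequent amino acids at a site are
modelled; carriers of anything else, or of a gap, are excluded from that
site's tests (a gap is missing data, not a third allele). Frequency ties
break alphabetically. State 0 is assigned to the amino acid whose carriers
have the lower median mass, so transitions read small → large and fitted
logistic slopes are positive.

**Tests.** Mass association is a two-sided Mann–Whitney U comparing
carrier masses. The p-value is exact — full enumeration of group
assignments, two-sidedness defined as rank sums at least as far from the
null expectation as observed — whenever `n0 + n1 ≤ 12` or
`min(n0, n1) ≤ 3`; small clades and lopsided sites are exactly where the
normal approximation is worst. Larger sites use the normal approximation
with tie and continuity corrections. Being rank-based, the p-value is
invariant under any monotone transform of mass, so the log₁₀ convention is
immaterial here. Clade association is a two-sided Fisher exact test
(hypergeometric summation of tables no more probable than the observed
one) on the 2×2 of state by clade, restricted to the two major clades;
minor-clade species stay in the mass test but cannot enter a 2×2. When the
top-two encoding excludes an entire major clade the site's clade test is
undefined and its classification is NA rather than a guess.

**Multiplicity.** The Bonferroni family is the number of sites actually
tested in the run, recorded in every output row; at 52 tested sites the
5 % and 1 % per-test thresholds are 9.62×10⁻⁴ and 1.92×10⁻⁴. A site is
`mass_only` when only the mass test clears the adjusted threshold,
`clade_only` for the mirror case, otherwise `both`/`neither`. Tests are
two-sided throughout.

**Transition masses.** The logistic model
`logit P(state 1) = β₀ + β₁·log10(mass)` gives the midpoint `−β₀/β₁` (the
mass at which both residues are equally likely) and the 10–90 % transition
range `2·log(9)/β₁ ≈ 4.39/β₁`. Steep, well-separated sites — the
interesting ones — break maximum likelihood: under complete separation the
MLE diverges. We detect separation (glm warnings, or |β₁| > 20) and refit
with a Jeffreys-prior (Firth-type) penalty,
`ℓ(β) + ½ log det I(β)`, maximised by BFGS from a centred
parameterisation; the estimate is finite, the midpoint lands between the
flanking log-masses, and a separation flag is set. The test suite checks
the penalized fit against a brute-force grid maximiser.

**Annotation overlap** distinguishes position-level matches from exact
substitution matches (same residue *and* same replacement amino acid),
since a shared position with a different substitution is weak evidence of
shared mechanism. Default hypervariable regions (N-terminus 1–36, Loop 1
201–215, Loop 2 615–637, reference numbering, inclusive bounds) flag sites
whose variability is background rather than signal.

## Independent contrasts

A correlation between identity and mass could in principle reflect shared
ancestry. The contrasts module implements Felsenstein's recursions
directly — contrast `(x_i − x_j)/√(v_i + v_j)`, ancestral value the
variance-weighted mean, parent branch extended by `v_i v_j/(v_i + v_j)` —
in a deterministic post-order (children ordered by smallest descendant tip
label). The contrasts regression is through the origin with t-based
inference on `tips − 2` degrees of freedom, standard for through-origin
PIC regression. Numerical guards: polytomies are resolved arbitrarily with
zero-length branches (warned), and any zero combined branch length entering
a division is replaced by `1e-8 × tree height` (warned). Identity values
are used untransformed even though they are bounded at 100; with >90 %
identity throughout the bound is far from the data, and fidelity to the
plain identity scale was preferred over a logit nicety. The implementation
is cross-checked against `ape::pic` in tests but never delegates to it,
and a 1000-replicate null simulation (independent Brownian traits on a
32-tip tree) verifies the 5 % level empirically.

## Crossbridge kinetics

The detachment-limited model says the unloaded shortening velocity is set
by how fast the bound crossbridge lets go: `V₀ = d/τ` with working stroke
`d`, and for slow/β-cardiac myosin the strongly-bound lifetime is the ADP
release time, `k₋ADP = 1/τ`. The module is mostly careful arithmetic with
units (ms, μm/s, nm) plus fitting:

* **d defaults to 10 nm.** The built-in lifetime table is internally
  consistent with `τ_V0 = 10/V₀` in every cell, so 10 nm is the value that
  reproduces it; estimates of the working stroke in the literature vary
  (5 nm is also commonly quoted, and half-sarcomere conventions differ by
  a factor of 2), so `d` is an explicit parameter everywhere.
* Table reproduction rounds half-up to the printed precision of each cell,
  since printed tables in this literature round half up.
* **Exponential transients** are fitted by Levenberg–Marquardt least
  squares with deterministic log-linear probe initialisation. Two-phase
  fits parameterise the slow rate as a fraction of the fast rate bounded
  at 1/3, avoiding the exchange degeneracy of two nearly equal rates.
  Traces whose total amplitude is within 3× the point-to-point noise are
  flagged flat (rate unidentifiable) instead of fitted.
* **Competition fits** use `k_obs = k0/(1 + [ADP]/K_ADP)`; a series with
  under 1 % relative inhibition is flagged unbounded rather than returning
  a meaningless huge affinity. The second-order ATP-binding constant is an
  ordinary least-squares slope with a free (reported) intercept.

## The synthetic generator

The generator produces the study conditions the pipeline is validated
under: 67 species — 32 + 30 in two major clades plus 4 + 1 minor-clade
species — on an ultrametric clade-structured pure-birth tree of height 1;
log₁₀ masses uniform in [log₁₀ 0.006, 4] (6 g to 10,000 kg, the same
bounds in every clade so that clade is not mass-confounded by default);
800 columns comprising 632 conserved, 144 neutrally drifting
(Poisson substitutions at rate 0.05 per unit branch length, keeping most
of them nearly invariant), 12 clade markers (basal-split amino acid,
flipped with probability ε) and 12 mass-threshold sites (state 1 with
probability `logistic(10 × (log₁₀m − midpoint))`, midpoints evenly spaced
in [−1.5, 3], then flipped with probability ε = 0.05). Mass sites are
generated *independently of the tree* — a pure mass-threshold model — so
planted mass and clade signals are cleanly separable truth. A
`confounded = TRUE` mode caps the first clade at 140 kg while the second
spans the full range, reproducing the real-data caveat that the very
largest mammals all come from one clade.

What passing the recovery suite shows: under steep transitions with ≤5 %
state noise, the scan recovers ≥10/12 planted mass sites as `mass_only`
with ≤1 false call (averaged over 20 seeds), never calls a planted clade
marker `mass_only`, and recovers central transition midpoints within
±0.1 log₁₀ units at n = 200 (noiseless) and ±0.3 at n = 64 with ε = 0.05.
What it does not show: performance on real alignments with indels,
empirical substitution processes, heritable (tree-correlated) masses, or
mass–clade confounding — the generator deliberately idealises all four
(Brownian masses and the confounded mode exist precisely to probe the
latter two).

## Problem sizes and reproducibility

Every stochastic component is seeded and bit-reproducible. The shipped
validation uses sizes chosen to exercise the asymptotics without waste:
exhaustive enumeration oracles up to n = 10, LP cross-checks up to 20
points, 1000-replicate bootstrap and perturbation runs, a 1000-replicate
type-I-error simulation on 32 tips, and the 20-seed recovery suite on the
full 67 × 800 configuration.

## Known limitations

* The Mann–Whitney exact path enumerates only small groups; intermediate
  sizes rely on the corrected normal approximation (tests verify it to
  within 10 % of a permutation oracle at n₀ = n₁ = 30).
* The top-two encoding discards third alleles; sites with three common
  amino acids are reported but not modelled beyond the reduction.
* The clade test conditions on the two major clades; minor clades
  contribute to mass evidence only.
* LAD R² is a descriptive, clamped quantity, not a variance decomposition.
* Contrast inference assumes Brownian trait evolution and an accurate,
  fully bifurcating chronogram; zero-length-branch epsilons are a
  pragmatic guard, not a model.
* The analysis workflow (`analysis/` scripts) is the intended interface;
  there is no shell CLI beyond them, by design.
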