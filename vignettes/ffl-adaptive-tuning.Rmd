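---
title: "Adaptive tuning of an incoherent feedforward loop: models and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive tuning of an incoherent feedforward loop: models and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflevo)
```

## The biological problem

In the yeast nitrogen catabolite repression (NCR) network, the GATA-family
activator GAT1 drives both the high-affinity ammonium transporter gene
*MEP2* and the repressor *DAL80*, which in turn represses *MEP2*. This
three-node wiring is an incoherent type-1 feedforward loop (I1-FFL): the
direct arm activates the target while the indirect arm suppresses it.
Under ammonium limitation, selection repeatedly favours missense mutations
in the GAT1 DNA binding domain that *weaken* its binding — and yet *MEP2*
expression goes *up*. `fflevo` packages the quantitative machinery needed
to understand and test that counterintuitive claim: an ODE model of the
loop, binding dose-response fits, per-codon dN/dS profiling, a gene-set
permutation test, and competition-assay fitness estimation, all backed by
synthetic-data generators with known ground truth.

## The I1-FFL model

The model is deliberately minimal — linear production and first-order
decay:

$$\frac{d\,GAT1}{dt} = 0,\qquad
\frac{d\,DAL80}{dt} = A X \cdot GAT1 - c \cdot DAL80,\qquad
\frac{d\,MEP2}{dt} = A \cdot GAT1 - R \cdot DAL80 - c \cdot MEP2.$$

`A` is the activation strength of the *MEP2* promoter, `A·X` that of the
*DAL80* promoter (so `X` compares the two arms), `R` the repression
strength, and `c` a shared degradation rate. Setting derivatives to zero
gives the closed form implemented in `analytic_steady_state()`:

$$DAL80_{ss} = \frac{A X \cdot gat1}{c}, \qquad
MEP2_{ss} = \frac{A \cdot gat1\,(1 - R X / c)}{c}.$$

Two structural facts follow immediately and drive everything else:

* `MEP2_ss` depends on the mutant parameters only through `A` and the
  combination `R X / c`. A mutation that lowers both `A` and `X` — weaker
  binding at *both* promoters, but disproportionately weaker at *DAL80* —
  can raise `MEP2_ss`. With the default reference `(A = 1, X = 0.4)` the
  adaptive region is exactly `A'(1 - 2X') > 0.2`.
* `MEP2_ss` is exactly linear in the GAT1 level, so raising GAT1 itself
  also raises MEP2 whenever net activation is positive (`X < c/R`).

```{r ffl}
anc <- ffl_params(A = 1, X = 0.4, R = 2, c = 1)
relative_mep2(ffl_params(A = 0.8, X = 0.2, R = 2, c = 1), anc)
```

Because the model is linear it admits negative steady states when
repression outweighs activation (`X > c/R`). We report the raw value with
a `negative_mep2` flag rather than clamping: the phase diagram is a
continuous surface and clamping would hide the boundary.

Numerical integration (`integrate_ffl()`, via `deSolve::ode` with
lsoda and 1e-9 absolute/relative tolerances) exists for two reasons: to
verify the closed form independently (the two agree to well below 1e-6
over a 20x20 parameter grid) and to expose the transient. From rest, the
direct arm acts before the repressor accumulates, so MEP2 overshoots its
steady state — the signature pulse of the I1-FFL. A state counts as a
numeric steady state when the largest absolute derivative falls below
1e-8; the default horizon `t_end = 100/c` is many decay half-lives. These
tolerances are implementation choices.

The `sweep_parameter_grid()` default (101 x 101 over `A` in [0, 2], `X`
in [0, 1]) resolves the adaptive region cleanly while staying instant to
compute; the reference point is configurable because the ancestral
coordinates are a modelling choice, not a measured quantity — we require
only that the ancestor's *MEP2* activation exceeds its *DAL80* activation
(`X < 1`), and pick `(1, 0.4)` comfortably inside the positive-expression
regime.

## EMSA binding curves

Gel-shift assays titrate protein against labelled DNA;
`fraction_bound()` turns band intensities into the bound fraction, and
`fit_michaelis_menten()` fits the saturating two-parameter model

$$Fr = \frac{Fr_{max}\, x}{x + K_x}$$

with `Frmax` the binding ceiling and `Kx` the dose (ug) at half-maximal
binding. Fitting is plain nonlinear least squares (Levenberg-Marquardt),
with deterministic starts (`frmax0` = max observed fraction, `kx0` = dose
nearest half that) — no random restarts, so fits are reproducible.
Standard errors come from the asymptotic covariance at the optimum and
per-parameter p-values from t-statistics on n − 2 degrees of freedom;
`mm_fit_significant()` applies the conventional p < 0.02 reporting
threshold for calling both parameters estimated. The zero-dose point is
kept in the fit (the curve passes through the origin), and fractions
nudged outside [0, 1] by densitometry noise are retained and flagged —
least squares is well defined regardless, and discarding them would bias
the ceiling.

A note on precision honestly learned from simulation: with only six doses
and noise of sd 0.02, `Kx` is recovered with a median relative error of
about 10% — the dose series simply brackets the half-maximal point
sparsely. `Frmax` does three times better, and the nominal 95% intervals
cover truth at close to nominal rate for both parameters.

`pwm_from_top_kmers()` reproduces the standard motif-summary step from
protein binding microarray practice: take the `top_n` (default 10) k-mers
by score and tally per-position base frequencies. We align ungapped at
offset zero, optionally flipping each k-mer to its reverse complement when
that matches the top-scoring k-mer better (forward orientation wins ties);
score ties at the selection boundary break lexicographically so the PWM is
deterministic. The alignment procedure is our design choice — the
upstream convention is not specified beyond "align the top ten".

## Per-codon dN/dS

`dnds_profile()` quantifies purifying selection along a coding sequence,
e.g. a transcription factor's DNA binding domain across dozens of
isolates. For each codon, potential synonymous sites `S` are the fraction
of the nine single-base neighbours that preserve the amino acid (divided
by 3), with `N = 3 − S`; changes creating stop codons count as
nonsynonymous, keeping `S + N = 3`. Observed substitutions between two
codons differing at k positions are averaged over all k! single-step
pathways, excluding pathways through stop codons and re-weighting the
remainder equally. Across an alignment we pool counts over all unordered
sequence pairs before dividing (Nei-Gojobori-style averaged pairwise
counting): `dN = sum(Nd)/sum(N)` per position. Pooling counts rather than
averaging per-pair proportions is our choice where the two differ; it
weights every observed substitution equally.

These are raw proportions, not rates: no multiple-hit (Jukes-Cantor)
correction is applied, values can exceed 1 (a single synonymous
difference at a codon with `S = 1/3` gives `dS = 3`), and positions with
no potential sites of a class are `NA`, never 0. Pairs containing gaps,
ambiguity codes or stop codons are skipped position-wise with a recorded
count. Only the standard nuclear code is supported.

```{r dnds}
dnds_profile(codon_alignment(c("TTTGGG", "TTCGGG")))
```

## Fitness and expression statistics

`estimate_fitness()` is the classical competition-assay estimator: the
selection coefficient `s` is the OLS slope of `ln(query/reference)`
against generations, with a t-based 95% CI. Following the field's
reporting convention, the CI is suppressed (flagged, not silently
dropped) when fewer than 5 time points were sampled, although it is
computable from 3. Frequencies and counts give identical slopes, so both
are accepted.

`correlation_with_permutation()` asks whether a focal gene set (e.g. 41
NCR targets among ~6000 genes) shows a stronger promoter-affinity vs
expression-change correlation than random gene sets of the same size. The
null is built by drawing `n_perm` (default 10,000) random same-size sets
from all genes — including the focal genes themselves by default, with an
exclusion option — and the p-value uses the add-one convention
`(1 + #{null >= obs})/(n_perm + 1)`, which never returns 0. The test is
one-sided toward positive association by default because that is the
directional hypothesis (higher affinity, higher expression); a two-sided
option compares absolute values. Both Spearman (default, robust to
monotone transforms) and Pearson are available since both appear in
common use for this design; the package does not adjudicate between them.

`normalize_gfp()` is the standard flow-cytometry reporter normalization:
`log10(gfp/fsc)` per event, dropping non-positive GFP events with a
count.

## What the synthetic data emulate — and what they do not

Every generator is a pure function of its parameters and seed, and its
defaults are the study conditions the analyses assume: six-point dose
series (0, 1, 5, 10, 15, 20 ug); 42-sequence codon alignments; a
6000-gene background with a 41-gene focal set; 1:9 initial mixing with
10,000 cells per time point.

* `gen_emsa_data()`: i.i.d. Gaussian noise on the true curve. Real gels
  have dose-dependent, correlated densitometry error.
* `gen_codon_alignment()`: star phylogeny, one hit per codon per lineage,
  uniform rates outside the constrained window. Real isolates share
  phylogenetic structure, so real pairwise counts are correlated; the
  generator keeps the ground truth analytically transparent instead.
* `gen_gene_table()`: bivariate normal focal set over an uncorrelated
  background. Real affinity scores and fold changes are heavy-tailed and
  the background is not exactly null.
* `gen_competition()`: binomial sampling of a deterministic
  logistic-ratio trajectory; no drift, no frequency-dependent selection.
  `depth = Inf` gives the exact no-sampling limit.

Passing tests therefore demonstrate correctness of the estimators under
their own generative assumptions — recovery, calibration, invariances —
not robustness to the messier error structure of real data.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulation sizes are chosen as the
smallest that make the Monte-Carlo checks statistically meaningful: 200
replicate EMSA fits for recovery/coverage, 500 null permutation runs at
`n_perm = 1000` for the calibration KS test (with a 2000-gene background,
since the null distribution of a size-41 subset correlation does not
depend on background size), 200 powered runs at the full 6000-gene scale,
and 500 binomial competition replicates. Integrator tolerances are
1e-9/1e-9 with steady-state residual 1e-8; NLS runs up to 200
Levenberg-Marquardt iterations with `kx` bounded away from 0.

## Known limitations

* The FFL model is linear: no promoter saturation (Hill functions), no
  stochasticity, and no attempt to fit the model to measured expression.
* dN/dS is phylogeny-blind and uncorrected; it is a descriptive profile,
  not a likelihood-based selection test.
* Gel image processing, PBM score computation, FCS parsing and
  differential-expression calling are upstream of this package and out of
  scope.
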