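---
title: "Models and methods in gpcrpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gpcrpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrpharm)
```

gpcrpharm analyzes the assay battery of a receptor-subtype selectivity
study: signaling concentration–response curves, operational-model bias
quantification, equilibrium and kinetic radioligand binding, and
structure-derived pocket metrics. This vignette documents the models,
their assumptions, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Units and data layout

All analysis runs in molar, seconds, s⁻¹ and M⁻¹s⁻¹. CSV readers
convert at the I/O boundary (`dose_unit` column or a declared default;
`time_unit` likewise), because assay tables habitually mix nM/µM and
minutes, and a single internal convention removes a whole class of
silent errors. Tables are long/tidy — one measurement per row keyed by
(ligand, receptor, pathway, dose, replicate) — and duplicate keys are
rejected at parse time. Rows with dose = 0 are vehicle wells; they
anchor normalization and are excluded from fits, where doses must be
strictly positive.

## Concentration–response

Raw signals are normalized per (receptor, pathway) group to the mean
vehicle signal (0%) and the mean signal of the reference agonist at its
highest dose (100%), the standard convention when a well-characterized
endogenous full agonist is on every plate.

The four-parameter logistic is parameterized in log10(EC50), with the
Hill slope kept positive through a log parameterization. Fitting is
Levenberg–Marquardt (via minpack.lm) with a deterministic multi-start:
seven log-spaced EC50 initializations spanning the observed dose range;
the best residual sum of squares wins and ties go to the slope closest
to 1, so repeated runs give identical answers. Standard errors come
from the Gauss–Newton covariance (JᵀJ)⁻¹·RSS/dof, which is what
commercial curve fitters report; no bootstrap is attempted by default.
Replicates are pooled as individual points into one fit by default;
`replicates = "average"` fits each replicate separately and averages
the estimates, for designs where between-plate variation dominates.
Degenerate inputs (constant responses) return a non-converged fit with
an explicit unidentifiable status rather than an error, so a plate
batch continues past unusable wells.

Real-time second-messenger accumulation assays are handled in two
stages: a single-exponential rise fitted inside a window (default
5–305 s, the span over which such fluorescence traces are effectively
single-exponential) gives a rate constant per agonist concentration,
and a 4PL fit of rate versus concentration gives the potency. A trace
with no resolvable rate is dropped with a warning rather than aborting
the batch. Whether the second-stage logistic should constrain its slope
to 1 is not settled practice; the slope is left free here.

## Operational model and bias

Within one (receptor, pathway), all ligand curves are fitted globally
to E = Em·τⁿAⁿ/((A+K_A)ⁿ + τⁿAⁿ) with the system maximum Em and
transducer slope n shared across ligands — the sharing scheme of the
standard operational-bias methodology. The transducer slope starts at 1
and is bounded to [0.3, 3]: slopes outside that range indicate misfit
rather than transduction, and the bounds stabilize the global fit.

Full versus partial agonists: for a full agonist, τ and K_A enter the
response only through τ/K_A, so the curve is fitted in the limiting
form E = Em·(R·A)ⁿ/(1+(R·A)ⁿ) with R = τ/K_A. The switch uses the
observed plateau — at least 90% of the largest plateau in the group
(configurable) — because beyond that point the separate parameters are
numerically hopeless even when formally distinct.

Two identifiability facts shape the interface:

* If every ligand is full, Em is not separately identifiable and is
  anchored to the reference ligand's observed plateau, with a status
  note.
* With no full agonist and a slope near 1, Em trades off against the
  per-ligand parameters along a ridge of equal fit; absolute
  log(τ/K_A) values then shift by a common constant while differences
  Δlog(τ/K_A) are unaffected. The `em_fixed` argument lets a known
  system maximum pin the scale when absolute coefficients are wanted.
  All bias quantities (RE, bias factors) are built from Δ and ΔΔ and do
  not depend on this convention.

Standard errors of log(τ/K_A) use the joint fit covariance (delta
method on log τ − log K_A for partial agonists). Across pathways the
reference ligand's coefficient is treated as independent and SEs
combine in quadrature at each subtraction — mildly conservative, since
the two pathway fits share no data. RE and bias factors are reported
from pooled fits (per-experiment averaging is a reasonable alternative
the data layout supports but the package does not automate).

## Equilibrium binding

Saturation data fit the one-site hyperbola B_max·L/(K_D+L), either on
specific binding (total minus matched nonspecific wells) or in a
one-step model with a linear nonspecific term — both designs occur in
practice. A fitted K_D more than three-fold above the highest sampled
concentration is flagged unidentifiable: the curve shows no curvature
there. Competition curves use a descending logistic with free Hill
slope; the Cheng–Prusoff conversion K_i = IC50/(1+[L]/K_D) assumes
one-site competition, so a fitted slope outside [0.8, 1.2] raises a
reported caveat rather than silently converting. The radioligand
concentration is a per-experiment input (assay protocols quote a range
such as 0.2–0.3 nM), so the schema carries it per record rather than
hard-coding a value.

## Kinetics of competitive binding

The two-ligand mass-action system (labeled ligand k1/k2, unlabeled
competitor k3/k4, no ligand depletion) has a closed-form solution for
labeled binding with eigenvalues K_F and K_S. When K_F ≈ K_S the
expression is a 0/0 form; rather than jittering parameters, the
implementation switches to the analytic series limit when
K_F − K_S < 1e-9·K_F, which keeps evaluation deterministic and
testable. A direct ODE integration (deSolve, rtol 1e-10) is shipped as
the reference implementation; the closed form is required by test to
agree with it to better than 0.1% of B_max across random parameter
draws spanning three orders of magnitude per rate. The model reproduces
the known transient overshoot of labeled binding when the competitor
equilibrates more slowly than the radioligand.

Fitting is global across association traces with shared k3, k4 and
signal scale, all log-parameterized, with the radioligand's own rates
fixed — they come from prior experiments, and co-fitting them with the
competitor's is poorly conditioned. Multi-start uses a deterministic
grid over plausible kinetic K_D (10⁻⁸–10⁻⁵ M) and k4 (10⁻⁴–10⁻² s⁻¹)
values. At least two association traces at distinct competitor
concentrations (one non-zero) are required; otherwise only the product
structure of the model is constrained and the fit declines to report
k3/k4, with an identifiability warning. Dissociation chases fit
y = ns + (y0 − ns)·e^(−koff·t); a rising trace is rejected. Nonspecific
binding in association traces is assumed removed by the washing
protocol (default additive constant 0).

## Structure metrics

Coordinates come from PDB or mmCIF via bio3d; only the first model is
kept and alternate locations resolve to the highest occupancy (ties to
altloc A). Selectors use author chain/residue numbering only —
position-generic GPCR numbering schemes require alignment machinery
that is out of scope, and published distances are reproducible from
author numbering. Cα RMSD matches residues by number intersection
within a user-selected chain/range (fusion partners and nanobody chains
are excluded by selection, since "all Cα atoms" in a paper rarely means
the crystallization chaperones), then superposes by the Kabsch
orthogonal-Procrustes rotation with a reflection guard. Per-residue
B-factors are unweighted means over non-hydrogen atoms (Cα-only
offered), normalized by the selection-wide atom mean so the
atom-weighted average is exactly 1; deltas between structures carry a
sign classification matching the blue/red stabilization coloring
convention. Torsions follow the IUPAC sign convention and refuse
collinear configurations.

## Synthetic data: what it emulates, and what it does not

Each generator draws from the exact forward model its fitter inverts,
with additive Gaussian noise on the signal scale (assay papers rarely
report an error model; heteroscedastic options are deferred) and the
ground truth in a sidecar, never in the data table. The default study
battery mirrors the designs this package targets: catecholamine dose
series over 10⁻¹⁰–10⁻⁴ M, competition binding in triplicate at 0.25 nM
radioligand against a 0.080 nM-K_D / B_max 2.7 site, association
kinetics in the absence or presence of three competitor concentrations
with a competitor at k3 = 10⁶ M⁻¹s⁻¹ and k4 = 5×10⁻³ s⁻¹, a
dissociation chase with a 10% nonspecific plateau, and a two-pathway
operational design with a built-in ΔΔlog(τ/K_A) of 0.7. The labeled
ligand's synthetic rates (k1 = 3×10⁷ M⁻¹s⁻¹, k2 = 3×10⁻³ s⁻¹, K_D
0.1 nM) are plausible for a high-affinity antagonist radioligand but
are placeholders: real analyses must supply the measured values. Noise
defaults to 2% of scale, a choice in the 1–3% band typical of
plate-reader replicates; it is a convention, not an estimate.

Passing recovery tests on these data shows the estimators invert their
own forward models under Gaussian noise at realistic designs. It does
not show robustness to features real plates have and the generator
lacks: heteroscedastic and correlated errors, edge effects, ligand
depletion, receptor reserve differences between assay formats, or
hand-pipetting dose errors.

Monte-Carlo problem sizes used by the tests and the acceptance script —
200 seeds for kinetics recovery, 100 for 4PL and for the end-to-end
bias pipeline, 100 random parameter sets for the ODE-oracle
comparison — keep each study's Monte-Carlo error comfortably below the
tolerance it checks while completing in seconds.

## Known limitations

No biphasic or two-site dose–response models, no Schild analysis, no
alternative bias scales, no kinetic (time-dependent) bias models, no
ligand-depletion or two-state receptor kinetics, no two-site
competition, and no electron-density handling. The deposited-structure
comparison in the acceptance suite requires coordinate files the
package does not redistribute.
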