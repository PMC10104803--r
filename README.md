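# gpcrpharm

Quantitative pharmacology for GPCR subtype-selectivity studies, built
around the assay battery used to characterize catecholamine agonists at
the β1 and β2 adrenergic receptors: concentration–response fitting,
operational-model quantification of ligand bias, equilibrium and kinetic
radioligand binding analysis, and structure-derived binding-pocket
metrics. A seeded synthetic-data generator reproduces the statistical
structure of every assay so that each fitting stage can be validated
against known ground truth.

## Who this is for

Molecular pharmacologists analyzing plate-based signaling assays
(β-arrestin recruitment, cAMP/IP-one accumulation), radioligand binding
experiments (saturation, competition, association/dissociation time
courses), and the matching crystal-structure comparisons. Everything is
driven from R; inputs are tidy CSV tables and PDB/mmCIF coordinate
files.

## The models at the core

**Concentration–response.** Normalized signals (vehicle = 0%, reference
agonist maximum = 100%) are fitted with the four-parameter logistic

    E(A) = basal + (Emax − basal) / (1 + 10^(n·(logEC50 − log10 A)))

by Levenberg–Marquardt least squares with deterministic multi-start.
Real-time accumulation assays use a two-stage pipeline: a
single-exponential rate per agonist concentration, then a logistic fit
of rate versus concentration.

**Ligand bias (operational model of agonism).** Per pathway, responses
of all ligands are fitted globally to

    E = Em·τⁿ·Aⁿ / ((A + K_A)ⁿ + τⁿ·Aⁿ)

with Em and the transducer slope n shared. Each ligand's transduction
coefficient log(τ/K_A) combines efficacy τ and functional affinity K_A.
Against a reference agonist, Δlog(τ/K_A) gives the relative
effectiveness RE = 10^Δ; across two pathways, the bias factor is
10^ΔΔlog(τ/K_A) (1 = unbiased). Standard errors propagate from the fit
covariance and combine in quadrature at each subtraction. Full agonists
are fitted in a reparameterized limiting form in which only log(τ/K_A)
is identifiable.

**Equilibrium binding.** One-site saturation (B_max, K_D; with matched
nonspecific subtraction or a one-step linear-nonspecific model),
competition IC50 by descending logistic fit, and the Cheng–Prusoff
conversion K_i = IC50 / (1 + [L]/K_D).

**Binding kinetics.** The closed-form time course of labeled-ligand
binding in the presence of an unlabeled competitor (kinetics of
competitive binding), fitted globally across association traces at
several competitor concentrations to recover the competitor's on-rate
k3 and off-rate k4, with the radioligand's own rates held fixed. An
independent mass-action ODE integration serves as the reference
implementation, and dissociation chases are fitted as single
exponentials.

**Structure metrics.** Atom-pair distances, residue-matched Cα RMSD
after Kabsch superposition, normalized per-residue B-factors (residue
mean divided by the selection-wide mean) and their between-structure
deltas, and IUPAC-signed torsion angles, from PDB or mmCIF input.

## Worked example

Generate a two-pathway synthetic study with a built-in pathway bias of
ΔΔlog(τ/K_A) = 0.7, fit the operational model per pathway, and compute
the bias factor:

```r
library(gpcrpharm)

spec <- synthetic_spec("dose_response_operational",
                       noise = list(sigma = 2, type = "percent"), seed = 42)
study <- generate(spec)

coeffs <- do.call(rbind, lapply(c("camp", "arrestin"), function(pw) {
  curves <- Filter(function(cv) attr(cv, "pathway") == pw, study$data)
  transduction_coefficients(fit_operational(curves, "ref"))
}))
coeffs
#>   ligand receptor  pathway log_r se_log_r
#> 1    ref       R1     camp  7.37   0.0465
#> 2   test       R1     camp  6.85   0.1287
#> 3    ref       R1 arrestin  7.39   0.0528
#> 4   test       R1 arrestin  7.44   0.1362

bias_factor(coeffs, test = "test", reference = "ref",
            pathway_a = "arrestin", pathway_b = "camp")
#> Bias: test vs ref on R1 (arrestin over camp)
#>   RE[arrestin] = 1.13, RE[camp] = 0.298
#>   ddlog(tau/KA) = 0.578 +/- 0.200, bias factor = 3.79
```

The test ligand is about as effective as the reference in the arrestin
pathway (RE ≈ 1.1) but three-fold less effective in the cAMP pathway
(RE ≈ 0.3), giving an arrestin-directed bias factor of ≈ 3.8 for this
noisy realization (true value 10^0.7 ≈ 5; the ± 0.2 log-unit SE covers
the difference).

Recovering competitor binding kinetics from association traces:

```r
rl  <- radioligand_kinetics(k1 = 3e7, k2 = 3e-3, conc_l = 0.25e-9)
kin <- generate(synthetic_spec("kinetics_association",
                               noise = list(sigma = 2, type = "percent"),
                               seed = 42))
fit_competitor_kinetics(kin$data, rl)
#> Competitor kinetics fit
#>   k3 = 1.048e+06 /M/s, k4 = 0.005262 /s, kinetic KD = 5.019e-09 M
```

against generating values k3 = 1e6 /M/s, k4 = 5e-3 /s (kinetic
K_D = 5 nM).

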