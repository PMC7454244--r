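---
title: "Virtual clinical trials of T-cell-engager and PD-L1 blockade combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual clinical trials of T-cell-engager and PD-L1 blockade combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcevct)
```

## The scientific problem

Microsatellite-stable (MSS) colorectal cancer is immunologically "cold":
PD-L1 expression on cancer cells is modest, tumor mutational burden is low,
and checkpoint blockade alone rarely works. Two therapeutic routes are
modelled here, alone and in combination:

* **atezolizumab**, a bivalent anti-PD-L1 antibody that derepresses T-cell
  killing at the tumor synapse and restores proliferative capacity during
  priming in the tumor-draining lymph node (TdLN); and
* **cibisatamab**, a CEA x CD3 bispecific T-cell engager (TCE) that forms a
  cytolytic synapse between cancer cells and T cells independently of
  MHC-restricted antigen recognition.

`tcevct` implements a quantitative systems pharmacology (QSP) simulator of
these therapies: quasi-steady-state binding chemistry at the two synapses,
closed-form two-compartment antibody pharmacokinetics, a compiled
tumor-immune ODE core over four compartments (blood, periphery, tumor,
TdLN), a Latin-hypercube virtual-patient generator with a physiological
plausibility screen, a three-arm RECIST trial engine, and the biomarker
statistics used to interrogate the results (PRCC, rank-sum tests, ROC/AUC,
binned response-rate curves).

## Binding chemistry

Surface binding is fast relative to cellular dynamics, so all complexes are
treated algebraically (quasi-steady state) and re-evaluated from the local
drug concentration whenever needed, rather than carried as ODE states.

**Checkpoint axis.** PD-1 on the T cell binds PD-L1 and PD-L2 on the
opposing cell with surface dissociation constants expressed in sites/cell.
The drug binds PD-L1 monovalently from solution (`kd_drug`, molar) and
captures a second PD-L1 with cross-arm efficiency `chi`, an avidity
multiplier on the second-arm dissociation; `chi = 0` reduces the antibody to
a monovalent binder. A single `contact_area_scale` (sites/cell per molar)
converts solution-phase constants to the surface scale. The equilibrium
reduces to one scalar root on free PD-L1; free PD-1 and PD-L2 follow from a
stable quadratic. Inhibitory signal is the Hill factor of
`S = [PD1.PDL1] + delta * [PD1.PDL2]`, where `delta` weights the PD-L2
complex; downstream terms multiply by `1 - H`.

Per-patient PD-L2 is tied to PD-L1 through the sampled ratio `r_pdl2` in
[0, 0.07]: PD-L2 is never expressed alone and never exceeds a small fraction
of PD-L1. Note a structural consequence exercised by the trial engine: since
high-PD-L1 patients mechanically carry more PD-L2, any appreciable PD-1/PD-L2
signalling creates an unblockable inhibition that correlates with PD-L1.
The packaged default places the PD-1/PD-L2 surface coupling in a weak regime
(`kd_pd1_pdl2 = 1e6` on the sites/cell scale), consistent with the
conclusion of the PD-L2 sampling experiment below that PD-L2 has little
impact on response.

**TCE axis.** The trimer CEA-TCE-CD3 forms through either dimer path with a
thermodynamically consistent cycle; `lam` is the TCE cross-arm efficiency
(`lam = 0` means no synapse at any dose). Because high drug concentrations
occupy each arm separately, the trimer-versus-dose curve is bell-shaped (the
"hook" effect); the solver is closed-form and is property-tested against an
independent fixed-point oracle. TCE-mediated killing is the Hill factor of
trimer density.

## Tumor-immune dynamics

Fourteen states: cancer cells, dying cells, shed antigen, immature/mature
APCs (tumor) and mature APCs (TdLN), naive T cells, TdLN-activated T cells,
effector T cells in blood/periphery/tumor, and a three-state regulatory
T-cell mirror. The right-hand side is compiled C (deSolve's compiled-model
convention) with the three Hill factors supplied as forcing functions
precomputed per patient and arm — they depend on time only through drug
concentration, so each is tabulated once on a log-spaced concentration grid
and mapped through the closed-form plasma series.

Killing combines two routes,

```
K = [ k_kill_tcr * h_clone * Teff/(C + Teff + 1) * (1 - H_syn)
    + k_kill_tce * H_tce * Teff/(f_tce*C + Teff + 1) * (1 - beta_tce*H_syn) ]
    / (1 + k_treg_suppress * Treg/(Treg + Teff + 1))
```

with logistic tumor growth toward a patient-specific carrying capacity.
Three deliberate design choices here, each of which proved necessary to
reproduce the reported arm-level behaviour during calibration:

* **Separate effector-contact saturation for the TCE route** (`f_tce`).
  TCE-engaged killing is serial and MHC-independent; it saturates at a much
  lower effector:target ratio than native TCR killing. With a single shared
  contact term, checkpoint-driven T-cell expansion multiplies straight into
  the TCE route and the combination arm's response rate runs far above
  anything reported for these therapies.
* **Weak checkpoint coupling of the TCE route** (`beta_tce`, default 0.02).
  CD3 crosslinking partly bypasses PD-1 proximal inhibition. The arm
  arithmetic of the reference trial (combination roughly the union of the
  two monotherapy responder sets plus a small increment) requires the two
  routes to act nearly independently.
* **Priming inhibition as lost division rounds.** PD-L1 on APCs scales the
  effective number of proliferation generations,
  `2^(n_div * (1 - H_ln))`, so blockade in the TdLN restores clonal
  expansion. The packaged `n_div` is a small effective value (0.3): with
  large amplification factors the combination arm explodes multiplicatively.
  Atezolizumab's effect is therefore carried mainly by tumor-synapse
  derepression.

Clonal recognition follows a steep Hill in the number of activatable clones
(`n_clone_exp = 6`, half-max 85 clones), making TMB the dominant response
determinant — the property that produces the characteristic
response-versus-TMB profile (silent below ~76 clones, near-total above 200).

Antigen release includes a small spontaneous turnover term (`k_apo`) so the
antigen-presentation cascade does not require immune killing to ignite.

## Pharmacokinetics

Both antibodies follow linear two-compartment disposition with repeated
intravenous bolus dosing solved in closed form (superposed bi-exponentials)
and injected into the ODE as forcing functions; an ODE-coupled mode exists
and is used to validate the closed form to 1e-6 relative, including a
mass-balance audit. Tumor and TdLN interstitial concentrations are algebraic
fractions of plasma (`gamma_tumor = 0.1`, `gamma_ln = 0.3`, configurable).
The atezolizumab disposition values are literature-typical for an IgG1
(clearance 0.20 L/day, central volume 3.28 L); cibisatamab values are
typical for an IgG-based 2+1 TCE. Both are stated as replaceable defaults,
not fitted quantities. Dosing windows are half-open: a dose falling exactly
on the horizon is not given.

## The virtual-patient generator

Each patient is a draw over 16 axes (17 when the PD-L2 weight `delta` is
sampled): growth rate and baseline diameter, carrying capacity, TMB,
receptor densities (PD-1, PD-L1 on cancer cells and APCs, CEA, CD3),
cross-arm efficiencies, CD3-arm affinity, the PD-L2:PD-L1 ratio, effector
perfusion, and naive/regulatory supply rates. Sampling is stratified
(Latin hypercube): every axis is cut into n equal-probability strata on its
linear or log10 scale with one jittered draw per stratum and independent
permutations across axes.

The defaults define the study conditions rather than tunable dials; the
main choices and their reasoning:

* baseline diameter 1-5 cm, linear — the measurable target-lesion range for
  trial entry;
* growth rate log-uniform 0.007-0.014 per day — volume doubling times of
  about 50-100 days, the aggressive end of colorectal disease;
* TMB (activatable clones) log-uniform 1-220, so 0.8 of the normalized axis
  corresponds to about 75 clones and the top of the range exceeds 200;
* PD-L1 on cancer cells 1e4-10^5.5 sites/cell: every tumor has a blockable
  checkpoint (values below ~1e4 describe tumors whose immune escape is not
  checkpoint-driven, which belong to a different disease model than the one
  studied here);
* carrying capacity 2.2e10-2e12 cells: its lower reaches create tumors close
  to their growth ceiling whose slow progression yields the stable-disease
  fraction;
* `r_pdl2` uniform on [0, 0.07].

Pre-treatment initialization grows each tumor from a 1e4-cell seed until it
reaches its sampled baseline diameter (cap 6000 days); tumors that never get
there — too slow, or controlled by baseline immunity — are non-patients.
The physiological screen then bounds tumor diameter (1-15 cm), blood T-cell
density (500-3000 per uL), intratumoral activated-T density (1e2-1e7 per
cm^3) and the Teff:Treg ratio (0.1-50). Implausible patients are flagged and
retained, never deleted. At the reference scale (2000 draws) about two
thirds pass, matching the screening yield of the study the package
re-implements.

What the generator deliberately does not emulate: inter-axis correlation
(beyond the PD-L2:PD-L1 tie), measurement noise on lesion diameters,
multi-lesion disease, acquired resistance, toxicity-driven dose changes, and
survival endpoints. Passing acceptance checks therefore demonstrates that
the mechanistic engine reproduces the reported cohort-level statistics under
these idealized conditions, not that it predicts individual real patients.

## The trial engine and statistics

Every plausible patient is simulated in every arm from the identical
pre-treatment state (paired arms; day 0 is the first dose). Response is the
day-400 percent change of sphere-equivalent diameter under a single-lesion
RECIST 1.1 simplification: CR below a 0.2 cm detection floor, PR at -30% or
better, PD at +20% or worse (the 5 mm absolute clause is dropped for a
noiseless synthetic lesion), SD otherwise; thresholds closed. Response rates
carry Agresti-Coull 95% intervals; small-trial behaviour is mimicked by
percentile bootstrap over 31- or 25-patient resamples (10 000 replicates).

The biomarker layer mirrors standard LHS practice: PRCC with rank-residual
partial correlation and a t-approximation for p-values; two-sided Wilcoxon
rank-sum comparisons of responders versus non-responders (exact for tiny
untied samples, tie-corrected normal approximation otherwise, star notation
at 0.05/0.01/0.001/0.0001, no multiplicity correction by default); ROC/AUC
as Mann-Whitney concordance with half-credit ties; and response rate over
consecutive 20-patient bins of each sorted biomarker, normalized on the
axis's sampling scale (log axes in log space — required for the TMB anchor
at 0.8 of the axis). The trailing remainder forms a flagged short bin; the
headline top bin is the highest full bin, computed for the combination arm.

## Numerical choices

* Checkpoint equilibrium: simultaneous bisection on free PD-L1 across the
  concentration grid (70 iterations, machine precision); residual mass
  balances checked to 1e-8 relative, solver errors carry the residuals.
* TCE equilibrium: stable closed-form quadratic (no cancellation in either
  root regime).
* Integration: `lsoda`, rtol 1e-6, atol 1e-3 cells, maximum step 1 day
  during treatment; halving the tolerances moves day-400 diameters by less
  than 0.1%. Pre-treatment uses `lsodar` with a root function on diameter.
* States are clamped non-negative inside the right-hand side; killing
  denominators carry a one-cell epsilon.
* Hill-forcing tabulation: 80 log-spaced concentration points, 1601 time
  points over 400 days; interpolation error is far below solver tolerance.

## Calibration

The packaged defaults were calibrated, in the package authors' judgment and
before freezing, so that the full-scale reference trial (2000 virtual
patients) reproduces the published operating characteristics this simulator
is meant to emulate: monotherapy response rates of a few percent with the
checkpoint arm above the TCE arm, a combination arm near 11%, a screening
yield near two thirds, a TMB-dominated response profile with the printed
anchor points, and a PD-L2 sampling experiment that raises the checkpoint
arm's response by about one point while the sampled weight does not separate
responders from non-responders. Problem sizes used throughout the shipped
tests and the acceptance script are the full 2000-patient cohort; module
tests use miniature cohorts (24-70 patients) and 1000-draw property sweeps.

## Known limitations

The state vector is a structural condensation (14 states) of a much larger
published equation system; agreement is targeted at reproduced statistics
and orderings, not state-by-state parity. Arm-level response rates at the
reference scale vary by one to two percentage points across cohort seeds;
single-bin quantities (the 20-patient top-TMB bin) can move by one patient.
The model shares all paired-arm limitations of virtual trials: no dropout,
no interim decisions, no toxicity, and a single synthetic lesion per
patient.
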