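---
title: "Modeling tamoxifen-driven GPER/EGFR signaling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tamoxifen-driven GPER/EGFR signaling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`gpersig` simulates the crosstalk between two receptor axes in MCF-7 breast
cancer cells: the classical growth-factor axis (EGF binding EGFR, receptor
dimerization and autophosphorylation, Shc/Grb2/SOS assembly, Ras/Raf/MEK/ERK,
PI3K/Akt/PTEN, JAK/STAT) and the G-protein-coupled estrogen receptor axis
(tamoxifen acting as a GPR30/GPER agonist, G-protein dissociation, PLC/PKC,
Src-driven MMP maturation and HB-EGF shedding that transactivates EGFR, and
GRK/beta-arrestin receptor internalization with recycling). The headline
readout is ppERK, doubly phosphorylated ERK, summed over its free, complexed
and nuclear pools.

Kinetics are pure mass action. Every reaction is uni- or bimolecular on the
reactant side; the net velocity is

$$v = k_f \prod_i [X_i]^{s_i} \; - \; k_r \prod_j [Y_j]^{s_j},$$

with the reverse term present only for reversible reactions. Units are fixed
package-wide: concentrations in uM, time in seconds, first-order constants
in 1/s, second-order constants in 1/(uM s). There is no unit-conversion
layer and no Michaelis--Menten or Hill term anywhere; saturation, where it
occurs, emerges from explicit enzyme--substrate complexes (for example the
Raf.MEK and MEK.ERK intermediates of the dual-phosphorylation cascade).

The system of ODEs is $\dot x = N v(x)$, with $N$ the integer stoichiometry
matrix. Clamped inputs (the tamoxifen dose, the membrane HB-EGF pool, the
constitutive-synthesis drivers) are boundary species: they appear in the
state vector with derivative pinned at zero, so the treated and untreated
models share one state layout. The tamoxifen clamp is the model's single
assignment rule, `Tam = Tam_dose`, backed by a global parameter; perturbing
`Tam_dose` is how sensitivity to the tamoxifen input is probed.

## The packaged network transcription

The packaged files `signaling_network_synthetic.tsv` and
`signaling_species_synthetic.tsv` are a *synthetic transcription* of the
network: the reaction list was reconstructed from the canonical pathway
biology rather than exported from a curated model database, and the rate
constants are this package's own order-of-magnitude choices. The structure
reproduces the documented size exactly — 128 species, 143 reactions
(69 reversible), 213 parameters (143 forward constants, 69 reverse
constants, 1 dose parameter) and 1 rule — and the kinetics were calibrated
once, during construction, to place the network in the biologically
expected regime: low basal ERK activity without stimulus, strong ppERK
induction under tamoxifen, and cascade amplification of relative
sensitivities. After that calibration the table was frozen; the package's
tests treat it as data.

Three calibration decisions matter for interpretation:

* **Receptor occupancy.** The default tamoxifen input is 1 uM against a
  GPR30 Kd of 4 uM, i.e. ~20% occupancy. Bath concentrations at which
  tamoxifen kills MCF-7 cells over 48 h (hundreds of uM) would saturate
  any plausible receptor; the model works with an effective free-ligand
  scale at which the dose-response is still graded, which is the only
  regime in which a sensitivity ranking is informative.
* **Micro-reversibility.** Product-release steps of catalytic cycles are
  written reversible with very small reverse constants (1e-4 of the forward
  scale). Larger values would create thermodynamically inconsistent
  "phantom pump" cycles in which a phosphatase complex runs backwards and
  sustains phosphorylation with no kinase input; at 1e-4 the effect is
  negligible against the stimulated fluxes.
* **Basal G-protein tone.** The heterotrimer reassembly reaction is nearly
  irreversible (reverse constant 1e-5/s); a faster leak gives untreated
  cells a constitutive Gbg pool that erodes the treated-versus-untreated
  contrast.

The EGF input is shared by both conditions as a small initial bolus
(5e-4 uM) that clears with a 50-s half-life; the treated condition
additionally produces EGF continuously through the Src/MMP/HB-EGF shedding
arm, which is what makes even the EGFR-axis observables
tamoxifen-responsive.

## Numerical choices

Integration uses `deSolve::lsoda`, which switches automatically between
stiff (BDF) and non-stiff methods — the network is stiff in the usual way
of signaling cascades (fast binding equilibria against slow transcription).
Defaults: horizon 3600 s with 600 output points, `rtol = 1e-6`,
`atol = 1e-9` uM. One simulated hour covers both the fast transient and the
sustained phase of ERK activation. Concentrations in `[-atol, 0)` are
clipped to zero and counted; anything below `-atol` aborts loudly.
Tightening tolerances to `rtol = 1e-9` changes ppERK trajectories by well
under 0.1%, which the test suite checks.

Sensitivities are central finite differences on a 1% relative perturbation,
normalized to $S(t) = (\partial y/\partial p)(p/y)$. The baseline is floored
at `atol` before dividing; ranking treats summaries below 1e-6 as exact
zeros (integrator noise), and falls back to name order with a warning when
everything is zero. Forward sensitivity equations were deliberately
omitted: at this scale finite differences are accurate, and they stay
agnostic to the solver.

Conserved moieties are computed over the integer stoichiometry matrix with
exact fraction-free elimination (all arithmetic stays on integers), so the
left null space basis is free of floating-point rank decisions. Basis
vectors are reduced by their GCD and sign-normalized.

Rate-constant fitting optimizes log-parameters (positivity by construction)
with multi-start L-BFGS-B; start points are drawn log-uniformly inside the
bounds from a seeded stream. The parameter-recovery study in the acceptance
suite fits the input-clearance and ERK-dephosphorylation constants of the
MAPK motif from 50-point ppERK time courses with 5% multiplicative noise;
those two constants shape the pulse's duration and decay and are therefore
identifiable, unlike the near-saturated kinase constants, whose flat
likelihood makes them a poor recovery target. The study size (20 seeded
replicates, 3 starts each) was fixed before measuring the outcome.

## Expression statistics

The downstream stage implements the standard formulas of an RNA-seq
differential-expression analysis as small pure functions:

* `phred_q(E, base)` — $Q = -10 \log_b E$. The base defaults to 10 (the
  Phred standard, under which the Q20 filter threshold means a 1% error
  rate); a base-2 variant is also exposed explicitly, although it
  conflicts with the Q20 threshold convention.
* `filter_reads` — three independent discard rules: adapter contamination,
  more than 20% ambiguous bases, more than 50% of bases below Q20.
* `rpkm` — counts / (mapped reads in millions x exon length in kb).
* `bh_adjust` — Benjamini--Hochberg step-up, delegated to
  `stats::p.adjust(method = "BH")` and cross-checked in the tests against a
  naive quadratic step-up oracle.
* `call_degs` — BH across genes, then `q < 0.01` with the fold-change sign
  deciding direction. Differential-expression p-values are inputs: the
  package does not re-implement count-based DE testing, which third-party
  tools own.
* `hypergeom_enrichment` — one-sided upper-tail hypergeometric test per
  gene set (`stats::phyper`), BH across terms; the tests verify it against
  exhaustive enumeration of all draws for universes up to 20 genes.

## What the synthetic generators emulate — and what they do not

`synthetic_counts` draws negative-binomial counts (variance
$\mu + \mu^2 d$) around log-normal baseline means and plants a chosen
number of up/down-regulated genes at a chosen log2 fold change. Its default
of two samples per group mirrors a two-biological-replicate RNA-seq
design. Per-gene p-values come from the exact Wilcoxon rank-sum
test on library-size-normalized counts (normal approximation under ties).
Two consequences are worth stating plainly. First, an exact rank test on
2 vs 2 samples cannot produce a p-value below 1/3, so no gene can reach
q < 0.01 at the default design; power studies in the tests therefore raise
the group size to 10. Second, rank-test p-values are discrete, so "uniform
under the null" holds only in the conservative sense
$P(p \le \alpha) \le \alpha$; the calibration tests assert exactly that
bound rather than a continuous-uniformity statistic, which discreteness
would fail for reasons that carry no information about correctness.

`planted_enrichment` oversamples one designated term's members into the
gene list with a configurable weight; `random_network` and
`noisy_timecourse` provide seeded mass-action models and lognormal-noise
observables for the simulation and fitting stages. All generators are pure
functions of (parameters, seed), derive their stream from the seed plus a
generator label, and restore the caller's RNG state.

None of the generators emulate read-level artifacts (FASTQ qualities,
alignment ambiguity, batch effects) or real transcriptome correlation
structure. Passing the calibration and recovery tests therefore
demonstrates that the *statistics* are implemented correctly, not that the
pipeline's behavior on real sequencing data is validated.

## SBML exchange

Models are written as SBML Level 3 Version 1 (single dimensionless
compartment of size 1; explicit two-term mass-action kinetic laws with
local rate-constant parameters; assignment/rate rules as MathML), and read
back from Level 2 or 3. On import every kinetic law is verified to be pure
mass action by evaluating its MathML numerically at probe states and
solving for the two rate constants; any law that does not fit — a
Michaelis--Menten form, say — is rejected with a diagnostic naming the
reaction. Reversible reactions are kept as single two-term reactions rather
than split into irreversible pairs, the conventional presentation of
reversible mass-action kinetics.

## Known limitations

* The packaged network is a reconstruction: species naming, the exact
  complement of docking-site states, and all parameter values are this
  package's choices, constrained by the target structure counts and
  qualitative behavior rather than by quantitative measurements.
* The treated/untreated comparison and the sensitivity ranking are
  qualitative claims (direction and order), not quantitative fits; no
  axis values were available to fit against.
* Compartment volumes, stochastic kinetics, and spatial effects are out of
  scope; so are GO graph propagation and the internals of third-party DE
  callers.
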