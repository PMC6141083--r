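---
title: "Methods: methionine oxidation, folding free energies and forced unfolding"
author: "oxfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methionine oxidation, folding free energies and forced unfolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxfold)
```

## The scientific question

Methionine is the amino acid most easily attacked by oxidants such as
hypochlorite: a single oxygen adds to its sulphur, turning the apolar
thioether side chain into the markedly more hydrophilic methionine
sulfoxide.  In force-sensing proteins — the motivating system is the A2
domain of von Willebrand factor, which unfolds under the shear forces of
flowing blood — buried methionines sit inside hydrophobic packing, and
their oxidation can change both the *thermodynamic* stability of the
fold and the *mechanical* force needed to unfold it.

`oxfold` implements, at desk scale, the two analysis arms used to
quantify these effects:

1. **Thermodynamics.**  An alchemical transformation gradually converts
   methionine into methionine sulfoxide along a coupling parameter
   $\lambda \in [0, 1]$, once in the folded environment and once in an
   unfolded-state proxy (an Ala-Met-Ala tripeptide, fully solvent
   exposed).  A thermodynamic cycle turns the two alchemical legs into
   the change in folding free energy,
   $$\Delta\Delta G \;=\; \Delta G_{\mathrm{alch,folded}}
     \;-\; \Delta G_{\mathrm{alch,unfolded}},$$
   with the sign convention that a positive value means oxidation
   destabilizes the fold.
2. **Kinetics / mechanics.**  A constant-velocity pulling protocol
   attaches a virtual spring (stiffness $k$ = 2 kcal/mol/Å², velocity
   5 Å/ns) between the chain terminus and a dummy point, records the
   Hookean force $F = k\,\Delta x$, and identifies the rupture force of
   the event in which a C-terminal helix undocks and exposes a
   hydrophobic core: the force peak within a 400 ps window around the
   time the core's solvent accessible surface area (SASA) first exceeds
   50 Å², with both curves smoothed by 20 ps running averages.

All-atom solvated molecular dynamics is out of scope.  Every input the
pipeline needs is produced by seeded generators with machine-readable
ground truth, so each operator can be scored exactly, and the two
directional results — buried-site oxidation destabilizes while
exposed-site oxidation does not, and oxidized models rupture at lower
force — are reproduced on toy systems built for that purpose.

## Free-energy estimators

Per window $i$ of a schedule of $n$ states, the sampler records forward
energy differences $\Delta U^F = u(\lambda_{i+1}) - u(\lambda_i)$ at
state $\lambda_i$ and backward differences at $\lambda_{i+1}$.  The
default schedule mirrors the reference protocol shape: 100 states, 100
ps each (10 ns total), first half equilibration, second half
collection.  The backward pass starts from the final forward
configuration, the stated behavior of the forward/backward protocol
(`backwardStart = "independent"` is available as a diagnostic).

Two estimators are provided:

* **EXP (Zwanzig)**: $\Delta G = -k_BT \ln \langle e^{-\Delta U / k_BT}
  \rangle$, computed per window with an overflow-guarded
  log-mean-exp and summed.  It is one-directional and biased at poor
  overlap — high from the forward side, low from the backward side
  (the package folds the sign so both directions estimate the same
  forward $\Delta G$).  Its standard error comes from a block
  bootstrap (20 blocks, 200 replicates) within windows.
* **BAR (Bennett acceptance ratio)**: per window the self-consistent
  equation
  $$\sum_i f\!\big(\beta(\Delta U^F_i - C)\big) \;=\;
    \sum_j f\!\big(\beta(\Delta U^B_j + C)\big), \qquad
    f(x) = \frac{1}{1+e^{x}},$$
  with the $\ln(n_F/n_B)$ sample-count shift folded in, is solved by
  bracket expansion around the forward-EXP guess plus Brent refinement
  to $10^{-8}\,k_BT$; window estimates are summed and Bennett's
  asymptotic variances added in quadrature.

Correctness is checked against constructions with known answers:
delta-distributed work (every estimator must be exact), Crooks-Gaussian
work pairs (forward $\sim N(\Delta G + \sigma^2/2, \sigma^2)$, backward
$\sim N(-\Delta G + \sigma^2/2, \sigma^2)$ in $k_BT$ units, which
satisfy the Crooks fluctuation relation exactly), a harmonic stiffening
transformation with the closed form $\tfrac{1}{2} k_BT \ln(k_1/k_0)$,
and soft-core insertion systems scored by deterministic Boltzmann
quadrature in one dimension.

A caution that the tests encode only in expectation: with good overlap
($\sigma = 2\,k_BT$) and thousands of samples, the EXP biases
(~$10^{-2}\,k_BT$) are far smaller than the EXP sampling noise
(~$10^{-1}\,k_BT$), so on any single fixture the Bennett estimate need
*not* lie numerically between the two EXP estimates; the bracketing
inequality emerges only when estimates are averaged over many seeds.

### Error bars at two levels

The within-run BAR variance treats collection samples as independent;
the sampler therefore thins its Metropolis chain (default: 1 of every
10 steps recorded) so that this assumption is approximately honest.
The error bar to quote across repeated simulations is the
replicate-level SEM produced by the statistics layer, which is how
replicate averages (n = 3 in the reference protocol) are reported.

### Soft core

Van der Waals interactions of the appearing/disappearing atom use the
Beutler-style form implemented in `softcorePotential()` (default
$\alpha = 0.5$, applied to the van der Waals term only; electrostatics
scale linearly with $\lambda$).  The pad $\alpha(1-\lambda)$ keeps the
potential finite at $r = 0$ for every $\lambda < 1$, which is the whole
point: without it the first windows of an insertion diverge.  The
functional form and $\alpha$ are this package's documented choices; the
reference protocol names the technique but not its parameters.

### The buried/exposed contrast

The folded "buried site" toy places fixed neighbors 3.2 Å on either
side of a harmonically restrained particle, so coupling the soft-core
repulsion on costs several kcal/mol; the quadrature reference for the
default system is ≈ 5.6 kcal/mol, and the cycle against the
tripeptide-like leg is positive at many standard errors.  The "exposed
site" uses neighbors 30 Å away — the same local environment as the
tripeptide proxy, as is physically appropriate for a fully
solvent-exposed methionine — so its $\Delta\Delta G$ differs from zero
only by sampling noise and must sit within two combined standard
errors of zero.

## Structural metrics

**SASA** uses Shrake-Rupley sphere sampling with a deterministic
golden-section spiral point set (default 960 points/atom, probe 1.4 Å).
Determinism matters for regression tests; the quadrature agrees with a
10^5-point Monte-Carlo rejection oracle within 3% on random 20-atom
clusters and is rotation-invariant within 1% at the default density.
The probe radius and point density are package defaults — the
reference analysis names the quantity, not the algorithm.

**Hydrogen bonds** follow the geometric criteria used for hydration
analysis of sulfoxides: H···acceptor ≤ 2.7 Å and donor-H···acceptor
angle ≥ 120°, both boundaries inclusive (a documented convention; the
criteria are stated as cutoffs only).  Because plain PDB fixtures carry
no bond table, hydrogens attach to their donor heavy atom geometrically
(name starts with H, distance < 1.2 Å).  "Hydration" of a residue is
operationalized strictly as the fraction of frames with at least one
qualifying bond to the solvent group, in either donor/acceptor role.

**Interaction energies** between two atom groups sum switched Coulomb
($k_e = 332.0636$ kcal·Å/mol/e²) and Lennard-Jones terms (geometric-mean
well depths, arithmetic-mean minimum distances) with the C¹ switching
polynomial
$$S(r) = \frac{(r_{off}^2 - r^2)^2\,(r_{off}^2 + 2r^2 - 3 r_{on}^2)}
  {(r_{off}^2 - r_{on}^2)^3}$$
between 8 and 10 Å, the cutoff convention of the reference setup,
applied to both terms.

**Sulfoxide building** adds exactly one OD oxygen to the methionine
sulphur — mass spectrometry shows oxidants add a single oxygen, so the
sulfone is never built — at a fixed 1.50 Å S=O length along the
negative bisector of the CG–SD–CE angle, then resolves clashes by
scanning 24 rotations (15° grid) about the CG–SD axis and keeping the
lowest steric-overlap score (ties to the smallest angle).  This
geometric relief replaces force-field minimization deliberately: it is
reproducible, testable, and honors the constraint that all atoms
outside the mutated residue stay fixed.  The S=O geometry is a
documented stand-in, not a literature-derived parameter.

## The pulling model

The simulator integrates Langevin dynamics with the BAOAB splitting
(friction 1 ps⁻¹, 300 K, bead mass 100 amu).  With zero friction it
reduces to velocity Verlet and conserves energy to ~10⁻⁵ relative over
10⁵ steps at 2 fs; with the thermostat on, per-bead kinetic energy
equipartitions to $\tfrac32 k_BT$ within 5%.  The default 5 fs step is
comfortable: the stiffest mode (a 20 kcal/mol contact) has a ~240 fs
period.  The thermal noise stream is the only seed-dependent input, so
runs are exactly reproducible.

The toy domain is a 22-bead Gō-like chain: an 18-bead rigid "body"
(two 3×3 layers, serpentine connectivity, strong 12-10 native contacts
of 20 kcal/mol) whose top face carries a three-bead hydrophobic core,
and a 4-bead "C-terminal helix" docked over the core by weaker
oxidizable contacts (1.5 kcal/mol each).  Bead radius 2.2 Å and a
3.4 Å docking gap put the built core SASA near 27 Å² — safely under
the 50 Å² rupture threshold, with equilibrium fluctuations peaking in
the low 40s over nanoseconds — while helix release exposes ≈ 90 Å².
The stiff body is a deliberate design choice: with a soft body the
pulling tension stretches the whole chain and the core SASA creeps
over the threshold long before the helix releases, decoupling the
detector's crossing from the actual undocking event.

Oxidation multiplies the well depth of the oxidizable docking contacts
by `oxidationFactor`.  The comparison condition uses 0.7: hydration of
the sulfoxide-bearing interface weakens core packing by ~30%, enough
that the oxidized helix still docks (crossing times of 100–400 ps
under pulling) but releases at visibly lower force.  At matched seeds
the mean rupture force drops from roughly 230 pN to 140 pN and a
one-tailed Student t-test over 10 seeds per condition rejects equality
far below 0.05.  The factor is a model parameter, not a measured
quantity.

Rupture identification follows the documented rule exactly: smooth the
force and core-SASA series with 20 ps running averages, find the first
time the SASA exceeds 50 Å² and stays above for two consecutive
records (the persistence guard keeps single-record noise from
triggering), and report the highest smoothed force within a 400 ps
window *centered* on that crossing (the reference rule states the
window length but not its anchoring; centering is the symmetric
choice).  Ties take the earliest peak.  A trace whose SASA never
crosses the threshold yields a no-event result, not an error.

## Synthetic data and what passing tests mean

Each generator is a pure function of (spec, seed) and writes a
ground-truth sidecar: Crooks-Gaussian work samples with known
$\Delta G$; burial fixtures whose exposed/partial/buried sites are
verified against free-sphere SASA fractions (buried: a closed 3 Å
shell; partial: a 6 Å hemisphere leaving the site about half exposed);
an extended Ala-Met-Ala tripeptide whose central side chain retains
> 90% of its free SASA — a deliberately coarse bead model whose
side-chain column stands 5.5 Å off the backbone, because with covalent
geometry the Cβ–Cα contact alone forfeits about a third of the Cβ
sphere and caps the group near 70%; a
pulling fixture with a logistic SASA step (40 ps width, so the
persistence rule always engages) and a triangular force peak (30 ps
half-width) plus optional Gaussian noise; and hydrogen-bond frames
posing water probes at exact distances and angles.

The generators emulate statistical structure — work distributions
obeying the Crooks relation, rupture events with coupled SASA steps,
burial contrasts — not real solvent, force-field energetics, or the
actual A2 topology.  Passing tests therefore demonstrate that the
estimators, detectors and statistics are implemented correctly and
behave directionally as the real system does, not that they reproduce
any particular experimental number.

## Statistics layer

Replicate reporting is mean ± SEM (n−1 denominator).  Comparisons use a
one-tailed two-sample Student t-test with pooled variance (the stated
test for n = 3 force-peak comparisons; Welch is available behind a
flag since pooling is not stated explicitly), with the conventions
p = 0.5 for identical degenerate groups and 0/1 for separated
degenerate groups.  Tiers follow the reporting thresholds: p < 0.05
significant, 0.05 ≤ p < 0.10 marginally significant, else not
significant — boundaries half-open, a documented resolution of
ambiguous wording.  A 10⁴-trial null simulation holds the empirical
type-I error within [0.04, 0.06] at nominal 0.05.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 50 Crooks fixtures of
5000 samples/side; the full 100-state schedule for the harmonic system
(≈ 10⁴ Metropolis steps per direction, seconds of runtime) and a
40-state, 50 ps schedule for the site systems; 10 pulling seeds per
oxidation condition at 4 ns each; 100 noisy rupture fixtures; 10⁴
t-test null trials.  These sizes make every stochastic criterion
decisive (z-scores of the directional effects are ≫ 2) while keeping
the whole suite in the minutes range on one core.

Other numerical conventions: $k_B = 0.0019872041$ kcal/mol/K;
1 kcal/mol/Å = 69.4786 pN; Bennett tolerance $10^{-8} k_BT$; Metropolis
step sizes chosen for ~50% acceptance with a hard failure below 1%
acceptance; PDB coordinates carry the format's 3-decimal precision, and
serial/residue numbering is preserved exactly as read.

## Known limitations

* The alchemical toy systems are one-dimensional; they validate the
  estimators and the cycle, not conformational sampling.
* The within-run BAR error bar ignores residual autocorrelation beyond
  the thinning; replicate-level SEM is the robust error bar.
* The sulfoxide geometry (1.50 Å, bisector placement, 15° clash grid)
  is a stand-in; downstream energetics on built sulfoxides inherit it.
* The pulling model's forces live on the toy's energy scale; they are
  comparable between conditions, not calibrated to experimental pN
  values.
* Shrake-Rupley with a fixed lattice is deterministic but only
  approximately rotation-invariant (≤ 1% at 960 points).
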