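---
title: "Modelling multi-site palmitoylation of ZDHHC6: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multi-site palmitoylation of ZDHHC6: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmcycle)
```

## The system and the model

ZDHHC6, an ER palmitoyltransferase, is itself reversibly S-palmitoylated
on three cysteines of its SH3 domain (Cys-328, Cys-329, Cys-343) by the
upstream writer enzyme ZDHHC16, and depalmitoylated by the acyl protein
thioesterase APT2.  With three sites the folded protein populates
$2^3 = 8$ occupancy states, written `C000` (unmodified) through `C111`
(fully occupied) with the site order 328, 329, 343.  `palmcycle` models
this as an open reaction network:

* zero-order synthesis of an unfolded precursor `U` at rate `kSyn`
  (a.u. h^-1^);
* first-order folding `U -> C000` at `kFold` (h^-1^);
* one ZDHHC16-catalysed palmitoylation and one APT2-catalysed
  depalmitoylation per (state, site) pair — the edges of the occupancy
  hypercube;
* first-order degradation of every species, each state with its own
  constant `kd[state]` (the biological heart of the model: degradation is
  state-dependent, so palmitoylation reroutes protein turnover).

Cysteine-to-alanine mutants (`ACC`, `CAC`, `CCA`, `AAC`, `ACA`, `CAA`,
`AAA`; letter k codes site k) restrict the network to the surviving
sites; `applyMutant()` performs the restriction, and removing a site is
exactly equivalent to setting its palmitoylation `kcat` to zero in the
full network (a tested identity; see below).

### Enzymatic rate law

Writer and eraser concentrations are comparable to the substrate, so
Michaelis–Menten kinetics (which assume vanishing enzyme) are not valid.
Reactions instead use the total quasi-steady-state approximation (tQSSA)
with substrate competition.  For reaction $r$ of one enzyme family
(total enzyme $E_T$, per-site constants $k_{cat,r}$, $K_{m,r}$, substrate
pool $S_r$):

$$
v_r \;=\; \frac{k_{cat,r}\,E_T\,S_r}
{K_{m,r}\left(1 + \sum_{r' \neq r} S_{r'}/K_{m,r'}\right) + E_T + S_r}
$$

where the sum runs over every other substrate/site pairing served by the
same enzyme — all species with a free site compete for ZDHHC16, all
palmitoylated species for APT2.  The form reduces to Michaelis–Menten
when $E_T \ll K_m + S$ with no competitors, and is bounded by
$k_{cat} E_T$.  Kinetic constants are properties of the *site*, not of
the occupancy of the other sites; coupling between sites enters only
through the competition term and the per-state degradation constants.
Two conventions are worth making explicit:

* **Competition is enumerated per enzyme–substrate–site pairing.**  A
  species with two free sites appears twice in the writer's competition
  sum, once per addable site.
* **Reactions with `kcat = 0` are treated as absent**: they neither carry
  flux nor compete for enzyme.  This is what makes "site knockout =
  `kcat = 0`" exact; a dead site does not sequester the writer.

Because the exact algebra behind this closed form is a modelling choice,
it is pinned by behaviour rather than by transcription: the test suite
integrates an independent explicit-complex mass-action model (binding,
unbinding and catalysis as separate reactions, complexed substrate
degraded at its state's rate) on one- and two-site networks and requires
the tQSSA trajectories to agree within 5% in the regime where the
reduction is valid (fast binding equilibration, $E_T$ below
$K_m + S$ and of the order of the substrate totals).  The first-order
(Padé) closed form degrades when $E_T$ approaches $K_m + S$; this is a
property of the approximation, not of the implementation.

### Deterministic solution

`simulateNetwork()` integrates the stiff ODE with `deSolve::lsoda`
(rtol 1e-8, atol 1e-10).  `solveSteadyState()` finds stationary states by
long integration followed by damped-Newton polishing
(finite-difference Jacobian over the folded subsystem, `U` solved
exactly), to a residual below `1e-8 * kSyn`; the `"newton"` method tries
the polish first from a cheap heuristic with a staged loose-tolerance
integration fallback, which is what the calibration loop uses.  Mass
bookkeeping (d(total)/dt = synthesis − total degradation), species-wise
flux balance at steady state, and non-negativity are asserted as
invariants in the tests.

## In-silico labelling experiments

The calibration currency of the model is normalized labelling
time-courses, reproduced in silico on top of the deterministic model:

* **^35^S pulse-chase** (`simulatePulseChase35S`): the unlabelled system
  is brought to steady state; during the pulse (20 min by default,
  encoded exactly as 1/3 h) synthesis produces backbone-labelled
  protein without changing total synthesis; during the chase hot
  synthesis stops.  The hot cohort is co-integrated with the full
  system, its per-molecule rates evaluated on the total pools, and the
  signal is total hot protein normalized to 100% at the end of the
  pulse.
* **^3^H-palmitate incorporation and release** (`simulatePalmIncorporation`,
  `simulatePalmChase`): the label-resolved model refines each occupancy
  state by the label of every attached palmitate (empty/cold/hot, $3^m$
  states; `expandLabelStates()`), with palmitate in excess so every
  attachment during the pulse is hot.  Summing label states over label
  assignments reproduces the unlabelled model *exactly* (a tested
  identity, tolerance 1e-7), and the hot signal is monotone
  non-increasing during the chase.
* **PEGylation stoichiometry** (`simulatePegylation`): the steady-state
  distribution over palmitate counts 0..m.  The unfolded precursor `U`
  is excluded by default (gel assays detect the mature protein); an
  `includeUnfolded` flag adds it to the zero-palmitate bin, since
  published fraction statements are ambiguous about the denominator.

Because the labelling protocols start from, and do not displace, the
steady state, every labelled sub-population evolves under a linear
constant-coefficient system.  The package exploits this with
matrix-exponential solvers (internal fast path) that are exact at
stationary background and ~100x faster than re-integration; the
co-integrated ODE implementations remain the reference and the test
suite asserts agreement between the two routes.

`apparentHalfLife()` reports the first 50% crossing of a normalized
decay curve by linear interpolation, raising a typed error
(`palmcycle_no_halflife`) when the curve never crosses — the
*apparent* half-life of a cohort mixes the intrinsic state half-lives
`halfLife()` = ln(2)/kd and is generally very different from them.

## Calibration

`makeObjectives()` builds one objective per experiment (mean squared
residual on the percent scale, pulse time included in the simulation);
the default calibration partition mirrors the study design: ^35^S decay
for WT, ACC, CAA and AAA with both the 20-min and the 2-h pulse, the WT
^3^H incorporation course over the 2 h pulse, and ^3^H release for WT,
ACC and CAA; everything else (the cross-construct incorporation panel,
enzyme perturbation variants) is validation.  Both pulse lengths are
included because the long-pulse decay experiments proved pivotal for
parameter estimation, and because identifiability demands them: purely
normalized decay data admit a degenerate slow-folding solution family
in which hours-long maturation parks the labelled cohort in the
undegradable precursor and mimics slow degradation.  Long pulses
penalize that family but do not eliminate it; what eliminates it is a
biological prior on the folding rate — maturation and membrane
insertion of the protein complete within tens of minutes (it is mature
within the 20-min pulse), so the calibration space bounds `kFold` to
0.5–20 h^-1 by default (configurable in `palmParamSpace()`), while all
other rates range over 1e-4–1e2 and Km/enzyme totals over 1e-2–1e2.  A scalar WT-normalized
incorporation value would be identically 100% and carry no information,
which is why the calibration entry is the incorporation *time course*
normalized to its end-of-pulse value.

`runGA()` is an elitist nondominated-sorting genetic algorithm over the
23 free parameters (folding rate, eight state degradation constants,
per-site kcat/Km for writer and eraser, two enzyme totals) searched in
log10 space (the synthesis rate is fixed because normalized signals
carry no concentration scale; bounds as above).  Operators are simulated binary
crossover and polynomial mutation.  Within a Pareto rank, selection
uses by default the *aggregate* secondary criterion — the
min-max-normalized objective sum — rather than crowding distance:
with a dozen objectives that all vanish at the generating parameters,
almost every member of a population is mutually nondominated and
crowding alone provides no convergence pressure (a well-known
many-objective failure mode).  The aggregate key restores pressure
toward the common optimum while the nondominated sort still guarantees
a Pareto front as output; classic crowding is available via
`gaConfig(selection = "crowding")` for genuinely conflicting
objectives.  Runs are bit-reproducible given the seed.

`selectEnsemble()` ranks front members by the same normalized aggregate
and keeps the best k (deterministic ties by index; k = 152 reproduces
the published ensemble size from a 10,000-model population), and
`ensemblePredict()` simulates each member independently, reporting
pointwise mean, population standard deviation and first/third
quartiles, excluding failed members with an explicit warning.

At desk scale (population 200, 100 generations, three seeds — about
5 minutes per seed on one CPU) calibration on noise-free synthetic data
from the reference parameters reproduces every calibration curve
within 2% RMS and recovers `kd[C000]` within a factor of two: the AAA
decay series is a nearly single-exponential readout of that constant.
Most of the remaining 22 parameters are not individually identifiable
from a dozen normalized curves — the Pareto ensemble, not a point
estimate, is the calibration result.

## Steady-state and perturbation analysis

`reactionFluxes()` evaluates every reaction at steady state (per-species
balance < 1e-6 kSyn, synthesis = total degradation);
`speciesDistribution()` and `contentResponse()` report composition and
total mature content under the named scenarios: control, ZDHHC16
overexpression (fold unquantified experimentally; the package default
is 10, configurable), APT2 silencing (eraser set to zero) and APT2 at
10%.  "Content" excludes `U` by default, matching Western quantification
of the mature protein.

## Stochastic simulation and single-molecule tracking

`toMoleculeUnits()` rescales the model so the deterministic steady-state
total equals a target copy number (default 1600 molecules per cell):
concentrations, Km constants, enzyme totals and the zero-order synthesis
rate scale by \(\Omega\), first-order constants are untouched.
`simulateSSA()` is an exact Gillespie direct-method simulation with
tQSSA propensities on current counts; the tests require the mean of
1,000 runs to stay within three standard errors of the ODE solution at
five checkpoints, and the stationary law of a pure birth–death reduction
to pass a chi-square test against its Poisson limit.

`trackSingleMolecules()` follows individual molecules from synthesis to
degradation as a continuous-time Markov chain whose jump rates are the
per-molecule tQSSA rates frozen at the deterministic steady state
(mean-field background): at stationarity a single tagged molecule in a
large population sees effectively constant rates, and the chain is then
exactly solvable by absorbing-Markov algebra, which the tests use as an
independent oracle for passage counts.  Default 10,000 molecules
(tests use smaller batches for speed).  Per state the tracker reports
the mean number of passages per molecule, the median per-visit residence
time, and — because "cumulative median" admits more than one reading —
the median of the per-molecule *total* time in the state, computed over
the molecules that visit it.  `countTransitionEvents()` totals
palmitoylation/depalmitoylation events adjacent to a state or between a
pair of neighbouring states.

## Synthetic data and the reference parameter set

`generateDataset()` emulates the structure of the study's labelling
campaign (grids: 0–30 h for ^35^S chases, 0–8 h for ^3^H release,
five points inside the 2 h incorporation pulse) with multiplicative
Gaussian measurement noise (default 10% relative, three replicates —
published error bars report standard deviations but no magnitudes, and
10% is typical of quantified autoradiography).  Noise is applied to
every point including t = 0, i.e. curves are not renormalized after
noising, so replicate scatter directly reflects the nominal sigma.
`generateGroundTruth()` draws random parameter sets log-uniformly with
optional qualitative constraints reflecting the fitted regime:
degradation fastest for every Cys-328-occupied state, slowest for
C010/C011, and Cys-328 depalmitoylation faster than the other sites.

`referencePalmParams()` is the package's hand-curated synthetic ground
truth.  Published state half-lives are used exactly where stated
(C000 40 h, C100 5 h, C111 0.3 h, C001 18 h, C010 "beyond 100 h" set to
120 h); the remaining constants were chosen once, by scoring candidate
sets against the system-level behaviours the study reports, and then
frozen: a WT apparent ^35^S half-life near 16 h against ~40 h for AAA,
half the pulse-incorporated palmitate lost in about an hour, about
two-thirds of mature protein non-palmitoylated, Cys-328 cycling as the
dominant flux with a few passages through C100 per molecule lifetime,
and WT content markedly more robust than the single-site CAA mutant to
writer overexpression.

**A structural finding worth recording:** under site-independent
kinetics with this competitive tQSSA form and a fast-degrading C111
(t½ = 0.3 h), not all reported behaviours are jointly attainable.  The
multi-site robustness mechanism requires the doubly palmitoylated
Cys-328 states reached from the C010 "safe harbor" to be long-lived
(the reference sets t½(C110) = 38 h — still shorter-lived than C000, so
the degradation ordering holds, but barely) and Cys-343 palmitoylation
to be nearly inert; as a consequence the steady-state C011 abundance is
essentially zero, C100 carries a larger share of the steady state
(~20%) than the study's fitted ensemble suggests, and the
APT2-silencing/10% content responses are weaker than reported.  Reproducing those numbers exactly would require
the study's own optimized parameter sets (supplementary material not
redistributed with data); the package therefore treats them as
qualitative signatures, and its robustness claim — WT strictly less
sensitive than CAA to a 1→10 writer scaling under the constrained
degradation orderings — is the tested property.

## Numerical choices

* Canonical state order: lexicographic on the occupancy bits, `C000`
  first; reduced-network labels use one bit per active site.
* ODE: `lsoda`, rtol 1e-8 / atol 1e-10; state clamped at zero inside
  the right-hand side to guard against −1e-12-scale excursions.
* Steady state: Newton polish with damped line search, residual
  tolerance 1e-8·kSyn; integration fallback ladder (loose then strict
  tolerances) for ill-conditioned parameter draws.
* Matrix exponentials: `Matrix::expm`, with per-time-step caching keyed
  by step length.
* Degenerate inputs: all-zero degradation has no steady state — the
  labelling simulators then fall back to a long-integration background,
  and the single-molecule tracker refuses to run (molecules never
  absorb); `kd = 0` half-lives return `Inf` explicitly.
* GA member failures (steady-state non-convergence) score a large
  penalty rather than aborting the run; ensemble prediction excludes
  failing members with a warning.

## What the synthetic tests do and do not show

The generator reproduces the *design* of the labelling campaign —
protocols, grids, constructs, replicate structure, noise scale — from a
known ground truth, which is what makes parameter recovery and
round-trip tests meaningful.  It does not emulate systematic errors of
real quantified autoradiography (gel loading, antibody capture,
background subtraction, normalization drift between blots), inter-cell
heterogeneity, or enzyme-level regulation (ZDHHC16 and APT2 are constant
parameters, never dynamic species).  Passing recovery tests therefore
demonstrates the identifiability and correctness of the machinery under
the stated noise model, not that real data of this type would constrain
all 23 parameters.

## Problem sizes used by the test suite

Mass-action comparisons run two random draws on one- and two-site
networks over 25–30 h grids; SSA checks use 1,000 runs on the AAA and
CAA networks; single-molecule oracles use 4,000–10,000 molecules;
calibration recovery runs population 200 x 100 generations for three
seeds.  These sizes were chosen as the smallest at which the Monte-Carlo
tolerances (three standard errors) are meaningful.
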