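# palmcycle

Kinetic modelling of multi-site S-palmitoylation dynamics of the ER
palmitoyltransferase ZDHHC6.

ZDHHC6 carries three palmitoylatable cysteines (Cys-328, Cys-329,
Cys-343) written by the upstream enzyme ZDHHC16 and erased by the
thioesterase APT2. Because each of the 2^3 = 8 occupancy states
`C000` … `C111` (site order 328, 329, 343) degrades at its own rate,
palmitoylation reroutes protein turnover, and the three-site
architecture buffers the cellular ZDHHC6 content against fluctuations
in writer activity. `palmcycle` implements this system end to end for
modellers and quantitative cell biologists:

* an open synthesis → folding → palmitoylation-hypercube → degradation
  reaction network over all eight states and every cysteine-to-alanine
  mutant (`ACC` … `AAA`), with total quasi-steady-state (tQSSA)
  enzyme kinetics including substrate competition,

  v_r = kcat_r·E_T·S_r / ( Km_r·(1 + Σ_{r'≠r} S_{r'}/Km_{r'}) + E_T + S_r );

* in-silico radiolabelling: ³⁵S-Met/Cys pulse-chase, ³H-palmitate
  incorporation and release, and PEGylation stoichiometry, with exact
  label bookkeeping on the 3^m label-resolved state space;
* multi-objective genetic-algorithm calibration (NSGA-II-style
  nondominated sorting, log-space operators) returning Pareto
  ensembles with ensemble-level prediction bands;
* steady-state, flux, intrinsic half-life (ln 2 / kd) and perturbation
  analysis (writer overexpression, eraser silencing);
* exact Gillespie simulation in molecule-count units and
  single-molecule tracking (passage counts, residence times,
  transition-event censuses);
* a synthetic-data generator reproducing the structure of the
  calibration/validation labelling campaign from a known ground truth.

## Worked example

```r
library(palmcycle)

p <- referencePalmParams()          # synthetic reference parameter set

## steady-state composition of mature ZDHHC6 (percent)
x <- solveSteadyState(p)
round(100 * speciesDistribution(x), 1)
#> C000 C001 C010 C011 C100 C101 C110 C111
#> 67.4  0.0  8.2  0.0 21.3  0.0  3.1  0.0

## intrinsic state half-lives, ln(2)/kd (hours)
round(halfLife(p), 2)
#>  C000  C001  C010  C011  C100  C101  C110  C111
#>  40.0  18.0 120.0  60.0   5.0   1.6  38.0   0.3

## apparent turnover of newly synthesized protein (20-min 35S pulse)
tc <- simulatePulseChase35S(
  protocol("S35_pulse_chase", chaseTimes = seq(0, 48, 2)), p)
apparentHalfLife(tc)
#> [1] 16.1

## palmitate release after a 2-h 3H pulse
h3 <- simulatePalmChase(protocol("H3_chase", chaseTimes = seq(0, 8, 0.5)), p)
apparentHalfLife(h3)
#> [1] 1.13

## single-molecule view: how often does a molecule visit each state?
trackSingleMolecules(p, nMolecules = 2000, seed = 1)
#> TrajectoryStats over 2000 molecules
#>      passages median_visit_hr median_total_hr
#> U       1.000           0.236           0.236
#> C000    3.935           2.764          10.764
#> C010    0.573           2.343           7.620
#> C100    3.563           0.961           3.710
#> ...
```

The unmodified state dominates the steady state while each molecule
still cycles repeatedly through the short-lived Cys-328-palmitoylated
state `C100` — the reversible mark acts as a degradation timer rather
than a stable modification. The whole-population apparent half-life
(16 h) sits far below the intrinsic 40 h of `C000` because of those
excursions.

Calibration round-trip on synthetic data:

```r
df  <- generateDataset(p, noise = noiseModel(sigma = 0))   # noise-free
obj <- makeObjectives(df)                                  # 12 objectives
ens <- runGA(obj, gaConfig(popSize = 200, generations = 100, seed = 1))
best <- members(selectEnsemble(ens, 1))[[1]]
max(sqrt(obj$evalParams(best)))       # worst per-curve RMS, percent units
#> [1] 1.32
```

A command-line interface wrapping the same functions is installed at
`inst/cli/palmcycle` (subcommands `generate`, `calibrate`, `analyze`,
`simulate`, `track`; see `?cliDispatch`).

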