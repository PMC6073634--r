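---
title: "The GARD model: kinetics, composomes and compositional evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The GARD model: kinetics, composomes and compositional evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gardsim)
```

## The model

The graded autocatalysis replication domain (GARD) model describes a
molecular assembly — a micelle or small vesicle — exchanging amphiphilic
monomers with its environment. A repertoire of $N_G$ molecule types
$A_1, \ldots, A_{N_G}$ is available outside at concentrations $\rho_i$; the
assembly state is the compositional vector
$\mathbf{n} = (n_1, \ldots, n_{N_G})$ with total size $N = \sum_i n_i$.
Each exchange reaction is catalysed by the molecules already inside,
through the graded rate-enhancement matrix $\beta$: the factor

$$ C_i \;=\; 1 + \frac{1}{N}\sum_j \beta_{ij}\, n_j $$

multiplies both the entry propensity $k_i\,\rho_i\,N\,C_i$ and the exit
propensity $k_{-i}\,n_i\,C_i$. Because the same factor scales both
directions, catalysis changes only the *speed*, never the equilibrium
constant $K_i = k_i/k_{-i}$ — mutual catalysis is a purely kinetic agent,
and everything interesting in GARD is kinetic selection away from
equilibrium.

Reproduction is growth–fission: the assembly grows from $N_{MIN}$ to
$N_{MAX} = 2 N_{MIN}$, then splits at random into two halves
(multivariate hypergeometric), one of which is followed further ("trace
mode"). For some compositions — *composomes* — growth is homeostatic: the
composition vector keeps its direction while $N$ doubles, so fission
yields two progeny similar to the parent and to each other, and
compositional information is inherited.

## Stochastic engine

The dynamics is simulated with the exact Gillespie direct method over the
$2N_G$ entry/exit channels (plus $2N_G^2$ dimerization/cleavage channels
in the polymer extension). Exact SSA was chosen over approximate
tau-leaping because assemblies are small ($N \le$ a few hundred) and
because exactness gives sharp testability: every simulation is a pure
function of (state, parameters, seed), consuming exactly two uniform
deviates per event, and the single-step function `step_ssa()` reproduces
the compiled growth loop `grow_to_size()` event for event under a shared
seed. The catalytic loads $\sum_j \beta_{ij} n_j$ are updated
incrementally ($O(N_G)$ per event). Exits are disabled at $N = 1$, so an
assembly never empties; a stall guard (default $10^7$ steps per growth
phase) turns pathological parameter sets into explicit errors instead of
hangs.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| $\mu, \sigma$ | $-4, 4$ | mean and sd of $\ln\beta$ (lognormal) |
| $k_f$ | $10^{-2}$ | basal forward rate, 1/(concentration·time) |
| $k_b$ | $10^{-5}$ | basal backward rate, 1/time |
| $\rho_i$ | $10^{-2}$ | external concentration per type |
| $N_{MAX}$ | $N_G$ | fission size ($N_{MIN} = N_{MAX}/2$) |
| similarity threshold | 0.9 | composome membership (`detect_composomes`) |
| minimum run | 5 | generations per composome episode |

Time and concentration units are arbitrary: only products like
$k_f \rho_i$ and the ratio $K_i = k_f/k_b$ matter, and all results here
are reported as ratios, frequencies or counts per split. The lognormal
parameters are the historical GARD choice, motivated by receptor-affinity
statistics: most pairwise catalytic interactions are negligible and a few
are very strong. That heavy tail is essential — with a light-tailed
(normal) distribution of $\beta$ the model shows almost no compositional
inheritance. The composome similarity threshold (0.9) and minimum episode
length (5) are not printed anywhere authoritative; they are configuration
keys here, and the package's claims are insensitive across thresholds
0.8–0.95.

`similarity_H()` is the cosine (normalized dot product) between
compositional vectors — scale-free, so assemblies of different sizes
compare directly. An episode is a maximal run of generations whose
*pairwise* similarities all stay at or above the threshold (an
alternative running-centroid criterion is available via `mode =
"centroid"`); episodes cluster into *compotypes* greedily in time order,
which is deterministic and order-stable.

## What a typical run shows

```{r composomes}
beta <- sample_beta(100, mu = -4, sigma = 4, seed = 11)
params <- gard_params(beta, n_max = 100)
trace <- run_trace(params, 500, seed = 42)
episodes <- detect_composomes(trace, threshold = 0.9, min_len = 5)
nrow(episodes)
weighted.mean(episodes$n_mol, episodes$length) # restricted repertoire
```

A random assembly of 100 molecules over 100 types holds $63.4 \pm 3.1$
distinct types (`expected_repertoire(100, 100)`, the exact occupancy
moments). Composome episodes restrict this to a much smaller repertoire
(typically 15–35 types) with correspondingly lower Shannon entropy — the
local entropy decrease of a dissipative system that pays for its order
with the free energy of monomer accretion.

## The experiments

**Finite-supply equilibrium** (`run_to_equilibrium`): with fission off and
a finite external budget (shared per-type budgets, equal initial
allocations; entry decrements, exit restores), the assembly first shows
composome-like unequal molar fractions, then — because $C_i$ cancels from
detailed balance — relaxes to the equilibrium dictated by $K_i \rho_i$
alone: equal fractions when all $K_i$ and $\rho_i$ are equal. This is the
package's demonstration that composomes are out-of-equilibrium states.

**Depletion screen** (`depletion_screen`): for each compound, its row and
column of $\beta$ are zeroed (the matrix representation of removing the
compound from the environment; optionally $\rho_i = 0$ as well, which is
kinetically equivalent) and the trace growth rate (splits per unit
simulated time) is compared before and after. At the reduced scale run
here (100 matrices, $N_G = 30$, 200 generations; the original used 1000
matrices and 500 generations) the histogram of after/before ratios is
modal at 1 with a minority outside the 0.79–1.25 neutral band and both
diminished and enhanced tails — most single-compound environmental
changes are near neutral, a few matter, and a few *help*.

**Constant-population reactor** (`run_reactor`): a fixed population of
assemblies grows independently; the first to reach $N_{MAX}$ splits, both
progeny stay, and a uniformly random other assembly is removed (victim
selection is uniform — the original publications do not specify it).
Compotype frequencies are tracked against reference centroids built from
a long trace-mode pre-run of the same matrix (self-consistent labelling).
Takeovers — sustained changes of dominance — are detected by
`detect_takeover` and their rises fitted by `fit_logistic`
($f(t) = K/(1 + Ae^{-rt})$, Levenberg–Marquardt).

**Environment shift** (`run_shift_experiment`): at a chosen split count
the external concentrations are blended towards a minority compotype's
centroid, $\rho_i' = (1-w)\rho_i(0) + w\,\tilde n_i$ with $w = 0.1$. The
target composition is first rescaled to the total of $\rho(0)$ so counts
and concentrations share a unit and the total external concentration is
conserved (the original normalization is unstated; this is the
unit-consistent choice). The paired control continues from an identical
population and RNG snapshot, so the environmental cause of any
post-switch difference is isolated exactly.

**Error catastrophe** (`keq_sweep`): scaling $k_f$ down at fixed $k_b$
lowers $K_{eq}$ and raises the weight of highly mutated compositions;
composome persistence (fraction of generations inside episodes) falls
monotonically across a 10× downward sweep — a thermodynamic error
catastrophe, possible only because catalysis preserves $K_i$.

**Chiral GARD** (`build_chiral_beta`): each of $S$ scaffolds exists as D
and L enantiomers ($N_G = 2S$); physics cannot distinguish handedness, so
$\beta(i,j) = \beta(\sigma(i), \sigma(j))$ exactly under the antipode map
$\sigma$, with within- and cross-handedness blocks drawn independently
from the same lognormal (their relative structure is otherwise
unconstrained in the sources). In an exactly racemic environment,
small-number seeding noise plus mutual catalysis breaks the symmetry:
composome episodes with enantiomeric excess $ee \ge 0.5$ appear in a
minority of runs (an existence phenomenon, not the typical outcome), at
the published simulation scale $S = 100$, $N_{MAX} = 300$.

**Dimer P-GARD** (`run_pgard_trace`): catalysed dimerization and cleavage
are layered onto the basic dynamics. Catalytic enhancements are computed
on the fly from the monomer matrix as additive sub-site averages
(`dimer_gamma`): a monomer catalyst contributes
$(\beta(i,a)+\beta(j,a))/2$ to the dimerization of $(i,j)$, a dimer
catalyst $(a,b)$ contributes $(\beta(i,a)+\beta(j,b))/2$
(templating-like pairing). The published combinatorial algorithm is not
printed; this additive rule is the simplest faithful reading and is
isolated in a single function so alternatives can be swapped. Dimers are
endogenous (no entry/exit), $N$ counts monomer equivalents, and fission
partitions dimers as indivisible units — progeny sizes may differ by one
equivalent when an odd split is unavoidable. With zero dimer rates the
machinery reduces to basic GARD *exactly*, event for event under a shared
seed; with elevated dimer rates ($k_{dim} = k_{cleave} = 10^{-5}$, of the
order of $k_b$) sustained dimer takeovers (>10% of monomer equivalents in
dimers for ≥50 consecutive generations) appear readily.

## The synthetic-data generator

All tests run on data the package generates itself: lognormal matrices,
simulated traces, planted-composome composition matrices, and noisy
logistic series (`make_fixture`). The generator emulates the *model's*
world — well-stirred kinetics, a fixed repertoire, exact halving fission.
It does not emulate real lipid chemistry: no measured rate constants, no
spatial structure, vesicle geometry, or covalent chemistry beyond dimers.
Passing tests therefore certify the kinetic theory and its
implementation, not any laboratory system.

## Numerical choices and degenerate inputs

* Multiset counts (`n_compositions`) are computed exactly with a small
  base-$10^9$ big-integer arithmetic (the exact binomial recurrence
  multiplies and divides by machine integers only), since the counts
  overflow doubles near $N = N_G \approx 150$; log-scale values use
  `lchoose`.
* `canonical_composome` uses the dense eigendecomposition;
  Perron–Frobenius guarantees a simple positive leading eigenvector for
  strictly positive matrices. Post-cutoff matrices with zero rows warn;
  ties in the leading eigenvalue are an error, not a silent choice.
* `fit_logistic` detects exactly constant series and returns the
  degenerate solution $r = 0$ directly, because $K$ and $A$ are not
  jointly identifiable there; anything else that fails to converge is an
  error, never a silent result.
* The cutoff scale of `apply_cutoff` is mean-normalized
  ($\beta_{ij}/\bar\beta$), the simplest scale-free normalization; the
  original normalization is not printed. The operation is idempotent.
* Takeover detection requires *strict* dominance through a window on each
  side of a crossing, so tied series never report a takeover.
* One root seed derives independent sub-streams for screen matrices,
  traces and sweep replicates, so paired arms (control vs shifted,
  before vs after depletion) stay comparable and null experiments
  reproduce controls bit for bit.

## Problem sizes

The shipped tests and the acceptance script use reduced but
behaviour-preserving scales, chosen as the package's own defaults: 500
generations and 20 matrices for composome statistics, 100 matrices
× $N_G = 30$ for the depletion screen, populations of 30 assemblies for
600 splits in reactor experiments, $3\times10^5$ SSA steps for the
equilibrium relaxation, and 10 runs of 500 generations for the chiral
existence check. The compiled core simulates roughly $10^6$ growth–split
generations per minute at $N_G = 100$ on one CPU, so all of these
complete in about a minute; the original publications' larger scales
(1000 matrices, populations of 1000) are reachable by changing the
corresponding arguments.

## Known limitations

* The restricted composome repertoire reproduces the published
  *direction* (far below the random 63.4) but not the exact published
  $15.9 \pm 5.5$, whose generating parameters are not printed; measured
  values here are typically 20–35.
* Reference compotypes come from a single pre-run trace; rare compotypes
  that never appear in the pre-run are counted as drift in reactor
  frequencies.
* The raw parent–progeny cosine is not comparable across repertoire
  sizes (dense low-$N_G$ compositions have a high similarity floor);
  inheritance comparisons across $N_G$ use similarity in excess of the
  run's own distant-pair baseline.
* Only dimers, not longer oligomers; no inner/outer universe exchange; no
  real-lipid parameterization.
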