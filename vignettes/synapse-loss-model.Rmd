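---
title: "Modeling network degeneration from progressive synapse loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling network degeneration from progressive synapse loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodecay)
```

## The model and its assumptions

`neurodecay` models a population of neurons as a directed, weighted
small-world network and asks how the network-level capacity for signal
transmission degrades as synapses are progressively lost. The model makes
four structural assumptions:

1. **Topology.** Neuronal networks are small-world: high local clustering
   with short global paths. The generator is a directed Watts–Strogatz
   construction — a ring lattice in which node *i* sends links to its
   `k_out` clockwise neighbours, with each link's head rewired with
   probability `rewire_prob` (self-loops and duplicates rejected). The edge
   count is exactly `n * k_out`.
2. **Decay process.** Disease progression is a two-stage stochastic process
   on links. A healthy link is *affected* on day *t* with probability
   `p(t) = p0 + p1 * t`: `p0` sets the initial spread of synapse loss, and
   the slow ramp `p1` captures progressive worsening, netting out loss
   against repair/regeneration (which is why repair is not modelled as a
   separate process). Once affected at day `t_a`, a link's coupling strength
   decays exponentially, `eps = eps0 * exp(-(t - t_a)/tau)`.
3. **Removal.** A link whose strength has fallen to `1/e` of its initial
   value is non-functional and removed. With daily steps and integer `tau`
   this happens exactly `tau` days after affection; decayed-but-functional
   links still carry signal, at higher path weight `1/eps`.
4. **Readout.** Connectivity is summarised by the fractional size `f` of the
   largest strongly connected component (the order parameter of the
   breakdown) and by weighted global efficiency (the mean best-path
   efficiency `1/w_ij` over ordered node pairs, zero for unreachable pairs —
   a convention chosen so GE falls to 0 as the network disintegrates).

## Parameters, units, defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `n`, `k_out` | nodes, out-degree | 10^4, 10 | 10^4 neurons with 10^5 synapses, the scale the model targets |
| `rewire_prob` | head-rewiring probability | 0.1758 | calibrated once (bisection, `calibrate_rewire_prob()`) so clustering is 0.4 at the default size; path length then comes out near 5.3 |
| `p0` | initial affection probability/day | 0.01 | mouse-culture scenario; 0.1 models a much wider initial spread |
| `p1` | daily increment of p | 1e-4 | slow progressive worsening |
| `tau` | decay timescale, days | 30 | spine density halves in 3 weeks: `calibrate_tau(0.5, 21)` = 21/ln 2 ≈ 30.3; the 20–40 day band brackets biological variability |
| `dt` | step, days | 1 | one step is one day in the mouse scenario; for region-level (human connectome) runs steps are abstract and any step-to-calendar mapping is the user's |
| `horizon` | last simulated day | 250 | past complete breakdown for the defaults |
| `metric_cadence` | days between expensive metrics | 5 | all-pairs shortest paths dominate cost; the curves are smooth |
| `removal_fraction` | removal threshold as fraction of eps0 | 1/e | the model's definition; 0 disables removal (useful for closed-form checks) |

The comparison `eps <= eps0/e` (not `<`) makes the removal day exactly
`t_a + tau` for integer `tau`; strengths are always recomputed from `eps0`
and the elapsed time rather than by repeated multiplication, so there is no
floating-point drift and the crossing is exact.

Initial strengths: `identical` (all 1 — strengths are then interpreted
relative to each synapse's own healthy state), truncated `normal`
(mean 0.7, sd 0.2 in the non-uniform scenario; redrawn until inside (0, 1],
which keeps the distribution shape with minimal distortion), and
`lognormal` (parameters read as the underlying normal's mean/sd, rescaled
into (0, 1) by division by the realised maximum — the simplest mapping onto
the required support; after rescaling, the alternative reading of the
parameters changes only the shape, not the support).

## Critical-time estimation

Near breakdown the order parameter is fitted with a power law
`f = a * (Tc - T)^beta` for `T < Tc`. The fit is a grid search: candidate
`Tc` on integer days around the observed breakdown day, candidate `beta` in
{0.5, 1, 1.5, 2} (1 always included), selecting the pair with maximum R²
of the through-origin linear regression of `f` on `(Tc - T)^beta`.

Numerical choices worth stating:

- A fitted **prefactor** `a` is required — a pure power law cannot match
  the scale of `f` — and the regression must pass through the origin:
  with an intercept, every `Tc` gives the same R² at `beta = 1` and the
  problem is ill-posed.
- R² is computed against the window mean and clamped to [0, 1]; the selected
  candidate's R² is by construction the grid maximum.
- The default **fit window** keeps points with `0.01 <= f <= 0.3`, the
  near-critical region; it is exposed as an argument. Fits are intended for
  ensemble-mean traces.
- `extrapolate_tc()` regresses the per-size `Tc` on `1/N`; the intercept is
  the infinite-size critical time. (The slope is reported but has no
  theoretical identification with `beta`; `beta` comes from the power-law
  fit.)

On this simulator the R²-maximizing exponent at the default window is
typically 1.5 rather than the undirected mean-field value 1. That is not a
fitting artifact: the strongly connected component of a *directed* network
requires both an in- and an out-giant component, whose product gives a
steeper order parameter near threshold (asymptotic mean-field exponent 2),
so an effective exponent between 1 and 2 over a finite window is expected.
Fixing `beta = 1` (pass `beta_grid = 1`) reproduces the classical
undirected-style analysis; both choices give `Tc` within a couple of days
of each other.

## Ensembles, seeds, problem sizes

`run_ensemble()` derives independent per-realization seeds for network
generation, weight assignment and the decay process from one `base_seed`
(three streams drawn from a generator seeded with `base_seed`), so any run
is exactly reproducible and realizations are independent. Traces are
averaged pointwise on the common day grid; a run stops early only when no
functional edge remains, after which every recorded quantity is constant, so
early-stopped traces are padded with their exact continuation.

The packaged analyses use ensembles of 20 realizations at sizes up to
N = 10^4 and 10 realizations for the onset-day metric pass — sizes chosen as
the smallest at which the ensemble means are visibly stable (100-realization
averages are customary for such curves, but the dispersion of `f` at
N = 10^4 is already below a percent, so the mean changes negligibly
beyond ~20).

Weighted shortest-path metrics (global efficiency, weighted path length,
efficiency histograms) are exact up to 2000 nodes and estimated above that
from 500 sampled source nodes (Dijkstra from each source to all targets).
Sampling sources gives an unbiased estimate of any mean over ordered pairs;
sources are drawn with a seed fixed by the network size, so repeated
evaluations are comparable. `n_sources = Inf` forces the exact computation.

## The connectome-like fixture

`generate_connectome_fixture()` is a *synthetic* stand-in for a mesoscale
human connectome (it ships in place of subject-derived data, which the
package deliberately does not include): 360 nodes, 43,516 directed weighted
edges — extremely dense (mean degree ≈ 121), with edges sampled without
replacement under an exponential ring-distance kernel plus a uniform floor,
giving clustering far above the uniform-random expectation and very short
paths. With the region-level parameters (p0 = 0.004, p1 = 1e-6, tau = 40,
abstract steps) it reproduces the qualitative connectome behaviour: the LSCC
is extremely robust for a long initial period (massive path redundancy),
then deteriorates rapidly past a critical time, while normalized global
efficiency declines in two regimes — a shallow slope while paths merely
lengthen, then a steep one once disconnection dominates. Quantitative
year-scale statements require a real connectome and a step-to-calendar
mapping, both outside the package's scope.

## What the generators do and do not emulate

The synthetic networks match the reference conditions in edge count,
clustering, path length, density and weight distributions. They do not
reproduce neuron morphology, spatial embedding beyond ring locality, degree
correlations, reciprocity structure, or multi-scale modularity of real
cortical tissue; passing tests therefore validate the *model dynamics and
estimators*, not claims about any particular biological network.

## Known limitations and open choices

- **Breakdown timing.** With the stated parameters the ensemble-mean LSCC
  collapses steeply over days ~140–160 (f ≈ 0.005 at day 160) but only
  reaches the strict `2/N` floor around day 170; per-size fitted `Tc` is
  159–162 and the infinite-size extrapolation lands near 160 days. The
  qualitative knee-then-collapse shape and the ~10% drop at day 120 are
  robust; the exact day a "vanished" LSCC is declared depends strongly on
  the threshold convention.
- **Onset markers.** The first day the ensemble-mean `f` reaches 0.9 falls
  near day 118, by which time ~70% of links are removed; clustering and
  path-length changes at that marker are correspondingly large (CC down
  ~70%, weighted path length ~14). Markers placed earlier in the process
  give much milder values; the package computes the metrics at any day,
  leaving the choice of marker to the analyst.
- **Average path length** is taken over all reachable ordered pairs by
  default; an LSCC-restricted variant is available (`scope = "lscc"`).
  The two agree on healthy networks and diverge during disintegration.
- **Histogram bins** are half-open `[lo, hi)` with the final bin closed,
  default width 0.05.
- Betweenness/centrality measures, community structure, neuron-level firing
  dynamics, activity-dependent plasticity and explicit repair processes are
  out of scope.
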