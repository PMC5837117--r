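---
title: "The IICR under structured demography: model, conventions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The IICR under structured demography: model, conventions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iicr)
```

## The quantity

For a sample of two haploid genomes with coalescence time $T_2$, the
inverse instantaneous coalescence rate is

$$\mathrm{IICR}(t) \;=\; \frac{\mathbb{P}(T_2 > t)}{f_{T_2}(t)},$$

the reciprocal of the hazard rate of $T_2$. In a panmictic Wright–Fisher
population the pair coalesces at rate $1/N(t)$, so the IICR *is* the
population size trajectory; this identity is what PSMC-style methods
exploit. Under population structure the hazard depends on where the two
lineages currently sit, and the IICR becomes a time-dependent curve even
when every deme size and migration rate is constant. The curve also depends
on the sampling scheme — two genes from the same deme (written $IICR_s$)
versus from different demes ($IICR_d$) — which no single-number effective
size can express. The package therefore treats the IICR as what it is: a
summary of the model *and* the sample, useful for predicting what PSMC
would infer under a candidate demography and for excluding demographies
whose curves are incompatible with an observed one.

## The model class and its conventions

A `demographic_model` is an ordered list of epochs, each a set of demes
with relative haploid sizes $s_i$ and a migration matrix, plus a reference
size $N_{\mathrm{ref}}$. All computations use the coalescent scaling:

* **time** is counted in units of $N_{\mathrm{ref}}$ generations;
* **coalescence**: two lineages in deme $i$ coalesce at rate $1/s_i$;
* **migration**: `migration[i, j]` is the scaled rate $M_{ij} = 2 N m_{ij}$
  at which deme $i$ receives genes from deme $j$; an ancestral lineage in
  deme $i$ therefore jumps to deme $j$ at rate $M_{ij}/2$.

This is the unique scaling under which the lumped two-state chain of the
symmetric n-island model has smallest eigenvalue

$$\beta = \tfrac12\Big(1 + \tfrac{n}{n-1}M -
  \sqrt{(1 + \tfrac{n}{n-1}M)^2 - \tfrac{4M}{n-1}}\Big),$$

so that the ancient plateau of $IICR_s$ is exactly $N/\beta$; the test
suite pins the package's generator to this formula and, independently, to a
coalescent simulation cross-check. The factor $1/2$ on per-lineage jumps is
easy to get wrong by a factor of two; the $\beta$ identity is what fixes it
unambiguously.

Between epochs, deme counts and identities may change through a *remap*
applied instantaneously at the epoch boundary (backward in time): lineage
locations are pushed through a map, with an optional per-deme probability
$p < 1$ for admixture pulses (the lineage stays put with probability
$1-p$). A population split is the deterministic special case — all derived
demes map to one ancestral deme — which is how `add_population_split`
represents a forward-time split backward in time.

## Exact curves: the phase-type route

Conditional on the locations of the two uncoalesced lineages, the
structured coalescent for a pair is a continuous-time Markov chain over the
unordered deme pairs $\{i, j\}$ plus one absorbing (coalesced) state —
$n(n+1)/2 + 1$ states for $n$ demes, exact because the lineages are
exchangeable. $T_2$ is the absorption time: a phase-type distribution,
piecewise across epochs. `survival_and_density` propagates the initial
pair-location distribution with per-epoch matrix exponentials, applying
remaps at boundaries (as a transition matrix on pair states, the two
lineages moving independently), and reads off

* $S(t) = \mathbb{P}(T_2 > t)$: the transient mass, and
* $f(t)$: the absorption flux, transient mass times per-state coalescence
  rates.

**Numerics.** Each epoch's transient generator is eigendecomposed once;
survival and density on a whole grid are then two small matrix products,
which is what makes $10^5$-point evaluations (for Kolmogorov–Smirnov tests
against simulations) cheap. Because asymmetric migration makes the
generator non-normal, the decomposition is accepted only if it reconstructs
the generator to a relative $10^{-9}$; otherwise the code falls back to
Padé-based matrix exponentials (`Matrix::expm`) per time point. Complex
eigenvalue pairs are handled by taking real parts at the end. At $t = 0$
the survival and density are evaluated directly from the entering
distribution so that the different-deme density is exactly zero, and
`exact_iicr` reports the analytic limits: the local deme size $s_i$ for
same-deme sampling, $+\infty$ for different-deme sampling. Epoch boundaries
are left-continuous: a boundary time evaluates under the epoch it closes.

Models in which coalescence is not certain (fully disconnected demes with a
cross-deme sample) are refused by default; `allow_infinite = TRUE` accepts
them and documents the curve as conditional, with interior zero-density
points recorded as $+\infty$ under a warning.

For the n-island family the chain lumps into two transient states (same
deme / different demes) and `nisland_iicr_closed_form` evaluates the
resulting two-exponential expression with analytically computed
eigenvalues $-\alpha, -\beta$ (with $\alpha\beta = M/(n-1)$ and
$\alpha + \beta = 1 + nM/(n-1)$; $\alpha$ is simply the companion root of
the same quadratic). Closed form and matrix route agree to $\le 10^{-10}$
relative on 64-point log grids across $n \in \{2,5,10\}$,
$M \in \{0.1,1,10\}$ — a genuine dual-route check, since neither shares
code with the other.

## Preset families and the choices behind them

Some published model families leave details open; the package fixes them
as follows, exposing each choice as a flag rather than a hidden constant.

* **Stepping stones** (`make_stepping_stone`): nearest-neighbour exchange
  on a line or grid, row-major indexing. The lattice is **bounded by
  default** — edge and corner demes genuinely have fewer neighbours, which
  is what makes edge versus central sampling informative; `circular = TRUE`
  gives the ring/torus. Rates default to **total emigration $M$ per deme,
  split equally over its neighbours**, so immigrant counts are comparable
  with an n-island model of the same $M$ (the comparison the curves are
  used for); `rate_mode = "per_link"` puts $M$ on every edge instead. With
  two demes both conventions collapse onto the two-island model.
* **Continent–island** (`make_continent_island`): deme 1 is the continent,
  `size_ratio` times the island. Default exchange is **conservative** —
  island immigration $M$, continent immigration $M/\mathrm{ratio}$, so both
  directions carry the same expected number of migrant genes per
  generation; `symmetric = TRUE` sets both scaled rates to $M$.
* **Splits** (`add_population_split`): persisting demes keep their mutual
  migration and exchange at `ancestral_M` with the new ancestral deme
  (appended last); with no persisting demes the ancestor is panmictic.
  Degenerate splits at $T \to 0^+$ reduce exactly to the ancestral model.
* Asymmetric-gene-flow models have no dedicated builder: a three-island
  model with six unequal rates is ambiguous to parameterise by shortcut, so
  `make_custom_model` takes the explicit matrix.

## The simulator

`simulate_t2` draws i.i.d. $T_2$ values by exact stochastic simulation of
the same pair chain — exponential waits at the current state's total rate,
categorical jumps, remap sampling at boundaries. A waiting time that would
cross an epoch boundary is discarded and the state held to the boundary
(truncate-and-resample), which is exact for piecewise-constant rates by the
memoryless property; thinning would be needed only for time-varying rates
within an epoch, which the model class excludes. The implementation is
vectorised over replicates grouped by state, so $10^6$ draws take seconds.
Everything is driven by one integer seed; identical inputs give
bit-identical samples.

The simulator is also the package's synthetic-data generator: it produces
exactly the $T_2$ batches the estimator consumes, under the study
conditions used throughout ($10^6$ replicates for estimator-fidelity
claims, $10^5$ for distributional tests — the replicate counts at which the
quoted tolerances hold). What it deliberately does **not** emulate is
sequence data: no recombination, no mutation, no along-genome correlation
of coalescence times. Passing tests therefore validate the estimator fed
with ideal independent draws; they say nothing about the additional noise
and bias a PSMC-style inference from one genome adds on top.

`emit_ms_command` prints an equivalent Hudson's-ms command for external
cross-validation. ms counts time in $4N_0$ generations and migration as
$4N_0 m$; identifying $N_{\mathrm{ref}} = 2N_0$ carries relative sizes and
$M$-entries over unchanged and halves times. The scaling behind this
identification is validated in development against an independent
coalescent simulator; the emitted string is also checked structurally
(`-I`/`-ej`/`-en` placement and converted times). Probabilistic remaps are
refused rather than approximated.

## The estimator

Given draws $t^{(1)}, \dots, t^{(R)}$ and a grid of bin edges
$t_1 < \dots < t_k$, `estimate_iicr` forms the empirical survival
$1 - \widehat F$ and a histogram density
$\widehat f_i = (\widehat F(t_{i+1}) - \widehat F(t_i)) / (t_{i+1} - t_i)$,
and reports $\widehat{\mathrm{IICR}} = (1 - \widehat F(m_i)) / \widehat f_i$
at the **geometric bin midpoint** $m_i = \sqrt{t_i t_{i+1}}$. The midpoint
attribution matters: a histogram density is the bin-average of $f$, and
attributing it to the left edge incurs a first-order bias of roughly half
the bin's log-width times the local decay rate — at the elbow of an IICR
curve, where $f$ falls at rate $\alpha \approx 1 + M$, this reaches tens of
percent on a 64-bin log grid and cannot be removed by refining the grid
without starving the bins. Midpoint attribution cancels the first-order
term, leaving second-order bias plus multinomial noise; under the
$10^6$-draw n-island experiment the worst bin error drops from ~45% to
3–6%. Kernel smoothing was deliberately left out: the histogram keeps the
bias structure transparent and the estimator free of bandwidth choices.

Empty bins yield `NA`, flagged rather than fatal, and per-bin counts are
returned; accuracy statements are restricted by convention to bins holding
at least 100 draws (a package convention for reporting, not a property of
the estimator). The defaults — 64 log-spaced points on $[10^{-3}, 10^2]$
coalescent time units — cover the dynamics of every preset family here;
the estimator-fidelity tests use $[10^{-2}, 10^2]$ so that the first bins
of a $10^6$-draw sample are themselves well populated.

## Comparing curves, scaling, units

`compare_curves` interpolates two curves (log–log linearly) onto a common
log grid over their overlapping range and returns the mean absolute
difference of $\log \mathrm{IICR}$ — symmetric, zero iff equal on the
grid, and scale-aware in the way that matters for curves spanning orders
of magnitude (a doubled curve is $\log 2$ away everywhere). As a
model-exclusion statistic: the exact 10-island curve above sits at
distance ≈ 2.9 from the flat line at its own Nei–Takahata $N_e$, while
estimator runs of the true model land within a few hundredths of the exact
curve.

`scale_curve` moves between coalescent units, generations and years by
multiplying times with $N_{\mathrm{ref}}$ (and the generation time) and
sizes with $N_{\mathrm{ref}}$; it is exactly invertible, and a diploid flag
divides sizes by two with explicit labelling. Default constants
($N_{\mathrm{ref}} = 500$, 25 years per generation, $\mu = 2.5 \times
10^{-8}$ carried as metadata) are the conventional humanised scaling for
eyeballing against published PSMC plots; they affect labels, never shapes.

## Problem sizes and limitations

The shipped tests run the full acceptance battery — nine closed-form/matrix
comparisons, five $10^5$-replicate KS tests, one $10^6$-replicate estimator
experiment, and the structural property checks — in well under a minute;
these sizes were chosen as the smallest at which the quoted tolerances are
comfortably stable across seeds.

Known limitations: samples of size two only (no $T_k$ for $k > 2$); no
likelihood or ABC-style parameter inference; no sequence-level simulation,
so nothing here *estimates* an IICR from a genome — the package predicts
curves for models and compares curves, which is the model-exclusion side of
that workflow. Continuous-space models and selection are out of scope, and
per-generation (unscaled) parameterisations must be converted to the
$M = 2Nm$ convention before entry.
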