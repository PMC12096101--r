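---
title: "The swidden labour-exchange model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The swidden labour-exchange model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swidden)
```

## The system being modelled

Swidden ("slash-and-burn") agriculture couples a social system to an
ecological one. A village of $N$ households cultivates a community
forest, represented as an $L \times L$ lattice of cells that are either
forested or empty. Each round (a cultivation season) every household
states a clearing request $x_i$ — the number of forest cells it wants
to convert to fields — and households decide whether to lend each
other clearing labour. Work parties determine harvests; cleared cells
later regenerate at a rate that depends on the surrounding forest.
There is no central regulator: whatever restraint emerges must come
from the households' own helping decisions.

Two social forces drive those decisions:

* **Direct reciprocity.** Household $i$ keeps an exponentially
  weighted memory $h_{j,i} \in [0,1]$ of help received from $j$ and is
  more inclined to return it.
* **Normative reasoning (sanctioning).** Household $i$ holds an
  acceptability threshold $y_i$: requests larger than $y_i$ are judged
  excessive and are refused on principle. Withholding labour from
  over-requesters is a graduated sanction — the community's only
  enforcement device.

The probability that $i$ helps $j$ mixes the two with weight $\mu$:

$$q_{i,j} \;=\; (1-\mu)\,h_{j,i} \;+\; \mu\,\mathbb{1}\{x_j \le y_i\}.$$

After each round the memory updates as
$h'_{i,j} = (1-\alpha)h_{i,j} + \alpha\,\mathbb{1}\{i \text{ helped } j\}$.

## Harvests, costs and payoffs

A household alone clears at most $h$ cells; each helper adds another
$h$. With $N_i^+$ helpers the harvest is

$$x_{a,i} = \min\{x_i,\; h(1+N_i^+),\; \lfloor \mathrm{forest}/N \rfloor\},$$

the last term being the common-pool cap: no household may clear more
than an $N$-th of the standing forest. Participating in $j$'s clearing
costs $c_0\mathbb{1}\{i \ne j\} + c\,x_{a,j}/(h(1+N_j^+))$ — a fixed
cost for helping someone else plus a variable cost that reaches $c$
when the party works at full capacity. The payoff is harvest minus
total costs, $\pi_i = x_{a,i} - C_i$.

## Strategy revision

Each round, independently per household:

* With probability $\nu_0$ the clearing request is revised by **myopic
  best response**: the household forms the belief
  $\tilde N_i^+(x) = \sum_{j \ne i} \big[(1-\mu_j)h_{i,j} + \mu_j
  \mathbb{1}\{x \le y_j\}\big]$ — the expected number of helpers a
  request $x$ would attract, given others' current thresholds and the
  reciprocity they owe — and picks the integer
  $x \in \{0,\dots,\lfloor \mathrm{forest}/N\rfloor\}$ maximizing the
  expected own-clearing payoff
  $m(x) - c\,m(x)/(h(1+\tilde N_i^+(x)))$ with
  $m(x)=\min\{x, h(1+\tilde N_i^+(x))\}$. Ties break to the smallest
  maximizer. Helping-others costs are excluded: they do not depend on
  one's own request.
* With probability $\nu_1$ the threshold is revised by **logit
  payoff-based imitation**: $y_j$ is copied with probability
  $\propto e^{\lambda \pi_j}$ (previous-round payoffs, self included).
* With probability $\nu_2$ the threshold is **innovated**: a Gaussian
  step with s.d. `innov_sd` (default 0.5 cells) is added, clamped to
  $[0, hN]$.

All revisions are simultaneous and evaluate against the previous
round's state. Round 1 has no payoffs yet, so threshold revision is
skipped there; request revision proceeds against the blank history.

## Forest dynamics

An empty cell regenerates with a probability that is piecewise linear
in the fraction $f_k$ of its neighbouring cells occupied by trees:
rising from $p_0$ at $f_k = 0$ to $p_{\max}$ at $f_k = F$, then
falling to $p_1$ at $f_k = 1$. $F \approx 0.5$ makes recruitment best
at intermediate local density (competition for light and resources);
$F$ near 1 approximates logistic growth. Updates are synchronous: all
regeneration draws in a round use the pre-update grid.

Three optional stressors: a revegetation **time lag** $l$ (a newly
emptied cell is ineligible for regeneration for $l$ rounds), external
**shocks** (with probability $p_{sh}$ per round from `shock_start`
onwards, $\mathrm{round}(f_{sh} L^2)$ forest cells are destroyed, or
the whole forest if fewer remain), and **heterogeneous** normative
weights $\mu_i \sim \mathcal N(\mu, \sigma_\mu)$ clipped to $[0,1]$.

## Round order

Each round executes: (1) strategy revision; (2) helping decisions;
(3) harvests, capped by the round-start forest count; (4) clearing of
harvested cells (uniformly chosen, the model has no household
locations); (5) costs and payoffs; (6) history update;
(7) regeneration; (8) shock, if enabled; (9) recording, with $f$ taken
at the end of the round so it reflects any shock. The integer identity
$\mathrm{forest}_{t} = \mathrm{forest}_{t-1} - \sum_i x_{a,i} +
\Delta f^+_t - \mathrm{shock\ losses}_t$ holds exactly every round and
is asserted in the test suite.

## Default parameters

`swidden_params()` returns the baseline configuration: $N=40$
households, $L=120$, $T=1000$ rounds, $p_0=0.01$, $p_1=0.06$,
$p_{\max}=0.12$, $F=0.5$, $h=3$ cells per worker, $c_0=0.1$, $c=0.2$,
$\alpha=0.3$, $\mu=0.75$, $\lambda=10$, $\nu_0=\nu_1=0.2$,
$\nu_2=0.1$, a fully forested grid ($f_0=1$), blank histories,
requests initialized uniformly on $\{1,\dots,5\}$ and thresholds
uniformly on $\{0,\dots,hN\}$. A run is **sustainable** when the mean
forest fraction over the last 25% of rounds exceeds 0.05.

## The three regimes

```{r regimes, eval = FALSE}
summarize_run(run_simulation(swidden_params(mu = 1.0, seed = 1)))
summarize_run(run_simulation(swidden_params(mu = 0.75, seed = 1)))
summarize_run(run_simulation(swidden_params(mu = 0.4, seed = 1)))
```

* **Low-intensity swidden** (high $\mu$): severe sanctions evolve
  ($\bar y \to 0$), labour exchange dies out, every household clears
  $h$ cells alone and the forest settles near the mean-field
  equilibrium below.
* **Sustainable high-intensity swidden** (intermediate $\mu$): the
  sanctioning norm, helping network, harvest and forest cycle around
  intermediate values; helping is dense enough for large harvests but
  sanctioning prevents runaway clearing.
* **Deforestation** (low $\mu$): helping runs on reciprocity, which
  cannot discriminate against over-requesters fast enough; the forest
  collapses and stays pinned near zero, harvests capped by the
  common-pool share.

At the default $\mu = 0.75$ the model is bistable: across seeds both
the sustainable-cycling and the deforestation attractor are reached,
and `bistability_fraction()` of a 100-run ensemble lies strictly
between 0 and 1.

## Mean-field forest equilibrium

When nobody helps, each household clears $h$ cells per round, so per
cell the harvest rate is $h\nu$ with density $\nu = N/L^2$. Ignoring
spatial correlation, the forest fraction settles where regeneration
balances harvest, $(1-f)\,p(f) = h\nu$, on the declining branch of
the recruitment curve. With $A=(p_{\max}-p_1 F)/(1-F)$ and
$B=(p_{\max}-p_1)/(1-F)$ (note $A-B = p_1$):

$$f^\ast = \frac{(A+B) - \sqrt{p_1^2 + 4Bh\nu}}{2B}.$$

```{r meanfield}
mean_field_f_star(swidden_params())$f_star
```

The closed form is cross-validated against a bisection root-finder to
$10^{-10}$ in the test suite, and 20-run ensembles at $\mu = 1$ land
within 0.1 of $f^\ast$. The solution exists only while
$h\nu \le (1-F)p_{\max}$; beyond that harvest pressure exceeds the
maximum regeneration flux and `branch_valid` is `FALSE`.

## Design choices in the open parts of the model

Several micro-mechanisms are not pinned down by the model's
published description; the package commits to the following, each
exposed where a knob is useful.

* **Neighbourhood and boundary.** Moore 8-neighbourhood (focal cell
  excluded) on a torus, the common lattice-ecology default that
  avoids edge artifacts; von-Neumann-4 and clipped boundaries are
  config options.
* **Innovation kernel.** Threshold innovation is a *local* Gaussian
  step (s.d. 0.5 cells, clamped to $[0, hN]$), so thresholds are
  continuous after their integer initialization. A global
  uniform-redraw innovation was examined and rejected: redrawing
  $y$ uniformly on $\{0,\dots,hN\}$ at rate $\nu_2$ maintains a
  selection-independent stock of roughly
  $\nu_2 N/(\nu_1+\nu_2) \approx 13$ permissive households at all
  times, which keeps $\bar y$ pinned near 20 and guarantees every
  large request a work party of $\sim$10 — under that kernel severe
  sanctioning can never consolidate and the forest collapses at every
  $\mu$, contradicting the existence of a low-intensity regime. Local
  innovation supplies variation for imitation to select on without
  re-injecting extreme norms. A caveat worth knowing: in the
  deforestation regime the threshold norm is nearly
  selection-neutral, so over long horizons it random-walks; in a
  small fraction of low-$\mu$ runs it wanders below the request range
  within 1000 rounds, labour exchange starves, and the forest
  temporarily recovers. The kernel scale was fixed from this
  qualitative analysis and not revisited.
* **Time-lag semantics.** The lag delays *eligibility*: a cell
  emptied in round $t$ with lag $l$ sits out the regeneration steps
  of rounds $t, \dots, t+l-1$ and regenerates with its usual
  probability from round $t+l$ on.
* **Shock timing.** Shocks apply after regeneration, as the round's
  final step, so the recorded forest fraction reflects them.
* **Cleared-cell placement.** Uniformly random over forest cells:
  households have no spatial identity, and imposing clustering would
  add unmodelled structure.
* **Tie-breaking.** Myopic optimization returns the smallest
  maximizing request — deterministic and conservative.
* **Round-1 threshold revision** is skipped (the logit rule is
  undefined without payoffs; with zero payoffs it would be uniform
  copying, so the two choices are distributionally close — skipping
  documents the intent).
* **Beliefs in the heterogeneous-$\mu$ extension** use each partner's
  true $\mu_j$ (common knowledge); the focal household's own weight
  is not substituted.

## Reproducibility and the two engines

A run is a pure function of its parameter set including the seed. All
randomness flows through R's RNG in a canonical per-round draw order
(revision draws, then the $N^2$ helping draws column-major, then one
uniform key per forested cell for clearing, then one draw per
eligible empty cell for regeneration, then shock draws only when
shocks are enabled). Cells to clear are the $k$ smallest keys — the
same uniform-without-replacement law as direct sampling, chosen so
both engines consume the stream identically. The package ships two
engines: a compiled round loop (the default) and a pure-R reference
implementation built from the exported module functions;
`run_simulation(params, engine = "r")` and the default engine produce
*identical* runs for identical seeds, which the test suite asserts
across neighbourhood, boundary, shock and lag configurations. A
single stream with extensions drawing only when enabled was preferred
over per-concern sub-streams because it makes this cross-engine
equivalence exact. Ensemble and sweep seeds derive deterministically
from a base seed (sweep combinations hash their parameter values, so
results are independent of grid order).

## The graduated sanctioning index

To quantify how strongly a community sanctions, the package computes,
per round, cross-household population z-scores of the clearing
requests and of the helpers received, and per household the
difference $z(x_i) - z(N_i^+)$. The run-level index averages these
differences weighted by the standardized request,

$$\mathrm{GSI} = \overline{\; z(x_i)\,\big(z(x_i) - z(N_i^+)\big)\;},$$

over the final window; per round this equals $1 - \mathrm{cor}(x,
N^+)$. The weighting matters: the *unweighted* mean of z-score
differences across households is identically zero in every round
(both z-score sets are centred), so it cannot distinguish runs. The
weighted form is 0 when help tracks requests, positive when large
requests are systematically refused — i.e. when sanctioning is
graduated — and `gsi(run, aggregate = ...)` accepts any other
aggregation. Zero-variance rounds contribute zero scores. Across the
$\mu \in \{0.5,\dots,1\}$ sweep, runs with a higher index retain more
forest (positive rank correlation, asserted in the tests).

## What the simulations do and do not show

The model is deliberately minimal: binary cells with no succession
stages, seed dispersal or soil; no household locations, land tenure
or kinship; myopic, boundedly rational agents. Passing tests
demonstrate the internal consistency of this idealized system and the
regime structure it generates — not predictions for any real forest.
Test and acceptance ensembles use 10–20 runs per condition (100 for
the bistability check) at the default $N=40$, $L=120$, $T=1000$;
these sizes give standard errors comfortably inside the tolerances
asserted while keeping the suite quick, and ensembles are shared
across assertions through a seed-keyed cache. Unit tests exercise the
modules on miniature lattices ($L \le 20$, $N \le 6$) where
brute-force oracles are feasible.

## Known limitations

* Near the bifurcation in $\mu$ the sustainable fraction changes
  steeply, so classification-based statistics there carry real
  seed-to-seed variance even at 20 runs.
* The deforestation state is metastable rather than absorbing (see
  the innovation-kernel caveat above): over horizons much longer than
  1000 rounds, rare norm-collapse/recovery cycles occur at low $\mu$.
* At $\mu = 0$ with blank initial histories helping can never ignite
  — $q \equiv 0$ is absorbing — so that corner of parameter space is
  degenerate low-intensity by construction, whatever the other
  parameters.
* The GSI is one of several defensible standardizations of
  "requests vs help received"; comparisons across studies should
  check the aggregation convention first.
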