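---
title: "Bow-tie structure and collective dynamics on directed networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bow-tie structure and collective dynamics on directed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowtiedyn)
```

## The problem

Directed networks — gene regulatory circuits, connectomes, follow
graphs — organize globally into a *bow tie*: a CORE (the largest
strongly connected component) surrounded by a hierarchically defined
periphery. IN nodes feed the CORE, OUT nodes drain it, tendrils and
tubes hang off the periphery, and the overall periphery connectivity is
feedforward, from SOURCE nodes (IN nodes with no in-links) to SINK
nodes (OUT nodes with no out-links). Because sources receive no
feedback, their states stay forever uncorrelated with the rest of the
network; they act as frozen noise injected into the CORE along IN→CORE
links. This package quantifies that mechanism on directed Erdős–Rényi
(ER) networks, where a single parameter — the mean in-degree
$\langle q_{in}\rangle = L/N$ — controls the whole architecture, and
measures its dynamical consequences with two canonical models of
collective behavior: Kuramoto phase oscillators (synchronization) and
heat-bath Ising spins (ferromagnetic ordering).

## The network model

Each network is built from an undirected skeleton: every one of the
$\binom{N}{2}$ labelled pairs is linked with probability
$2\langle q_{in}\rangle/(N-1)$, each link is oriented $i \to j$ ($i<j$)
and reversed with probability $1/2$. This yields Poisson in- and
out-degrees with mean $\langle q_{in}\rangle$ and *no reciprocal pairs
by construction*. Two samplers are provided — exhaustive
pairwise-Bernoulli (used up to $n = 3000$) and a geometric-skip sampler
that jumps between present pairs (used above; distributionally
identical, and cross-checked in the tests). Both consume the
Mersenne–Twister stream in sorted-pair order, first skeleton then
orientation draws, so a seed fully identifies a network.

```{r structure}
net <- generate_directed_er(20000, mean_in_degree = 1.5, seed = 1)
part <- bowtie_decompose(net)
part
```

### Generating-function theory

For an uncorrelated directed network with joint degree distribution
$P(q_{in}, q_{out})$, let $x_c$ ($y_c$) be the probability that an
in-link comes from (an out-link leads to) a *finite* component. For
independent Poisson($c$) marginals both satisfy
$u = e^{-c(1-u)}$, whose smallest root in $[0,1]$ is found by monotone
iteration from $0$ with a bisection fallback (residual $<10^{-12}$; the
subcritical root is $1$ for $c \le 1$). Then

* $N_{SOURCE}/N = \sum_{q_{out}} P(0, q_{out})\,(1 - y_c^{q_{out}})
  = e^{-c}(1 - y_c)$,
* $N_{CORE}/N = (1 - \hat x)(1 - \hat y) = (1 - y_c)^2$,
* $L_{IN\text{-}CORE} = N \sum q_{in} x_c P(q_{in}, q_{out})
  (1 - y_c^{q_{out}})(1 - x_c^{q_{in}-1})$, evaluated exactly as
  written (it closes to $N c\, u (1-u)^2$ in the Poisson case, which the
  tests verify against the truncated double sum; truncation at
  $q_{max} = \max(50,\ c + 12\sqrt c)$, tail mass checked against
  $10^{-10}$).

The CORE emerges at the directed percolation point
$\langle q_{in}\rangle = 1$:

```{r theory}
theory_curve(c(1.0, 1.2, 1.5, 1.8))
core_emergence_point()
```

At $\langle q_{in}\rangle = 1.5$ the theory gives the survey values
$0.130$ and $0.340$ that the 5-network ensemble at $N = 10^5$
reproduces to two decimals (see `reproduce_structure_row()` and the
acceptance tests).

## Dynamics

### Kuramoto

Phases obey $\dot\theta_n = \omega_n + K\sum_m A_{mn}
\sin(\theta_m-\theta_n)$ with $A_{mn}=1$ when $m \to n$, i.e. nodes
listen to their in-neighbours. Frequencies are N(0, 1) (time is
measured in units of the inverse frequency spread), initial phases
uniform on $(-\pi,\pi]$. Ordering is measured by
$r_X = |\,N_X^{-1}\sum_{n\in X} e^{i\theta_n}|$, the modulus of the
subset phasor: the two expressions of the order parameter (projection
on the mean phase and modulus) coincide only for the subset's own mean
phase, so the modulus form is used for every subset.

Numerical choices: fixed-step RK4 (default $dt = 0.01/\max(1,K)$) —
the system is non-stiff and a fixed step keeps runs bit-reproducible; a
stability guard refuses $dt\,(|\omega|_{max} + K q_{in}^{max}) \ge
0.5$. The same guard bounds every RK4 stage increment below 0.5 rad,
which lets the kernel advance each node's unit phasor by short
small-angle polynomials (absolute error $< 3\times 10^{-10}$, phasor
renormalized every step) instead of calling `sincos` four times per
node per step — a ~4x speedup with machine-precision agreement on the
closed-form checks (free oscillator, two-oscillator lock angle).
Defaults discard a transient of 200 time units and observe 200 more,
sampling every 0.5; a first-half/second-half stationarity check warns
(never errors). The onset scans extend the transient to 600 time units
because near the synchronization onset partially locked clusters relax
on a $O(100)$ time scale and a 200-unit transient leaves the
time-averaged $r$ biased upward by about 0.01 exactly where it
straddles the onset threshold. The fluctuation measure is
$C = N_X[\langle r^2\rangle_t - \langle r\rangle_t^2]$; since $r$ is
invariant under a global phase rotation, the rotating-frame qualifier
of the cos–cos definition is honored automatically and no group
frequency enters $C$. The group frequency $\Omega$ is still estimated
(finite differences of the unwrapped mean phase) and is used by the
test that an isolated CORE at large $K$ rotates at
$\langle\omega\rangle$. Per-node locked-group membership is *not*
computed — the $r$-based observables do not need it.

### Ising

Spins $s_n = \pm 1$ feel the in-neighbour field $h_n = \sum_m A_{mn}
s_m$ and equilibrate against a heat bath: $P(s_n = +1) =
1/(1+e^{-2h_n/T})$. Updates are random-sequential (one sweep =
$n$ single-site updates at uniformly random sites); synchronous
updating is rejected because it manufactures period-2 artifacts on
bipartite-like structures. $T = 0$ is the exact limit — deterministic
alignment with a fair coin at $h = 0$; that coin is load-bearing: it is
what makes sources ($q_{in} = 0$, hence $h \equiv 0$) permanent
coin-flippers at *any* temperature — the frustration mechanism by
which sources disrupt CORE ordering.
The update draws flip-vs-keep probabilities ("symmetric draw"), an
exact heat-bath rule whose trajectories negate update-for-update under
a global spin flip; a direct redraw variant is provided and tested to
sample the same equilibrium. Exactly two RNG draws per update keep
streams aligned.

Ordering is $m_X = N_X^{-1}\sum_{n \in X} s_n$ and the fluctuation
measure $\chi = N_X[\langle m^2\rangle_t - \langle m\rangle_t^2]$,
computed exactly as written over the declared window. For onset and
$T_C$ detection the package uses $\langle|m_X|\rangle$ and the $\chi$
peak rather than signed $\langle m_X\rangle$, because finite systems
flip sign over long windows; `estimate_critical_temperature()` returns
the $\chi$-peak grid location with the grid spacing as uncertainty and
errors when the maximum sits on the grid boundary. (Published $T_C$
values for this system are read off figures with an unstated
estimator; small offsets are possible, which is why only orderings —
denser CORE ⇒ higher $T_C$; IN restored ⇒ lower $T_C$ — are
asserted.)

### IN-removal experiments

`remove_in_fraction()` deletes $\lfloor f N_{IN}\rfloor$ nodes (at
least one when $f > 0$) drawn uniformly from the *original* IN set,
with all their links. Node ids stay stable — removed nodes remain as
isolated vertices — so the original CORE ids remain valid; removing IN
nodes cannot break the CORE's SCC, which re-decomposition tests
assert. `removal_sweep()` measures, per $f$ and seed, the steady-state
CORE ordering and pair correlation, always on the *pre-removal* CORE
set (re-partitioning per $f$ would silently change the observable).
`detect_critical_fraction()` reports the interior grid maximum of the
pair-correlation curve exceeding both endpoints by at least 2 pooled
standard errors — prominent enough that sampling bumps do not trigger —
or "none" for the already-ordered, monotonically decaying case. The
critical fractions have no printed reference values, so the package's
tests are property-based: peak
existence below full removal in the disordered regime, its coincidence
with the steepest rise of the ordering curve, monotone enhancement of
ordering with $f$.

```{r removal, eval = FALSE}
net <- generate_directed_er(2000, 1.4, seed = 21)
part <- bowtie_decompose(net)
removal_sweep(net, part, "ising", f_grid = seq(0, 1, 0.1),
              params = list(temperature = 0), seeds = 0:4)
```

## Onset criterion

The study reports ordering onsets as thresholds
($\langle q_{in}\rangle \gtrsim 1.5$ for synchronization,
$\gtrsim 1.9$ for zero-temperature magnetization) without an
estimator. `onset_scan()` therefore fixes one: the smallest grid value
whose ensemble-mean observable exceeds `noise_floor_multiplier` (= 3)
times a finite-size noise floor — $2/\sqrt n$ for $r$, $3/\sqrt n$ for
$|m|$ — with one grid step of uncertainty. Floor formulas and
multiplier are configuration-exposed, not tuned.

## What the synthetic generator does and does not emulate

The generator *is* the study's stated world: sparse directed ER
networks, reciprocal-free, Poisson degrees, one structural control
parameter. It deliberately does not produce degree heterogeneity
(hubs), degree–degree correlations, clustering, reciprocal links, or
weighted links — all present in real directed networks and all able to
shift critical points. A green test here therefore establishes the
mechanism (sources disrupt CORE ordering) for uncorrelated sparse ER
topologies, not quantitative predictions for any real network. The
edge-list importer and census code do run on real networks, but no
numerical claims are attached.

## Scale choices and limitations

The published ensembles use 50 networks of $N = 10^5$; desk-scale
defaults here are $n = 2000$ (Kuramoto) and $n = 10^4$ (Ising) with
6–10 seeds, and the acceptance scan runs the Kuramoto stage at
$dt = 0.003$ (guard-safe at $K = 10$) with a 600-unit transient and a
200-unit observation window to fit a 20-minute single-CPU budget
(see the onset-scan note above on why the transient is longer, not
shorter, than the package default). No claim is made about matching the
published error bars; onset locations carry one-grid-step uncertainty
and at $n = 2000$ the synchronization onset lands at grid point 1.4 or
1.5 depending on seeds, inside the stated $1.5 \pm 0.1$ band. Known
limitations: no mean-field $T_C$ curve, no reciprocal-link bow-tie
variants, no tendril/tube size theory, no per-node locked-group
analysis, no targeted (non-uniform) removals.
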