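# bowtiedyn

Bow-tie structure and collective dynamics of directed networks.

Directed networks organize globally into a *bow tie*: a strongly
connected CORE, an IN component feeding it, an OUT component draining
it, plus tendrils, tubes and disconnected remnants. SOURCE nodes — IN
nodes with no incoming links — receive no feedback, so their states
stay uncorrelated forever and act as frozen noise driven into the CORE.
`bowtiedyn` is for network scientists and systems biologists who want
to quantify how this global organization constrains collective
dynamics: it generates directed Erdős–Rényi (ER) networks controlled by
a single parameter (the mean in-degree ⟨q_in⟩ = L/N), decomposes
arbitrary directed edge lists into bow-tie classes, predicts the
structural fractions with generating functions, and simulates Kuramoto
synchronization and heat-bath Ising ordering on top, including
IN-node-removal experiments that locate the critical removed fraction
at which CORE ordering emerges.

## The quantities at the package's core

* **Structure.** CORE = largest SCC; sources have q_in = 0. For
  uncorrelated networks with degree distribution P(q_in, q_out), with
  u = exp(−c(1−u)) the finite-component branching probability of the
  Poisson(c) family:
  N_SOURCE/N = e^(−c)(1−u), N_CORE/N = (1−u)², and
  L_IN–CORE = N Σ q_in x_c P(q_in,q_out)(1−y_c^q_out)(1−x_c^(q_in−1)).
  The ratio ⟨q_in^ext⟩/⟨q_in^int⟩ = L_IN–CORE/L_CORE–CORE measures the
  CORE's susceptibility to its periphery. The CORE emerges at the
  directed percolation point ⟨q_in⟩ = 1.
* **Kuramoto.** dθ_n/dt = ω_n + K Σ_m A_mn sin(θ_m − θ_n), ω ~ N(0,1);
  ordering r_X = |N_X⁻¹ Σ e^{iθ}|; fluctuations
  C = N_X[⟨r²⟩_t − ⟨r⟩_t²].
* **Ising.** Heat bath: P(s_n = +1) = 1/(1 + e^(−2h_n/T)) with
  h_n = Σ_m A_mn s_m; magnetization m_X; χ = N_X[⟨m²⟩_t − ⟨m⟩_t²];
  T = 0 is the exact limit with a fair coin at h = 0 — which is what
  makes sources permanent noise at any temperature.

Synchronization emerges only for ⟨q_in⟩ ≳ 1.5 and zero-temperature
magnetization only for ⟨q_in⟩ ≳ 1.9 — both well above the percolation
point at 1, because sources frustrate the CORE.

## Worked example

```r
library(bowtiedyn)

net  <- generate_directed_er(1e5, mean_in_degree = 1.5, seed = 1)
part <- bowtie_decompose(net)
part
#> <bowtie_partition> 100000 nodes
#>            CORE              IN             OUT TENDRIL_FROM_IN  TENDRIL_TO_OUT
#>           34349           24294           24296            3854            4017
#>            TUBE    DISCONNECTED
#>            2327            6863
#>   sources: 13050  sinks: 13060

cen <- link_census(net, part)
external_internal_ratio(cen)
#> [1] 0.4142819

theory_curve(c(1.2, 1.5, 1.8))
#>     c       x_c source_frac  core_frac in_core_over_l
#> 1 1.2 0.6863017  0.09448412 0.09840664     0.06753664
#> 2 1.5 0.4171884  0.13004286 0.33966941     0.14170612
#> 3 1.8 0.2675700  0.12106986 0.53645366     0.14353892
```

34% of nodes form the CORE and 13% are sources, matching the theory
columns (0.340, 0.130); the census ratio ≈ 0.42 says a typical CORE
node receives roughly 0.4 external in-links per internal one. An
ensemble version with standard errors and theory side by side:
`reproduce_structure_row(n = 1e5, mean_in_degree = 1.5, n_networks = 5,
seed = 0)`.

Dynamics and removal experiments follow the same pattern:

```r
sim <- simulate_kuramoto(oscillator_system(net, K = 10), seed = 2,
                         subsets = list(core = part$core))
mean(sim$r[, "core"]); pair_correlation_C(sim, "core")

sweep <- removal_sweep(net, part, "ising", params = list(temperature = 0))
sweep$f_critical   # removed IN fraction at which CORE ordering emerges
```

A command-line entry point mirrors the R API
(`generate, decompose, theory, kuramoto, ising, removal-sweep,
onset-scan, table1`):

```sh
Rscript -e 'bowtiedyn::bowtie_cli()' decompose --edge-list net.txt --report row.tsv
```

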