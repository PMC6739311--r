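Package: bowtiedyn
Title: Bow-Tie Structure and Collective Dynamics of Directed Networks
Version: 0.1.0
Authors@R:
    person("Edgar", "Aveiro", email = "bowtiedyn@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the global bow-tie organization of
    directed networks constrains collective dynamics. Generates directed
    Erdos-Renyi networks without reciprocal links, classifies nodes into
    bow-tie components (CORE, IN, OUT, tendrils, tubes), censuses links
    between components, and provides generating-function predictions for
    the source-node fraction, CORE fraction and IN-CORE link count.
    Simulates Kuramoto phase oscillators and heat-bath Ising spins on
    these networks, measures subset order parameters, magnetization and
    pair-correlation (fluctuation) functions, and runs IN-node removal
    experiments that locate the critical removed fraction at which
    ordering emerges in the CORE.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
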