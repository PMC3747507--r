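Package: duplexgames
Title: Evolutionary Social-Dilemma Games on Interdependent Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Monte Carlo simulator for spatial evolutionary games (prisoner's
    dilemma and snowdrift) on two interdependent periodic lattices. A tunable
    fraction rho of "distinguished" players on each lattice draws extra
    utility, with strength alpha, from the payoff of a partner site on the
    other lattice, while strategies never cross between lattices. The package
    provides square and triangular lattice builders, Fermi, best-takes-over
    and proportional-imitation update rules with heterogeneous teaching
    activity, asynchronous full-Monte-Carlo-step dynamics with a compiled
    inner loop, cooperation observables split by player class, critical
    temptation estimation by bisection, desk-scale parameter sweeps, and a
    random-sequential-adsorption module for the jamming coverage that bounds
    the percolation of distinguished players.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
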