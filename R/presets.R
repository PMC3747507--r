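#' Desk-scale presets for the published scans
#'
#' Each preset names one of the headline scans and bundles a configuration
#' template with the grid it is evaluated on, at a reduced lattice size and
#' relaxation time chosen so a full preset completes in minutes on one CPU
#' (the published scans use L = 200-800 and long relaxations; the structure
#' of the results, not figure-quality statistics, is the goal here). All
#' values can be overridden downstream.
#'
#' Available presets:
#' * `fig1`: rho-alpha sweep, PD, Fermi rule, b = 1.05, square lattice
#' * `fig2`: single time-evolution run at b = 1.05, rho = 0.3, alpha = 0.8
#' * `fig3`: b-scans for teaching-activity variants at rho = 0.5
#' * `fig5`: b-scans for isolated / unilateral / bilateral coupling at
#'   rho = 0.5, alpha = 0.5
#' * `fig6a`: rho-alpha sweep, best-takes-over rule, b = 1.4
#' * `fig6b`: rho-alpha sweep, proportional imitation, b = 1.06
#' * `fig7a`: rho-alpha sweep on the triangular lattice, b = 1.1
#' * `fig7b`: rho-alpha sweep for the snowdrift game, r = 0.3
#'
#' @param name preset name
#' @param seed master seed for the preset's template
#' @return list with elements `kind` (`"run"`, `"sweep"` or `"scan_b"`),
#'   `cfg`, and the grids/variants the scan uses
#' @export
preset <- function(name = c(
                     "fig1", "fig2", "fig3", "fig5", "fig6a", "fig6b",
                     "fig7a", "fig7b"
                   ),
                   seed = 1L) {
  name <- match.arg(name)
  grid9 <- seq(0.1, 0.9, by = 0.1)
  base <- function(...) {
    do.call(sim_config, modifyList(
      list(L = 60L, mcs_relax = 4000L, mcs_sample = 1000L, seed = seed),
      list(...)
    ))
  }
  switch(name,
    fig1 = list(
      kind = "sweep", cfg = base(b = 1.05, rule = "fermi"),
      rho_grid = grid9, alpha_grid = grid9, replicates = 3
    ),
    fig2 = list(
      kind = "run",
      cfg = base(b = 1.05, rho = 0.3, alpha = 0.8, mcs_relax = 0L,
                 mcs_sample = 5000L)
    ),
    fig3 = list(
      kind = "scan_b",
      cfg = base(L = 50L, rho = 0.5),
      b_grid = seq(1.01, 1.13, by = 0.04),
      variants = list(
        w1_a0 = list(alpha = 0),
        w1_a05 = list(alpha = 0.5),
        wdist005_a0 = list(alpha = 0, w_dist = 0.05),
        wdist005_a05 = list(alpha = 0.5, w_dist = 0.05),
        word005_a0 = list(alpha = 0, w_ord = 0.05),
        word005_a05 = list(alpha = 0.5, w_ord = 0.05)
      ),
      replicates = 3
    ),
    fig5 = list(
      kind = "scan_b",
      cfg = base(L = 50L, rho = 0.5, alpha = 0.5),
      b_grid = seq(1.005, 1.03, by = 0.005),
      variants = list(
        isolated = list(alpha = 0),
        unilateral = list(link_mode = "unilateral_A"),
        bilateral = list(link_mode = "bilateral_paired")
      ),
      replicates = 3
    ),
    fig6a = list(
      kind = "sweep", cfg = base(b = 1.4, rule = "best_takes_over"),
      rho_grid = grid9, alpha_grid = grid9, replicates = 3
    ),
    fig6b = list(
      kind = "sweep", cfg = base(b = 1.06, rule = "proportional_imitation"),
      rho_grid = grid9, alpha_grid = grid9, replicates = 3
    ),
    fig7a = list(
      kind = "sweep", cfg = base(b = 1.1, topology = "triangular"),
      rho_grid = grid9, alpha_grid = grid9, replicates = 3
    ),
    fig7b = list(
      kind = "sweep", cfg = base(game = "SD", r = 0.3),
      rho_grid = grid9, alpha_grid = grid9, replicates = 3
    )
  )
}
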