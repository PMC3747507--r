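#' Initialize the lattice state
#'
#' Builds the lattice, draws the distinguished-player masks, and assigns each
#' player an initial strategy, cooperator or defector with equal probability.
#' Every random ingredient consumes its own named stream derived from the
#' master seed (`links-A`/`links-B`, `init-<layer>`), so variants of a run
#' (e.g. `alpha = 0` vs `alpha > 0`) share initial conditions, and a
#' single-layer state for layer `k` is initialized identically to layer `k`
#' of the two-layer state.
#'
#' @param cfg a [sim_config()]
#' @param layers integer vector of layer ids to instantiate: `c(1L, 2L)` for
#'   the interdependent pair (default), or a single id for an isolated
#'   reference lattice
#' @return a `duplex_state`: list with the `neighbor_table`, an
#'   `n_sites x length(layers)` strategy matrix (1 = cooperator,
#'   0 = defector), the `link_assignment`, per-layer distinguished masks
#'   (`dist`, a logical matrix), `layer_ids`, and `mcs_elapsed`
#' @export
init_state <- function(cfg, layers = c(1L, 2L)) {
  stopifnot(inherits(cfg, "sim_config"))
  layers <- as.integer(layers)
  stopifnot(length(layers) %in% c(1L, 2L), all(layers %in% 1:2))
  table <- build_lattice(cfg$topology, cfg$L)
  n <- table$n_sites
  links <- assign_interlinks(cfg$L, cfg$rho, cfg$link_mode,
                             seed = derive_seed(cfg$seed, "links"))
  masks <- list(links$distinguished_A, links$distinguished_B)

  strategies <- matrix(0L, nrow = n, ncol = length(layers))
  dist <- matrix(FALSE, nrow = n, ncol = length(layers))
  for (j in seq_along(layers)) {
    id <- layers[j]
    strategies[, j] <- with_local_seed(
      derive_seed(cfg$seed, sprintf("init-%d", id)),
      rbinom(n, 1L, 0.5)
    )
    dist[, j] <- masks[[id]]
  }
  # coupling is only defined for the full two-layer system
  if (length(layers) == 1L) dist[] <- FALSE

  structure(
    list(
      table = table, strategies = strategies, links = links, dist = dist,
      layer_ids = layers, mcs_elapsed = 0L
    ),
    class = "duplex_state"
  )
}

#' @export
print.duplex_state <- function(x, ...) {
  cat(sprintf(
    "<duplex_state> %d layer(s) on %s lattice L = %d, %d MCS elapsed\n",
    length(x$layer_ids), x$table$topology, x$table$L, x$mcs_elapsed
  ))
  invisible(x)
}

#' Utility of one player
#'
#' Distinguished players add `alpha` times the payoff that their partner site
#' earns from its own nearest neighbours on the other layer:
#' `U_x = pi_x + alpha * pi_x'`. Ordinary players have `U_x = pi_x`,
#' independent of the other layer. Reference implementation in R, mirrored by
#' the compiled engine.
#'
#' @param x 1-based site index
#' @param layer column index into the state's strategy matrix
#' @param state a `duplex_state` with two layers
#' @param cfg a [sim_config()]
#' @return the utility `U_x`
#' @export
utility <- function(x, layer, state, cfg) {
  M <- cfg$matrix
  u <- accumulate_payoff(x, layer, state, M)
  if (ncol(state$strategies) > 1L && state$dist[x, layer]) {
    partner <- state$links$partner[x]
    other <- if (layer == 1L) 2L else 1L
    u <- u + cfg$alpha * accumulate_payoff(partner, other, state, M)
  }
  u
}

#' Fermi strategy-adoption probability
#'
#' Probability that the focal player `x` adopts the strategy of the role
#' model `y`: `p = w_y / (1 + exp((U_x - U_y) / K))`, where `K` is the
#' selection noise and `w_y` is the teaching activity of the source (its
#' ability to pass on a strategy). The exponent is clamped at +/- 700 so the
#' probability saturates to 0 or `w_y` instead of overflowing.
#'
#' @param U_x,U_y utilities of the focal player and the role model
#' @param K selection noise, `K > 0`
#' @param w_y teaching activity of the role model, in `(0, 1]`
#' @return adoption probability, vectorized over the inputs
#' @export
#' @examples
#' fermi_adopt_prob(1, 2, K = 0.1)   # ~0.9999546
fermi_adopt_prob <- function(U_x, U_y, K = 0.1, w_y = 1) {
  stopifnot(all(K > 0), all(w_y > 0), all(w_y <= 1))
  ex <- pmin(pmax((U_x - U_y) / K, -700), 700)
  w_y / (1 + exp(ex))
}

#' Best-takes-over update decision (reference implementation)
#'
#' The focal player adopts the strategy of the highest-utility member of its
#' closed neighbourhood (itself plus its lattice neighbours); exact utility
#' ties are broken uniformly at random among the maximizers.
#'
#' @inheritParams utility
#' @return the strategy (1 = C, 0 = D) the focal player adopts
#' @export
best_takes_over_update <- function(x, layer, state, cfg) {
  cand <- c(x, state$table$neigh[x, ])
  u <- vapply(cand, utility, numeric(1), layer = layer, state = state,
              cfg = cfg)
  best <- cand[u == max(u)]
  pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
  state$strategies[pick, layer]
}

#' Proportional-imitation adoption probability (reference implementation)
#'
#' The focal player adopts the neighbour's strategy with probability
#' `max(0, U_y - U_x) / phi`, never imitating a worse-performing neighbour.
#' The normalization `phi` defaults to the maximum admissible utility
#' difference, `(1 + alpha) * degree * (payoff range)`.
#'
#' @param x focal site, `y` a neighbour of `x`
#' @param y role-model site
#' @inheritParams utility
#' @return adoption probability
#' @export
proportional_imitation_prob <- function(x, y, layer, state, cfg) {
  du <- utility(y, layer, state, cfg) - utility(x, layer, state, cfg)
  max(0, du) / cfg$phi
}

rule_code <- function(rule) {
  match(rule, c("fermi", "best_takes_over", "proportional_imitation")) - 1L
}

# stream seeds for a dynamics segment starting at MCS `start`: one update
# stream per layer id plus the layer-picker stream
segment_seeds <- function(cfg, layer_ids, start) {
  list(
    layers = vapply(
      layer_ids,
      function(id) derive_seed(cfg$seed, sprintf("upd-%d-%d", id, start)),
      numeric(1)
    ),
    picker = derive_seed(cfg$seed, sprintf("pick-%d", start))
  )
}

#' Run full Monte Carlo steps of the asynchronous dynamics
#'
#' One full Monte Carlo step (MCS) consists of `n_layers * L^2` elementary
#' steps, so each player on both lattices is selected once on average. In an
#' elementary step a focal player is drawn (uniformly across both layers under
#' `interleave = "pooled"`, round-robin under `"alternating"`), and updates
#' its strategy against a uniformly random same-layer neighbour (Fermi,
#' proportional imitation) or its closed neighbourhood (best-takes-over).
#' Strategies never transfer between layers; the other layer enters only
#' through the utilities of distinguished players.
#'
#' When both layers are homogeneous the dynamics is absorbed: stepping stops
#' and the remaining records repeat the absorbing values.
#'
#' @param state a `duplex_state`
#' @param cfg a [sim_config()]
#' @param n_mcs number of full Monte Carlo steps, `>= 0`
#' @param record if `TRUE`, record observables once per MCS (including the
#'   state before the first step)
#' @return list with the advanced `state`, a `trajectory` data frame (columns
#'   `mcs`, `layer`, `f_C`, `f_C_int`, `f_C_no`; `layer` is the layer id or
#'   `"pooled"`; `NULL` when `record = FALSE`), and flags `absorbed`,
#'   `absorbed_at`
#' @export
run_mcs <- function(state, cfg, n_mcs, record = TRUE) {
  stopifnot(inherits(state, "duplex_state"), inherits(cfg, "sim_config"))
  if (n_mcs < 0 || n_mcs != round(n_mcs))
    stop_validation("`n_mcs` must be a non-negative integer")
  n_mcs <- as.integer(n_mcs)
  M <- cfg$matrix
  seeds <- segment_seeds(cfg, state$layer_ids, state$mcs_elapsed)

  res <- cpp_run_engine(
    state$table$neigh - 1L, state$strategies, state$dist,
    state$links$partner - 1L,
    M$T, M$R, M$P, M$S, cfg$alpha, rule_code(cfg$rule), cfg$K,
    cfg$w_dist, cfg$w_ord, cfg$phi,
    n_mcs, -1, if (cfg$interleave == "pooled") 0L else 1L,
    seeds$layers, seeds$picker, record
  )

  traj <- NULL
  if (record) {
    traj <- records_to_trajectory(
      res$records, state, mcs0 = state$mcs_elapsed
    )
  }
  state$strategies <- res$strat
  state$mcs_elapsed <- state$mcs_elapsed + n_mcs
  list(
    state = state, trajectory = traj, absorbed = res$absorbed,
    absorbed_at = if (res$absorbed_at >= 0)
      state$mcs_elapsed - n_mcs + res$absorbed_at else NA_integer_
  )
}

#' Perform a fixed number of elementary steps (single-update granularity)
#'
#' Exposes the engine at the resolution of individual update attempts, mainly
#' for distributional checks of the elementary dynamics against exhaustive
#' enumeration on tiny lattices.
#'
#' @inheritParams run_mcs
#' @param n_steps number of elementary steps
#' @return the advanced `duplex_state`
#' @export
run_elementary_steps <- function(state, cfg, n_steps) {
  stopifnot(inherits(state, "duplex_state"))
  M <- cfg$matrix
  seeds <- segment_seeds(cfg, state$layer_ids, state$mcs_elapsed)
  res <- cpp_run_engine(
    state$table$neigh - 1L, state$strategies, state$dist,
    state$links$partner - 1L,
    M$T, M$R, M$P, M$S, cfg$alpha, rule_code(cfg$rule), cfg$K,
    cfg$w_dist, cfg$w_ord, cfg$phi,
    0L, as.double(n_steps), if (cfg$interleave == "pooled") 0L else 1L,
    seeds$layers, seeds$picker, FALSE
  )
  state$strategies <- res$strat
  state
}

#' Run a full simulation: initialize, relax, sample
#'
#' Convenience wrapper: builds the two-layer state from the configuration,
#' relaxes for `mcs_relax` MCS, then samples `mcs_sample` MCS with per-MCS
#' recording and returns stationary averages over the sampling window.
#'
#' @param cfg a [sim_config()]
#' @param record_relax if `TRUE`, also keep per-MCS records of the relaxation
#'   phase (for time-evolution plots); default `FALSE`
#' @return list with `trajectory` (sampling phase, plus relaxation if
#'   requested), `summary` (stationary means per layer, see
#'   [stationary_mean()]), the final `state`, and `absorbed`
#' @export
run_duplex <- function(cfg, record_relax = FALSE) {
  state <- init_state(cfg)
  relax <- run_mcs(state, cfg, cfg$mcs_relax, record = record_relax)
  sample_phase <- run_mcs(relax$state, cfg, cfg$mcs_sample, record = TRUE)
  traj <- sample_phase$trajectory
  if (record_relax && !is.null(relax$trajectory)) {
    # drop the duplicated boundary record at mcs = mcs_relax
    traj <- rbind(relax$trajectory, traj[traj$mcs > cfg$mcs_relax, ])
  }
  absorbed <- sample_phase$absorbed
  list(
    trajectory = traj,
    summary = stationary_mean(sample_phase$trajectory, cfg$mcs_sample),
    state = sample_phase$state,
    absorbed = absorbed,
    absorbed_at = if (relax$absorbed) relax$absorbed_at
                  else sample_phase$absorbed_at
  )
}
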