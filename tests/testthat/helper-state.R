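# Build a duplex_state with fully specified strategies / distinguished masks,
# bypassing the random initialization (for oracle tests on tiny lattices).
manual_state <- function(cfg, strat, dist = NULL) {
  table <- build_lattice(cfg$topology, cfg$L)
  n <- table$n_sites
  strat <- matrix(as.integer(strat), nrow = n)
  k <- ncol(strat)
  if (is.null(dist)) dist <- matrix(FALSE, n, k)
  dist <- matrix(as.logical(dist), nrow = n)
  links <- structure(
    list(
      distinguished_A = dist[, 1],
      distinguished_B = if (k > 1) dist[, 2] else logical(n),
      partner = seq_len(n), mode = cfg$link_mode, rho = cfg$rho, L = cfg$L
    ),
    class = "link_assignment"
  )
  structure(
    list(table = table, strategies = strat, links = links, dist = dist,
         layer_ids = seq_len(k), mcs_elapsed = 0L),
    class = "duplex_state"
  )
}

# small configs for unit tests
tiny_cfg <- function(...) {
  args <- modifyList(
    list(L = 3L, mcs_relax = 0L, mcs_sample = 1L, seed = 1),
    list(...)
  )
  do.call(sim_config, args)
}
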