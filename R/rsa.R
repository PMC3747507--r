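#' Random sequential adsorption with nearest- and next-nearest-neighbour
#' exclusion
#'
#' Deposits particles one at a time at uniformly random sites of a periodic
#' `L x L` square lattice. Each deposition blocks the site itself, its 4
#' nearest and its 4 diagonal neighbours (a 3 x 3 exclusion footprint), so no
#' two particles are ever nearest or next-nearest neighbours. Deposition
#' continues until no unblocked site remains (jamming). The jamming coverage
#' of this process, about 0.1869 for large `L`, is the percolation-style
#' lower bound on the density of distinguished players below which their
#' influence cannot span the lattice.
#'
#' Sampling is uniform over the currently unblocked sites via a maintained
#' unblocked-site list with swap-removal, so no rejection is needed as the
#' lattice fills.
#'
#' @param L lattice side length, `L >= 3`
#' @param seed integer seed
#' @return list with `coverage` (= deposited / L^2), `deposited`, and
#'   `occupied`, the logical occupation mask
#' @export
#' @examples
#' rsa_fill(3, seed = 1)$coverage  # 1/9: one footprint covers the 3x3 torus
rsa_fill <- function(L, seed = 1L) {
  if (!is.numeric(L) || length(L) != 1L || L < 3 || L != round(L)) {
    stop_validation("`L` must be a single integer >= 3, got ", deparse(L))
  }
  L <- as.integer(L)
  n <- L * L
  # 3x3 footprint offsets in (row, col)
  off <- expand.grid(dr = -1:1, dc = -1:1)

  with_local_seed(seed, {
    unblocked <- seq_len(n)
    pos <- seq_len(n)   # pos[site] = index into `unblocked`, 0 once removed
    n_unblocked <- n
    occupied <- logical(n)
    deposited <- 0L
    while (n_unblocked > 0L) {
      k <- sample.int(n_unblocked, 1L)
      site <- unblocked[k]
      occupied[site] <- TRUE
      deposited <- deposited + 1L
      r <- (site - 1L) %/% L
      c <- (site - 1L) %% L
      foot <- ((r + off$dr) %% L) * L + ((c + off$dc) %% L) + 1L
      for (s in unique(foot)) {
        j <- pos[s]
        if (j > 0L) {
          last <- unblocked[n_unblocked]
          unblocked[j] <- last
          pos[last] <- j
          pos[s] <- 0L
          n_unblocked <- n_unblocked - 1L
        }
      }
    }
    list(coverage = deposited / n, deposited = deposited, occupied = occupied)
  })
}

#' Jamming coverage over independent seeds
#'
#' @param L lattice side length
#' @param seeds vector of integer seeds (one run each)
#' @return data frame with columns `seed` and `coverage`
#' @export
rsa_coverage <- function(L, seeds) {
  data.frame(
    seed = seeds,
    coverage = vapply(seeds, function(s) rsa_fill(L, s)$coverage, numeric(1))
  )
}
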