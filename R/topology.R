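#' Build a periodic square lattice
#'
#' Sites are indexed row-major, 1-based, at coordinates (row, col) with
#' periodic wrap in both directions. Each site has the four von Neumann
#' neighbours (up, down, left, right). For `L = 2` the wrap makes opposite
#' directions coincide, so the four neighbour slots contain duplicates; the
#' degree (number of interaction partners per game round) is still 4.
#'
#' @param L lattice side length, `L >= 2`
#' @return a `neighbor_table`: list with `L`, `n_sites`, `degree`,
#'   `topology`, and `neigh`, an `n_sites x degree` integer matrix of 1-based
#'   neighbour site indices
#' @export
#' @examples
#' tab <- build_square_lattice(4)
#' tab$degree           # 4
#' n_edges(tab)         # 32
build_square_lattice <- function(L) {
  check_L(L)
  L <- as.integer(L)
  n <- L * L
  site <- seq_len(n) - 1L
  r <- site %/% L
  c <- site %% L
  idx <- function(rr, cc) (rr %% L) * L + (cc %% L) + 1L
  neigh <- cbind(
    idx(r - 1L, c), idx(r + 1L, c), idx(r, c - 1L), idx(r, c + 1L)
  )
  new_neighbor_table(L, "square", neigh)
}

#' Build a periodic triangular (6-regular) lattice
#'
#' Realized as the square lattice plus one consistent diagonal pair per site,
#' `(+1, +1)` and `(-1, -1)`, which yields a 6-regular periodic lattice in
#' which every site sits in 6 triangles, hence a local clustering coefficient
#' of 6 / choose(6, 2) = 2/5 at every site.
#'
#' @inheritParams build_square_lattice
#' @return a `neighbor_table` with degree 6
#' @export
build_triangular_lattice <- function(L) {
  check_L(L)
  L <- as.integer(L)
  n <- L * L
  site <- seq_len(n) - 1L
  r <- site %/% L
  c <- site %% L
  idx <- function(rr, cc) (rr %% L) * L + (cc %% L) + 1L
  neigh <- cbind(
    idx(r - 1L, c), idx(r + 1L, c), idx(r, c - 1L), idx(r, c + 1L),
    idx(r + 1L, c + 1L), idx(r - 1L, c - 1L)
  )
  new_neighbor_table(L, "triangular", neigh)
}

#' Build a lattice by topology name
#'
#' @param topology `"square"` or `"triangular"`
#' @inheritParams build_square_lattice
#' @return a `neighbor_table`
#' @export
build_lattice <- function(topology = c("square", "triangular"), L) {
  topology <- match.arg(topology)
  switch(topology,
    square = build_square_lattice(L),
    triangular = build_triangular_lattice(L)
  )
}

new_neighbor_table <- function(L, topology, neigh) {
  structure(
    list(
      L = L, n_sites = L * L, degree = ncol(neigh),
      topology = topology, neigh = neigh
    ),
    class = "neighbor_table"
  )
}

check_L <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || L < 2 || L != round(L)) {
    stop_validation("`L` must be a single integer >= 2, got ", deparse(L))
  }
}

#' Number of undirected edges of a lattice
#'
#' Counts neighbour slots as interaction channels, so for `L = 2` (where wrap
#' duplicates slots) it still equals `degree * n_sites / 2`.
#'
#' @param table a `neighbor_table`
#' @return edge count
#' @export
n_edges <- function(table) {
  table$degree * table$n_sites / 2
}

#' @export
print.neighbor_table <- function(x, ...) {
  cat(sprintf(
    "<neighbor_table> %s lattice, L = %d (%d sites, degree %d)\n",
    x$topology, x$L, x$n_sites, x$degree
  ))
  invisible(x)
}

#' Convert (row, col) coordinates to a site index
#'
#' @param table a `neighbor_table`
#' @param row,col 0-based coordinates (wrapped periodically)
#' @return 1-based site index
#' @export
site_index <- function(table, row, col) {
  (row %% table$L) * table$L + (col %% table$L) + 1L
}

#' Randomly select the distinguished players and the inter-lattice partner map
#'
#' Marks exactly `round(rho * L^2)` sites per participating layer as
#' distinguished (possessing an external link to the other lattice), chosen
#' uniformly without replacement. The partner map is the coordinate-identity
#' map between the two layers.
#'
#' Modes: `"bilateral_paired"` (default) distinguishes the same coordinates on
#' both layers; `"bilateral_independent"` draws the two layers' distinguished
#' sets independently (so a distinguished player's partner is typically an
#' ordinary player); `"unilateral_A"` distinguishes sites on layer A only, so
#' extra utility flows in one direction.
#'
#' @param L lattice side length
#' @param rho fraction of distinguished players, in `[0, 1]`
#' @param mode link mode, see Details
#' @param seed integer seed (selection is deterministic given the seed)
#' @return a `link_assignment`: list with logical masks `distinguished_A`,
#'   `distinguished_B`, integer vector `partner` (identity), and `mode`
#' @export
#' @examples
#' la <- assign_interlinks(10, 0.5, seed = 1)
#' sum(la$distinguished_A)  # 50
assign_interlinks <- function(L,
                              rho,
                              mode = c(
                                "bilateral_paired", "bilateral_independent",
                                "unilateral_A"
                              ),
                              seed = 1L) {
  check_L(L)
  mode <- match.arg(mode)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1) {
    stop_validation("`rho` must be a single number in [0, 1], got ",
                    deparse(rho))
  }
  n <- as.integer(L)^2
  k <- round(rho * n)
  pick <- function(subseed) {
    mask <- logical(n)
    if (k > 0) {
      sel <- with_local_seed(subseed, sample.int(n, k))
      mask[sel] <- TRUE
    }
    mask
  }
  mask_a <- pick(derive_seed(seed, "links-A"))
  mask_b <- switch(mode,
    bilateral_paired = mask_a,
    bilateral_independent = pick(derive_seed(seed, "links-B")),
    unilateral_A = logical(n)
  )
  structure(
    list(
      distinguished_A = mask_a, distinguished_B = mask_b,
      partner = seq_len(n), mode = mode, rho = rho, L = as.integer(L)
    ),
    class = "link_assignment"
  )
}

#' @export
print.link_assignment <- function(x, ...) {
  cat(sprintf(
    "<link_assignment> mode %s, rho = %g: %d/%d distinguished on A, %d on B\n",
    x$mode, x$rho, sum(x$distinguished_A), length(x$distinguished_A),
    sum(x$distinguished_B)
  ))
  invisible(x)
}
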