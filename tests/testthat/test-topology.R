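test_that("square lattice has von Neumann neighbourhoods with periodic wrap", {
  tab <- build_square_lattice(4)
  expect_equal(tab$degree, 4L)
  expect_equal(tab$n_sites, 16L)
  expect_equal(n_edges(tab), 32)

  # interior site of L = 3: neighbours are the four axis-adjacent sites
  tab3 <- build_square_lattice(3)
  x <- site_index(tab3, 1, 1)
  expect_setequal(
    tab3$neigh[x, ],
    c(site_index(tab3, 0, 1), site_index(tab3, 2, 1),
      site_index(tab3, 1, 0), site_index(tab3, 1, 2))
  )

  # L = 2: wrap makes opposite directions coincide, neighbour slots duplicate
  tab2 <- build_square_lattice(2)
  x00 <- site_index(tab2, 0, 0)
  expect_equal(
    sort(tab2$neigh[x00, ]),
    sort(c(site_index(tab2, 0, 1), site_index(tab2, 0, 1),
           site_index(tab2, 1, 0), site_index(tab2, 1, 0)))
  )

  expect_error(build_square_lattice(1), "L")
})

test_that("triangular lattice is 6-regular with clustering coefficient 2/5", {
  tab <- build_triangular_lattice(10)
  expect_equal(tab$degree, 6L)
  expect_equal(n_edges(tab), 300)

  # count triangles through each site by enumeration: 6 of the 15 neighbour
  # pairs are themselves adjacent
  local_cc <- function(tab, x) {
    nb <- tab$neigh[x, ]
    pairs <- combn(nb, 2)
    adj <- sum(apply(pairs, 2, function(p) p[2] %in% tab$neigh[p[1], ]))
    adj / ncol(pairs)
  }
  ccs <- vapply(seq_len(tab$n_sites), local_cc, numeric(1), tab = tab)
  expect_true(all(abs(ccs - 0.4) < 1e-12))

  # independent check through igraph
  skip_if_not_installed("igraph")
  edges <- cbind(rep(seq_len(tab$n_sites), tab$degree), as.vector(tab$neigh))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  expect_equal(
    unname(igraph::transitivity(g, type = "local")),
    rep(0.4, tab$n_sites)
  )

  # the (-1, -1) diagonal wraps (0,0) onto (2,2) for L = 3
  tab3 <- build_triangular_lattice(3)
  expect_true(site_index(tab3, 2, 2) %in% tab3$neigh[site_index(tab3, 0, 0), ])
})

test_that("adjacency is symmetric and regular for both topologies", {
  for (topology in c("square", "triangular")) {
    for (L in c(3L, 5L, 8L)) {
      tab <- build_lattice(topology, L)
      expect_true(all(tab$neigh != row(tab$neigh)[, 1]))  # no self-loops
      expect_equal(ncol(tab$neigh), tab$degree)
      for (x in seq_len(tab$n_sites)) {
        for (y in tab$neigh[x, ]) {
          expect_true(x %in% tab$neigh[y, ])
        }
      }
    }
  }
})

test_that("interlink assignment draws exact counts per mode, reproducibly", {
  la <- assign_interlinks(10, 0.5, "bilateral_paired", seed = 7)
  expect_equal(sum(la$distinguished_A), 50)
  expect_identical(la$distinguished_A, la$distinguished_B)
  expect_identical(la$partner, 1:100)

  la2 <- assign_interlinks(10, 0.5, "bilateral_paired", seed = 7)
  expect_identical(la, la2)
  la3 <- assign_interlinks(10, 0.5, "bilateral_paired", seed = 8)
  expect_false(identical(la$distinguished_A, la3$distinguished_A))

  ind <- assign_interlinks(10, 0.3, "bilateral_independent", seed = 1)
  expect_equal(sum(ind$distinguished_A), 30)
  expect_equal(sum(ind$distinguished_B), 30)
  expect_false(identical(ind$distinguished_A, ind$distinguished_B))

  uni <- assign_interlinks(10, 0.3, "unilateral_A", seed = 1)
  expect_equal(sum(uni$distinguished_A), 30)
  expect_equal(sum(uni$distinguished_B), 0)

  # boundary densities
  expect_equal(sum(assign_interlinks(5, 0, seed = 1)$distinguished_A), 0)
  full <- assign_interlinks(5, 1, seed = 1)
  expect_true(all(full$distinguished_A) && all(full$distinguished_B))

  expect_error(assign_interlinks(10, 1.2, seed = 1), "rho")
})
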