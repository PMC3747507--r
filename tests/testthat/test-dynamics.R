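test_that("Fermi adoption probability matches the closed form", {
  expect_equal(fermi_adopt_prob(2, 2, K = 0.1), 0.5)
  expect_equal(fermi_adopt_prob(1, 2, K = 0.1), 1 / (1 + exp(-10)))
  expect_equal(fermi_adopt_prob(1, 2, K = 0.1, w_y = 0.05),
               0.05 / (1 + exp(-10)))
  # overflow-safe saturation
  expect_equal(fermi_adopt_prob(0, 1e6, K = 0.1), 1)
  expect_equal(fermi_adopt_prob(1e6, 0, K = 0.1), 0)
  # symmetry p(dU) + p(-dU) = w_y, and bounds
  for (du in c(0.1, 1, 5)) {
    for (w in c(1, 0.4)) {
      p1 <- fermi_adopt_prob(0, du, K = 0.1, w_y = w)
      p2 <- fermi_adopt_prob(du, 0, K = 0.1, w_y = w)
      expect_equal(p1 + p2, w)
      expect_true(p1 >= 0 && p1 <= w)
    }
  }
  # monotone in U_y - U_x
  du <- seq(-3, 3, by = 0.25)
  p <- fermi_adopt_prob(0, du, K = 0.1)
  expect_true(all(diff(p) > 0))
})

test_that("utility couples distinguished players to the partner's payoff", {
  cfg <- tiny_cfg(b = 1.05, alpha = 0.8, rho = 0.5)
  tab <- build_lattice("square", 3)
  # layer 1: cooperator at site 5 with 3 C + 1 D neighbours -> pi = 3
  s1 <- rep(1L, 9)
  s1[tab$neigh[5, 1]] <- 0L
  # layer 2: the partner site 5 is a defector with 2 C neighbours -> pi' = 2.1
  s2 <- rep(0L, 9)
  s2[tab$neigh[5, 1:2]] <- 1L
  dist <- matrix(FALSE, 9, 2)
  dist[5, ] <- TRUE
  st <- manual_state(cfg, cbind(s1, s2), dist)

  expect_equal(utility(5, 1, st, cfg), 3 + 0.8 * 2.1)  # = 4.68

  # with alpha = 0 the coupling vanishes for everyone
  cfg0 <- tiny_cfg(b = 1.05, alpha = 0, rho = 0.5)
  expect_equal(utility(5, 1, st, cfg0), 3)

  # ordinary players never see the other layer
  st_ord <- manual_state(cfg, cbind(s1, s2))
  expect_equal(utility(5, 1, st_ord, cfg), 3)
  s2_flipped <- 1L - s2
  st_flip <- manual_state(cfg, cbind(s1, s2_flipped))
  expect_equal(utility(5, 1, st_flip, cfg), utility(5, 1, st_ord, cfg))
})

test_that("proportional imitation is payoff-monotone with normalized slope", {
  # phi = (1 + alpha) * degree * payoff range = 4 * 1.05 at alpha = 0
  cfg <- tiny_cfg(b = 1.05, alpha = 0, rule = "proportional_imitation")
  expect_equal(cfg$phi, 4 * 1.05)

  tab <- build_lattice("square", 3)
  # focal x = lone defector with no cooperating neighbours (U = 0); its
  # neighbour y is a defector with 2 cooperating neighbours (U = 2.1)
  s <- rep(0L, 9)
  y <- tab$neigh[5, 1]
  s[setdiff(tab$neigh[y, ], c(5L, tab$neigh[5, ]))[1:2]] <- 1L
  st <- manual_state(cfg, s)
  expect_equal(utility(y, 1, st, cfg), 2.1)
  expect_equal(proportional_imitation_prob(5, y, 1, st, cfg), 0.5)
  # never adopts from a weaker or equal neighbour
  expect_equal(proportional_imitation_prob(y, 5, 1, st, cfg), 0)
})

test_that("best-takes-over keeps strict winners and breaks exact ties 50/50", {
  # all-C: every closed neighbourhood is homogeneous, strategy kept
  cfg <- tiny_cfg(b = 1.5, rule = "best_takes_over")
  st <- manual_state(cfg, rep(1L, 9))
  expect_equal(best_takes_over_update(5, 1, st, cfg), 1L)

  # frozen pattern: sites 1-4 cooperate, rest defect, b = 1.5; the closed
  # neighbourhood of site 1 has exactly two maximizers at U = 3, one C and
  # one D, so the tie rule must pick each with probability 1/2
  s <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)
  st <- manual_state(cfg, s)
  cand <- c(1, st$table$neigh[1, ])
  u <- vapply(cand, utility, numeric(1), layer = 1, state = st, cfg = cfg)
  best <- cand[u == max(u)]
  expect_equal(length(best), 2L)
  expect_setequal(st$strategies[best, 1], c(0L, 1L))

  set.seed(99)
  draws <- replicate(10000, best_takes_over_update(1, 1, st, cfg))
  # 3 sigma of a fair coin over 10^4 trials is 0.015
  expect_lt(abs(mean(draws) - 0.5), 0.02)
})

test_that("homogeneous states are absorbing under all three rules", {
  for (rule in c("fermi", "best_takes_over", "proportional_imitation")) {
    cfg <- tiny_cfg(b = 1.5, rule = rule, seed = 3)
    for (s0 in c(0L, 1L)) {
      st <- manual_state(cfg, cbind(rep(s0, 9), rep(s0, 9)))
      st2 <- run_elementary_steps(st, cfg, 200)
      expect_identical(st2$strategies, st$strategies)
    }
  }
})

test_that("strategies never flow between layers", {
  # layer B homogeneous all-D: no same-layer source of C exists, so B must
  # stay all-D no matter what happens on layer A or how strong the coupling
  cfg <- sim_config(L = 10L, b = 1.05, rho = 0.5, alpha = 1, mcs_relax = 0L,
                    mcs_sample = 10L, seed = 2)
  st <- init_state(cfg)
  st$strategies[, 2] <- 0L
  out <- run_mcs(st, cfg, 10)
  expect_true(all(out$state$strategies[, 2] == 0L))
  expect_true(any(out$state$strategies[, 1] == 1L))  # A still mixed
})

test_that("trajectories are reproducible seed-for-seed", {
  cfg <- sim_config(L = 10L, b = 1.05, rho = 0.4, alpha = 0.6,
                    mcs_relax = 0L, mcs_sample = 30L, seed = 17)
  r1 <- run_mcs(init_state(cfg), cfg, 30)
  r2 <- run_mcs(init_state(cfg), cfg, 30)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$state$strategies, r2$state$strategies)

  cfg2 <- cfg
  cfg2$seed <- 18
  r3 <- run_mcs(init_state(cfg2), cfg2, 30)
  expect_false(identical(r1$state$strategies, r3$state$strategies))
})

test_that("n_mcs = 0 records only the initial observation", {
  cfg <- sim_config(L = 5L, b = 1.05, mcs_relax = 0L, mcs_sample = 1L,
                    seed = 1)
  out <- run_mcs(init_state(cfg), cfg, 0)
  expect_equal(unique(out$trajectory$mcs), 0)
  expect_equal(nrow(out$trajectory), 3)  # two layers + pooled
})

test_that("all-defector duplex states are flagged absorbed with f_C = 0", {
  cfg <- sim_config(L = 4L, b = 1.5, rho = 0.5, mcs_relax = 0L,
                    mcs_sample = 5L, seed = 1)
  st <- manual_state(cfg, matrix(0L, 16, 2))
  out <- run_mcs(st, cfg, 5)
  expect_true(out$absorbed)
  expect_true(all(out$trajectory$f_C == 0))
})

test_that("alpha = 0 with alternating interleave reproduces isolated runs", {
  cfg <- sim_config(L = 8L, b = 1.1, rho = 0.4, alpha = 0,
                    interleave = "alternating", mcs_relax = 0L,
                    mcs_sample = 40L, seed = 23)
  duo <- run_mcs(init_state(cfg, layers = c(1L, 2L)), cfg, 40)
  iso1 <- run_mcs(init_state(cfg, layers = 1L), cfg, 40)
  iso2 <- run_mcs(init_state(cfg, layers = 2L), cfg, 40)
  expect_identical(duo$state$strategies[, 1], iso1$state$strategies[, 1])
  expect_identical(duo$state$strategies[, 2], iso2$state$strategies[, 1])
  # per-MCS cooperation series coincide as well
  expect_equal(
    duo$trajectory$f_C[duo$trajectory$layer == "1"],
    iso1$trajectory$f_C[iso1$trajectory$layer == "1"]
  )
})
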