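test_that("measure reports exact class-resolved cooperation fractions", {
  cfg <- tiny_cfg(rho = 0.5)
  st <- manual_state(cfg, cbind(rep(1L, 9), rep(1L, 9)))
  m <- measure(st)
  expect_true(all(m$f_C == 1))
  expect_true(all(m$f_C_int[!is.na(m$f_C_int)] == 1))

  # L = 2, strategies {C, C, D, D}, distinguished = the two cooperator sites
  cfg2 <- sim_config(L = 2L, b = 1.05, rho = 0.5, mcs_relax = 0L,
                     mcs_sample = 1L, seed = 1)
  s <- c(1L, 1L, 0L, 0L)
  dist <- c(TRUE, TRUE, FALSE, FALSE)
  st2 <- manual_state(cfg2, cbind(s, s), cbind(dist, dist))
  m2 <- measure(st2)
  pooled <- m2[m2$layer == "pooled", ]
  expect_equal(pooled$f_C, 0.5)
  expect_equal(pooled$f_C_int, 1)
  expect_equal(pooled$f_C_no, 0)

  # empty classes are reported as missing
  m_all <- measure(manual_state(tiny_cfg(rho = 0), cbind(s0 <- rep(1L, 9))))
  expect_true(all(is.na(m_all$f_C_int)))
})

test_that("pooled f_C decomposes exactly into the class-weighted mean", {
  for (seed in 1:3) {
    cfg <- sim_config(L = 6L, b = 1.1, rho = 0.3, alpha = 0.5,
                      mcs_relax = 0L, mcs_sample = 20L, seed = seed)
    out <- run_mcs(init_state(cfg), cfg, 20)
    traj <- out$trajectory
    n <- cfg$L^2
    n_int <- round(cfg$rho * n)
    for (layer in c("1", "2")) {
      sub <- traj[traj$layer == layer, ]
      recon <- (n_int * sub$f_C_int + (n - n_int) * sub$f_C_no) / n
      expect_equal(sub$f_C, recon, tolerance = 1e-12)
    }
  }
})

test_that("stationary averages summarize the tail window", {
  mk_traj <- function(fc) {
    data.frame(mcs = seq_along(fc), layer = "pooled", f_C = fc,
               f_C_int = fc, f_C_no = fc)
  }
  s <- stationary_mean(mk_traj(rep(0.37, 50)), 20)
  expect_equal(s$mean_fC, 0.37)
  expect_equal(s$sd_fC, 0)

  s2 <- stationary_mean(mk_traj(rep(c(0.3, 0.5), 10)), 20)
  expect_equal(s2$mean_fC, 0.4)

  s3 <- stationary_mean(mk_traj(rep(0, 10)), 10)  # absorbed all-D
  expect_equal(s3$mean_fC, 0)
  expect_equal(s3$sd_fC, 0)

  expect_error(stationary_mean(mk_traj(rep(0.5, 5)), 10), "sample_window")
})

test_that("critical-b bisection recovers a mock extinction threshold", {
  cfg <- tiny_cfg(b = 1.05)
  mock <- function(b, replicate) b < 1.07

  est <- estimate_critical_b(cfg, 1.0, 1.2, tol = 0.001, replicates = 3,
                             survival_fn = mock)
  expect_lt(abs(est$b_c - 1.07), 0.001)
  expect_lte(est$width, 0.001)

  # degenerate bracket
  est0 <- estimate_critical_b(cfg, 1.05, 1.05, survival_fn = mock)
  expect_equal(est0$b_c, 1.05)
  expect_equal(est0$width, 0)

  # enlarging the bracket never moves the estimate outside the original one
  est_wide <- estimate_critical_b(cfg, 0.9, 1.5, tol = 0.001, replicates = 3,
                                  survival_fn = mock)
  expect_gte(est_wide$b_c, 1.0)
  expect_lte(est_wide$b_c, 1.2)
  expect_lt(abs(est_wide$b_c - 1.07), 0.002)

  # invalid bracket raises a classed error carrying the diagnostic runs
  err <- tryCatch(
    estimate_critical_b(cfg, 1.1, 1.2, survival_fn = mock),
    dg_bracket_error = function(e) e
  )
  expect_s3_class(err, "dg_bracket_error")
  expect_true(is.data.frame(err$evaluations))
})
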