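#' Cooperation levels of the current state
#'
#' Exact counts, no sampling: the overall fraction of cooperators `f_C`, the
#' fraction among distinguished players `f_C_int` (those with an external
#' link), and among ordinary players `f_C_no`, per layer and pooled across
#' layers. `f_C_int` is `NA` when a class is empty (`rho = 0`), likewise
#' `f_C_no` when `rho = 1`.
#'
#' @param state a `duplex_state`
#' @return a data frame with one row per layer plus a pooled row, columns
#'   `mcs`, `layer`, `f_C`, `f_C_int`, `f_C_no`
#' @export
measure <- function(state) {
  n <- state$table$n_sites
  k <- ncol(state$strategies)
  nC <- colSums(state$strategies == 1L)
  nCd <- vapply(seq_len(k), function(j) {
    sum(state$strategies[state$dist[, j], j] == 1L)
  }, numeric(1))
  counts_to_trajectory(
    matrix(as.numeric(rbind(nC, nCd)), nrow = 1),
    n_sites = n, n_dist = colSums(state$dist),
    layer_ids = state$layer_ids, mcs = state$mcs_elapsed
  )
}

# records: matrix with one row per record, columns (nC, nCd) per layer
counts_to_trajectory <- function(records, n_sites, n_dist, layer_ids, mcs) {
  k <- length(layer_ids)
  frac <- function(num, den) {
    if (den > 0) num / den else rep(NA_real_, length(num))
  }
  out <- vector("list", k + 1L)
  for (j in seq_len(k)) {
    nC <- records[, 2 * j - 1]
    nCd <- records[, 2 * j]
    nd <- n_dist[j]
    out[[j]] <- data.frame(
      mcs = mcs, layer = as.character(layer_ids[j]),
      f_C = nC / n_sites,
      f_C_int = frac(nCd, nd),
      f_C_no = frac(nC - nCd, n_sites - nd)
    )
  }
  nC_tot <- rowSums(records[, 2 * seq_len(k) - 1, drop = FALSE])
  nCd_tot <- rowSums(records[, 2 * seq_len(k), drop = FALSE])
  nd_tot <- sum(n_dist)
  out[[k + 1L]] <- data.frame(
    mcs = mcs, layer = "pooled",
    f_C = nC_tot / (k * n_sites),
    f_C_int = frac(nCd_tot, nd_tot),
    f_C_no = frac(nC_tot - nCd_tot, k * n_sites - nd_tot)
  )
  res <- do.call(rbind, out)
  res <- res[order(res$mcs), , drop = FALSE]
  rownames(res) <- NULL
  res
}

records_to_trajectory <- function(records, state, mcs0) {
  counts_to_trajectory(
    records,
    n_sites = state$table$n_sites,
    n_dist = colSums(state$dist),
    layer_ids = state$layer_ids,
    mcs = mcs0 + seq_len(nrow(records)) - 1L
  )
}

#' Stationary time averages of a trajectory
#'
#' Averages `f_C`, `f_C_int` and `f_C_no` over the final `sample_window`
#' per-MCS records of each layer (and the pooled series). For an absorbed
#' trajectory the records are constant, so the mean is the absorbing value
#' and the sd is 0.
#'
#' @param traj a trajectory data frame as returned by [run_mcs()]
#' @param sample_window number of final records to average over
#' @return a data frame with one row per layer, columns `layer`, `n_records`,
#'   and mean/sd of each cooperation fraction
#' @export
stationary_mean <- function(traj, sample_window) {
  stopifnot(is.data.frame(traj), sample_window >= 1)
  layers <- unique(traj$layer)
  rows <- lapply(layers, function(l) {
    sub <- traj[traj$layer == l, , drop = FALSE]
    sub <- sub[order(sub$mcs), , drop = FALSE]
    if (nrow(sub) < sample_window) {
      stop_validation(
        "sample_window (", sample_window, ") exceeds trajectory length (",
        nrow(sub), ") for layer ", l
      )
    }
    sub <- sub[seq(nrow(sub) - sample_window + 1L, nrow(sub)), , drop = FALSE]
    sd0 <- function(v) if (all(is.na(v))) NA_real_ else sd(v, na.rm = TRUE)
    mean0 <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    data.frame(
      layer = l, n_records = nrow(sub),
      mean_fC = mean0(sub$f_C), sd_fC = sd0(sub$f_C),
      mean_fC_int = mean0(sub$f_C_int), sd_fC_int = sd0(sub$f_C_int),
      mean_fC_no = mean0(sub$f_C_no), sd_fC_no = sd0(sub$f_C_no)
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Estimate the critical temptation to defect by bisection
#'
#' Cooperators survive at temptation `b` when the mean stationary pooled
#' cooperation fraction exceeds the extinction threshold `eps` in at least
#' half of the replicate runs. The estimator bisects on `b` between a bracket
#' where survival holds at `b_lo` and fails at `b_hi`, and returns the final
#' bracket midpoint and width.
#'
#' On a finite lattice extinction is absorbing, so any `eps` below the
#' single-site resolution `1 / L^2` identifies the same event; `eps` and the
#' replicate count are exposed for sensitivity checks.
#'
#' @param cfg a [sim_config()] template; `b` is overridden during the scan
#' @param b_lo,b_hi initial bracket, `b_lo <= b_hi`
#' @param tol bracket width at which bisection stops
#' @param replicates independent runs (distinct derived seeds) per `b`
#' @param eps extinction threshold on the mean stationary `f_C`
#' @param survival_fn optional override: `function(b, replicate)` returning
#'   `TRUE` when cooperators survive; used to test the estimator against a
#'   mock simulator
#' @return list with `b_c` (bracket midpoint), `width`, `bracket`, and
#'   `evaluations`, a data frame of all (b, replicate, survived) evaluations
#' @export
estimate_critical_b <- function(cfg, b_lo, b_hi, tol = 0.01, replicates = 5,
                                eps = 1e-3, survival_fn = NULL) {
  stopifnot(b_lo <= b_hi, tol > 0, replicates >= 1)
  evals <- list()
  if (is.null(survival_fn)) {
    survival_fn <- function(b, replicate) {
      cfg_b <- cfg
      cfg_b$b <- b
      cfg_b$matrix <- pd_matrix(b, cfg$S)
      cfg_b$seed <- derive_seed(
        cfg$seed, sprintf("critb-%.10f-%d", b, replicate)
      )
      res <- run_duplex(cfg_b)
      pooled <- res$summary[res$summary$layer == "pooled", ]
      pooled$mean_fC > eps
    }
  }
  majority_survives <- function(b) {
    hits <- vapply(seq_len(replicates), function(rep) {
      isTRUE(survival_fn(b, rep))
    }, logical(1))
    evals[[length(evals) + 1L]] <<- data.frame(
      b = b, replicate = seq_len(replicates), survived = hits
    )
    mean(hits) >= 0.5
  }
  if (b_lo == b_hi) {
    return(list(b_c = b_lo, width = 0, bracket = c(b_lo, b_hi),
                evaluations = NULL))
  }
  lo_ok <- majority_survives(b_lo)
  hi_ok <- majority_survives(b_hi)
  if (!lo_ok || hi_ok) {
    cond <- structure(
      class = c("dg_bracket_error", "error", "condition"),
      list(
        message = sprintf(
          paste0(
            "invalid bracket: survival at b_lo = %g is %s, at b_hi = %g is ",
            "%s (need survival at b_lo and extinction at b_hi)"
          ),
          b_lo, lo_ok, b_hi, hi_ok
        ),
        call = sys.call(-1), evaluations = do.call(rbind, evals)
      )
    )
    stop(cond)
  }
  while (b_hi - b_lo > tol) {
    mid <- (b_lo + b_hi) / 2
    if (majority_survives(mid)) b_lo <- mid else b_hi <- mid
  }
  list(
    b_c = (b_lo + b_hi) / 2, width = b_hi - b_lo, bracket = c(b_lo, b_hi),
    evaluations = do.call(rbind, evals)
  )
}
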