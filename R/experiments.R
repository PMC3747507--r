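
# seed for one sweep cell: depends only on the master seed and the cell
# coordinates, never on evaluation order
cell_seed <- function(seed, rho, alpha, b, variant, replicate) {
  derive_seed(seed, sprintf(
    "cell-%.10f-%.10f-%.10f-%s-%d", rho, alpha, b, variant, replicate
  ))
}

# run one configured cell, returning the pooled stationary summary
run_cell <- function(cfg, overrides, variant, replicate) {
  keys <- overrides
  keys$seed <- cell_seed(
    cfg$seed,
    rho = if (!is.null(overrides$rho)) overrides$rho else cfg$rho,
    alpha = if (!is.null(overrides$alpha)) overrides$alpha else cfg$alpha,
    b = if (!is.null(overrides$b)) overrides$b else if (is.na(cfg$b)) 0
        else cfg$b,
    variant = variant, replicate = replicate
  )
  cfg_cell <- do.call(sim_config, modifyList(config_as_list(cfg), keys))
  res <- run_duplex(cfg_cell)
  pooled <- res$summary[res$summary$layer == "pooled", ]
  list(mean_fC = pooled$mean_fC, sd_fC = pooled$sd_fC,
       absorbed = res$absorbed, seed = cfg_cell$seed)
}

# user-settable keys of a sim_config, for rebuilding with overrides
config_as_list <- function(cfg) {
  keys <- cfg[intersect(config_keys(), names(cfg))]
  if (cfg$game == "PD") keys$r <- NULL else keys$b <- NULL
  keys[!vapply(keys, function(v) is.null(v) || all(is.na(v)), logical(1))]
}

#' Sweep the interdependence parameters rho and alpha
#'
#' Runs `replicates` independent simulations per grid cell (distinct derived
#' seeds per cell and replicate) and records the pooled stationary cooperation
#' level. Per-cell failures are caught and reported in the result rather than
#' aborting the grid.
#'
#' @param cfg a [sim_config()] template (its `rho`/`alpha` are overridden)
#' @param rho_grid,alpha_grid numeric grids within `[0, 1]`
#' @param replicates independent runs per cell
#' @return a `sweep_result` data frame in long format with columns `rho`,
#'   `alpha`, `b`, `variant`, `replicate`, `mean_fC`, `sd_fC`, `absorbed`,
#'   `seed`, `error`; the configuration template and master seed are attached
#'   as attributes
#' @export
sweep_rho_alpha <- function(cfg, rho_grid, alpha_grid, replicates = 3) {
  stopifnot(length(rho_grid) >= 1, length(alpha_grid) >= 1,
            all(rho_grid >= 0 & rho_grid <= 1),
            all(alpha_grid >= 0 & alpha_grid <= 1))
  grid <- expand.grid(
    rho = rho_grid, alpha = alpha_grid, replicate = seq_len(replicates),
    KEEP.OUT.ATTRS = FALSE
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    base <- data.frame(
      rho = g$rho, alpha = g$alpha,
      b = if (is.na(cfg$b)) NA_real_ else cfg$b,
      variant = "base", replicate = g$replicate,
      mean_fC = NA_real_, sd_fC = NA_real_, absorbed = NA, seed = NA_real_,
      error = NA_character_
    )
    out <- tryCatch(
      run_cell(cfg, list(rho = g$rho, alpha = g$alpha), "base", g$replicate),
      error = function(e) e
    )
    if (inherits(out, "error")) {
      base$error <- conditionMessage(out)
    } else {
      base$mean_fC <- out$mean_fC
      base$sd_fC <- out$sd_fC
      base$absorbed <- out$absorbed
      base$seed <- out$seed
    }
    base
  })
  res <- do.call(rbind, rows)
  structure(res, class = c("sweep_result", "data.frame"),
            template = cfg, master_seed = cfg$seed)
}

#' Scan the temptation to defect for a family of model variants
#'
#' Each variant is a named list of configuration overrides (e.g.
#' `list(alpha = 0.5, w_dist = 0.05)` or `list(link_mode = "unilateral_A")`);
#' every variant is evaluated over the same `b_grid` with `replicates`
#' independent runs per point.
#'
#' @param cfg a [sim_config()] template (PD game)
#' @param variants named list of override lists
#' @param b_grid temptation values, each in `(1, 2]`
#' @param replicates independent runs per (variant, b) cell
#' @return a `sweep_result` data frame (long format, one row per replicate)
#' @export
scan_b <- function(cfg, variants, b_grid, replicates = 3) {
  stopifnot(length(b_grid) >= 1, length(variants) >= 1,
            !is.null(names(variants)), all(nzchar(names(variants))))
  rows <- list()
  for (v in names(variants)) {
    for (b in b_grid) {
      for (rep in seq_len(replicates)) {
        overrides <- modifyList(variants[[v]], list(b = b))
        base <- data.frame(
          rho = if (!is.null(overrides$rho)) overrides$rho else cfg$rho,
          alpha = if (!is.null(overrides$alpha)) overrides$alpha
                  else cfg$alpha,
          b = b, variant = v, replicate = rep,
          mean_fC = NA_real_, sd_fC = NA_real_, absorbed = NA,
          seed = NA_real_, error = NA_character_
        )
        out <- tryCatch(run_cell(cfg, overrides, v, rep),
                        error = function(e) e)
        if (inherits(out, "error")) {
          base$error <- conditionMessage(out)
        } else {
          base$mean_fC <- out$mean_fC
          base$sd_fC <- out$sd_fC
          base$absorbed <- out$absorbed
          base$seed <- out$seed
        }
        rows[[length(rows) + 1L]] <- base
      }
    }
  }
  res <- do.call(rbind, rows)
  structure(res, class = c("sweep_result", "data.frame"),
            template = cfg, master_seed = cfg$seed)
}

#' Locate the cooperation-optimal fraction of distinguished players
#'
#' Evaluates the mean stationary cooperation level over a grid of `rho`
#' values and returns the argmax together with a bootstrap standard error and
#' a non-monotonicity certificate: `TRUE` when the peak exceeds both grid
#' endpoints by more than twice the pooled standard error, i.e. when the
#' optimum is demonstrably interior.
#'
#' @param cfg a [sim_config()] template
#' @param rho_grid at least 3 grid points in `[0, 1]`
#' @param replicates independent runs per grid point
#' @param n_boot bootstrap resamples for the standard error of each mean
#' @param runner optional override: `function(rho, replicate)` returning a
#'   mean stationary `f_C`; used to test the search against a mock response
#' @return list with `rho_opt`, `fC_opt`, `se_opt`, `certificate` (logical),
#'   and `table`, the per-rho summary (mean, bootstrap se, replicate count)
#' @export
find_optimal_rho <- function(cfg, rho_grid, replicates = 3, n_boot = 200,
                             runner = NULL) {
  stopifnot(length(rho_grid) >= 3, all(rho_grid >= 0 & rho_grid <= 1))
  rho_grid <- sort(rho_grid)
  if (is.null(runner)) {
    runner <- function(rho, replicate) {
      run_cell(cfg, list(rho = rho), "rho-opt", replicate)$mean_fC
    }
  }
  per_rho <- lapply(rho_grid, function(rho) {
    vapply(seq_len(replicates), function(rep) runner(rho, rep), numeric(1))
  })
  boot_se <- function(v) {
    if (length(v) == 1L) return(0)
    means <- vapply(seq_len(n_boot), function(i) {
      mean(v[sample.int(length(v), length(v), replace = TRUE)])
    }, numeric(1))
    sd(means)
  }
  tab <- data.frame(
    rho = rho_grid,
    mean_fC = vapply(per_rho, mean, numeric(1)),
    se_fC = with_local_seed(
      derive_seed(cfg$seed, "rho-opt-boot"),
      vapply(per_rho, boot_se, numeric(1))
    ),
    n_replicates = replicates
  )
  i_opt <- which.max(tab$mean_fC)
  pooled_se <- function(i, j) sqrt(tab$se_fC[i]^2 + tab$se_fC[j]^2)
  n <- nrow(tab)
  certificate <- i_opt > 1L && i_opt < n &&
    (tab$mean_fC[i_opt] - tab$mean_fC[1]) > 2 * pooled_se(i_opt, 1L) &&
    (tab$mean_fC[i_opt] - tab$mean_fC[n]) > 2 * pooled_se(i_opt, n)
  list(
    rho_opt = tab$rho[i_opt], fC_opt = tab$mean_fC[i_opt],
    se_opt = tab$se_fC[i_opt], certificate = certificate, table = tab
  )
}
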