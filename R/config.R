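
# classed conditions so the CLI can map validation failures to exit code 1
stop_validation <- function(...) {
  msg <- paste0(...)
  stop(structure(
    class = c("dg_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Simulation configuration
#'
#' Collects every model and run parameter, validates ranges, and fills
#' defaults. The defaults are the baseline model: prisoner's dilemma on two
#' square lattices with Fermi updating at selection noise `K = 0.1`, full
#' teaching activity for everyone, paired bilateral interdependence, and
#' pooled asynchronous drawing of the focal player from both layers.
#'
#' @param L lattice side length (default 100)
#' @param topology `"square"` or `"triangular"`
#' @param game `"PD"` or `"SD"`
#' @param b PD temptation to defect (`1 < b <= 2`); used when `game = "PD"`
#' @param r SD cost-to-benefit ratio (`0 < r <= 1`); used when `game = "SD"`
#' @param S PD sucker's payoff override (default 0)
#' @param rho fraction of distinguished players per layer, in `[0, 1]`
#' @param alpha external-link strength, in `[0, 1]`
#' @param rule `"fermi"`, `"best_takes_over"` or `"proportional_imitation"`
#' @param K Fermi selection noise, `K > 0` (default 0.1)
#' @param w_dist,w_ord teaching activity (multiplier on the adoption
#'   probability of the role model) for distinguished / ordinary players, in
#'   `(0, 1]` (defaults 1)
#' @param link_mode `"bilateral_paired"`, `"bilateral_independent"` or
#'   `"unilateral_A"`
#' @param interleave `"pooled"` (focal layer drawn uniformly per elementary
#'   step) or `"alternating"` (layers visited round-robin; preserves exact
#'   per-layer stream alignment with isolated runs)
#' @param phi proportional-imitation normalization; default
#'   `(1 + alpha) * degree * (max(T,R,P,S) - min(T,R,P,S))`, the maximum
#'   admissible utility difference, which guarantees probabilities in `[0, 1]`
#' @param mcs_relax relaxation Monte Carlo steps before sampling
#' @param mcs_sample sampled Monte Carlo steps for stationary averages
#' @param seed integer master seed; all streams are derived from it
#' @return a validated `sim_config` list
#' @export
#' @examples
#' cfg <- sim_config(L = 20, b = 1.05, rho = 0.3, alpha = 0.8,
#'                   mcs_relax = 50, mcs_sample = 20, seed = 1)
sim_config <- function(L = 100L,
                       topology = c("square", "triangular"),
                       game = c("PD", "SD"),
                       b = 1.05,
                       r = 0.3,
                       S = 0,
                       rho = 0.5,
                       alpha = 0.5,
                       rule = c(
                         "fermi", "best_takes_over", "proportional_imitation"
                       ),
                       K = 0.1,
                       w_dist = 1,
                       w_ord = 1,
                       link_mode = c(
                         "bilateral_paired", "bilateral_independent",
                         "unilateral_A"
                       ),
                       interleave = c("pooled", "alternating"),
                       phi = NULL,
                       mcs_relax = 10000L,
                       mcs_sample = 2000L,
                       seed = 1L) {
  check_L(L)
  topology <- match.arg(topology)
  game <- match.arg(game)
  rule <- match.arg(rule)
  link_mode <- match.arg(link_mode)
  interleave <- match.arg(interleave)

  M <- if (game == "PD") pd_matrix(b, S) else sd_matrix_from_r(r)

  check_range <- function(value, name, lo, hi, lo_open = FALSE) {
    bad <- !is.numeric(value) || length(value) != 1L || is.na(value) ||
      value > hi || (if (lo_open) value <= lo else value < lo)
    if (bad) {
      stop_validation(sprintf(
        "`%s` must be a single number in %s%g, %g], got %s",
        name, if (lo_open) "(" else "[", lo, hi, deparse(value)
      ))
    }
  }
  check_range(rho, "rho", 0, 1)
  check_range(alpha, "alpha", 0, 1)
  check_range(K, "K", 0, Inf, lo_open = TRUE)
  check_range(w_dist, "w_dist", 0, 1, lo_open = TRUE)
  check_range(w_ord, "w_ord", 0, 1, lo_open = TRUE)
  if (!is.numeric(mcs_relax) || mcs_relax < 0 || mcs_relax != round(mcs_relax))
    stop_validation("`mcs_relax` must be a non-negative integer")
  if (!is.numeric(mcs_sample) || mcs_sample < 1 ||
      mcs_sample != round(mcs_sample))
    stop_validation("`mcs_sample` must be a positive integer")
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop_validation("`seed` must be a single integer")

  degree <- if (topology == "square") 4L else 6L
  pay <- c(M$T, M$R, M$P, M$S)
  phi_default <- (1 + alpha) * degree * (max(pay) - min(pay))
  if (is.null(phi)) phi <- phi_default
  check_range(phi, "phi", 0, Inf, lo_open = TRUE)

  structure(
    list(
      L = as.integer(L), topology = topology, game = game,
      b = if (game == "PD") b else NA_real_,
      r = if (game == "SD") r else NA_real_,
      S = S, matrix = M, rho = rho, alpha = alpha, rule = rule, K = K,
      w_dist = w_dist, w_ord = w_ord, link_mode = link_mode,
      interleave = interleave, phi = phi, degree = degree,
      mcs_relax = as.integer(mcs_relax), mcs_sample = as.integer(mcs_sample),
      seed = as.double(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  gp <- if (x$game == "PD") sprintf("b = %g, S = %g", x$b, x$S)
        else sprintf("r = %g", x$r)
  cat(sprintf(
    paste0(
      "<sim_config> %s on %s lattice L = %d (%s)\n",
      "  rho = %g, alpha = %g, link_mode = %s\n",
      "  rule = %s (K = %g, w_dist = %g, w_ord = %g)\n",
      "  mcs_relax = %d, mcs_sample = %d, seed = %.0f\n"
    ),
    x$game, x$topology, x$L, gp, x$rho, x$alpha, x$link_mode,
    x$rule, x$K, x$w_dist, x$w_ord, x$mcs_relax, x$mcs_sample, x$seed
  ))
  invisible(x)
}

# Config keys a user may set (in a config file or as CLI overrides).
config_keys <- function() {
  c(
    "L", "topology", "game", "b", "r", "S", "rho", "alpha", "rule", "K",
    "w_dist", "w_ord", "link_mode", "interleave", "phi",
    "mcs_relax", "mcs_sample", "seed"
  )
}

#' Build a simulation configuration from a file and/or overrides
#'
#' Reads a flat key-value YAML file, applies overrides (CLI flags take
#' precedence over file keys), rejects unknown keys, validates everything
#' through [sim_config()], and warns when a parameter is set that the chosen
#' update rule ignores (`K` or teaching activity outside the Fermi rule).
#'
#' @param path path to a YAML config file, or `NULL`
#' @param overrides named list of config values taking precedence over the file
#' @return a validated `sim_config`
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  keys <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_validation("config file not found: ", path)
    file_keys <- yaml::read_yaml(path)
    if (!is.list(file_keys) && !is.null(file_keys))
      stop_validation("config file must be a flat key: value mapping")
    keys <- as.list(file_keys)
  }
  if (length(overrides))
    keys <- modifyList(keys, overrides[!vapply(overrides, is.null, TRUE)])

  unknown <- setdiff(names(keys), config_keys())
  if (length(unknown)) {
    stop_validation(
      "unknown config key(s): ", paste(unknown, collapse = ", "),
      "; admissible keys: ", paste(config_keys(), collapse = ", ")
    )
  }
  cfg <- do.call(sim_config, keys)
  if (cfg$rule != "fermi") {
    for (k in intersect(names(keys), c("K", "w_dist", "w_ord"))) {
      warning(sprintf("`%s` is set but unused under rule `%s`", k, cfg$rule),
              call. = FALSE)
    }
  }
  cfg
}
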