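#' Prisoner's dilemma payoff matrix
#'
#' Parameterized by the temptation to defect `b`: a defector exploiting a
#' cooperator earns `T = b`, mutual cooperation pays `R = 1`, mutual defection
#' `P = 0`, and the exploited cooperator receives the sucker's payoff
#' `S` (0 by default, the weak-dilemma convention; exposed for sensitivity
#' runs). `1 < b <= 2` keeps the payoff ranking a proper dilemma.
#'
#' @param b temptation to defect, `1 < b <= 2`
#' @param S sucker's payoff override, `-1 <= S <= 0` (default 0)
#' @return a `game_matrix`: list with `T`, `R`, `P`, `S` and the game label
#' @export
#' @examples
#' pd_matrix(1.05)
pd_matrix <- function(b, S = 0) {
  if (!is.numeric(b) || length(b) != 1L || b <= 1 || b > 2) {
    stop_validation("`b` must be a single number with 1 < b <= 2, got ",
                    deparse(b))
  }
  if (!is.numeric(S) || length(S) != 1L || S < -1 || S > 0) {
    stop_validation("`S` must be a single number in [-1, 0], got ", deparse(S))
  }
  structure(
    list(T = b, R = 1, P = 0, S = S, game = "PD", b = b),
    class = "game_matrix"
  )
}

#' Snowdrift payoff matrix from the cost-to-benefit ratio
#'
#' The snowdrift game uses `T = beta`, `R = beta - 1/2`, `S = beta - 1`,
#' `P = 0`, with the dilemma strength expressed through the cost-to-benefit
#' ratio `r = 1 / (2 beta - 1)`, i.e. `beta = (1 + 1/r) / 2`. For
#' `0 < r < 1` the snowdrift ranking `T > R > S > P` holds.
#'
#' @param r cost-to-benefit ratio, `0 < r <= 1`
#' @return a `game_matrix`
#' @export
#' @examples
#' sd_matrix_from_r(0.3)
sd_matrix_from_r <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1) {
    stop_validation("`r` must be a single number with 0 < r <= 1, got ",
                    deparse(r))
  }
  beta <- (1 + 1 / r) / 2
  structure(
    list(T = beta, R = beta - 0.5, P = 0, S = beta - 1, game = "SD",
         r = r, beta = beta),
    class = "game_matrix"
  )
}

#' @export
print.game_matrix <- function(x, ...) {
  cat(sprintf(
    "<game_matrix> %s: T = %g, R = %g, P = %g, S = %g\n",
    x$game, x$T, x$R, x$P, x$S
  ))
  invisible(x)
}

# pairwise payoff of a player with strategy sx against sy (1 = C, 0 = D),
# vectorized over sx/sy
pair_payoff <- function(M, sx, sy) {
  n <- max(length(sx), length(sy))
  sx <- rep_len(sx, n)
  sy <- rep_len(sy, n)
  ifelse(sx == 1L,
         ifelse(sy == 1L, M$R, M$S),
         ifelse(sy == 1L, M$T, M$P))
}

#' Nearest-neighbour payoff of one player
#'
#' Sums the pairwise game payoff of site `x` against each of its lattice
#' neighbours on its own layer, given the instantaneous strategy
#' configuration. Pure reference implementation in R; the Monte Carlo engine
#' recomputes the same quantity in compiled code.
#'
#' @param x 1-based site index
#' @param layer layer index (column of the strategy matrix)
#' @param state a `duplex_state` (see [init_state()])
#' @param M a `game_matrix`
#' @param table a `neighbor_table` (defaults to the state's own)
#' @return the payoff `pi_x`
#' @export
accumulate_payoff <- function(x, layer, state, M, table = state$table) {
  sx <- state$strategies[x, layer]
  sy <- state$strategies[table$neigh[x, ], layer]
  sum(pair_payoff(M, sx, sy))
}
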