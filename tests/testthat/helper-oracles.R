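# Exhaustive enumeration of the single-elementary-step outcome distribution.
#
# An outcome is either "none" (state unchanged) or "l<layer>:x<site>:<s>"
# (site x on layer l now holds strategy s). Probabilities follow the chain
# focal-layer (uniform, pooled drawing) -> focal site (uniform) -> role model
# (uniform neighbour, or closed-neighbourhood argmax for best-takes-over) ->
# adoption probability of the configured rule, evaluated with the R reference
# implementations (utility, fermi_adopt_prob, proportional_imitation_prob) --
# a route fully independent of the compiled engine.
outcome_key <- function(l, x, s) sprintf("l%d:x%d:%d", l, x, s)

enumerate_step_dist <- function(state, cfg) {
  n <- state$table$n_sites
  k <- ncol(state$strategies)
  deg <- state$table$degree
  probs <- c(none = 0)
  add <- function(key, p) {
    probs[key] <<- if (key %in% names(probs)) probs[[key]] + p else p
  }
  for (l in seq_len(k)) {
    for (x in seq_len(n)) {
      px <- 1 / (k * n)
      sx <- state$strategies[x, l]
      if (cfg$rule == "best_takes_over") {
        cand <- c(x, state$table$neigh[x, ])
        u <- vapply(cand, utility, numeric(1), layer = l, state = state,
                    cfg = cfg)
        best <- cand[u == max(u)]
        for (s in unique(state$strategies[best, l])) {
          p_s <- mean(state$strategies[best, l] == s)
          if (s == sx) add("none", px * p_s)
          else add(outcome_key(l, x, s), px * p_s)
        }
      } else {
        for (j in seq_len(deg)) {
          y <- state$table$neigh[x, j]
          py <- px / deg
          sy <- state$strategies[y, l]
          p <- if (cfg$rule == "fermi") {
            fermi_adopt_prob(
              utility(x, l, state, cfg), utility(y, l, state, cfg),
              K = cfg$K,
              w_y = if (state$dist[y, l]) cfg$w_dist else cfg$w_ord
            )
          } else {
            proportional_imitation_prob(x, y, l, state, cfg)
          }
          if (sy == sx) {
            add("none", py)
          } else {
            add(outcome_key(l, x, sy), py * p)
            add("none", py * (1 - p))
          }
        }
      }
    }
  }
  probs
}

# Empirical outcome frequencies of single engine steps from a fixed state,
# one independent derived seed per trial.
empirical_step_dist <- function(state, cfg, n_trials, seed = 1) {
  n <- state$table$n_sites
  keys <- character(n_trials)
  for (i in seq_len(n_trials)) {
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(seed, sprintf("trial-%d", i))
    st2 <- run_elementary_steps(state, cfg_i, 1)
    changed <- which(st2$strategies != state$strategies)
    keys[i] <- if (!length(changed)) {
      "none"
    } else {
      x <- (changed[1] - 1L) %% n + 1L
      l <- (changed[1] - 1L) %/% n + 1L
      outcome_key(l, x, st2$strategies[x, l])
    }
  }
  table(keys)
}

# Pearson chi-squared goodness-of-fit p-value against enumerated
# probabilities, pooling categories with expected count < 5.
chisq_pvalue <- function(observed, probs, n_trials) {
  all_keys <- names(probs)
  obs <- setNames(numeric(length(all_keys)), all_keys)
  obs[names(observed)] <- as.numeric(observed)
  expected <- probs * n_trials
  pool <- expected < 5
  if (any(pool)) {
    obs <- c(obs[!pool], pooled = sum(obs[pool]))
    expected <- c(expected[!pool], pooled = sum(expected[pool]))
  }
  keep <- expected > 0
  obs <- obs[keep]
  expected <- expected[keep]
  x2 <- sum((obs - expected)^2 / expected)
  stats::pchisq(x2, df = length(obs) - 1, lower.tail = FALSE)
}
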