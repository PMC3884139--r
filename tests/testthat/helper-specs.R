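# shared fixtures, all built in code

two_state_spec <- function() {
  pm_spec(states = c("alive", "dead"),
          transitions = data.frame(from = 1, to = 2),
          baselines = list(bl_constant(labels = "lam")))
}

three_state_spec <- function() {
  # adjacent-reversible 3-state chain
  pm_spec(states = c("a", "b", "c"),
          transitions = data.frame(from = c(1, 2, 2, 3), to = c(2, 1, 3, 2)),
          baselines = list(bl_constant(labels = "l12"),
                           bl_constant(labels = "l21"),
                           bl_constant(labels = "l23"),
                           bl_constant(labels = "l32")))
}

three_state_rates <- c(l12 = 0.2, l21 = 0.1, l23 = 0.3, l32 = 0.4)

# brute-force forward likelihood by enumeration over all hidden sequences
brute_force_forward <- function(spec, params, times, codes, zmat = NULL,
                                init, condition = 0) {
  ns <- spec$n_states
  nv <- length(times)
  P <- lapply(seq_len(nv - 1), function(v)
    transition_probability(spec, params, t0 = times[v], t1 = times[v + 1]))
  E <- matrix(1, ns, nv)
  for (v in seq_len(nv)) {
    if (!is.null(spec$emission)) {
      M <- emission_matrix(spec$emission, params, zmat[v, ])
      E[, v] <- M[, codes[v]]
    } else {
      E[, v] <- 0
      E[codes[v], v] <- 1
    }
  }
  grid <- do.call(expand.grid, rep(list(seq_len(ns)), nv))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    r <- as.integer(grid[g, ])
    p <- unname(init[r[1]]) * E[r[1], 1]
    for (v in seq_len(nv - 1)) p <- p * P[[v]][r[v], r[v + 1]] * E[r[v + 1],
                                                                   v + 1]
    tot <- tot + p
  }
  if (condition >= 1) tot <- tot / sum(init * E[, 1])
  unname(log(tot))
}

# analytic log-likelihood of a fully observed continuous-time path
path_loglik_analytic <- function(spec, params, path, t_max) {
  resolved <- resolve_parameters(spec, params)
  tr <- spec$transitions
  ll <- 0
  n <- nrow(path)
  for (i in seq_len(n)) {
    s <- path$state[i]
    t0 <- path$time[i]
    t1 <- if (i < n) path$time[i + 1] else t_max
    for (j in which(tr$from == s))
      ll <- ll - baseline_cumhaz(resolved[[j]]$baseline, t0, t1)
    if (i < n) {
      j <- which(tr$from == s & tr$to == path$state[i + 1])
      ll <- ll + log(baseline_hazard(resolved[[j]]$baseline, t1))
    }
  }
  ll
}

# convert a simulated path into exact-transition panel records
path_to_exact_panel <- function(path, t_max, subject = 1) {
  n <- nrow(path)
  data.frame(subject = subject,
             time = c(path$time, t_max),
             state = as.character(c(path$state, path$state[n])),
             exact = c(0L, rep(1L, n - 1), 0L))
}
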