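test_that("transition probabilities match closed forms and CK identity", {
  sp <- two_state_spec()
  P <- transition_probability(sp, c(lam = 0.5), t0 = 0, t1 = 2)
  expect_equal(P[1, 1], exp(-1), tolerance = 1e-12)
  expect_equal(rowSums(P), c(alive = 1, dead = 1), tolerance = 1e-12)
  expect_equal(transition_probability(sp, c(lam = 0.5), t0 = 1, t1 = 1),
               diag(2))
  # piecewise: rate 0.5 on [0,1), 1.0 on [1,2)
  spw <- pm_spec(states = c("alive", "dead"),
                 transitions = data.frame(from = 1, to = 2),
                 baselines = list(bl_piecewise(1, labels = c("l1", "l2"))))
  P2 <- transition_probability(spw, c(l1 = 0.5, l2 = 1.0), t0 = 0, t1 = 2)
  expect_equal(P2[1, 1], exp(-1.5), tolerance = 1e-12)
  # Chapman-Kolmogorov and split invariance, including a Weibull baseline
  sps <- list(three_state_spec(),
              pm_spec(states = c("a", "b"),
                      transitions = data.frame(from = c(1, 2), to = c(2, 1)),
                      baselines = list(bl_weibull(labels = c("a12", "b12")),
                                       bl_constant(labels = "l21"))))
  prs <- list(three_state_rates, c(a12 = 0.3, b12 = 1.6, l21 = 0.2))
  for (i in 1:2) {
    P03 <- transition_probability(sps[[i]], prs[[i]], t0 = 0, t1 = 3)
    Pstep <- transition_probability(sps[[i]], prs[[i]], t0 = 0, t1 = 1) %*%
      transition_probability(sps[[i]], prs[[i]], t0 = 1, t1 = 2) %*%
      transition_probability(sps[[i]], prs[[i]], t0 = 2, t1 = 3)
    expect_lt(max(abs(P03 - Pstep)), 1e-10)
    Psplit <- transition_probability(sps[[i]], prs[[i]], t0 = 0,
                                     t1 = 1.234567) %*%
      transition_probability(sps[[i]], prs[[i]], t0 = 1.234567, t1 = 3)
    expect_lt(max(abs(P03 - Psplit)), 1e-10)
  }
  # time homogeneity: P depends only on the interval length
  expect_equal(transition_probability(three_state_spec(), three_state_rates,
                                      t0 = 2.5, t1 = 4),
               transition_probability(three_state_spec(), three_state_rates,
                                      t0 = 0, t1 = 1.5), tolerance = 1e-12)
})

test_that("subject likelihood handles states, sets and exact transitions", {
  sp <- two_state_spec()
  lam <- c(lam = 0.5)
  surv <- data.frame(subject = 1, time = c(0, 1), state = "1", exact = 0L)
  expect_equal(subject_loglik(sp, surv, lam), -0.5, tolerance = 1e-12)
  death <- data.frame(subject = 1, time = c(0, 1), state = c("1", "2"),
                      exact = c(0L, 1L))
  expect_equal(subject_loglik(sp, death, lam), -0.5 + log(0.5),
               tolerance = 1e-12)
  cens <- data.frame(subject = 1, time = c(0, 1), state = c("1", "1,2"),
                     exact = 0L)
  expect_equal(subject_loglik(sp, cens, lam), 0, tolerance = 1e-12)
  star <- data.frame(subject = 1, time = c(0, 1), state = c("1", "*"),
                     exact = 0L)
  expect_equal(subject_loglik(sp, star, lam), 0, tolerance = 1e-12)
  # impossible sequence -> -Inf, not an error
  imp <- data.frame(subject = 1, time = c(0, 1), state = c("2", "1"),
                    exact = 0L)
  expect_identical(subject_loglik(sp, imp, lam), -Inf)
  # additivity and empty data
  two <- rbind(surv, transform(surv, subject = 2))
  expect_equal(total_loglik(sp, two, lam), 2 * subject_loglik(sp, surv, lam))
  expect_equal(total_loglik(sp, surv[0, ], lam), 0)
})

test_that("likelihood of a fully observed path equals the analytic product", {
  sp <- three_state_spec()
  sp$meta$exact_times <- TRUE  # continuously observed: no hidden excursions
  set.seed(42)
  for (rep in 1:5) {
    path <- simulate_path(sp, three_state_rates, init_state = 1, t_max = 20)
    pan <- path_to_exact_panel(path, t_max = 20)
    expect_equal(total_loglik(sp, pan, three_state_rates),
                 path_loglik_analytic(sp, three_state_rates, path, 20),
                 tolerance = 1e-8)
  }
})

test_that("generating parameters beat a perturbed rate on simulated panels", {
  sp <- three_state_spec()
  wrong <- three_state_rates; wrong["l12"] <- wrong["l12"] * 2
  wins <- 0L
  for (r in 1:20) {
    pan <- do.call(rbind, lapply(1:50, function(i) {
      set.seed(panelmsm:::substream_seed(1000 + r, i))
      path <- simulate_path(sp, three_state_rates, init_state = 1,
                            t_max = 10)
      obs <- observe_panel(path, 0:10)
      data.frame(subject = i, time = obs$time, state = obs$state, exact = 0L)
    }))
    wins <- wins + (total_loglik(sp, pan, three_state_rates) >
                      total_loglik(sp, pan, wrong))
  }
  expect_gte(wins, 19L)  # >= 95% of replicates
})

test_that("occupancy and length of stay are mutually consistent", {
  sp <- two_state_spec()
  occ <- state_occupancy(sp, c(lam = 0.5), initial_state = 1,
                         times = c(0, 2))
  expect_equal(unname(occ[2, ]), c(exp(-1), 1 - exp(-1)), tolerance = 1e-10)
  # absorbing initial state stays put
  occ2 <- state_occupancy(sp, c(lam = 0.5), initial_state = 2,
                          times = seq(0, 40, 10))
  expect_true(all(occ2[, 2] == 1))
  # grid end equals the one-shot transition probability
  sp3 <- three_state_spec()
  occ3 <- state_occupancy(sp3, three_state_rates, initial_state = 1,
                          times = seq(0, 6, 0.5))
  expect_lt(max(abs(occ3[13, ] -
                      transition_probability(sp3, three_state_rates,
                                             t0 = 0, t1 = 6)[1, ])), 1e-10)
  expect_lt(max(abs(rowSums(occ3) - 1)), 1e-10)
  # two-state closed-form length of stay over [0, 2]
  los <- length_of_stay(sp, c(lam = 0.5), initial_state = 1, horizon = 2)
  expect_equal(unname(los), c((1 - exp(-1)) / 0.5, 2 - (1 - exp(-1)) / 0.5),
               tolerance = 1e-8)
  # conservation at T = 40 for the 3-state spec
  los3 <- length_of_stay(sp3, three_state_rates, initial_state = 2,
                         horizon = 40)
  expect_equal(sum(los3), 40, tolerance = 1e-6)
  # absorbing start: all 40 years in that state
  losa <- length_of_stay(sp, c(lam = 0.5), initial_state = 2, horizon = 40)
  expect_equal(unname(losa), c(0, 40), tolerance = 1e-8)
})

test_that("panel CSV dialect round-trips bit-exactly", {
  d <- sim_damage(n = 3, n_loc = 2, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(d, f1)
  d2 <- read_panel_csv(f1)
  write_panel_csv(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(as.data.frame(d2), as.data.frame(pm_panel(d)))
})

test_that("panel validation reports informative errors", {
  bad <- data.frame(subject = 1, time = c(0, 0), state = "1", exact = 0L)
  expect_error(pm_panel(bad), "duplicated")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,time,state,exact", "1,0,9,0", "1,1,1,0"), f)
  sp <- two_state_spec()
  expect_error(total_loglik(sp, read_panel_csv(f), c(lam = 0.5)),
               "unknown state code")
})
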