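test_that("recode_zero_runs applies the O1/O2/O3 and Model B/C rules", {
  r <- recode_zero_runs(c(3, 0, 0, 0, 0, 2))
  expect_equal(r$O, c("O1", "O2", "O2", "O3", "O3", "O1"))
  expect_equal(r$state_B, c(1, 1, 1, 2, 2, 1))
  expect_equal(r$state_C, c(1, 2, 2, 2, 2, 1))
  r2 <- recode_zero_runs(c(0, 0, 5))
  expect_equal(r2$O, c("O2", "O2", "O1"))
  expect_true(all(r2$state_B == 1) && all(r2$state_C == 1))
  r3 <- recode_zero_runs(c(0, 0, 0))  # run starting at enrollment
  expect_equal(r3$O, c("O2", "O2", "O3"))
  expect_equal(r3$Z, c(1, 0, NA))
  expect_true(all(is.na(r3$Z) == (r3$code != 2)))  # Z defined iff O2
  expect_error(recode_zero_runs(c(1, -1)), "nonnegative")
})

test_that("emission matrices are stochastic with the remission structure", {
  em <- emission_remission()
  p <- c(gamma0 = 0, gammaZ = 0)
  M <- emission_matrix(em, p, c(Z = 1, blocked = 0))
  expect_equal(M["S1", ], c(O1 = 0.5, O2 = 0.5, O3 = 0))
  expect_equal(unname(M["S2", ]), c(0, 1, 0))
  expect_equal(unname(M["S3", ]), c(0, 0, 1))
  expect_equal(unname(rowSums(M)), c(1, 1, 1))
  # gamma'z -> -Inf: no misclassification
  M2 <- emission_matrix(em, c(gamma0 = -40, gammaZ = 0), c(Z = 0,
                                                           blocked = 0))
  expect_equal(unname(M2["S1", ]), c(1, 0, 0), tolerance = 1e-12)
  # structural blocking forces Pr(O2|S1) = 0
  M3 <- emission_matrix(em, c(gamma0 = 5, gammaZ = 0), c(Z = 0,
                                                         blocked = 1))
  expect_equal(unname(M3["S1", ]), c(1, 0, 0))
})

test_that("forward likelihood agrees with brute-force enumeration", {
  spec <- build_remission_model(cutpoints = NULL)
  params <- c(q12 = 0.3, q23 = 1.2, q31 = 0.4, gamma0 = -0.5, gammaZ = 1.5)
  times <- c(0.7, 1.9, 2.5, 4.1)
  cases <- list(c(1, 2, 2, 1), c(2, 2, 3, 3), c(1, 2, 3, 1), c(2, 1, 2, 3))
  for (codes in cases) {
    zf <- c(1, ifelse(codes[-length(codes)] >= 2, 0, 1))
    zmat <- data.frame(Z = zf, blocked = 0)
    pan <- data.frame(subject = 1, time = times, state = codes, exact = 0L,
                      Z = zf, blocked = 0)
    # delayed entry: occupancy row from S1 at the diagnosis origin
    init <- transition_probability(spec, params, t0 = 0, t1 = times[1])[1, ]
    bf <- brute_force_forward(spec, params, times, codes, zmat, init,
                              condition = 1)
    expect_equal(subject_loglik(spec, pan, params), bf, tolerance = 1e-10)
  }
})

test_that("identity emission reduces the HMM to the plain panel likelihood", {
  spec <- build_remission_model(cutpoints = NULL, condition_entry = TRUE)
  plain <- pm_spec(states = c("S1", "S2", "S3"),
                   transitions = data.frame(from = c(1, 2, 3),
                                            to = c(2, 3, 1)),
                   baselines = list(bl_constant(labels = "q12"),
                                    bl_constant(labels = "q23"),
                                    bl_constant(labels = "q31")),
                   meta = list(init = list(kind = "occupancy", state = 1,
                                           time = 0, condition = TRUE)))
  rates <- c(q12 = 0.3, q23 = 1.2, q31 = 0.4)
  pan <- data.frame(subject = 1, time = c(0.5, 1.5, 3, 4.5),
                    state = c(1, 2, 3, 1), exact = 0L, Z = c(1, 1, 0, 0),
                    blocked = 0)
  # gamma -> -Inf surrogate: S1 is never misclassified, codes = states
  ll_hmm <- total_loglik(spec, pan, c(rates, gamma0 = -40, gammaZ = 0))
  ll_plain <- total_loglik(plain, pan[, c("subject", "time", "state",
                                          "exact")], rates)
  expect_equal(ll_hmm, ll_plain, tolerance = 1e-8)
})

test_that("forward_loglik with an explicit prior obeys the one-step formula", {
  spec <- build_remission_model(cutpoints = NULL)
  params <- c(q12 = 0.3, q23 = 1.2, q31 = 0.4, gamma0 = -0.5, gammaZ = 1.5)
  pan <- data.frame(subject = 1, time = 2, state = 2, exact = 0L, Z = 1,
                    blocked = 0)
  init <- c(0.5, 0.3, 0.2)
  e <- emission_matrix(spec$emission, params, c(Z = 1, blocked = 0))[, "O2"]
  expect_equal(forward_loglik(spec, pan, params, init = init),
               log(sum(init * e)), tolerance = 1e-12)
})

test_that("a phantom fully-censored visit leaves the likelihood unchanged", {
  spec <- build_remission_model(cutpoints = NULL)
  params <- c(q12 = 0.3, q23 = 1.2, q31 = 0.4, gamma0 = -0.5, gammaZ = 1.5)
  pan <- data.frame(subject = 1, time = c(1, 2, 3.5), state = c(1, 2, 2),
                    exact = 0L, Z = c(1, 1, 0), blocked = 0)
  ins <- rbind(pan[1:2, ],
               data.frame(subject = 1, time = 2.8, state = "*", exact = 0L,
                          Z = 0, blocked = 0),
               pan[3, ])
  expect_equal(total_loglik(spec, ins, params),
               total_loglik(spec, pan, params), tolerance = 1e-10)
})

test_that("the remission model builder encodes the intended structure", {
  spec <- build_remission_model()
  expect_equal(spec$transitions, data.frame(from = c(1, 2, 3),
                                            to = c(2, 3, 1)))
  expect_equal(unname(spec$meta$state_groups[c("S2", "S3")]),
               c("remission", "remission"))
  expect_equal(spec_cutpoints(spec), 15)
  expect_equal(length(spec$baselines[[1]]$labels), 2)  # two intervals
  expect_true(is.null(spec$terms[[2]]) || length(spec$terms[[2]]) == 0)
})

test_that("misclassification posterior follows Bayes' rule", {
  expect_equal(misclassification_posterior(0.3, 0.8, 0.2), 0.24 / 0.44)
  expect_equal(misclassification_posterior(0, 0.8, 0.2), 0)
  expect_equal(misclassification_posterior(0.7, 0.8, 0), 1)
  expect_error(misclassification_posterior(0.3, 0, 0), "pi1")
})

test_that("counts_to_panel produces model-ready data for A, B and C", {
  counts <- data.frame(subject = c(1, 1, 1, 1, 2, 2),
                       time = c(0, 1, 2, 3, 0, 1.5),
                       count = c(2, 0, 0, 0, 0, 0))
  a <- counts_to_panel(counts, "A")
  expect_equal(a$state[a$subject == 1], c("1", "2", "2", "3"))
  expect_equal(a$Z[a$subject == 1], c(1, 1, 0, 0))
  expect_equal(a$blocked[a$subject == 1], c(0, 0, 0, 1))
  b <- counts_to_panel(counts, "B")
  expect_equal(b$state[b$subject == 1], c("1", "1", "1", "2"))
  c_ <- counts_to_panel(counts, "C")
  expect_equal(c_$state[c_$subject == 1], c("1", "2", "2", "2"))
  expect_equal(c_$state[c_$subject == 2], c("1", "1"))  # run of 2 is active
})
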