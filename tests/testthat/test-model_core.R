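test_that("baseline hazards evaluate their closed forms", {
  expect_equal(baseline_hazard(bl_weibull(0.5, 1), 3), 0.5)
  expect_equal(baseline_hazard(bl_weibull(0.5, 2), 2), 2.0)
  pw <- bl_piecewise(15, levels = c(0.1, 0.3))
  expect_equal(baseline_hazard(pw, 14.9), 0.1)
  expect_equal(baseline_hazard(pw, 15.0), 0.3)  # right-continuous
  expect_error(baseline_hazard(pw, -1), "negative")
  expect_error(bl_constant(rate = -1), "positive")
  expect_error(bl_piecewise(c(2, 1), levels = c(1, 2, 3)), "increasing")
  # cumulative hazards match numerical integration
  for (b in list(bl_constant(0.4), bl_weibull(0.3, 1.7),
                 bl_piecewise(c(1, 4), levels = c(0.1, 0.5, 0.2)))) {
    num <- stats::integrate(function(t) baseline_hazard(b, t), 0.5, 6,
                            subdivisions = 400L, rel.tol = 1e-10)$value
    expect_equal(baseline_cumhaz(b, 0.5, 6), num, tolerance = 1e-8)
  }
})

test_that("intensity_matrix builds proportional-intensity generators", {
  sp <- three_state_spec()
  Q <- intensity_matrix(sp, three_state_rates)
  expect_equal(unname(Q), rbind(c(-0.2, 0.2, 0), c(0.1, -0.4, 0.3),
                                c(0, 0.4, -0.4)))
  # a covariate multiplies only its own transition
  sp2 <- pm_spec(states = c("a", "b", "c"),
                 transitions = data.frame(from = c(1, 2, 2, 3),
                                          to = c(2, 1, 3, 2)),
                 baselines = list(bl_constant(labels = "l12"),
                                  bl_constant(labels = "l21"),
                                  bl_constant(labels = "l23"),
                                  bl_constant(labels = "l32")),
                 terms = list(c(x = "beta"), character(), character(),
                              character()))
  Q2 <- intensity_matrix(sp2, c(three_state_rates, beta = log(2)),
                         covariates = list(x = 1))
  expect_equal(Q2[1, 2], 0.4)
  expect_equal(Q2[2, 3], 0.3)
  expect_equal(Q2[1, 3], 0)  # non-adjacent moves are structurally zero
  expect_error(intensity_matrix(sp2, c(three_state_rates, beta = log(2)),
                                covariates = list(y = 1)),
               "missing covariate")
  # invariants: nonnegative off-diagonals, zero row sums, frailty linearity
  for (u in c(0.5, 1, 3)) {
    Qu <- intensity_matrix(sp, three_state_rates, frailty = u)
    expect_true(all(Qu[row(Qu) != col(Qu)] >= 0))
    expect_lt(max(abs(rowSums(Qu))), 1e-12)
    expect_equal(Qu, u * Q)
  }
})

test_that("constraint resolution honours sharing, ratio and offset rules", {
  wsp <- build_whitehall_model(k = 1)
  p <- c(a1 = 0.01, b1 = 1.2, a2 = 0.005, b2 = 1.1, a3 = 0.04, b3 = 1.3,
         a4 = 0.02, b4 = 1.0, a6 = 0.008, b6 = 1.4)
  r <- resolve_parameters(wsp, p)
  # lambda3 == lambda7 bit-identical (NF->F and NF_LTF->F)
  expect_identical(r[[3]]$baseline$params, r[[7]]$baseline$params)
  # k = 1 and lambda1 == lambda2 -> lambda5 == lambda6 pointwise
  p2 <- p; p2[c("a2", "b2")] <- p2[c("a1", "b1")]
  r2 <- resolve_parameters(build_whitehall_model(k = 1), p2)
  tt <- c(0.5, 2, 7)
  expect_equal(baseline_hazard(r2[[5]]$baseline, tt),
               baseline_hazard(r2[[6]]$baseline, tt), tolerance = 1e-12)
  # doubling k halves lambda5 pointwise in t
  rk2 <- resolve_parameters(build_whitehall_model(k = 2), p)
  expect_equal(baseline_hazard(rk2[[5]]$baseline, tt),
               baseline_hazard(r[[5]]$baseline, tt) / 2, tolerance = 1e-12)
  # resolving twice is idempotent
  expect_identical(resolve_parameters(wsp, p), r)
  expect_error(resolve_parameters(wsp, p[-1]), "missing")
  # derived rules may not chain (keeps the dependency graph trivially acyclic)
  expect_error(pm_spec(states = c("a", "b", "c"),
                       transitions = data.frame(from = c(1, 1), to = c(2, 3)),
                       baselines = list(derived_exp_offset(2, "g1"),
                                        derived_exp_offset(1, "g2"))),
               "derived")
})

test_that("working-scale transforms round-trip and respect types", {
  sp <- build_damage_model()
  p <- c(lam012 = 0.02, lam013 = 0.03, gamma24 = 1.2, gamma34 = -0.4,
         alpha = 0.2, tau1 = 0.5, eps1 = 1.1, tau2 = 0.3, eps2 = 0.4,
         phi_trans1 = 0.7, phi_opp = 0.1, phi_trans2 = 0.3, theta = 0.5)
  w <- pm_to_working(sp, p)
  expect_equal(w[["lam012"]], log(0.02))
  expect_equal(w[["gamma24"]], 1.2)  # offsets are real-scale
  expect_equal(pm_from_working(sp, w), p[names(w)], tolerance = 1e-14)
})

test_that("spec validation rejects malformed graphs", {
  expect_error(pm_spec(states = c("a", "a"),
                       transitions = data.frame(from = 1, to = 2),
                       baselines = list(bl_constant(labels = "l"))),
               "duplicate state")
  expect_error(pm_spec(states = c("a", "b"),
                       transitions = data.frame(from = 1, to = 1),
                       baselines = list(bl_constant(labels = "l"))),
               "distinct")
  expect_error(pm_spec(states = c("a", "b"),
                       transitions = data.frame(from = 1, to = 3),
                       baselines = list(bl_constant(labels = "l"))),
               "unknown state")
  expect_equal(absorbing_states(two_state_spec()), 2L)
})

test_that("JSON configuration round-trips a working model", {
  sp <- build_remission_model()  # piecewise + emission + delayed entry
  f <- withr::local_tempfile(fileext = ".json")
  spec_to_json(sp, f)
  sp2 <- spec_from_json(f)
  expect_equal(sp2$states, sp$states)
  expect_equal(sp2$transitions, sp$transitions)
  expect_equal(sp2$par_info, sp$par_info)
  d <- sim_remission(n = 8, seed = 4, mechanism = "model")
  p <- c(q12_1 = 0.1, q12_2 = 0.2, q23_1 = 1, q23_2 = 1, q31_1 = 0.3,
         q31_2 = 0.2, gamma0 = -1, gammaZ = 2)
  expect_equal(total_loglik(sp2, d, p), total_loglik(sp, d, p),
               tolerance = 1e-12)
  # whitehall spec with derived + fixed parameters
  ws <- build_whitehall_model(k = 2)
  f2 <- withr::local_tempfile(fileext = ".json")
  spec_to_json(ws, f2)
  ws2 <- spec_from_json(f2)
  expect_equal(ws2$fixed, c(k = 2))
  pw <- c(a1 = 0.01, b1 = 1.2, a2 = 0.005, b2 = 1.1, a3 = 0.04, b3 = 1.3,
          a4 = 0.02, b4 = 1.0, a6 = 0.008, b6 = 1.4)
  expect_equal(baseline_hazard(resolve_parameters(ws2, pw)[[5]]$baseline, 3),
               baseline_hazard(resolve_parameters(ws, pw)[[5]]$baseline, 3))
})
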