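wh_pars <- c(a1 = 0.01, b1 = 1.2, a2 = 0.005, b2 = 1.1, a3 = 0.04,
             b3 = 1.3, a4 = 0.02, b4 = 1.0, a6 = 0.008, b6 = 1.4)

test_that("the five-state builder enforces the structural constraints", {
  spec <- build_whitehall_model(k = 1)
  got <- paste(spec$states[spec$transitions$from],
               spec$states[spec$transitions$to], sep = ">")
  expect_setequal(got, c("H>NF", "H>F", "NF>F", "H>LTF", "LTF>NF_LTF",
                         "LTF>F", "NF_LTF>F"))
  expect_equal(spec$unobservable, "NF_LTF")
  expect_error(build_whitehall_model(k = 0), "positive")
  expect_error(build_whitehall_model(k = -2), "positive")
  # k is fixed, never free
  expect_false("k" %in% pm_free_labels(spec))
  # shared mortality effects when requested
  sh <- build_whitehall_model(k = 1, terms = list(lam2 = c(g = "betaF")),
                              share_f_effects = TRUE)
  r <- resolve_parameters(sh, c(wh_pars, betaF = 0.7))
  expect_identical(r[[2]]$coefs, r[[3]]$coefs)
  expect_identical(r[[2]]$coefs, r[[6]]$coefs)
})

test_that("k only enters through post-loss-to-follow-up paths", {
  histories <- list(
    data.frame(subject = 1, time = c(0, 10), state = "1", exact = 0L),
    data.frame(subject = 1, time = c(0, 4), state = c("1", "5"),
               exact = c(0L, 1L)),
    data.frame(subject = 1, time = c(0, 3, 9), state = c("1", "2", "2"),
               exact = c(0L, 1L, 0L)),
    data.frame(subject = 1, time = c(0, 3, 7), state = c("1", "2", "5"),
               exact = c(0L, 1L, 1L)))
  for (h in histories) {
    lls <- vapply(c(0.5, 1, 2), function(k)
      whitehall_subject_loglik(build_whitehall_model(k = k), h, wh_pars), 0)
    expect_lt(max(abs(lls - lls[1])), 1e-12)
  }
  # ... but an LTF history does depend on k
  hl <- data.frame(subject = 1, time = c(0, 3, 9), state = c("1", "3", "3,4"),
                   exact = c(0L, 1L, 0L))
  lls <- vapply(c(0.5, 2), function(k)
    whitehall_subject_loglik(build_whitehall_model(k = k), hl, wh_pars), 0)
  expect_gt(abs(diff(lls)), 1e-6)
})

test_that("post-LTF marginalization matches closed forms in limits", {
  # lambda1 ~ 0 forces lambda5 ~ 0: death density reduces to the one-path
  # closed form exp(-Lambda6(l, t)) * lambda6(t)
  p0 <- wh_pars; p0["a1"] <- 1e-12
  spec <- build_whitehall_model(k = 1)
  h <- data.frame(subject = 1, time = c(0, 3, 8), state = c("1", "3", "5"),
                  exact = c(0L, 1L, 1L))
  ll <- whitehall_subject_loglik(spec, h, p0)
  r <- resolve_parameters(spec, p0)
  lam6 <- function(t) baseline_hazard(r[[6]]$baseline, t)
  H6 <- function(a, b) baseline_cumhaz(r[[6]]$baseline, a, b)
  H124 <- sum(vapply(c(1, 2, 4), function(i)
    baseline_cumhaz(r[[i]]$baseline, 0, 3), 0))
  lam4 <- baseline_hazard(r[[4]]$baseline, 3)
  closed <- -H124 + log(lam4) - H6(3, 8) + log(lam6(8))
  expect_equal(ll, closed, tolerance = 1e-8)
})

test_that("cumulative incidence has its closed-form and structural limits", {
  spec <- build_whitehall_model(k = 1)
  grid <- seq(0, 15, 1)
  # only H -> F active: CIF = 1 - exp(-a t^b)
  p1 <- wh_pars; p1[c("a1", "a4")] <- 1e-12
  cif <- chd_cumulative_incidence(spec, p1, grid = grid)
  expect_equal(cif, 1 - exp(-p1["a2"] * grid^p1["b2"]), tolerance = 1e-8,
               ignore_attr = TRUE)
  cif2 <- chd_cumulative_incidence(spec, wh_pars, grid = grid)
  expect_equal(cif2[1], 0)
  expect_true(all(diff(cif2) >= -1e-12) && all(cif2 <= 1))
  # constant rates: closed form for the no-LTF part plus a quadrature oracle
  # for the LTF-then-event part
  pc <- c(a1 = 0.03, b1 = 1, a2 = 0.01, b2 = 1, a3 = 0.05, b3 = 1,
          a4 = 0.04, b4 = 1, a6 = 0.02, b6 = 1)
  k <- 1
  l124 <- 0.03 + 0.01 + 0.04
  l5 <- 0.03 * 0.02 / (k * 0.01)
  for (t in c(2, 5, 10)) {
    direct <- (0.03 + 0.01) / l124 * (1 - exp(-l124 * t))
    ltf_path <- stats::integrate(function(s)
      exp(-l124 * s) * 0.04 * (1 - exp(-(l5 + 0.02) * (t - s))),
      0, t, rel.tol = 1e-10)$value
    expect_equal(chd_cumulative_incidence(spec, pc, grid = c(0, t))[2],
                 direct + ltf_path, tolerance = 1e-6)
  }
})

test_that("RK4 occupancy conserves mass and cross-checks the quadrature", {
  spec <- build_whitehall_model(k = 1)
  grid <- seq(0, 12, 2)
  occ <- whitehall_occupancy(spec, wh_pars, grid = grid)
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-8)
  cif <- chd_cumulative_incidence(spec, wh_pars, grid = grid)
  # two independent numerical routes (quadrature vs RK4)
  expect_equal(cif, 1 - occ[, "H"] - occ[, "LTF"], tolerance = 1e-4,
               ignore_attr = TRUE)
  # larger k -> pointwise smaller lambda5 -> less NF_LTF occupancy
  occ_k2 <- whitehall_occupancy(build_whitehall_model(k = 2), wh_pars,
                                grid = grid)
  expect_true(all(occ_k2[, "NF_LTF"] <= occ[, "NF_LTF"] + 1e-12))
})

test_that("histories that violate the graph are rejected", {
  spec <- build_whitehall_model(k = 1)
  bad <- data.frame(subject = 1, time = c(0, 2, 4),
                    state = c("1", "5", "2"), exact = c(0L, 1L, 1L))
  expect_error(whitehall_subject_loglik(spec, bad, wh_pars), "death")
  bad2 <- data.frame(subject = 1, time = c(0, 2), state = c("2", "2"),
                     exact = 0L)
  expect_error(whitehall_subject_loglik(spec, bad2, wh_pars), "start")
})
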