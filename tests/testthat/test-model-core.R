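# the quadratic-root oracle: alpha/beta straight from the sum/product relations
ab_oracle <- function(k12, k21, k10, k13) {
  s <- k12 + k21 + k10 + k13
  p <- k21 * k10 + k21 * k13
  sort(Re(polyroot(c(p, -s, 1))), decreasing = TRUE)
}

test_that("macro constants satisfy the sum/product relations", {
  cases <- list(
    c(2.26, 1.10, 0.56, 0.14),        # patient A estimates
    c(0.75, 0.95, 0.39, 1.5 / 13.46)  # cohort mean with tied k13
  )
  frozen <- list(c(3.8605, 0.1994), c(1.9581, 0.2433)) # oracle values
  for (i in seq_along(cases)) {
    k <- cases[[i]]
    ab <- derive_macro_constants(micro_params(10, k[1], k[2], k[3], k[4]))
    expect_equal(unname(ab), ab_oracle(k[1], k[2], k[3], k[4]), tolerance = 1e-12)
    expect_equal(unname(ab), frozen[[i]], tolerance = 1e-4)
    expect_equal(sum(ab), k[1] + k[2] + k[3] + k[4], tolerance = 1e-12)
    expect_equal(prod(ab), k[2] * (k[3] + k[4]), tolerance = 1e-12)
  }
})

test_that("with k12 = 0 the characteristic quadratic factors exactly", {
  ab <- derive_macro_constants(micro_params(10, 0, 0.95, 0.39, 0.11))
  expect_equal(unname(ab), c(0.95, 0.50), tolerance = 1e-14)
})

test_that("sum/product relations hold over random parameter sets", {
  for (p in random_micro(100, seed = 11)) {
    ab <- derive_macro_constants(p)
    s <- p$k12 + p$k21 + p$k10 + p$k13
    expect_lt(abs(sum(ab) - s) / s, 1e-12)
    expect_lt(abs(prod(ab) - p$k21 * (p$k10 + p$k13)) / prod(ab), 1e-12)
    expect_gt(ab[["alpha"]], ab[["beta"]])
  }
})

test_that("near-coincident rate constants raise a degeneracy error", {
  # k12 = 0 and k10 + k13 = k21 makes alpha = beta exactly
  expect_error(derive_macro_constants(micro_params(10, 0, 0.5, 0.5, 0)),
               "degenerate")
  expect_error(macro_params(10, 0.9, 1, 1 - 1e-12), "degenerate")
  expect_error(macro_params(10, 0.9, 0.5, 0.6), "alpha > beta")
})

test_that("filter constants are tied exactly to flows, SC and volumes", {
  chdf <- chdf_settings(Q_D = 0.53, Q_F = 1.0, SC = 1.0, V3 = 0.1)
  fk <- derive_filter_constants(chdf, V1 = 11.09)
  expect_equal(unname(fk["k13"] * 11.09), 1.53 * 1.0, tolerance = 1e-14)
  expect_equal(unname(fk["k30"] * 0.1), 1.53, tolerance = 1e-14)
  expect_equal(unname(fk["k13"]), 0.138, tolerance = 0.01) # prints as 0.14
  # SC = 0 shuts the membrane regardless of flows
  expect_equal(unname(derive_filter_constants(chdf_settings(SC = 0), 10)["k13"]), 0)
  # direct evaluation
  expect_equal(unname(derive_filter_constants(chdf_settings(), 13.46)["k13"]),
               1.5 / 13.46, tolerance = 1e-12)
  expect_error(derive_filter_constants(chdf, V1 = -1), "V1")
})

test_that("steady-state plasma curve is continuous, periodic and nonnegative", {
  m <- as_macro_params(mean_micro())
  r <- q6h()
  eps <- 1e-9
  expect_equal(conc_central_ss(r$tinf - eps, m, r), conc_central_ss(r$tinf + eps, m, r),
               tolerance = 1e-6)
  expect_equal(conc_central_ss(0, m, r), conc_central_ss(r$tau, m, r), tolerance = 1e-9)
  tt <- seq(0, r$tau, by = 0.01)
  expect_true(all(conc_central_ss(tt, m, r) >= 0))
  # steady-state trough, frozen from the ODE oracle
  expect_equal(conc_central_ss(6, m, r), 3.147, tolerance = 1e-3)
})

test_that("single-dose mode starts from zero and drops accumulation", {
  m <- as_macro_params(mean_micro())
  r <- q6h()
  expect_equal(conc_central_ss(0, m, r, single_dose = TRUE), 0)
  # single-dose curve lies below the steady-state curve everywhere
  tt <- seq(0.01, 6, by = 0.1)
  expect_true(all(conc_central_ss(tt, m, r, single_dose = TRUE) <
                  conc_central_ss(tt, m, r)))
})

test_that("filtrate-dialysate curve vanishes with k13 = 0 and guards k30 ties", {
  p0 <- micro_params(13.46, 0.75, 0.95, 0.39, 0, k30 = 15, V3 = 0.1)
  expect_equal(conc_fd_ss(seq(0, 6, 0.5), p0, q6h()), rep(0, 13))
  p_tmp <- micro_params(13.46, 0.75, 0.95, 0.39, 0.11)
  ab <- derive_macro_constants(p_tmp)
  p_bad <- micro_params(13.46, 0.75, 0.95, 0.39, 0.11, k30 = ab[["alpha"]], V3 = 0.1)
  expect_error(conc_fd_ss(1, p_bad, q6h()), "degenerate")
})

test_that("effluent exposure over an interval equals SC times plasma exposure", {
  # (Q_F+Q_D) * AUC_FD = CL_CHDF * AUC_plasma, i.e. AUC ratio = SC
  for (sc in c(1.0, 0.8)) {
    chdf <- chdf_settings(SC = sc)
    fk <- derive_filter_constants(chdf, 13.46)
    p <- micro_params(13.46, 0.75, 0.95, 0.39, fk[["k13"]], fk[["k30"]], chdf$V3)
    r <- q6h()
    auc1 <- stats::integrate(function(t) conc_central_ss(t, p, r), 0, r$tau,
                             rel.tol = 1e-10, subdivisions = 500)$value
    auc3 <- stats::integrate(function(t) conc_fd_ss(t, p, r), 0, r$tau,
                             rel.tol = 1e-10, subdivisions = 500)$value
    # C3 is effluent-side; mass leaving via the filter is (QF+QD)*AUC_FD
    expect_equal(effluent_flow(chdf) * auc3,
                 effluent_flow(chdf) * chdf$SC * auc1, tolerance = 1e-6)
    expect_equal(auc3 / auc1, sc, tolerance = 1e-6)
  }
})

test_that("steady-state plasma AUC over the interval equals dose / (V1 (k10+k13))", {
  p <- mean_micro()
  r <- q6h()
  auc <- stats::integrate(function(t) conc_central_ss(t, p, r), 0, r$tau,
                          rel.tol = 1e-10, subdivisions = 500)$value
  expect_equal(auc, r$dose / (p$V1 * (p$k10 + p$k13)), tolerance = 1e-7)
})

test_that("ODE simulator conserves mass and reduces to known limits", {
  r <- q6h()
  # no elimination, no transfer: X1 ramps linearly during the infusion
  p0 <- micro_params(10, 0, 1e-9, 0, 0, k30 = 1, V3 = 0.1)
  # k21 must be > 0 by construction; use a negligible value
  sim0 <- simulate_ode(p0, r, n_doses = 1, dt = 0.1)
  during <- sim0$time <= r$tinf
  expect_equal(sim0$X1[during], r$r_inf * sim0$time[during], tolerance = 1e-6)
  # mass balance at full tolerance
  p <- mean_micro()
  sim <- simulate_ode(p, r, n_doses = 3, dt = 0.05)
  expect_lt(mass_balance_error(sim, r, 3), 1e-8)
  # k12 = k13 = 0: one-compartment post-infusion log-slope equals -k10
  p1 <- micro_params(10, 0, 0.5, 0.4, 0, k30 = 1, V3 = 0.1)
  sim1 <- simulate_ode(p1, regimen(300, 24, 1), n_doses = 1, dt = 0.1)
  post <- sim1[sim1$time >= 2 & sim1$time <= 10, ]
  slope <- stats::coef(stats::lm(log(post$C1) ~ post$time))[2]
  expect_equal(unname(slope), -0.4, tolerance = 1e-6)
})

test_that("closed forms agree with the ODE ground truth at steady state", {
  r <- q6h()
  for (p in random_micro(8, seed = 21)) {
    nd <- n_doses_to_ss(p, r)
    sim <- simulate_ode(p, r, n_doses = nd, dt = 0.1, rtol = 1e-11, atol = 1e-11)
    win <- sim$time >= (nd - 1) * r$tau
    tloc <- sim$time[win] - (nd - 1) * r$tau
    c1 <- conc_central_ss(tloc, p, r)
    c3 <- conc_fd_ss(tloc, p, r)
    expect_lt(max(abs(sim$C1[win] - c1) / pmax(c1, 1e-6)), 0.005)
    expect_lt(max(abs(sim$C3[win] - c3) / pmax(c3, 1e-6)), 0.005)
  }
})
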