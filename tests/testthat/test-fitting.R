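test_that("noise-free fit recovers the generating parameters", {
  tab <- reference_micro()
  i <- 3 # patient C estimates as generating truth
  chdf <- std_chdf()
  fk <- derive_filter_constants(chdf, tab$V1[i])
  p <- micro_params(tab$V1[i], tab$k12[i], tab$k21[i], tab$k10[i],
                    tab$k13[i], k30 = fk[["k30"]], V3 = chdf$V3)
  r <- regimen(300, 12, 1)
  s <- noise_free_series(p, r, id = "C")
  sc_meas <- tab$k13[i] * tab$V1[i] / effluent_flow(chdf)
  f <- fit_patient(s, r, chdf, sc_measured = sc_meas, seed = 7)
  expect_true(f$converged)
  for (nm in c("V1", "k12", "k21", "k10")) {
    expect_lt(abs(f$params[[nm]] - p[[nm]]) / p[[nm]], 0.005)
  }
  # tied constraint holds at the optimum
  expect_equal(f$params$k13 * f$params$V1, effluent_flow(chdf) * sc_meas,
               tolerance = 1e-10)
})

test_that("the objective is minimal at the truth on noise-free data", {
  p <- mean_micro()
  r <- q6h()
  s <- noise_free_series(p, r)
  chdf <- std_chdf()
  obj <- function(v1, k12, k21, k10) {
    k13 <- effluent_flow(chdf) / v1
    pp <- micro_params(v1, k12, k21, k10, k13,
                       k30 = effluent_flow(chdf) / chdf$V3, V3 = chdf$V3)
    sum((conc_central_ss(s$obs$time_h, pp, r) - s$obs$plasma)^2) +
      sum((conc_fd_ss(s$obs$time_h, pp, r) - s$obs$fd)^2)
  }
  at_truth <- obj(p$V1, p$k12, p$k21, p$k10)
  set.seed(31)
  for (rep in 1:10) {
    fac <- 1 + 0.1 * sample(c(-1, 1), 4, replace = TRUE)
    expect_gt(obj(p$V1 * fac[1], p$k12 * fac[2], p$k21 * fac[3], p$k10 * fac[4]),
              at_truth)
  }
})

test_that("derived clearances follow the defining products", {
  chdf <- std_chdf()
  pA <- micro_params(11.09, 2.26, 1.10, 0.56, 0.14)
  cl <- derived_clearances(pA, chdf, sc = 1.0)
  expect_equal(unname(cl["cl_nonchdf"]), 6.21, tolerance = 0.1) # prints 6.24 unrounded
  expect_equal(unname(cl["cl_chdf"]), 1.5)
  p0 <- micro_params(11.09, 2.26, 1.10, 0, 0.14)
  expect_equal(unname(derived_clearances(p0, chdf, sc = 1)["cl_nonchdf"]), 0)
})

test_that("summed model clearances regress onto NCA clearance with unit slope", {
  mic <- reference_micro()
  nca <- reference_nca()
  reg <- clearance_validation_regression(mic$cl_chdf + mic$cl_nonchdf, nca$cl_tot)
  expect_lt(abs(reg$slope - 1.01), 0.005)
  expect_lt(abs(reg$intercept - (-0.02)), 0.01)
  expect_gt(reg$r_squared, 0.99)
})

test_that("two-stage summary reproduces the cohort means and handles edge cases", {
  mic <- reference_micro()
  ab <- t(vapply(seq_len(7), function(i)
    derive_macro_constants(micro_params(mic$V1[i], mic$k12[i], mic$k21[i],
                                        mic$k10[i], mic$k13[i])), numeric(2)))
  st <- two_stage(data.frame(V1 = mic$V1, k21 = mic$k21,
                             alpha = ab[, 1], beta = ab[, 2]))
  expect_equal(unname(st$mean["V1"]), 13.46, tolerance = 0.005)
  expect_equal(unname(st$mean["k21"]), 0.95, tolerance = 0.005)
  expect_equal(unname(st$mean["alpha"]), 1.956, tolerance = 0.001)
  expect_equal(unname(st$sd["alpha"]), 0.981, tolerance = 0.001)
  expect_equal(unname(st$mean["beta"]), 0.257, tolerance = 0.001)
  expect_equal(unname(st$sd["beta"]), 0.098, tolerance = 0.001)
  # identical subjects: zero SD
  same <- data.frame(V1 = rep(10, 3), k21 = rep(1, 3),
                     alpha = rep(2, 3), beta = rep(0.3, 3))
  st0 <- two_stage(same)
  expect_true(all(st0$sd == 0))
  expect_error(two_stage(same[1, , drop = FALSE]), "at least 2")
})

test_that("model total clearance from a fit matches dose over fitted AUC", {
  p <- mean_micro()
  r <- q6h()
  chdf <- std_chdf()
  s <- noise_free_series(p, r)
  f <- fit_patient(s, r, chdf, sc_measured = 1, seed = 3)
  auc <- stats::integrate(function(t) conc_central_ss(t, f$params, r), 0, r$tau,
                          rel.tol = 1e-10)$value
  expect_equal(f$params$V1 * (f$params$k10 + f$params$k13), r$dose / auc,
               tolerance = 0.01)
})

test_that("parameter recovery under 10% proportional noise is unbiased", {
  # replicate-cohort simulation study: median |error| in V1 under 15%,
  # and two-stage means within 2 SE of the generating means
  chdf <- std_chdf()
  n_cohorts <- 20
  v1_err <- numeric(0)
  for (cc in seq_len(n_cohorts)) {
    spec <- cohort_spec(n = 7, cv_prop = 0.10, chdf = chdf, seed = 101 + cc)
    ds <- generate_dataset(spec)
    fits <- lapply(seq_len(nrow(ds$cohort)), function(i) {
      s <- ds$series[[i]]
      # small-k12 subjects legitimately pin k12 at the search floor
      suppressWarnings(
        fit_patient(s, regimen(s$dose, s$tau, s$tinf), chdf,
                    sc_measured = ds$cohort$sc[i], n_starts = 4, seed = cc * 100 + i))
    })
    v1_hat <- vapply(fits, function(f) f$params$V1, numeric(1))
    v1_err <- c(v1_err, abs(v1_hat - ds$cohort$V1) / ds$cohort$V1)
  }
  expect_lt(median(v1_err), 0.15)
  # one larger cohort: two-stage means within 2 SE of the generating means
  spec <- cohort_spec(n = 24, cv_prop = 0.10, chdf = chdf, seed = 500)
  ds <- generate_dataset(spec)
  fits <- lapply(seq_len(24), function(i) {
    s <- ds$series[[i]]
    suppressWarnings(
      fit_patient(s, regimen(s$dose, s$tau, s$tinf), chdf,
                  sc_measured = ds$cohort$sc[i], n_starts = 4, seed = 7000 + i))
  })
  st <- two_stage(fits)
  for (nm in c("V1", "k21")) {
    se <- st$sd[nm] / sqrt(st$n)
    expect_lt(abs(st$mean[nm] - c(V1 = 13.46, k21 = 0.95)[nm]), 2 * se)
  }
})
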