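#' Fit the compartment model to one patient's plasma and FD curves
#'
#' Concurrent nonlinear least-squares fit of the steady-state closed-form
#' plasma (`C1`) and filtrate-dialysate (`C3`) curves to a patient's
#' observed concentrations. Free parameters are `V1`, `k12`, `k21`, `k10`,
#' optimised on the log scale (which enforces positivity); `k13` is tied to
#' `(Q_F + Q_D) * SC / V1` at every iterate using the NCA-measured sieving
#' coefficient, and `k30` is fixed by the circuit flows and filter volume.
#' Levenberg-Marquardt minimisation is restarted from a Latin-hypercube of
#' initial values around NCA-informed guesses and the best optimum is kept.
#'
#' @param series a [conc_time_series()] with both channels
#' @param r the patient's [regimen()]
#' @param chdf the patient's [chdf_settings()]
#' @param sc_measured sieving coefficient from NCA (defaults to `chdf$SC`)
#' @param n_starts number of multi-start points (>= 1)
#' @param seed optional integer seed controlling the multi-start design
#' @param weighting `"uniform"` (unweighted, default) or `"inv_pred2"`
#'   (1/prediction^2 weights)
#' @return An object of class `pk_fit`: list with `params`
#'   ([micro_params()]), `objective`, `residuals` (list per channel),
#'   `converged`, `cl_chdf`, `cl_nonchdf`, `n_starts_converged`.
#' @export
fit_patient <- function(series, r, chdf, sc_measured = NULL,
                        n_starts = 8, seed = NULL,
                        weighting = c("uniform", "inv_pred2")) {
  stopifnot(inherits(series, "conc_series"), inherits(r, "regimen"),
            inherits(chdf, "chdf_settings"))
  weighting <- match.arg(weighting)
  if (is.null(sc_measured)) sc_measured <- chdf$SC
  obs <- series$obs
  keep_pl <- !obs$bql_plasma
  if (sum(keep_pl) < 5) stop("at least 5 quantifiable plasma points are required")
  keep_fd <- series$has_fd & !obs$bql_fd & !is.na(obs$fd)
  q <- effluent_flow(chdf)
  k30 <- q / chdf$V3
  single <- isTRUE(series$first_dose)

  predict_both <- function(theta) {
    v1 <- exp(theta[1]); k12 <- exp(theta[2]); k21 <- exp(theta[3]); k10 <- exp(theta[4])
    k13 <- q * sc_measured / v1
    p <- tryCatch(micro_params(v1, k12, k21, k10, k13, k30, chdf$V3),
                  error = function(e) NULL)
    if (is.null(p)) return(NULL)
    c1 <- tryCatch(conc_central_ss(obs$time_h[keep_pl], p, r, single_dose = single),
                   error = function(e) NULL)
    if (is.null(c1)) return(NULL)
    c3 <- NULL
    if (any(keep_fd)) {
      c3 <- tryCatch(conc_fd_ss(obs$time_h[keep_fd], p, r, single_dose = single),
                     error = function(e) NULL)
      if (is.null(c3)) return(NULL)
    }
    list(p = p, c1 = c1, c3 = c3)
  }

  resid_fn <- function(theta) {
    pr <- predict_both(theta)
    if (is.null(pr)) return(rep(1e6, sum(keep_pl) + sum(keep_fd)))
    r1 <- pr$c1 - obs$plasma[keep_pl]
    r3 <- if (any(keep_fd)) pr$c3 - obs$fd[keep_fd] else numeric(0)
    res <- c(r1, r3)
    if (weighting == "inv_pred2") {
      w <- pmax(c(pr$c1, pr$c3), 1e-3)
      res <- res / w
    }
    res
  }

  # NCA-informed center: V1 from dose and end-of-infusion Cmax; physiologic
  # box bounds keep the search off the flat large-k ridge
  cmax <- max(obs$plasma)
  v1_0 <- series$dose / cmax
  lo <- log(c(v1_0 / 3, 0.05, 0.05, 0.05))
  hi <- log(c(v1_0 * 3, 3, 3, 3))
  bound_lo <- log(c(0.5, 1e-3, 1e-3, 1e-4))
  bound_hi <- log(c(200, 20, 20, 20))
  if (!is.null(seed)) set.seed(seed)
  starts <- lhs::randomLHS(max(1L, n_starts), 4)
  starts <- sweep(sweep(starts, 2, hi - lo, "*"), 2, lo, "+")

  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                         lower = bound_lo, upper = bound_hi,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-8,
                           maxiter = 1000, maxfev = 4000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    if (ok) n_conv <- n_conv + 1L
    ssq <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || ssq < best$ssq) best <- list(fit = fit, ssq = ssq, ok = ok)
  }
  if (is.null(best) || !best$ok)
    stop("model fit failed to converge from any start; best objective so far: ",
         if (is.null(best)) NA else signif(best$ssq, 4))
  if (any(abs(best$fit$par - bound_lo) < 1e-6) || any(abs(best$fit$par - bound_hi) < 1e-6))
    warning("fitted parameter at a search bound for patient ", series$patient_id)

  theta <- best$fit$par
  pr <- predict_both(theta)
  p <- pr$p
  res1 <- obs$plasma[keep_pl] - pr$c1
  res3 <- if (any(keep_fd)) obs$fd[keep_fd] - pr$c3 else numeric(0)
  structure(list(params = p, objective = best$ssq,
                 residuals = list(plasma = res1, fd = res3),
                 converged = TRUE, n_starts_converged = n_conv,
                 cl_chdf = q * sc_measured, cl_nonchdf = p$k10 * p$V1,
                 sc_measured = sc_measured, patient_id = series$patient_id),
            class = "pk_fit")
}

#' Model-derived clearances
#'
#' Extracorporeal and non-CHDF clearance from a converged fit:
#' `CL_CHDF = (Q_F + Q_D) * SC` and `CL_nonCHDF = k10 * V1`. Their sum is
#' the model total clearance.
#'
#' @param fit a `pk_fit` object (or a [micro_params()] with `sc` supplied)
#' @param chdf the [chdf_settings()] used in the fit
#' @param sc sieving coefficient (needed only when `fit` is a bare
#'   parameter set)
#' @return Named numeric vector `c(cl_chdf = , cl_nonchdf = )` (L/h).
#' @export
derived_clearances <- function(fit, chdf, sc = NULL) {
  stopifnot(inherits(chdf, "chdf_settings"))
  if (inherits(fit, "pk_fit")) {
    p <- fit$params
    sc <- fit$sc_measured
  } else {
    stopifnot(inherits(fit, "micro_params"))
    p <- fit
    if (is.null(sc)) sc <- chdf$SC
  }
  c(cl_chdf = effluent_flow(chdf) * sc, cl_nonchdf = p$k10 * p$V1)
}

#' Standard two-stage population summary
#'
#' Each subject is fitted separately; the population is then summarised by
#' the arithmetic mean and sample SD (n-1 denominator) of `V1`, `k21` and
#' the per-subject macro constants `alpha`, `beta`. These four moments are
#' the inputs of the Monte Carlo population simulator.
#'
#' @param fits either a list of `pk_fit` objects or a data.frame with
#'   columns `V1`, `k21`, `alpha`, `beta` (extra columns are summarised
#'   too)
#' @return An object of class `population_stats`: list with named vectors
#'   `mean`, `sd`, `var` and the subject count `n`.
#' @export
two_stage <- function(fits) {
  if (is.data.frame(fits)) {
    df <- fits
  } else {
    stopifnot(all(vapply(fits, inherits, logical(1), "pk_fit")))
    df <- do.call(rbind, lapply(fits, function(f) {
      ab <- derive_macro_constants(f$params)
      data.frame(V1 = f$params$V1, k12 = f$params$k12, k21 = f$params$k21,
                 k10 = f$params$k10, k13 = f$params$k13,
                 alpha = ab[["alpha"]], beta = ab[["beta"]],
                 cl_chdf = f$cl_chdf, cl_nonchdf = f$cl_nonchdf)
    }))
  }
  if (nrow(df) < 2) stop("two-stage summary requires at least 2 subjects")
  num <- df[vapply(df, is.numeric, logical(1))]
  structure(list(mean = vapply(num, mean, numeric(1)),
                 sd = vapply(num, stats::sd, numeric(1)),
                 var = vapply(num, stats::var, numeric(1)),
                 n = nrow(df)),
            class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("Two-stage population summary (n = %d):\n", x$n))
  print(round(data.frame(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}

#' Construct population statistics directly
#'
#' For running the Monte Carlo simulator from externally supplied moments
#' rather than from fits.
#'
#' @param mean,sd named numeric vectors containing at least
#'   `V1`, `k21`, `alpha`, `beta`
#' @param n subject count behind the moments (informational)
#' @return A `population_stats` object.
#' @export
population_stats <- function(mean, sd, n = NA_integer_) {
  need <- c("V1", "k21", "alpha", "beta")
  if (!all(need %in% names(mean)) || !all(need %in% names(sd)))
    stop("mean and sd must name V1, k21, alpha, beta")
  if (any(sd[need] < 0)) stop("SDs must be >= 0")
  structure(list(mean = mean, sd = sd, var = sd^2, n = n),
            class = "population_stats")
}

#' Model-validation regression of summed clearances against NCA clearance
#'
#' Least-squares regression of non-compartmental total clearance (`y`) on
#' the model total clearance `CL_CHDF + CL_nonCHDF` (`x`) across patients.
#' Agreement (slope ~1, intercept ~0, r2 ~1) supports the compartment
#' model.
#'
#' @param cl_model per-patient `CL_CHDF + CL_nonCHDF` (L/h)
#' @param cl_nca per-patient NCA total clearance (L/h)
#' @return List with `slope`, `intercept`, `r_squared`, and the `lm` fit.
#' @export
clearance_validation_regression <- function(cl_model, cl_nca) {
  stopifnot(length(cl_model) == length(cl_nca), length(cl_model) >= 3)
  fit <- stats::lm(cl_nca ~ cl_model)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       fit = fit)
}
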