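#' Specification of a synthetic CHDF cohort
#'
#' Defines the virtual-patient generator that stands in for the study's raw
#' concentration data. True per-patient parameters are drawn log-normally
#' (guaranteeing positivity) with moments matched to the reference cohort's
#' two-stage estimates; observations follow the study sampling template
#' (pre-dose, end of infusion, 0.5/1/2/4 h post-infusion, trough) with
#' multiplicative proportional error and an assay floor of 0.1 ug/mL.
#'
#' @param n number of patients (>= 0; default 7, the study size)
#' @param param_means,param_sds named vectors over `V1`, `k12`, `k21`,
#'   `k10`; defaults are the reference cohort means/SDs
#' @param sc_mean,sc_sd moments of the membrane sieving coefficient
#' @param cv_prop proportional residual error CV (default 0.10)
#' @param lloq assay lower limit of quantification (ug/mL)
#' @param regimens list of [regimen()] objects assigned to patients in
#'   turn (recycled); default is the study's assignment pattern
#' @param chdf a [chdf_settings()]
#' @param seed optional integer seed
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 7,
                        param_means = c(V1 = 13.46, k12 = 0.75, k21 = 0.95, k10 = 0.39),
                        param_sds = c(V1 = 5.29, k12 = 0.71, k21 = 0.27, k10 = 0.22),
                        sc_mean = 1.00, sc_sd = 0.06,
                        cv_prop = 0.10, lloq = 0.1,
                        regimens = NULL, chdf = chdf_settings(), seed = NULL) {
  stopifnot(n >= 0, cv_prop >= 0, sc_mean > 0, sc_sd >= 0)
  need <- c("V1", "k12", "k21", "k10")
  if (!all(need %in% names(param_means)) || !all(need %in% names(param_sds)))
    stop("param_means and param_sds must name V1, k12, k21, k10")
  if (is.null(regimens)) {
    ref <- reference_patients()
    regimens <- lapply(seq_len(nrow(ref)), function(i)
      regimen(ref$dose_mg[i], ref$tau_h[i], ref$tinf_h[i]))
  }
  structure(list(n = n, param_means = param_means[need], param_sds = param_sds[need],
                 sc_mean = sc_mean, sc_sd = sc_sd, cv_prop = cv_prop,
                 lloq = lloq, regimens = regimens, chdf = chdf, seed = seed),
            class = "cohort_spec")
}

# lognormal draws with matched arithmetic mean and SD
.rlnorm_matched <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  sigma2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Generate a virtual cohort with true micro parameters
#'
#' Draws each patient's true `(V1, k12, k21, k10)` and membrane SC
#' log-normally with moments matched to the spec, ties `k13` to the circuit
#' flows and the true SC, and assigns regimens cyclically.
#'
#' @param spec a [cohort_spec()]
#' @return data.frame with one row per patient: `id`, true parameters,
#'   `sc`, `k13`, `k30`, and the regimen columns `dose`, `tau`, `tinf`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  if (n == 0) {
    return(data.frame(id = character(0), V1 = numeric(0), k12 = numeric(0),
                      k21 = numeric(0), k10 = numeric(0), sc = numeric(0),
                      k13 = numeric(0), k30 = numeric(0), dose = numeric(0),
                      tau = numeric(0), tinf = numeric(0)))
  }
  m <- spec$param_means; s <- spec$param_sds
  q <- effluent_flow(spec$chdf)
  out <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    V1 = .rlnorm_matched(n, m[["V1"]], s[["V1"]]),
    k12 = .rlnorm_matched(n, m[["k12"]], s[["k12"]]),
    k21 = .rlnorm_matched(n, m[["k21"]], s[["k21"]]),
    k10 = .rlnorm_matched(n, m[["k10"]], s[["k10"]]),
    sc = .rlnorm_matched(n, spec$sc_mean, spec$sc_sd),
    stringsAsFactors = FALSE
  )
  out$k13 <- q * out$sc / out$V1
  out$k30 <- q / spec$chdf$V3
  reg <- spec$regimens[((seq_len(n) - 1) %% length(spec$regimens)) + 1]
  out$dose <- vapply(reg, `[[`, numeric(1), "dose")
  out$tau <- vapply(reg, `[[`, numeric(1), "tau")
  out$tinf <- vapply(reg, `[[`, numeric(1), "tinf")
  out
}

#' Study sampling schedule for a regimen
#'
#' Pre-dose (t = 0, the steady-state trough), end of infusion, 0.5, 1, 2
#' and 4 h after the end of infusion (dropping any that fall beyond the
#' interval), and the trough just before the next infusion.
#'
#' @param r a [regimen()]
#' @return Numeric vector of sampling times (h since infusion start).
#' @export
sampling_schedule <- function(r) {
  post <- r$tinf + c(0, 0.5, 1, 2, 4)
  sort(unique(c(0, post[post < r$tau], r$tau)))
}

#' Simulate noisy observations for one virtual patient
#'
#' Evaluates the noise-free steady-state plasma and filtrate-dialysate
#' curves at the sampling schedule and applies independent multiplicative
#' lognormal error (median 1, CV as configured) to each observation.
#' Values below the assay floor are flagged below-quantification.
#'
#' @param patient one row of a [generate_cohort()] data.frame (or a list
#'   with the same fields), including `V3` via `chdf`
#' @param chdf the [chdf_settings()] used for the cohort
#' @param schedule sampling times (h); default [sampling_schedule()] of the
#'   patient's regimen
#' @param cv proportional error CV
#' @param lloq assay floor (ug/mL)
#' @param seed optional integer seed
#' @return A [conc_time_series()] object.
#' @export
simulate_observations <- function(patient, chdf = chdf_settings(),
                                  schedule = NULL, cv = 0.10, lloq = 0.1,
                                  seed = NULL) {
  r <- regimen(patient$dose, patient$tau, patient$tinf)
  if (is.null(schedule)) schedule <- sampling_schedule(r)
  if (any(schedule < 0) || any(schedule > r$tau))
    stop("sampling schedule must lie within the dosing interval [0, tau]")
  p <- micro_params(patient$V1, patient$k12, patient$k21, patient$k10,
                    patient$k13, k30 = patient$k30, V3 = chdf$V3)
  c1 <- conc_central_ss(schedule, p, r)
  c3 <- conc_fd_ss(schedule, p, r)
  if (!is.null(seed)) set.seed(seed)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    c1 <- c1 * stats::rlnorm(length(c1), 0, sdlog)
    c3 <- c3 * stats::rlnorm(length(c3), 0, sdlog)
  }
  conc_time_series(patient_id = patient$id, time_h = schedule,
                   plasma = c1, fd = c3, dose = r$dose, tau = r$tau,
                   tinf = r$tinf, lloq = lloq)
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: draws a cohort and simulates one steady-state
#' interval of noisy observations per patient. All randomness flows from
#' the spec seed.
#'
#' @param spec a [cohort_spec()]
#' @return List with `cohort` (truth) and `series` (list of
#'   [conc_time_series()]).
#' @export
generate_dataset <- function(spec) {
  cohort <- generate_cohort(spec) # consumes spec$seed
  series <- lapply(seq_len(nrow(cohort)), function(i)
    simulate_observations(cohort[i, ], chdf = spec$chdf,
                          cv = spec$cv_prop, lloq = spec$lloq))
  list(cohort = cohort, series = series)
}
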