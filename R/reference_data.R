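#' Reference cohort: patient characteristics
#'
#' Demographics, dosing assignment and pre-CHDF renal function of the seven
#' adult patients of the clinical biapenem-during-CHDF study that the
#' package's defaults and validation checks are built around. GFR is the
#' per-body value (mL/min) evaluated just before CHDF was started.
#'
#' @return data.frame with columns `patient`, `sex`, `age`, `ht_cm`,
#'   `bw_kg`, `bsa_m2`, `tau_h`, `dose_mg`, `tinf_h`, `gfr_mlmin`.
#' @export
reference_patients <- function() {
  data.frame(
    patient = LETTERS[1:7],
    sex = c("M", "M", "F", "M", "M", "M", "F"),
    age = c(64, 70, 33, 65, 75, 55, 80),
    ht_cm = c(167, 157, 160, 166, 162, 164, 145),
    bw_kg = c(95.1, 53.1, 57.5, 65.0, 47.8, 64.8, 66.7),
    bsa_m2 = c(2.03, 1.50, 1.61, 1.70, 1.45, 1.69, 1.60),
    tau_h = c(12, 8, 12, 6, 8, 6, 8),
    dose_mg = rep(300, 7),
    tinf_h = c(1, 1, 1, 1, 1, 0.5, 0.5),
    gfr_mlmin = c(20.4, 17.0, 15.8, 58.8, 31.0, 63.3, 8.4),
    stringsAsFactors = FALSE
  )
}

#' Reference cohort: non-compartmental results
#'
#' Published per-patient NCA metrics of the reference cohort: plasma and
#' filtrate-dialysate AUC over the sampled interval (patient B: first-dose
#' AUC extrapolated to infinity), sieving coefficient, total clearance,
#' Vd_ss, Cmax and terminal half-lives.
#'
#' @return data.frame, one row per patient.
#' @export
reference_nca <- function() {
  data.frame(
    patient = LETTERS[1:7],
    auc_plasma = c(37.7, 72.4, 63.2, 31.4, 54.3, 32.2, 78.2),
    auc_fd = c(37.6, 79.7, 61.2, 29.9, 55.3, 29.9, 79.6),
    sc = c(1.00, 1.10, 0.97, 0.95, 1.02, 0.93, 1.02),
    cl_tot = c(7.96, 4.14, 4.75, 9.54, 5.53, 9.32, 3.84),
    vdss = c(0.33, 0.46, 0.30, 0.35, 0.33, 0.24, 0.17),
    cmax_plasma = c(11.92, 15.93, 20.08, 12.15, 19.42, 23.93, 25.80),
    cmax_fd = c(11.29, 12.09, 19.43, 9.13, 19.55, 15.37, 24.24),
    thalf_plasma = c(3.99, 3.97, 3.42, 2.05, 2.83, 1.38, 3.39),
    thalf_fd = c(3.20, 5.43, 3.62, 2.20, 2.73, 1.25, 3.66),
    first_dose = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Reference cohort: compartmental parameter estimates
#'
#' Published per-patient micro constants of the three-compartment model and
#' the derived clearances `CL_CHDF = (Q_F + Q_D) * SC` and
#' `CL_nonCHDF = k10 * V1`.
#'
#' @return data.frame with columns `patient`, `V1`, `k12`, `k21`, `k10`,
#'   `k13`, `cl_chdf`, `cl_nonchdf`.
#' @export
reference_micro <- function() {
  data.frame(
    patient = LETTERS[1:7],
    V1 = c(11.09, 17.45, 9.51, 23.84, 11.74, 10.19, 10.43),
    k12 = c(2.26, 0.33, 0.74, 0.18, 0.26, 0.69, 0.79),
    k21 = c(1.10, 0.66, 0.92, 1.13, 0.51, 1.08, 1.25),
    k10 = c(0.56, 0.15, 0.33, 0.34, 0.33, 0.78, 0.22),
    k13 = c(0.14, 0.09, 0.16, 0.06, 0.14, 0.14, 0.15),
    cl_chdf = c(1.53, 1.65, 1.55, 1.43, 1.63, 1.39, 1.53),
    cl_nonchdf = c(6.24, 2.54, 3.11, 8.04, 3.93, 7.92, 2.27),
    stringsAsFactors = FALSE
  )
}

#' Two-stage population statistics of the reference cohort
#'
#' Derives per-patient macro constants (`alpha`, `beta`) from the published
#' micro constants and returns the standard two-stage mean/SD of
#' `V1`, `k21`, `alpha`, `beta` — the sampling space of the Monte Carlo
#' population simulator.
#'
#' @return A `population_stats` object (see [two_stage()]).
#' @export
reference_population_stats <- function() {
  tab <- reference_micro()
  ab <- t(vapply(seq_len(nrow(tab)), function(i) {
    derive_macro_constants(micro_params(tab$V1[i], tab$k12[i], tab$k21[i],
                                        tab$k10[i], tab$k13[i]))
  }, numeric(2)))
  two_stage(data.frame(V1 = tab$V1, k21 = tab$k21,
                       alpha = ab[, 1], beta = ab[, 2]))
}

#' Mean micro-constant parameter set of the reference cohort
#'
#' The cohort-mean compartmental parameters (V1 13.46 L, k12 0.75, k21 0.95,
#' k10 0.39 1/h) with `k13` and `k30` tied to the CHDF settings
#' (`k13 = (Q_F+Q_D) * SC / V1`). This is the parameter set used for the
#' deterministic regimen exploration of the fraction of time above the MIC.
#'
#' @param chdf a [chdf_settings()]; default standard circuit (effluent
#'   1.5 L/h, SC 1)
#' @return A [micro_params()] object.
#' @export
reference_mean_micro <- function(chdf = chdf_settings()) {
  fk <- derive_filter_constants(chdf, 13.46)
  micro_params(V1 = 13.46, k12 = 0.75, k21 = 0.95, k10 = 0.39,
               k13 = fk[["k13"]], k30 = fk[["k30"]], V3 = chdf$V3)
}
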