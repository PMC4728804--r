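#' Area under the curve by the logarithmic trapezoidal rule
#'
#' Interval-wise AUC: when both endpoint concentrations are positive and
#' unequal the logarithmic rule
#' `(c_i - c_{i+1}) * dt / log(c_i / c_{i+1})` is used (exact on
#' exponential segments); when the endpoints are equal, rising, or either is
#' zero the linear trapezoid is used.
#'
#' @param times sampling times (h), strictly increasing
#' @param concs concentrations (ug/mL), all >= 0
#' @return AUC in mg.h/L.
#' @export
#' @examples
#' auc_log_trapezoid(c(0, 1, 2), 10 * exp(-0.5 * c(0, 1, 2)))
auc_log_trapezoid <- function(times, concs) {
  stopifnot(is.numeric(times), is.numeric(concs), length(times) == length(concs))
  if (length(times) < 2) stop("at least 2 points are required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(concs < 0)) stop("concentrations must be >= 0")
  c1 <- concs[-length(concs)]
  c2 <- concs[-1]
  dt <- diff(times)
  uselog <- c1 > 0 & c2 > 0 & c1 != c2
  auc <- ifelse(uselog,
                (c1 - c2) * dt / log(c1 / c2),
                (c1 + c2) / 2 * dt)
  sum(auc)
}

# first moment integral (t * C), linear trapezoid; used for Vd_ss only
.aumc_linear <- function(times, concs) {
  y <- times * concs
  sum((y[-length(y)] + y[-1]) / 2 * diff(times))
}

#' Terminal elimination rate and half-life
#'
#' Least-squares fit of `log(conc)` against time over the last
#' `n_terminal` quantifiable post-infusion points; `lambda_z` is minus the
#' slope and `T1/2 = log(2) / lambda_z`.
#'
#' @param times sampling times (h)
#' @param concs concentrations (ug/mL)
#' @param n_terminal number of terminal points to use (>= 3)
#' @return List with `lambda_z` (1/h), `t_half` (h), `r2_adj`, `n_used`.
#' @export
terminal_halflife <- function(times, concs, n_terminal = 3) {
  stopifnot(length(times) == length(concs))
  keep <- concs > 0
  times <- times[keep]; concs <- concs[keep]
  if (n_terminal < 3) stop("at least 3 terminal points are required")
  if (length(times) < n_terminal) stop("fewer positive points than n_terminal")
  idx <- seq(length(times) - n_terminal + 1, length(times))
  fit <- stats::lm(log(concs[idx]) ~ times[idx])
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("terminal phase is not declining; cannot estimate lambda_z")
  lambda <- -slope
  # summary.lm warns on exact fits; noise-free data are legitimate here
  r2 <- suppressWarnings(summary(fit)$adj.r.squared)
  list(lambda_z = lambda, t_half = log(2) / lambda,
       r2_adj = r2, n_used = n_terminal)
}

#' Extrapolate AUC to infinity
#'
#' `AUC(0, Inf) = AUC(0, t_last) + c_last / lambda_z`. The extrapolated
#' fraction is reported and flagged (with a warning) when it exceeds 20%.
#'
#' @param auc_0_tlast AUC up to the last quantifiable sample (mg.h/L)
#' @param c_last last quantifiable concentration (ug/mL, > 0)
#' @param lambda_z terminal elimination rate constant (1/h, > 0)
#' @return List with `auc_inf`, `extrap_pct`, `flagged`.
#' @export
auc_extrapolate_inf <- function(auc_0_tlast, c_last, lambda_z) {
  if (c_last <= 0) stop("c_last must be > 0")
  if (lambda_z <= 0) stop("lambda_z must be > 0")
  tail <- c_last / lambda_z
  auc_inf <- auc_0_tlast + tail
  pct <- 100 * tail / auc_inf
  flagged <- pct > 20
  if (flagged) warning(sprintf("extrapolated AUC fraction is %.1f%% (> 20%%)", pct))
  list(auc_inf = auc_inf, extrap_pct = pct, flagged = flagged)
}

#' Concentration-time series for one patient
#'
#' Paired plasma and filtrate-dialysate observations over one dosing
#' interval, with the dosing context needed for NCA and model fitting.
#' Values below the assay lower limit of quantification are flagged; they
#' are treated as zero for AUC tails and excluded from terminal-slope
#' estimation.
#'
#' @param patient_id identifier
#' @param time_h sampling times since the start of the infusion (h),
#'   strictly increasing
#' @param plasma plasma concentrations (ug/mL)
#' @param fd filtrate-dialysate concentrations (ug/mL), or `NULL` if the FD
#'   channel was not collected
#' @param dose dose amount (mg)
#' @param tau dosing interval (h)
#' @param tinf infusion duration (h)
#' @param lloq assay lower limit of quantification (ug/mL)
#' @param first_dose logical; `TRUE` when the series follows the first
#'   administration (AUC is then extrapolated to infinity) rather than a
#'   steady-state interval
#' @return An object of class `conc_series`.
#' @export
conc_time_series <- function(patient_id, time_h, plasma, fd = NULL,
                             dose, tau, tinf, lloq = 0.1, first_dose = FALSE) {
  stopifnot(is.numeric(time_h), is.numeric(plasma))
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (any(plasma < 0)) stop("plasma concentrations must be >= 0")
  if (!is.null(fd)) {
    stopifnot(length(fd) == length(plasma))
    if (any(fd < 0)) stop("FD concentrations must be >= 0")
  }
  if (any(time_h < 0) || any(time_h > tau + 1e-9))
    stop("all observations must lie within one dosing interval [0, tau]")
  obs <- data.frame(time_h = time_h, plasma = plasma,
                    fd = if (is.null(fd)) NA_real_ else fd)
  obs$bql_plasma <- obs$plasma < lloq
  obs$bql_fd <- !is.na(obs$fd) & obs$fd < lloq
  structure(list(patient_id = patient_id, obs = obs, dose = dose, tau = tau,
                 tinf = tinf, lloq = lloq, first_dose = first_dose,
                 has_fd = !is.null(fd)),
            class = "conc_series")
}

#' Non-compartmental summary of a concentration-time series
#'
#' Computes the standard exposure metrics for one patient: log-trapezoidal
#' AUC over the interval for plasma and filtrate-dialysate, sieving
#' coefficient `SC = AUC_FD / AUC_plasma`, total clearance
#' `CL_tot = dose / AUC_plasma`, Cmax and terminal half-life per channel,
#' and a steady-state-interval moment estimate of Vd_ss
#' (`dose * AUMC / AUC^2`, also per kg when a body weight is supplied).
#' For a first-dose series the plasma AUC is extrapolated to infinity using
#' the terminal slope.
#'
#' @param series a [conc_time_series()]
#' @param n_terminal terminal points for the half-life fit
#' @param weight_kg optional body weight for the per-kg Vd_ss
#' @return One-row data.frame with columns `patient_id`, `auc_plasma`,
#'   `auc_fd`, `sc`, `cl_tot`, `vdss_l`, `vdss_l_kg`, `cmax_plasma`,
#'   `cmax_fd`, `thalf_plasma`, `thalf_fd`, `extrap_pct`.
#' @export
nca_summary <- function(series, n_terminal = 3, weight_kg = NULL) {
  stopifnot(inherits(series, "conc_series"))
  obs <- series$obs
  pl <- ifelse(obs$bql_plasma, 0, obs$plasma)
  auc_pl <- auc_log_trapezoid(obs$time_h, pl)
  hl_pl <- tryCatch(terminal_halflife(obs$time_h[!obs$bql_plasma],
                                      obs$plasma[!obs$bql_plasma], n_terminal),
                    error = function(e) NULL)
  extrap_pct <- NA_real_
  if (isTRUE(series$first_dose)) {
    if (is.null(hl_pl)) stop("first-dose extrapolation requires a terminal slope")
    qlast <- max(which(!obs$bql_plasma))
    ext <- auc_extrapolate_inf(auc_pl, obs$plasma[qlast], hl_pl$lambda_z)
    auc_pl <- ext$auc_inf
    extrap_pct <- ext$extrap_pct
  }
  cl_tot <- series$dose / auc_pl
  aumc <- .aumc_linear(obs$time_h, pl)
  vdss <- series$dose * aumc / auc_pl^2
  auc_fd <- sc <- cmax_fd <- thalf_fd <- NA_real_
  if (series$has_fd) {
    fd <- ifelse(obs$bql_fd, 0, obs$fd)
    auc_fd <- auc_log_trapezoid(obs$time_h, fd)
    sc <- auc_fd / auc_pl
    cmax_fd <- max(fd)
    hl_fd <- tryCatch(terminal_halflife(obs$time_h[!obs$bql_fd],
                                        obs$fd[!obs$bql_fd], n_terminal),
                      error = function(e) NULL)
    if (!is.null(hl_fd)) thalf_fd <- hl_fd$t_half
  }
  data.frame(patient_id = series$patient_id,
             auc_plasma = auc_pl, auc_fd = auc_fd, sc = sc, cl_tot = cl_tot,
             vdss_l = vdss,
             vdss_l_kg = if (is.null(weight_kg)) NA_real_ else vdss / weight_kg,
             cmax_plasma = max(pl), cmax_fd = cmax_fd,
             thalf_plasma = if (is.null(hl_pl)) NA_real_ else hl_pl$t_half,
             thalf_fd = thalf_fd, extrap_pct = extrap_pct,
             stringsAsFactors = FALSE)
}
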