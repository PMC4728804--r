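#' CHDF circuit settings
#'
#' Container for the continuous hemodiafiltration operating conditions that
#' determine extracorporeal drug clearance. Defaults are the standard circuit
#' settings of the study cohort: blood flow 80 mL/min, dialysate flow
#' 500 mL/h, substitution flow 500 mL/h, filtration flow 1000 mL/h, a freely
#' sieved solute (SC = 1) and a hemofilter blood (priming) volume of 0.10 L,
#' typical for a 1.3 m2 hollow-fiber polysulfone filter.
#'
#' All flows are in L/h; convert mL/min inputs with [mlmin_to_lh()] at the
#' boundary. The effluent flow `Q_F + Q_D` drives both the plasma-side
#' transfer constant `k13 = (Q_F + Q_D) * SC / V1` and the filter washout
#' constant `k30 = (Q_F + Q_D) / V3`.
#'
#' @param Q_B blood flow rate (L/h)
#' @param Q_D dialysate flow rate (L/h)
#' @param Q_F filtration flow rate (L/h)
#' @param Q_S substitution flow rate (L/h)
#' @param SC sieving coefficient of the membrane (dimensionless, >= 0)
#' @param V3 hemofilter blood volume (L, > 0)
#' @return An object of class `chdf_settings`.
#' @export
#' @examples
#' chdf <- chdf_settings()
#' effluent_flow(chdf) # 1.5 L/h
chdf_settings <- function(Q_B = 4.8, Q_D = 0.5, Q_F = 1.0, Q_S = 0.5,
                          SC = 1.0, V3 = 0.10) {
  stopifnot(is.numeric(Q_B), is.numeric(Q_D), is.numeric(Q_F),
            is.numeric(Q_S), is.numeric(SC), is.numeric(V3))
  if (any(c(Q_B, Q_D, Q_F, Q_S) < 0)) stop("CHDF flows must be >= 0")
  if (SC < 0) stop("sieving coefficient must be >= 0")
  if (V3 <= 0) stop("hemofilter volume V3 must be > 0")
  structure(list(Q_B = Q_B, Q_D = Q_D, Q_F = Q_F, Q_S = Q_S,
                 SC = SC, V3 = V3),
            class = "chdf_settings")
}

#' @rdname chdf_settings
#' @param chdf a `chdf_settings` object
#' @export
effluent_flow <- function(chdf) {
  stopifnot(inherits(chdf, "chdf_settings"))
  chdf$Q_F + chdf$Q_D
}

#' Dosing regimen
#'
#' An intermittent intravenous infusion regimen: dose amount, infusion
#' duration and dosing interval. The implied zero-order infusion rate
#' `R_inf = dose / T_inf` (mg/h) is stored on the object.
#'
#' @param dose dose per administration (mg, > 0)
#' @param tau dosing interval (h)
#' @param tinf infusion duration (h, `0 < tinf <= tau`)
#' @return An object of class `regimen`.
#' @export
#' @examples
#' regimen(300, tau = 6, tinf = 1)
regimen <- function(dose, tau, tinf) {
  stopifnot(is.numeric(dose), is.numeric(tau), is.numeric(tinf))
  if (dose <= 0) stop("dose must be > 0")
  if (tinf <= 0 || tinf > tau) stop("infusion time must satisfy 0 < tinf <= tau")
  structure(list(dose = dose, tau = tau, tinf = tinf, r_inf = dose / tinf),
            class = "regimen")
}

#' Micro-constant parameterisation of the three-compartment CHDF model
#'
#' Per-patient micro rate constants and volumes: a central compartment
#' (volume `V1`) exchanging with a peripheral compartment (`k12`, `k21`),
#' eliminating by non-CHDF routes (`k10`), and feeding the hemofilter
#' compartment (`k13`) which is washed out into the filtrate-dialysate
#' stream (`k30`, filter volume `V3`). `k30` and `V3` are only needed for
#' the filtrate-dialysate concentration and the ODE simulator; plasma
#' kinetics are fully determined by `V1, k12, k21, k10, k13`.
#'
#' @param V1 central volume of distribution (L, > 0)
#' @param k12,k21 inter-compartment rate constants (1/h)
#' @param k10 central (non-CHDF) elimination rate constant (1/h)
#' @param k13 central-to-filter transfer rate constant (1/h)
#' @param k30 filter washout rate constant (1/h); `NA` if unused
#' @param V3 hemofilter blood volume (L, > 0)
#' @return An object of class `micro_params`.
#' @seealso [derive_macro_constants()], [derive_filter_constants()]
#' @export
micro_params <- function(V1, k12, k21, k10, k13, k30 = NA_real_, V3 = 0.10) {
  stopifnot(is.numeric(V1), is.numeric(k12), is.numeric(k21),
            is.numeric(k10), is.numeric(k13))
  if (V1 <= 0) stop("V1 must be > 0")
  if (V3 <= 0) stop("V3 must be > 0")
  if (k21 <= 0) stop("k21 must be > 0")
  if (any(c(k12, k10, k13) < 0)) stop("k12, k10, k13 must be >= 0")
  if (!is.na(k30) && k30 < 0) stop("k30 must be >= 0")
  structure(list(V1 = V1, k12 = k12, k21 = k21, k10 = k10,
                 k13 = k13, k30 = as.numeric(k30), V3 = V3),
            class = "micro_params")
}

#' Macro-constant parameterisation of the plasma disposition
#'
#' The four-parameter set `(V1, k21, alpha, beta)` that fully determines the
#' bi-exponential plasma concentration profile, and is the sampling space of
#' the Monte Carlo population simulator. `alpha` and `beta` are the hybrid
#' rate constants of the distribution and elimination phases.
#'
#' @param V1 central volume (L, > 0)
#' @param k21 peripheral-to-central rate constant (1/h, > 0)
#' @param alpha,beta macro rate constants (1/h), `alpha > beta > 0`
#' @return An object of class `macro_params`.
#' @export
macro_params <- function(V1, k21, alpha, beta) {
  stopifnot(is.numeric(V1), is.numeric(k21), is.numeric(alpha), is.numeric(beta))
  if (V1 <= 0) stop("V1 must be > 0")
  if (k21 <= 0) stop("k21 must be > 0")
  if (beta <= 0) stop("beta must be > 0")
  if (alpha <= beta) stop("macro constants must satisfy alpha > beta")
  .check_distinct(alpha, beta, "alpha", "beta")
  structure(list(V1 = V1, k21 = k21, alpha = alpha, beta = beta),
            class = "macro_params")
}

# degeneracy guard: closed forms divide by differences of rate constants
.check_distinct <- function(a, b, na, nb, tol = 1e-9) {
  if (abs(a - b) < tol * max(abs(a), abs(b))) {
    stop(sprintf("degenerate rate constants: %s and %s coincide (relative gap < %g)",
                 na, nb, tol))
  }
  invisible(TRUE)
}

#' Macro rate constants from micro constants
#'
#' Computes the hybrid rate constants of the bi-exponential plasma profile
#' from the micro constants via the sum/product relations
#' `alpha + beta = k12 + k21 + k10 + k13` and
#' `alpha * beta = k21 * (k10 + k13)` (elimination `k10 + k13` acting from
#' the central compartment).
#'
#' @param p a [micro_params()] object
#' @return Named numeric vector `c(alpha = , beta = )` with `alpha >= beta`.
#' @export
#' @examples
#' derive_macro_constants(micro_params(11.09, 2.26, 1.10, 0.56, 0.14))
derive_macro_constants <- function(p) {
  stopifnot(inherits(p, "micro_params"))
  s <- p$k12 + p$k21 + p$k10 + p$k13
  pr <- p$k21 * (p$k10 + p$k13)
  disc <- s^2 - 4 * pr
  if (disc < 0) stop("negative discriminant: invalid micro constants")
  d <- sqrt(disc)
  alpha <- (s + d) / 2
  beta <- (s - d) / 2
  .check_distinct(alpha, beta, "alpha", "beta")
  c(alpha = alpha, beta = beta)
}

#' Filter rate constants from CHDF settings
#'
#' The central-to-filter and filter-washout rate constants are fixed by the
#' circuit: `k13 = (Q_F + Q_D) * SC / V1` and `k30 = (Q_F + Q_D) / V3`.
#'
#' @param chdf a [chdf_settings()] object
#' @param V1 central volume (L, > 0)
#' @return Named numeric vector `c(k13 = , k30 = )` (1/h).
#' @export
derive_filter_constants <- function(chdf, V1) {
  stopifnot(inherits(chdf, "chdf_settings"))
  if (!is.numeric(V1) || V1 <= 0) stop("V1 must be > 0")
  q <- effluent_flow(chdf)
  c(k13 = q * chdf$SC / V1, k30 = q / chdf$V3)
}

#' Convert a micro-constant set to its macro form
#'
#' @param p a [micro_params()] or [macro_params()] object
#' @return A [macro_params()] object.
#' @export
as_macro_params <- function(p) {
  if (inherits(p, "macro_params")) return(p)
  stopifnot(inherits(p, "micro_params"))
  ab <- derive_macro_constants(p)
  macro_params(V1 = p$V1, k21 = p$k21, alpha = ab[["alpha"]], beta = ab[["beta"]])
}

#' @export
print.chdf_settings <- function(x, ...) {
  cat(sprintf("CHDF settings: Q_B %.2f, Q_D %.2f, Q_F %.2f, Q_S %.2f L/h; SC %.2f; V3 %.2f L\n",
              x$Q_B, x$Q_D, x$Q_F, x$Q_S, x$SC, x$V3))
  cat(sprintf("  effluent flow Q_F+Q_D = %.2f L/h\n", x$Q_F + x$Q_D))
  invisible(x)
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Regimen: %g mg over %g h every %g h (R_inf %.1f mg/h)\n",
              x$dose, x$tinf, x$tau, x$r_inf))
  invisible(x)
}

#' @export
print.micro_params <- function(x, ...) {
  cat(sprintf("Micro constants: V1 %.2f L; k12 %.3f, k21 %.3f, k10 %.3f, k13 %.3f, k30 %s 1/h; V3 %.2f L\n",
              x$V1, x$k12, x$k21, x$k10, x$k13,
              if (is.na(x$k30)) "NA" else sprintf("%.2f", x$k30), x$V3))
  invisible(x)
}

#' @export
print.macro_params <- function(x, ...) {
  cat(sprintf("Macro constants: V1 %.2f L; k21 %.3f; alpha %.4f, beta %.4f 1/h\n",
              x$V1, x$k21, x$alpha, x$beta))
  invisible(x)
}
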