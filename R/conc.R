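#' Steady-state plasma concentration under intermittent infusion
#'
#' Closed-form plasma (central compartment) concentration at time `t` within
#' a dosing interval, at steady state under repeated zero-order infusions.
#' The profile is the superposition of the current infusion and the
#' accumulated tail of all previous doses; it is continuous at the end of
#' infusion and periodic with period `tau`. With `single_dose = TRUE` the
#' accumulation factors are dropped and the curve is the response to one
#' infusion starting at `t = 0`.
#'
#' Times outside `[0, tau]` are folded back into the interval at steady
#' state (the profile is periodic); in single-dose mode the decline simply
#' continues.
#'
#' @param t time since the start of an infusion (h); vectorised
#' @param m a [macro_params()] or [micro_params()] object
#' @param r a [regimen()]
#' @param single_dose logical; evaluate the first-dose (no accumulation)
#'   profile instead of steady state
#' @return Concentration in ug/mL (= mg/L), same length as `t`.
#' @export
#' @examples
#' m <- macro_params(V1 = 13.46, k21 = 0.95, alpha = 1.9582, beta = 0.2433)
#' conc_central_ss(c(0, 1, 6), m, regimen(300, 6, 1))
conc_central_ss <- function(t, m, r, single_dose = FALSE) {
  m <- as_macro_params(m)
  stopifnot(inherits(r, "regimen"), is.numeric(t))
  if (any(t < 0)) stop("t must be >= 0")
  a <- m$alpha; b <- m$beta; k21 <- m$k21
  tau <- r$tau; tinf <- r$tinf
  tt <- if (single_dose) t else t %% tau
  # fold t = tau onto the end of the interval, not its start
  if (!single_dose) tt[t > 0 & tt == 0] <- tau
  Aa <- (k21 - a) / (a * (b - a))
  Ab <- (k21 - b) / (b * (a - b))
  acc <- function(rate) if (single_dose) 0 else exp(-rate * tau) / (1 - exp(-rate * tau))
  accpost <- function(rate) if (single_dose) 1 else 1 / (1 - exp(-rate * tau))
  during <- tt <= tinf
  out <- numeric(length(tt))
  if (any(during)) {
    td <- tt[during]
    out[during] <-
      Aa * (exp(a * tinf) - 1) * acc(a) * exp(-a * td) +
      Ab * (exp(b * tinf) - 1) * acc(b) * exp(-b * td) +
      Aa * (1 - exp(-a * td)) + Ab * (1 - exp(-b * td))
  }
  if (any(!during)) {
    tp <- tt[!during]
    out[!during] <-
      Aa * (exp(a * tinf) - 1) * accpost(a) * exp(-a * tp) +
      Ab * (exp(b * tinf) - 1) * accpost(b) * exp(-b * tp)
  }
  r$r_inf / m$V1 * out
}

#' Steady-state filtrate-dialysate concentration under intermittent infusion
#'
#' Closed-form concentration in the filtrate-dialysate (hemofilter effluent)
#' stream at time `t` within a dosing interval at steady state. Requires the
#' full micro-constant set including `k13`, `k30` and `V3`. When `k13 = 0`
#' no drug reaches the filter and the result is identically zero.
#'
#' @inheritParams conc_central_ss
#' @param p a [micro_params()] object with finite `k30`
#' @return Concentration in ug/mL, same length as `t`.
#' @export
conc_fd_ss <- function(t, p, r, single_dose = FALSE) {
  stopifnot(inherits(p, "micro_params"), inherits(r, "regimen"), is.numeric(t))
  if (any(t < 0)) stop("t must be >= 0")
  if (is.na(p$k30)) stop("conc_fd_ss requires k30 (set from CHDF flows and V3)")
  if (p$k13 == 0) return(rep(0, length(t)))
  ab <- derive_macro_constants(p)
  a <- ab[["alpha"]]; b <- ab[["beta"]]
  k21 <- p$k21; k30 <- p$k30
  .check_distinct(k30, a, "k30", "alpha")
  .check_distinct(k30, b, "k30", "beta")
  tau <- r$tau; tinf <- r$tinf
  tt <- if (single_dose) t else t %% tau
  if (!single_dose) tt[t > 0 & tt == 0] <- tau
  Ba <- (k21 - a) / (a * (b - a) * (k30 - a))
  Bb <- (k21 - b) / (b * (a - b) * (k30 - b))
  Bk <- (k21 - k30) / (k30 * (a - k30) * (b - k30))
  acc <- function(rate) if (single_dose) 0 else exp(-rate * tau) / (1 - exp(-rate * tau))
  accpost <- function(rate) if (single_dose) 1 else 1 / (1 - exp(-rate * tau))
  during <- tt <= tinf
  out <- numeric(length(tt))
  if (any(during)) {
    td <- tt[during]
    out[during] <-
      Ba * (exp(a * tinf) - 1) * acc(a) * exp(-a * td) +
      Bb * (exp(b * tinf) - 1) * acc(b) * exp(-b * td) +
      Bk * (exp(k30 * tinf) - 1) * acc(k30) * exp(-k30 * td) +
      Ba * (1 - exp(-a * td)) + Bb * (1 - exp(-b * td)) + Bk * (1 - exp(-k30 * td))
  }
  if (any(!during)) {
    tp <- tt[!during]
    out[!during] <-
      Ba * (exp(a * tinf) - 1) * accpost(a) * exp(-a * tp) +
      Bb * (exp(b * tinf) - 1) * accpost(b) * exp(-b * tp) +
      Bk * (exp(k30 * tinf) - 1) * accpost(k30) * exp(-k30 * tp)
  }
  r$r_inf * p$k13 / p$V3 * out
}
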