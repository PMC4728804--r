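#' Body surface area (Japanese sex-specific power law)
#'
#' `BSA = 105.29 * Ht^0.619 * BW^0.460 / 10000` for males and
#' `BSA = 82.84 * Ht^0.689 * BW^0.437 / 10000` for females.
#'
#' @param sex `"M"`/`"male"` or `"F"`/`"female"`; vectorised
#' @param ht_cm height (cm)
#' @param bw_kg body weight (kg)
#' @return BSA in m2.
#' @export
#' @examples
#' body_surface_area("M", 167, 95.1) # ~2.03
body_surface_area <- function(sex, ht_cm, bw_kg) {
  sex <- .norm_sex(sex)
  if (any(ht_cm <= 0) || any(bw_kg <= 0)) stop("height and weight must be > 0")
  ifelse(sex == "M",
         105.29 * ht_cm^0.619 * bw_kg^0.460 / 1e4,
         82.84 * ht_cm^0.689 * bw_kg^0.437 / 1e4)
}

#' Estimated GFR (Japanese equation)
#'
#' `eGFR = 194 * Scr^-1.094 * Age^-0.287` (mL/min/1.73 m2), multiplied by
#' 0.739 for females.
#'
#' @param sex `"M"` or `"F"`; vectorised
#' @param scr serum creatinine (mg/dL, > 0); convert umol/L inputs with
#'   [scr_umol_to_mgdl()]
#' @param age age (years, > 0)
#' @return eGFR in mL/min/1.73 m2.
#' @export
egfr_japanese <- function(sex, scr, age) {
  sex <- .norm_sex(sex)
  if (any(scr <= 0) || any(age <= 0)) stop("Scr and Age must be > 0")
  base <- 194 * scr^-1.094 * age^-0.287
  ifelse(sex == "F", 0.739 * base, base)
}

#' Per-body GFR from normalised eGFR
#'
#' `GFR = eGFR * BSA / 1.73` (mL/min/body).
#'
#' @param egfr eGFR (mL/min/1.73 m2)
#' @param bsa body surface area (m2)
#' @return GFR in mL/min/body.
#' @export
gfr_per_body <- function(egfr, bsa) {
  if (any(egfr <= 0) || any(bsa <= 0)) stop("inputs must be > 0")
  egfr * bsa / 1.73
}

#' Unit converters
#'
#' Flow/clearance and creatinine unit conversions applied at the I/O
#' boundary: internally the package works in L/h, hours and mg/dL.
#'
#' @param x numeric vector
#' @return Converted values.
#' @export
mlmin_to_lh <- function(x) x * 0.06

#' @rdname mlmin_to_lh
#' @export
lh_to_mlmin <- function(x) x / 0.06

#' @rdname mlmin_to_lh
#' @export
scr_umol_to_mgdl <- function(x) x / 88.4

#' Non-renal clearance of biapenem in healthy adults
#'
#' Descriptive reference value: total clearance times the fraction not
#' excreted in urine as unchanged drug or metabolites. With the reported
#' healthy-adult values (CL_tot 12.9 L/h, 60% unchanged urinary excretion,
#' 15% urinary metabolites) this gives about 3.23 L/h, the benchmark against
#' which the cohort's non-CHDF clearance is discussed.
#'
#' @param cl_tot total clearance (L/h)
#' @param f_urine_unchanged fraction excreted unchanged in urine
#' @param f_urine_metab fraction excreted as urinary metabolites
#' @return Non-renal clearance (L/h).
#' @export
nonrenal_clearance_healthy <- function(cl_tot = 12.9,
                                       f_urine_unchanged = 0.60,
                                       f_urine_metab = 0.15) {
  stopifnot(cl_tot > 0, f_urine_unchanged >= 0, f_urine_metab >= 0,
            f_urine_unchanged + f_urine_metab <= 1)
  cl_tot * (1 - f_urine_unchanged - f_urine_metab)
}

.norm_sex <- function(sex) {
  s <- toupper(substr(as.character(sex), 1, 1))
  if (any(!s %in% c("M", "F"))) stop("unknown sex code; use 'M'/'F'")
  s
}
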