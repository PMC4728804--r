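# shared fixtures: cohort-mean parameter set, standard circuit, q6h regimen
std_chdf <- function() chdf_settings() # effluent 1.5 L/h, SC 1, V3 0.1 L

mean_micro <- function(chdf = std_chdf()) reference_mean_micro(chdf)

q6h <- function() regimen(300, tau = 6, tinf = 1)

# random valid micro-constant sets inside a 3 SD box around the cohort means,
# truncated away from zero; used by the property tests
random_micro <- function(n, chdf = std_chdf(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- c(V1 = 13.46, k12 = 0.75, k21 = 0.95, k10 = 0.39)
  sd <- c(V1 = 5.29, k12 = 0.71, k21 = 0.27, k10 = 0.22)
  lapply(seq_len(n), function(i) {
    v <- pmax(mu + stats::runif(4, -3, 3) * sd, c(1, 0.01, 0.05, 0.01))
    fk <- derive_filter_constants(chdf, v[["V1"]])
    micro_params(v[["V1"]], v[["k12"]], v[["k21"]], v[["k10"]],
                 fk[["k13"]], fk[["k30"]], V3 = chdf$V3)
  })
}

# doses needed for the ODE to be within ~0.1% of steady state: the residual
# accumulation decays like exp(-beta * t)
n_doses_to_ss <- function(p, r) {
  beta <- derive_macro_constants(p)[["beta"]]
  max(15, ceiling(9 / (beta * r$tau)) + 1)
}

# noise-free steady-state series for a known parameter set
noise_free_series <- function(p, r, id = "X", schedule = NULL) {
  if (is.null(schedule)) schedule <- sampling_schedule(r)
  conc_time_series(id, schedule,
                   plasma = conc_central_ss(schedule, p, r),
                   fd = conc_fd_ss(schedule, p, r),
                   dose = r$dose, tau = r$tau, tinf = r$tinf)
}
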