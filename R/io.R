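#' Read a concentration table from CSV
#'
#' Expected columns: `patient_id`, `time_h`, `plasma_ugml`, `fd_ugml`,
#' `dose_mg`, `dose_start_h`, `tinf_h`, and optionally `tau_h` (defaults to
#' the last sampling time of each patient) and `first_dose` (logical).
#' Rows are validated (named by row number on error), re-sorted by
#' `(patient_id, time_h)` with a warning if they arrive shuffled, and
#' returned as a list of [conc_time_series()]. With `time_unit = "min"`
#' times are converted to hours on load.
#'
#' @param path CSV file path
#' @param time_unit unit of the time column: `"h"` (default) or `"min"`
#' @param lloq assay floor (ug/mL)
#' @return Named list of `conc_series`, one per patient.
#' @export
read_concentration_table <- function(path, time_unit = c("h", "min"), lloq = 0.1) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_h", "plasma_ugml", "fd_ugml",
            "dose_mg", "dose_start_h", "tinf_h")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (time_unit == "min") df$time_h <- df$time_h / 60
  bad <- which(df$plasma_ugml < 0 | (!is.na(df$fd_ugml) & df$fd_ugml < 0))
  if (length(bad)) stop("negative concentration at row(s): ", paste(bad, collapse = ", "))
  ord <- order(df$patient_id, df$time_h)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("rows were not sorted by (patient_id, time_h); re-sorting")
    df <- df[ord, ]
  }
  out <- lapply(split(df, df$patient_id), function(d) {
    if (any(duplicated(d$time_h)))
      stop("non-monotone or duplicated times for patient ", d$patient_id[1],
           " at row(s): ", paste(which(duplicated(d$time_h)), collapse = ", "))
    tau <- if ("tau_h" %in% names(d)) d$tau_h[1] else max(d$time_h)
    fd <- if (all(is.na(d$fd_ugml))) NULL else d$fd_ugml
    conc_time_series(patient_id = d$patient_id[1],
                     time_h = d$time_h - d$dose_start_h[1],
                     plasma = d$plasma_ugml, fd = fd,
                     dose = d$dose_mg[1], tau = tau, tinf = d$tinf_h[1],
                     lloq = lloq,
                     first_dose = if ("first_dose" %in% names(d)) isTRUE(d$first_dose[1]) else FALSE)
  })
  out
}

#' Write concentration series to CSV
#'
#' Inverse of [read_concentration_table()]: one row per observation with
#' the declared header, times in hours.
#'
#' @param series_list list of [conc_time_series()]
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(patient_id = s$patient_id, time_h = s$obs$time_h,
               plasma_ugml = s$obs$plasma, fd_ugml = s$obs$fd,
               dose_mg = s$dose, dose_start_h = 0, tinf_h = s$tinf,
               tau_h = s$tau, first_dose = s$first_dose,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration (JSON or YAML)
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`
#' @return Configuration as a named list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configurations")
    yaml::read_yaml(path)
  } else {
    stop("unsupported configuration format: ", ext)
  }
}

#' Run the complete analysis pipeline
#'
#' Orchestrates the end-to-end workflow: synthesise (or load) a cohort,
#' run per-patient NCA and compartmental fits, summarise the population by
#' the standard two-stage method, tabulate the deterministic regimen
#' exploration of %T>MIC, and run the Monte Carlo PTA/breakpoint
#' simulation for each regimen. All tables are written under `out_dir`
#' (CSV for tables, JSON for statistics) and every random stage is driven
#' by the single configuration seed, so a rerun with the same
#' configuration reproduces the outputs exactly.
#'
#' Configuration fields (all optional unless noted): `n_patients`,
#' `cohort_csv` (load instead of synthesise), `seed`, `cv_prop`, `mc_n`
#' (Monte Carlo draws, default 10000), `mic_grid`, `regimens` (data.frame
#' or list of `dose`/`tau`/`tinf`), `target_pct` (default 40),
#' `out_dir` (required), and CHDF settings under `chdf`. With an empty
#' cohort (`n_patients = 0`) the NCA/fit stages are skipped and the Monte
#' Carlo runs from `population_stats` supplied in the configuration (or
#' the reference-cohort statistics).
#'
#' @param config named list or path to a JSON/YAML file
#' @return Invisibly, a list with every stage's outputs.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  chdf <- do.call(chdf_settings, as.list(config$chdf %||% list()))
  mc_n <- config$mc_n %||% 10000L
  mic_grid <- config$mic_grid %||% 2^(-4:6)
  target <- config$target_pct %||% 40
  regs <- .config_regimens(config)
  out <- list(seed = seed, chdf = chdf)

  n_pat <- config$n_patients %||% 7L
  stats <- NULL
  if (!is.null(config$cohort_csv)) {
    series <- read_concentration_table(config$cohort_csv)
    n_pat <- length(series)
  } else if (n_pat > 0) {
    spec <- cohort_spec(n = n_pat, cv_prop = config$cv_prop %||% 0.10,
                        chdf = chdf, seed = seed)
    ds <- generate_dataset(spec)
    series <- ds$series
    out$cohort_truth <- ds$cohort
    write_concentration_table(series, file.path(config$out_dir, "concentrations.csv"))
  } else {
    series <- list()
  }

  if (length(series) > 0) {
    nca <- do.call(rbind, lapply(series, nca_summary))
    utils::write.csv(nca, file.path(config$out_dir, "nca_table.csv"), row.names = FALSE)
    out$nca <- nca
    fits <- lapply(seq_along(series), function(i) {
      s <- series[[i]]
      r <- regimen(s$dose, s$tau, s$tinf)
      fit_patient(s, r, chdf, sc_measured = nca$sc[i],
                  n_starts = config$n_starts %||% 8, seed = seed + i)
    })
    ptab <- do.call(rbind, lapply(fits, function(f) {
      ab <- derive_macro_constants(f$params)
      data.frame(patient_id = f$patient_id, V1 = f$params$V1, k12 = f$params$k12,
                 k21 = f$params$k21, k10 = f$params$k10, k13 = f$params$k13,
                 alpha = ab[["alpha"]], beta = ab[["beta"]],
                 cl_chdf = f$cl_chdf, cl_nonchdf = f$cl_nonchdf,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(ptab, file.path(config$out_dir, "parameter_table.csv"),
                     row.names = FALSE)
    out$fits <- fits
    out$parameter_table <- ptab
    stats <- two_stage(fits)
  }
  if (is.null(stats)) {
    stats <- if (!is.null(config$population_stats)) {
      population_stats(unlist(config$population_stats$mean),
                       unlist(config$population_stats$sd))
    } else {
      reference_population_stats()
    }
  }
  jsonlite::write_json(list(mean = as.list(stats$mean), sd = as.list(stats$sd),
                            n = stats$n),
                       file.path(config$out_dir, "population_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  out$population_stats <- stats

  out$tmic_grid <- tmic_regimen_grid()
  utils::write.csv(out$tmic_grid, file.path(config$out_dir, "tmic_grid.csv"),
                   row.names = FALSE)

  draws <- sample_population(stats, mc_n, seed = seed)
  pta_rows <- list(); bp <- list()
  for (i in seq_along(regs)) {
    r <- regs[[i]]
    res <- pta_curve(draws, r, mic_grid = mic_grid, target = target)
    lab <- sprintf("%gmg_q%gh_inf%gh", r$dose, r$tau, r$tinf)
    pta_rows[[lab]] <- transform(res$pta, regimen = lab)
    bp[[lab]] <- as.list(res$breakpoints)
  }
  pta_tab <- do.call(rbind, pta_rows)
  utils::write.csv(pta_tab, file.path(config$out_dir, "pta_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bp, file.path(config$out_dir, "breakpoints.json"),
                       auto_unbox = TRUE, digits = NA)
  out$pta <- pta_tab
  out$breakpoints <- bp
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_regimens <- function(config) {
  if (is.null(config$regimens)) {
    grid <- expand.grid(dose = c(300, 600), tau = c(6, 8, 12), tinf = c(0.5, 1))
    grid <- grid[!(grid$dose == 600 & grid$tau %in% c(6, 8)), ] # within 1200 mg/day
  } else if (is.data.frame(config$regimens)) {
    grid <- config$regimens
  } else {
    grid <- do.call(rbind, lapply(config$regimens, as.data.frame))
  }
  lapply(seq_len(nrow(grid)), function(i)
    regimen(grid$dose[i], grid$tau[i], grid$tinf[i]))
}
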