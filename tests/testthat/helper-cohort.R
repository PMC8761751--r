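# build per-repeat profiles for one specimen drawn from a group row
simulate_specimen_profiles <- function(params_row, config = study_config(),
                                       n_repeats = 3) {
  truth <- sample_tissue_truth(
    params_row, n = n_repeats,
    sem_n = config$sem_n,
    endpoint_correlation = config$endpoint_correlation,
    repeat_cv = config$repeat_cv,
    geometry_tolerance_mm = config$geometry_tolerance_mm
  )
  truth$sample_id <- sprintf("S%d", seq_len(n_repeats))
  truth$patient_id <- "P1"
  profiles <- lapply(seq_len(n_repeats), function(j) {
    rec <- forward_measurements(truth[j, ], config)
    build_profile(rec, config$chip, config$calib, truth[j, ])
  })
  list(truth = truth, profiles = do.call(rbind, profiles))
}

# group parameter table for a no-effect null: both groups identical, no
# temperature dependence (fold = 1), moderate spread
null_group_parameters <- function(spread = 30) {
  pars <- default_group_parameters()
  for (p in c("rho_b", "rho_s")) {
    pars[[paste0(p, "_25_mean")]] <- 300
    pars[[paste0(p, "_37_mean")]] <- 300
    pars[[paste0(p, "_25_spread")]] <- spread
    pars[[paste0(p, "_37_spread")]] <- spread
  }
  pars$k_25_mean <- 0.4; pars$k_37_mean <- 0.4
  pars$k_25_spread <- 0.04; pars$k_37_spread <- 0.04
  pars$fold_rho_b <- 1; pars$fold_rho_s <- 1; pars$fold_k <- 1
  pars
}
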