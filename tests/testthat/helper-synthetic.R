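# shared builders for hand-constructed study tables

# constant-enrichment arterial tables on the study grid, with a zero
# background sample at -150 (steady-state fixture: every Steele midpoint
# must equal F / E)
const_study_tables <- function(times = study_grid(),
                               conc_phe = 60, conc_tyr = 50,
                               e_d8 = 0.045, e_d7 = 0.005, e_d5 = 0.01,
                               e_d2 = 0.04, e_td7 = 0.003, e_td6 = 0.001) {
  tt <- setdiff(times, -150)
  iso <- tibble::tribble(
    ~analyte, ~isotopologue, ~ttr,
    "phe", "d8", e_d8,
    "phe", "d7", e_d7,
    "phe", "d5", e_d5,
    "tyr", "d2", e_d2,
    "tyr", "d7", e_td7,
    "tyr", "d6", e_td6
  )
  enr <- tidyr::crossing(time = tt, iso) |>
    dplyr::bind_rows(dplyr::mutate(iso, time = -150, ttr = 0))
  conc <- tidyr::crossing(time = tt, analyte = c("phe", "tyr")) |>
    dplyr::mutate(concentration = ifelse(analyte == "phe", conc_phe, conc_tyr))
  list(concentrations = conc, enrichments = enr)
}

demo_subject <- function() list(body_weight = 76, lean_mass = 50)

demo_protocols <- function() {
  list(
    phe = tracer_protocol("phe_d8", prime = 3, continuous_rate_nominal = 0.07),
    tyr = tracer_protocol("tyr_d2", prime = 2.3, continuous_rate_nominal = 0.04)
  )
}

# noise-free scenario used by the recovery tests
noisefree_config <- function(...) {
  scenario_config(noise_cv_enrichment = 0, noise_cv_concentration = 0,
                  noise_cv_flow = 0, background_ttr = 0, ...)
}

# site-filtered tables for feeding a synthetic subject into the pipelines
arterial_tables <- function(subj) {
  list(
    conc = dplyr::filter(subj$concentrations, site == "artery") |>
      dplyr::select(-site),
    enr = dplyr::filter(subj$enrichments, site %in% c("artery", "antecubital")) |>
      dplyr::select(-site)
  )
}

run_wholebody <- function(subj, ...) {
  at <- arterial_tables(subj)
  suppressWarnings(wholebody_kinetics(
    at$conc, at$enr, as.list(subj$subject),
    subj$protocols$phe, subj$protocols$tyr, subj$meal, ...
  ))
}
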