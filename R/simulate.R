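#' Scenario configuration for the forward study simulator
#'
#' Defines the physiological ground truth and study design emulated by
#' [simulate_subject()] and [simulate_cohort()]: a single well-mixed
#' phenylalanine pool (and a tyrosine pool fed by hydroxylation) driven by
#' endogenous proteolysis, a gamma-shaped absorption of the labelled meal,
#' primed-continuous D8-phenylalanine and D2-tyrosine infusions, tracer
#' incorporation into muscle and plasma proteins, arteriovenous gradients
#' across the leg and adipose tissue, and multiplicative lognormal
#' measurement noise.
#'
#' Group-level anthropometrics default to the two study groups
#' (healthy weight, obesity). Flux parameters are per kg lean mass.
#'
#' @param n_per_group Subjects per group.
#' @param groups Group labels.
#' @param visits Visit labels simulated (default `"saline"`).
#' @param body_weight_mean,body_weight_sd,lean_mass_mean,lean_mass_sd Named
#'   per-group normal parameters, kg.
#' @param basal_conc_phe,basal_conc_tyr Fasting plasma concentrations,
#'   umol/L.
#' @param basal_ra_phe,basal_ra_tyr Fasting endogenous appearance,
#'   umol/kg lean mass/min.
#' @param basal_ra_cv Between-subject CV of the basal appearance rates.
#' @param suppression_depth Peak fractional suppression of proteolysis
#'   after the meal (0-1).
#' @param suppression_peak_time Minute of maximal suppression.
#' @param suppression_cv Between-subject CV of the depth.
#' @param suppression_group_multiplier Named per-group multiplier on the
#'   depth (the injected-effect dial; 1 = no group effect).
#' @param hydrox_fraction Fraction of phenylalanine disposal hydroxylated
#'   to tyrosine at basal concentration.
#' @param hydrox_cv Between-subject CV of that fraction.
#' @param hydrox_substrate_exponent Exponent of the concentration
#'   dependence of hydroxylation (oxidation rises with amino-acid
#'   availability); 0 disables it.
#' @param meal A [meal_spec()].
#' @param systemic_fraction Fraction of ingested phenylalanine appearing in
#'   the systemic circulation (1 - first-pass splanchnic extraction).
#' @param absorption_shape,absorption_scale Gamma parameters of the
#'   absorption rate curve (defaults peak near 40 min).
#' @param tyr_to_phe_meal_ratio Systemic meal tyrosine appearance relative
#'   to phenylalanine.
#' @param prime_phe,rate_phe,prime_tyr,rate_tyr Tracer protocol: primes
#'   (umol/kg lean mass) and continuous rates (umol/kg lean mass/min).
#' @param infusate_conc_phe,infusate_conc_tyr Infusate concentrations,
#'   umol/mL (pump flows are derived so delivered = nominal rate).
#' @param transamination_share_d7 Share of the pooled D8+D7 phenylalanine
#'   enrichment reported as the D7 isotopologue.
#' @param tyr_d7_share Share of the pooled D7+D6 tyrosine enrichment
#'   reported as D7.
#' @param muscle_fsr_true Mixed-muscle protein FSR, %/h.
#' @param plasma_fsr_true Total plasma protein FSR, %/day.
#' @param fsr_cv Between-subject CV of the FSR truths.
#' @param flow_basal Fasting femoral arterial blood flow, L/min.
#' @param flow_postprandial_rise Fractional postprandial rise of flow.
#' @param av_fe_basal Fasting fractional extraction of phenylalanine
#'   across the leg.
#' @param av_net_basal Fasting net phenylalanine balance across the leg,
#'   umol/min/kg lean mass (negative = net release).
#' @param leg_uptake_rise Fractional postprandial rise of leg uptake.
#' @param leg_release_suppression Peak fractional postprandial suppression
#'   of leg release.
#' @param adipose_basal_diff,adipose_uptake_bump Fasting and peak
#'   postprandial arteriovenous concentration difference across adipose
#'   tissue, umol/L.
#' @param glucose_fasting,insulin_fasting Named per-group fasting glucose
#'   (mmol/L) and insulin (pmol/L).
#' @param glucose_amp,insulin_amp Named per-group postprandial excursion
#'   amplitudes.
#' @param background_ttr Natural-abundance background enrichment added to
#'   every measured TTR (subtracted again by the analysis pipelines via
#'   the -150 min sample).
#' @param noise_cv_enrichment,noise_cv_concentration,noise_cv_flow
#'   Measurement noise CVs; set to 0 for noise-free data.
#' @param sample_times Blood-sampling grid, min (must include -150, the
#'   pre-infusion background sample).
#' @param step Integration step of the dense grid, min.
#' @param seed Default RNG seed used when none is passed to the simulation
#'   functions.
#'
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(
    n_per_group = 12,
    groups = c("healthy_weight", "obesity"),
    visits = "saline",
    body_weight_mean = c(healthy_weight = 75.4, obesity = 111.8),
    body_weight_sd = c(healthy_weight = 5.4, obesity = 12.1),
    lean_mass_mean = c(healthy_weight = 58.1, obesity = 68.0),
    lean_mass_sd = c(healthy_weight = 5.2, obesity = 8.7),
    basal_conc_phe = 55,
    basal_conc_tyr = 50,
    basal_ra_phe = 0.75,
    basal_ra_tyr = 0.40,
    basal_ra_cv = 0.08,
    suppression_depth = 0.25,
    suppression_peak_time = 75,
    suppression_cv = 0.15,
    suppression_group_multiplier = c(healthy_weight = 1, obesity = 1),
    hydrox_fraction = 0.08,
    hydrox_cv = 0.10,
    hydrox_substrate_exponent = 1,
    meal = meal_spec(),
    systemic_fraction = 0.35,
    absorption_shape = 3,
    absorption_scale = 20,
    tyr_to_phe_meal_ratio = 1,
    prime_phe = 3, rate_phe = 0.07,
    prime_tyr = 2.3, rate_tyr = 0.04,
    infusate_conc_phe = 30, infusate_conc_tyr = 24,
    transamination_share_d7 = 0.1,
    tyr_d7_share = 0.6,
    muscle_fsr_true = 0.08,
    plasma_fsr_true = 10,
    fsr_cv = 0.10,
    flow_basal = 0.45,
    flow_postprandial_rise = 0.2,
    av_fe_basal = 0.45,
    av_net_basal = -0.05,
    leg_uptake_rise = 0.4,
    leg_release_suppression = 0.4,
    adipose_basal_diff = 0.5,
    adipose_uptake_bump = 2.5,
    glucose_fasting = c(healthy_weight = 5.30, obesity = 5.67),
    insulin_fasting = c(healthy_weight = 32, obesity = 90),
    glucose_amp = c(healthy_weight = 2.2, obesity = 3.0),
    insulin_amp = c(healthy_weight = 250, obesity = 420),
    background_ttr = 2e-4,
    noise_cv_enrichment = 0.02,
    noise_cv_concentration = 0.03,
    noise_cv_flow = 0.05,
    sample_times = study_grid(),
    step = 0.05,
    seed = 1L) {
  cfg <- as.list(environment())
  fr <- c("suppression_depth", "hydrox_fraction", "systemic_fraction",
          "av_fe_basal", "leg_uptake_rise", "leg_release_suppression",
          "flow_postprandial_rise")
  for (nm in fr) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop("scenario_config: ", nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!(-150 %in% cfg$sample_times)) {
    stop("scenario_config: sample_times must include the -150 min background sample",
         call. = FALSE)
  }
  if (cfg$step <= 0 || cfg$step > 0.1) {
    stop("scenario_config: step must lie in (0, 0.1] min", call. = FALSE)
  }
  stopifnot(inherits(cfg$meal, "meal_spec"))
  structure(cfg, class = "scenario_config")
}

# run code under a given seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

# normalised (peak 1) postprandial suppression shape: 0 before the meal
.suppression_shape <- function(t, peak_time) {
  s <- ifelse(t > 0, (t / peak_time) * exp(1 - t / peak_time), 0)
  pmax(s, 0)
}

# gamma-density meal shape normalised to peak 1 (for flow/hormone bumps)
.meal_shape <- function(t, shape, scale) {
  mode <- (shape - 1) * scale
  peak <- stats::dgamma(mode, shape = shape, scale = scale)
  ifelse(t > 0, stats::dgamma(t, shape = shape, scale = scale) / peak, 0)
}

# one-pool solution dC/dt = u(t) - k C via exponential integrator, exact for
# piecewise-linear inflow u (concentration units: u in umol/L/min)
.pool_integrate <- function(h, u, k, c0) {
  n <- length(u)
  if (k <= 0) {
    return(c0 + c(0, cumsum((u[-n] + u[-1]) / 2 * h)))
  }
  em <- exp(-k * h)
  a1 <- (1 - em) / k
  a2 <- (k * h - (1 - em)) / (k^2 * h)
  du <- u[-1] - u[-n]
  b <- u[-n] * a1 + du * a2                      # b_i: inflow over step i
  out <- numeric(n)
  out[1] <- c0
  i <- 1L
  block <- 2000L
  while (i < n) {
    j <- min(i + block, n)
    idx <- i:(j - 1L)
    pw <- em^seq_along(idx)
    out[(i + 1L):j] <- pw * (out[i] + cumsum(b[idx] / pw))
    i <- j
  }
  out
}

.cumtrapz <- function(t, y) {
  c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(t)))
}

# multiplicative mean-preserving lognormal noise
.noisy <- function(x, cv) {
  if (cv <= 0) return(x)
  sdlog <- sqrt(log1p(cv^2))
  x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# draw per-subject biology (RNG state must already be seeded)
.draw_pars <- function(config, group) {
  draw_pos <- function(mean, sd) {
    if (sd <= 0 || mean <= 0) return(mean)
    x <- stats::rnorm(1, mean, sd)
    while (x <= 0.2 * mean) x <- stats::rnorm(1, mean, sd)
    x
  }
  bw <- draw_pos(config$body_weight_mean[[group]], config$body_weight_sd[[group]])
  lm <- draw_pos(config$lean_mass_mean[[group]], config$lean_mass_sd[[group]])
  lm <- min(lm, 0.95 * bw)
  cv_draw <- function(mean, cv) draw_pos(mean, mean * cv)
  list(
    group = group,
    body_weight = bw, lean_mass = lm,
    basal_ra_phe = cv_draw(config$basal_ra_phe, config$basal_ra_cv),
    basal_ra_tyr = cv_draw(config$basal_ra_tyr, config$basal_ra_cv),
    suppression_depth = min(
      cv_draw(config$suppression_depth, config$suppression_cv) *
        config$suppression_group_multiplier[[group]], 0.9),
    hydrox_fraction = min(cv_draw(config$hydrox_fraction, config$hydrox_cv), 0.4),
    muscle_fsr = cv_draw(config$muscle_fsr_true, config$fsr_cv),
    plasma_fsr = cv_draw(config$plasma_fsr_true, config$fsr_cv),
    glucose_fasting = config$glucose_fasting[[group]],
    insulin_fasting = config$insulin_fasting[[group]],
    glucose_amp = config$glucose_amp[[group]],
    insulin_amp = config$insulin_amp[[group]]
  )
}

# deterministic forward model on the dense grid; returns dense series,
# conservation ledger, and true flux/AV profiles
.simulate_deterministic <- function(config, pars) {
  h <- config$step
  tg <- seq(-150, 360, by = h)
  n <- length(tg)
  constants <- kinetics_constants()
  v <- effective_pool_volume(pars$body_weight, pars$lean_mass, constants)
  cb <- config$basal_conc_phe
  k_phe <- pars$basal_ra_phe / (v * cb)

  supp <- .suppression_shape(tg, config$suppression_peak_time)
  ra_endo <- pars$basal_ra_phe * (1 - pars$suppression_depth * supp)
  oral_total_per_kg <- config$systemic_fraction *
    config$meal$total_phe_ingested / pars$lean_mass
  ra_oral <- ifelse(tg > 0,
                    oral_total_per_kg *
                      stats::dgamma(tg, shape = config$absorption_shape,
                                    scale = config$absorption_scale),
                    0)

  conc <- .pool_integrate(h, (ra_endo + ra_oral) / v, k_phe, cb)
  if (any(conc <= 0)) {
    stop("simulate: phenylalanine pool went non-positive; check basal_ra_phe ",
         "or suppression_depth", call. = FALSE)
  }
  rd <- k_phe * v * conc
  hfac <- pars$hydrox_fraction * (conc / cb)^config$hydrox_substrate_exponent
  if (any(hfac >= 1)) {
    stop("simulate: hydroxylation fraction reached 1; lower hydrox_fraction ",
         "or hydrox_substrate_exponent", call. = FALSE)
  }
  hydrox <- hfac * rd
  synthesis <- rd - hydrox

  f_phe <- config$rate_phe
  c87 <- .pool_integrate(h, rep(f_phe / v, n), k_phe, config$prime_phe / v)
  c5 <- .pool_integrate(h, config$meal$d5_to_tracee_ratio_r * ra_oral / v, k_phe, 0)
  e87 <- c87 / conc
  e5 <- c5 / conc

  # tyrosine pool: fed by its own proteolysis, meal tyrosine, and the
  # unlabelled product of phenylalanine hydroxylation
  cb_tyr <- config$basal_conc_tyr
  h_basal <- pars$hydrox_fraction * pars$basal_ra_phe
  k_tyr <- (pars$basal_ra_tyr + h_basal) / (v * cb_tyr)
  ra_endo_tyr <- pars$basal_ra_tyr * (1 - pars$suppression_depth * supp)
  oral_tyr <- config$tyr_to_phe_meal_ratio * ra_oral
  conc_tyr <- .pool_integrate(h, (ra_endo_tyr + oral_tyr + hydrox) / v, k_tyr, cb_tyr)
  f_tyr <- config$rate_tyr
  c2 <- .pool_integrate(h, rep(f_tyr / v, n), k_tyr, config$prime_tyr / v)
  c76 <- .pool_integrate(h, hydrox * e87 / v, k_tyr, 0)
  e2 <- c2 / conc_tyr
  e76 <- c76 / conc_tyr

  # protein-bound label accumulation (precursor-product forward model)
  eprec <- (c87 + c5) / conc
  fsr_m_min <- pars$muscle_fsr / 100 / 60
  fsr_p_min <- pars$plasma_fsr / 100 / 1440
  ep_muscle <- fsr_m_min * .cumtrapz(tg, eprec)
  ppl_inf <- fsr_p_min * .cumtrapz(tg, e87)
  ppl_meal <- fsr_p_min * .cumtrapz(tg, e5)

  # leg arteriovenous truth
  mshape <- .meal_shape(tg, config$absorption_shape, config$absorption_scale)
  flow <- config$flow_basal * (1 + config$flow_postprandial_rise * mshape)
  u0 <- config$av_fe_basal * cb * config$flow_basal / pars$lean_mass
  r0 <- u0 - config$av_net_basal
  leg_uptake <- u0 * (1 + config$leg_uptake_rise * mshape)
  rel_depth <- if (config$suppression_depth > 0) {
    pars$suppression_depth / config$suppression_depth
  } else 0
  leg_release <- r0 * (1 - config$leg_release_suppression * rel_depth * supp)
  leg_net <- leg_uptake - leg_release
  cv_leg <- conc - leg_net * pars$lean_mass / flow
  if (any(cv_leg <= 0)) {
    stop("simulate: femoral venous concentration went non-positive; check ",
         "av_net_basal or flow_basal", call. = FALSE)
  }
  fe_leg <- leg_uptake * pars$lean_mass / (flow * conc)
  if (any(fe_leg >= 1)) {
    stop("simulate: leg fractional extraction reached 1; check av_fe_basal ",
         "or leg_uptake_rise", call. = FALSE)
  }
  ev87 <- e87 * conc * (1 - fe_leg) / cv_leg
  ev5 <- e5 * conc * (1 - fe_leg) / cv_leg

  # adipose bed: concentration differences only (no flow measurement)
  adi_diff <- config$adipose_basal_diff + config$adipose_uptake_bump * mshape
  cv_adi <- conc - adi_diff
  cv_adi_tyr <- conc_tyr - 0.5 * adi_diff

  # conservation ledger per tracer channel (umol per kg lean mass)
  ledger <- function(channel, cvec, uvec, k, prime) {
    tibble::tibble(
      channel = channel,
      initial_pool = prime,
      infused = pracma::trapz(tg, uvec),
      final_pool = v * cvec[n],
      cleared = pracma::trapz(tg, k * v * cvec)
    )
  }
  conservation <- dplyr::bind_rows(
    ledger("phe_d8d7", c87, rep(f_phe, n), k_phe, config$prime_phe),
    ledger("phe_d5", c5, config$meal$d5_to_tracee_ratio_r * ra_oral, k_phe, 0),
    ledger("tyr_d2", c2, rep(f_tyr, n), k_tyr, config$prime_tyr),
    ledger("tyr_d7d6", c76, hydrox * e87, k_tyr, 0),
    ledger("phe_tracee", conc, ra_endo + ra_oral, k_phe, v * cb),
    ledger("tyr_tracee", conc_tyr, ra_endo_tyr + oral_tyr + hydrox, k_tyr, v * cb_tyr)
  )

  list(tg = tg, v = v, k_phe = k_phe, k_tyr = k_tyr,
       conc = conc, conc_tyr = conc_tyr,
       e87 = e87, e5 = e5, e2 = e2, e76 = e76, eprec = eprec,
       ra_endo = ra_endo, ra_oral = ra_oral, rd = rd,
       hydrox = hydrox, synthesis = synthesis,
       ra_endo_tyr = ra_endo_tyr, oral_tyr = oral_tyr,
       ep_muscle = ep_muscle, ppl_inf = ppl_inf, ppl_meal = ppl_meal,
       flow = flow, leg_uptake = leg_uptake, leg_release = leg_release,
       leg_net = leg_net, cv_leg = cv_leg, fe_leg = fe_leg,
       ev87 = ev87, ev5 = ev5, cv_adi = cv_adi, cv_adi_tyr = cv_adi_tyr,
       conservation = conservation,
       f_phe = f_phe, f_tyr = f_tyr)
}

# index of sample times on the dense grid
.grid_index <- function(tg, times, step) {
  idx <- round((times - tg[1]) / step) + 1
  if (any(idx < 1 | idx > length(tg)) ||
      any(abs(tg[idx] - times) > 1e-8)) {
    stop("simulate: sample_times must lie on the integration grid", call. = FALSE)
  }
  idx
}

#' Simulate one subject-visit of the tracer study
#'
#' Integrates the forward model of [scenario_config()] on a dense grid and
#' samples it on the study's blood-sampling grid with measurement noise.
#' The -150 min sample is drawn from the antecubital site before the
#' tracer prime and therefore carries only background enrichment. The
#' same seed reproduces the dataset bit-identically.
#'
#' @param config A [scenario_config()].
#' @param subject_id Subject label.
#' @param group Group label (must be one of `config$groups`).
#' @param visit Visit label.
#' @param seed Integer seed for the subject's biology and measurement
#'   noise (defaults to `config$seed`).
#' @param pars Optional pre-drawn biology (as produced internally), to
#'   share one subject's biology across visits.
#' @param keep_dense Keep the dense deterministic series in the output.
#'
#' @return A list of class `synthetic_subject` with elements `subject`,
#'   `concentrations`, `enrichments`, `flow`, `biopsy`, `plasma_protein`,
#'   `hormones`, `meal`, `protocols`, and `truth` (true flux profiles at
#'   1-min resolution, arteriovenous truth, FSR truths, drawn parameters,
#'   and a tracer-mass conservation ledger).
#' @export
simulate_subject <- function(config, subject_id = "S01",
                             group = config$groups[1],
                             visit = config$visits[1],
                             seed = config$seed,
                             pars = NULL, keep_dense = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (!group %in% config$groups) {
    stop("simulate_subject: unknown group '", group, "'", call. = FALSE)
  }
  .with_seed(seed, {
    if (is.null(pars)) pars <- .draw_pars(config, group)
    det <- .simulate_deterministic(config, pars)
    tg <- det$tg
    st <- sort(config$sample_times)
    post <- st[st != -150]
    idx <- .grid_index(tg, post, config$step)
    cve <- config$noise_cv_enrichment
    cvc <- config$noise_cv_concentration

    d7s <- config$transamination_share_d7
    t7s <- config$tyr_d7_share
    iso_lab <- c("d8", "d7", "d5", "d2", "d7", "d6")
    iso_ana <- c("phe", "phe", "phe", "tyr", "tyr", "tyr")
    np <- length(post)
    site_ttr <- function(e87, e5, e2, e76) {
      c((1 - d7s) * e87[idx], d7s * e87[idx], e5[idx],
        e2[idx], t7s * e76[idx], (1 - t7s) * e76[idx])
    }
    ttr_true <- c(rep(0, 6),                                   # background draw
                  site_ttr(det$e87, det$e5, det$e2, det$e76),  # artery
                  site_ttr(det$ev87, det$ev5, det$e2, det$e76)) # femoral vein
    enr <- tibble::tibble(
      site = c(rep("antecubital", 6),
               rep(c("artery", "femoral_vein"), each = 6 * np)),
      time = c(rep(-150, 6), rep(rep(post, times = 6), 2)),
      analyte = c(iso_ana, rep(rep(iso_ana, each = np), 2)),
      isotopologue = c(iso_lab, rep(rep(iso_lab, each = np), 2)),
      ttr = .noisy(ttr_true + config$background_ttr, cve)
    )

    conc_true <- c(config$basal_conc_phe, config$basal_conc_tyr,
                   det$conc[idx], det$conc_tyr[idx],
                   det$cv_leg[idx], det$conc_tyr[idx],
                   det$cv_adi[idx], det$cv_adi_tyr[idx])
    conc <- tibble::tibble(
      site = c("antecubital", "antecubital",
               rep(c("artery", "femoral_vein", "epigastric_vein"),
                   each = 2 * np)),
      time = c(-150, -150, rep(rep(post, times = 2), 3)),
      analyte = c("phe", "tyr", rep(rep(c("phe", "tyr"), each = np), 3)),
      concentration = .noisy(conc_true, cvc)
    )

    flow_tbl <- tibble::tibble(
      time = post, flow = .noisy(det$flow[idx], config$noise_cv_flow)
    )

    bio_t <- c(-30, 360)
    bidx <- .grid_index(tg, bio_t, config$step)
    biopsy <- tibble::tibble(
      time = bio_t,
      protein_bound_ttr = .noisy(det$ep_muscle[bidx], cve),
      free_pool_ttr = .noisy(det$eprec[bidx], cve)
    )

    ppl_t <- c(0, 60, 120, 240, 360)
    pidx <- .grid_index(tg, ppl_t, config$step)
    plasma_protein <- dplyr::bind_rows(
      tibble::tibble(time = ppl_t, channel = "infused",
                     ttr = .noisy(det$ppl_inf[pidx], cve)),
      tibble::tibble(time = ppl_t, channel = "meal",
                     ttr = .noisy(det$ppl_meal[pidx], cve))
    )

    horm_t <- c(-150, -30, 20, 30, 60, 90, 120, 180, 240, 300, 360)
    gsh <- .meal_shape(horm_t, 2.5, 20)
    ish <- .meal_shape(horm_t, 2.5, 25)
    hormones <- dplyr::bind_rows(
      tibble::tibble(time = horm_t, analyte = "glucose",
                     concentration = .noisy(pars$glucose_fasting +
                                              pars$glucose_amp * gsh, cvc)),
      tibble::tibble(time = horm_t, analyte = "insulin",
                     concentration = .noisy(pars$insulin_fasting +
                                              pars$insulin_amp * ish, cvc))
    )

    tru_t <- seq(-150, 360, by = 1)
    tru_i <- .grid_index(tg, tru_t, config$step)
    truth_fluxes <- tibble::tibble(
      time = tru_t,
      ra_endo = det$ra_endo[tru_i], ra_oral = det$ra_oral[tru_i],
      ra_total = det$ra_endo[tru_i] + det$ra_oral[tru_i],
      rd = det$rd[tru_i], hydroxylation = det$hydrox[tru_i],
      synthesis = det$synthesis[tru_i],
      conc = det$conc[tru_i], e87 = det$e87[tru_i], e5 = det$e5[tru_i]
    )
    truth_av <- tibble::tibble(
      time = post, flow = det$flow[idx],
      ca = det$conc[idx], cv = det$cv_leg[idx],
      uptake = det$leg_uptake[idx], release = det$leg_release[idx],
      net_balance = det$leg_net[idx], fe = det$fe_leg[idx]
    )

    lm <- pars$lean_mass
    protocols <- list(
      phe = tracer_protocol("phe_d8", config$prime_phe, config$rate_phe,
                            config$infusate_conc_phe,
                            config$rate_phe * lm / config$infusate_conc_phe),
      tyr = tracer_protocol("tyr_d2", config$prime_tyr, config$rate_tyr,
                            config$infusate_conc_tyr,
                            config$rate_tyr * lm / config$infusate_conc_tyr)
    )

    out <- list(
      subject = tibble::tibble(
        subject_id = subject_id, group = group, visit = visit,
        body_weight = pars$body_weight, lean_mass = pars$lean_mass
      ),
      concentrations = conc, enrichments = enr, flow = flow_tbl,
      biopsy = biopsy, plasma_protein = plasma_protein, hormones = hormones,
      meal = config$meal, protocols = protocols,
      truth = list(
        fluxes = truth_fluxes, av = truth_av,
        fsr = tibble::tibble(muscle_fsr = pars$muscle_fsr,
                             plasma_fsr = pars$plasma_fsr),
        pars = tibble::as_tibble(pars[c("body_weight", "lean_mass",
                                        "basal_ra_phe", "basal_ra_tyr",
                                        "suppression_depth", "hydrox_fraction",
                                        "muscle_fsr", "plasma_fsr")]),
        conservation = det$conservation
      ),
      seed = seed
    )
    if (keep_dense) out$dense <- det
    structure(out, class = "synthetic_subject")
  })
}

#' Simulate a full study cohort
#'
#' Draws independent subjects per group (biology shared across visits,
#' measurement noise drawn per visit) and simulates each with
#' [simulate_subject()]. Sub-seeds are derived deterministically from
#' `seed`, so the whole cohort is reproducible from one integer.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list of class `synthetic_cohort`: `index` (one row per
#'   subject-visit), `subjects` (list of `synthetic_subject`), and the
#'   `config` used.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  labels <- unlist(lapply(seq_along(config$groups), function(gi) {
    sprintf("%s%02d", toupper(substr(config$groups[gi], 1, 2)),
            seq_len(config$n_per_group))
  }))
  grp <- rep(config$groups, each = config$n_per_group)
  n_sub <- length(labels)
  seeds <- .with_seed(seed, matrix(
    sample.int(.Machine$integer.max %/% 2, n_sub * (1 + length(config$visits))),
    nrow = n_sub))
  subjects <- list()
  index <- list()
  for (i in seq_len(n_sub)) {
    pars <- .with_seed(seeds[i, 1], .draw_pars(config, grp[i]))
    for (vi in seq_along(config$visits)) {
      s <- simulate_subject(config, subject_id = labels[i], group = grp[i],
                            visit = config$visits[vi],
                            seed = seeds[i, 1 + vi], pars = pars)
      key <- paste(labels[i], config$visits[vi], sep = ".")
      subjects[[key]] <- s
      index[[key]] <- s$subject
    }
  }
  structure(list(
    index = dplyr::bind_rows(index),
    subjects = subjects,
    config = config,
    seed = seed
  ), class = "synthetic_cohort")
}
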