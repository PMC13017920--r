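test_that("scenario config validates fractions, grid and step", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(suppression_depth = 1.5), "0, 1")
  expect_error(scenario_config(systemic_fraction = -0.1), "0, 1")
  expect_error(scenario_config(sample_times = c(-60, 10)), "-150")
  expect_error(scenario_config(step = 0.5), "step")
})

test_that("same seed reproduces a subject bit-identically", {
  cfg <- scenario_config()
  a <- simulate_subject(cfg, seed = 99)
  b <- simulate_subject(cfg, seed = 99)
  expect_identical(a$concentrations, b$concentrations)
  expect_identical(a$enrichments, b$enrichments)
  expect_identical(a$truth$fluxes, b$truth$fluxes)
  d <- simulate_subject(cfg, seed = 100)
  expect_false(identical(a$enrichments$ttr, d$enrichments$ttr))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- runif(3)
  set.seed(1234)
  invisible(simulate_subject(scenario_config(), seed = 5))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("without a meal the arterial enrichment plateaus at F/Ra", {
  cfg <- noisefree_config(systemic_fraction = 0, suppression_depth = 0,
                          basal_ra_cv = 0, suppression_cv = 0,
                          hydrox_cv = 0, fsr_cv = 0)
  s <- simulate_subject(cfg, seed = 2)
  e87 <- s$enrichments |>
    dplyr::filter(site == "artery", analyte == "phe",
                  isotopologue %in% c("d8", "d7"), time == 360) |>
    dplyr::summarise(ttr = sum(ttr)) |>
    dplyr::pull(ttr)
  expect_equal(e87, cfg$rate_phe / s$truth$pars$basal_ra_phe,
               tolerance = 1e-6)
})

test_that("tracer mass is conserved in every channel", {
  for (sd in c(1, 23)) {
    s <- simulate_subject(scenario_config(), seed = sd)
    led <- s$truth$conservation
    rel <- abs(led$initial_pool + led$infused - led$final_pool - led$cleared) /
      (led$initial_pool + led$infused)
    expect_true(all(rel < 1e-6))
    expect_setequal(led$channel,
                    c("phe_d8d7", "phe_d5", "tyr_d2", "tyr_d7d6",
                      "phe_tracee", "tyr_tracee"))
  }
})

test_that("dense pool dynamics agree with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  cfg <- noisefree_config(basal_ra_cv = 0, suppression_cv = 0,
                          hydrox_cv = 0, fsr_cv = 0)
  s <- simulate_subject(cfg, seed = 4, keep_dense = TRUE)
  det <- s$dense
  pars <- s$truth$pars
  v <- 0.125 * pars$body_weight / pars$lean_mass
  oral_per_kg <- cfg$systemic_fraction * cfg$meal$total_phe_ingested /
    pars$lean_mass
  rhs <- function(t, y, p) {
    supp <- if (t > 0) (t / 75) * exp(1 - t / 75) else 0
    ra_e <- pars$basal_ra_phe * (1 - pars$suppression_depth * supp)
    ra_o <- if (t > 0) oral_per_kg * dgamma(t, shape = 3, scale = 20) else 0
    list((ra_e + ra_o) / v - det$k_phe * y)
  }
  sol <- deSolve::ode(y = c(C = cfg$basal_conc_phe), times = seq(-150, 360, 10),
                      func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-10)
  mine <- det$conc[match(sol[, "time"], det$tg)]
  expect_equal(mine, unname(sol[, "C"]), tolerance = 1e-6)
})

test_that("synthetic truth respects its own invariants", {
  s <- simulate_subject(scenario_config(), seed = 8)
  tr <- s$truth$fluxes
  expect_true(all(tr$ra_endo >= 0))
  expect_true(all(tr$ra_oral >= 0))
  expect_true(all(tr$hydroxylation >= 0))
  expect_true(all(tr$synthesis >= 0))
  expect_equal(tr$ra_total, tr$ra_endo + tr$ra_oral)
  expect_equal(range(tr$time), c(-150, 360))
  # samples land exactly on the study grid
  expect_setequal(unique(s$concentrations$time), study_grid())
  av <- s$truth$av
  expect_equal(av$uptake - av$net_balance - av$release, rep(0, nrow(av)),
               tolerance = 1e-12)
  expect_true(all(av$fe > 0 & av$fe < 1))
})

test_that("unstable parameter choices fail with a named parameter", {
  cfg <- noisefree_config(hydrox_fraction = 0.6, hydrox_substrate_exponent = 2)
  expect_error(simulate_subject(cfg, seed = 1), "hydrox_fraction")
  cfg2 <- noisefree_config(av_fe_basal = 0.95, leg_uptake_rise = 1,
                           flow_postprandial_rise = 0)
  expect_error(simulate_subject(cfg2, seed = 1), "av_fe_basal|leg_uptake_rise")
})

test_that("cohort simulation stacks groups and shares biology across visits", {
  cfg <- scenario_config(n_per_group = 2, visits = c("saline", "il6r_ab"))
  coh <- simulate_cohort(cfg, seed = 31)
  expect_s3_class(coh, "synthetic_cohort")
  expect_equal(nrow(coh$index), 2 * 2 * 2)
  expect_setequal(unique(coh$index$group), c("healthy_weight", "obesity"))
  # biology identical across visits, measurements not
  s1 <- coh$subjects[["HE01.saline"]]
  s2 <- coh$subjects[["HE01.il6r_ab"]]
  expect_identical(s1$truth$pars$basal_ra_phe, s2$truth$pars$basal_ra_phe)
  expect_false(identical(s1$enrichments$ttr, s2$enrichments$ttr))
})

test_that("an injected group effect raises postprandial proteolysis truth", {
  cfg <- noisefree_config(
    n_per_group = 1, basal_ra_cv = 0, suppression_cv = 0,
    hydrox_cv = 0, fsr_cv = 0,
    suppression_group_multiplier = c(healthy_weight = 1, obesity = 0.8))
  hw <- simulate_subject(cfg, group = "healthy_weight", seed = 3)
  ob <- simulate_subject(cfg, group = "obesity", seed = 3)
  t_post <- hw$truth$fluxes$time > 0
  supp_hw <- 1 - hw$truth$fluxes$ra_endo / hw$truth$pars$basal_ra_phe
  supp_ob <- 1 - ob$truth$fluxes$ra_endo / ob$truth$pars$basal_ra_phe
  expect_true(all(supp_hw[t_post] >= supp_ob[t_post]))
  expect_equal(max(supp_ob[t_post]) / max(supp_hw[t_post]), 0.8,
               tolerance = 1e-9)
})
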