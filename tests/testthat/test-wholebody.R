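test_that("Steele Ra reduces to F/E at steady state", {
  expect_equal(steele_ra(0.07, 0.19, 0, 10, 55, 55, 0.05, 0.05), 1.4)
  # any constant concentration, same answer
  for (cc in c(10, 55, 200)) {
    expect_equal(steele_ra(0.07, 0.19, 0, 10, cc, cc, 0.05, 0.05), 0.07 / 0.05)
  }
})

test_that("Steele Ra matches the hand-evaluated non-steady-state formula", {
  # oracle evaluated term by term
  cbar <- (55 + 60) / 2
  dedt <- (0.055 - 0.060) / 10
  ebar <- (0.060 + 0.055) / 2
  oracle <- (0.07 - 0.19 * cbar * dedt) / ebar
  est <- steele_ra(0.07, 0.19, 0, 10, 55, 60, 0.060, 0.055)
  expect_equal(est, oracle, tolerance = 1e-12)
  expect_equal(round(est, 4), 1.3124)
})

test_that("Steele Ra rejects degenerate inputs", {
  expect_error(steele_ra(0.07, 0.19, 0, 10, 55, 55, 0, 0), "degenerate")
  expect_error(steele_ra(0.07, 0.19, 10, 10, 55, 55, 0.05, 0.05), "t2 > t1")
  expect_error(steele_ra(0.07, 0.19, 20, 10, 55, 55, 0.05, 0.05), "t2 > t1")
})

test_that("Steele Rd subtracts the pool-size drift", {
  ra <- steele_ra(0.07, 0.19, 0, 10, 55, 60, 0.060, 0.055)
  rd <- steele_rd(ra, 0.19, 0, 10, 55, 60)
  expect_equal(rd, ra - 0.19 * 5 / 10, tolerance = 1e-12)
  expect_equal(round(rd, 4), 1.2174)
  # constant pool: Rd = Ra
  expect_equal(steele_rd(1.4, 0.19, 0, 10, 55, 55), 1.4)
  # falling pool raises Rd above Ra
  expect_equal(steele_rd(1.4, 0.19, 0, 10, 60, 55), 1.495)
})

test_that("oral Ra recovers the meal-label dilution estimate", {
  # steady-state label: derivative vanishes, both modes agree at Ra*E/r
  for (m in c("corrected", "printed")) {
    expect_equal(oral_ra(1.8, 0.19, 0, 10, 70, 70, 0.0125, 0.0125,
                         r = 0.05, mode = m), 0.45)
  }
  # hand oracle for the corrected mode
  dedt <- 0.0002
  e2 <- 0.011 + dedt * 5
  e1 <- 0.011 - dedt * 5
  oracle <- (1.80 * 0.011 + 0.19 * 70 * dedt) / 0.05
  est <- oral_ra(1.80, 0.19, 0, 10, 70, 70, e1, e2, r = 0.05)
  expect_equal(est, oracle, tolerance = 1e-12)
  expect_equal(round(est, 4), 0.4492)
  # printed mode drops the concentration factor in the pool term
  est_p <- oral_ra(1.80, 0.19, 0, 10, 70, 70, e1, e2, r = 0.05,
                   mode = "printed")
  expect_equal(est_p, (1.80 * 0.011 + 0.19 * dedt) / 0.05, tolerance = 1e-12)
  # no label in blood, no oral appearance
  expect_equal(oral_ra(1.8, 0.19, 0, 10, 70, 70, 0, 0, r = 0.05), 0)
  expect_error(oral_ra(1.8, 0.19, 0, 10, 70, 70, 0.01, 0.01, r = 0), "positive")
  expect_warning(oral_ra(1.8, 0.19, 0, 10, 70, 70, 0.01, 0.001, r = 0.05),
                 "clipped")
})

test_that("endogenous Ra subtracts meal (and optionally tracer) appearance", {
  expect_equal(endogenous_ra(1.80, 0.45), 1.35)
  expect_equal(endogenous_ra(1.80, 0.45, f = 0.07, mode = "subtract_tracer"),
               1.28)
  expect_equal(endogenous_ra(1.80, 0), 1.80) # fasting limit
  expect_error(endogenous_ra(1.8, 0.4, mode = "subtract_tracer"), "requires")
  expect_warning(out <- endogenous_ra(0.4, 0.5), "clipped")
  expect_equal(out, 0)
})

test_that("hydroxylation transfers the tyrosine label flux to phe units", {
  expect_equal(hydroxylation_rate(0.55, 0.004, 0.055, 0.055), 0.04)
  expect_equal(hydroxylation_rate(0.55, 0, 0.055, 0.055), 0)
  expect_error(hydroxylation_rate(0.55, 0.004, 0, 0), "degenerate")
})

test_that("hydroxylation is invariant to a common enrichment rescale", {
  base <- hydroxylation_rate(0.55, 0.004, 0.050, 0.060)
  for (s in c(0.5, 2, 7)) {
    expect_equal(hydroxylation_rate(0.55, 0.004 * s, 0.050 * s, 0.060 * s),
                 base, tolerance = 1e-12)
  }
})

test_that("synthesis, gram conversion and net gain compose correctly", {
  expect_equal(protein_synthesis_rate(1.2174, 0.04), 1.1774)
  expect_equal(protein_synthesis_rate(1.2, 0), 1.2)
  expect_warning(s <- protein_synthesis_rate(0.03, 0.04), "negative")
  expect_equal(s, -0.01)
  expect_equal(to_grams_per_day(273 / 1440), 1)
  expect_equal(to_grams_per_day(0), 0)
  expect_equal(to_grams_per_day(1.1774), 1.1774 * 1440 / 273)
  expect_equal(round(to_grams_per_day(1.1774), 4), 6.2105)
  # linearity
  expect_equal(to_grams_per_day(2 * 1.1774), 2 * to_grams_per_day(1.1774))
  expect_equal(net_protein_gain(6.21, 6.75), -0.54)
  expect_equal(net_protein_gain(5, 5), 0)
})

test_that("splanchnic appearance normalises the oral Ra AUC to intake", {
  m <- meal_spec(total_phe_ingested = 180 * 50) # 180 umol per kg LM at LM 50
  out <- splanchnic_appearance(c(0, 360), c(0.40, 0.40), m, lean_mass = 50)
  expect_equal(out$appearance_pct, 80)
  expect_equal(out$first_pass_pct, 20)
  out0 <- splanchnic_appearance(c(0, 360), c(0, 0), m, lean_mass = 50)
  expect_equal(out0$appearance_pct, 0)
  # AUC equal to intake is 100%
  m2 <- meal_spec(total_phe_ingested = 0.40 * 360 * 50)
  expect_equal(splanchnic_appearance(c(0, 360), c(0.40, 0.40), m2,
                                     50)$appearance_pct, 100)
})

test_that("pipeline on constant-enrichment input returns F/E at every midpoint", {
  tabs <- const_study_tables()
  wb <- wholebody_kinetics(tabs$concentrations, tabs$enrichments,
                           demo_subject(), demo_protocols()$phe,
                           demo_protocols()$tyr, meal_spec())
  expect_s3_class(wb, "kinetics_result")
  expect_equal(wb$ra_total, rep(0.07 / 0.05, nrow(wb)), tolerance = 1e-12)
  expect_equal(wb$rd_total, wb$ra_total, tolerance = 1e-12)
  expect_equal(wb$ra_total_tyr, rep(0.04 / 0.04, nrow(wb)), tolerance = 1e-12)
  # baseline pair lands on -45
  expect_true(-45 %in% wb$midpoint)
  expect_equal(wb$phase[wb$midpoint == -45], "fasting")
  # postprandial midpoints follow the study convention
  expect_true(all(c(15, 25, 35, 45, 55, 75, 105, 150, 210, 270, 330) %in%
                    wb$midpoint))
})

test_that("pipeline bridges a missing sample by pairing across the gap", {
  tabs <- const_study_tables()
  tabs$concentrations <- dplyr::filter(tabs$concentrations, time != 90)
  tabs$enrichments <- dplyr::filter(tabs$enrichments, time != 90)
  wb <- wholebody_kinetics(tabs$concentrations, tabs$enrichments,
                           demo_subject(), demo_protocols()$phe,
                           demo_protocols()$tyr, meal_spec())
  expect_false(75 %in% wb$midpoint)   # (60, 90) pair no longer exists
  expect_true(90 %in% wb$midpoint)    # (60, 120) pair at midpoint 90
  row <- wb[wb$midpoint == 90, ]
  expect_equal(row$t1, 60)
  expect_equal(row$t2, 120)
})

test_that("endogenous/oral/total appearance identity holds across modes", {
  tabs <- const_study_tables()
  for (mode in c("simple", "subtract_tracer")) {
    wb <- wholebody_kinetics(tabs$concentrations, tabs$enrichments,
                             demo_subject(), demo_protocols()$phe,
                             demo_protocols()$tyr, meal_spec(),
                             endo_mode = mode)
    f <- if (mode == "subtract_tracer") 0.07 else 0
    expect_equal(wb$ra_endo + wb$ra_oral + f, wb$ra_total, tolerance = 1e-9)
  }
})
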