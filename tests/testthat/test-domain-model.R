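test_that("constants validate and carry the standard defaults", {
  k <- kinetics_constants()
  expect_equal(k$pool_fraction_pv, 0.125)
  expect_equal(k$phe_per_gram_protein, 273)
  expect_equal(k$homa_denominator, 22.5)
  expect_equal(k$insulin_conversion, 7.18)
  expect_equal(k$glucose_conversion, 18)
  expect_equal(k$minutes_per_day, 1440)
  expect_error(kinetics_constants(pool_fraction_pv = -1), "positive")
  expect_error(kinetics_constants(phe_per_gram_protein = 0), "positive")
})

test_that("effective pool volume rescales body-weight pV to lean mass", {
  # oracle: 0.125 * BW / LM by hand
  expect_equal(effective_pool_volume(76, 50), 0.125 * 76 / 50)
  expect_equal(effective_pool_volume(76, 50), 0.19)
  expect_equal(effective_pool_volume(60, 60), 0.125)
  expect_equal(effective_pool_volume(111.8, 68.0), 0.125 * 111.8 / 68,
               tolerance = 1e-12)
  expect_equal(round(effective_pool_volume(111.8, 68.0), 4), 0.2055)
  expect_error(effective_pool_volume(-1, 50), "positive")
  expect_error(effective_pool_volume(76, 0), "positive")
  expect_error(effective_pool_volume(50, 76), "exceed")
})

test_that("effective pool volume is homogeneous in the two masses", {
  for (s in c(0.5, 1, 2, 10)) {
    expect_equal(effective_pool_volume(76 * s, 50 * s),
                 effective_pool_volume(76, 50))
  }
})

test_that("actual infusion rate reconstructs delivered tracer per kg lean mass", {
  expect_equal(actual_infusion_rate(30, 0.14, 60), 0.07)
  expect_equal(actual_infusion_rate(30, 0, 60), 0)
  expect_equal(actual_infusion_rate(24, 0.10, 60), 0.04)
  expect_error(actual_infusion_rate(30, 0.14, 0), "lean_mass")
  expect_error(actual_infusion_rate(-1, 0.14, 60), "non-negative")
})

test_that("tracer protocol falls back to nominal rate without pump data", {
  p <- tracer_protocol("phe_d8", prime = 3, continuous_rate_nominal = 0.07)
  expect_equal(protocol_infusion_rate(p, 60), 0.07)
  p2 <- tracer_protocol("phe_d8", 3, 0.07,
                        infusate_concentration = 30, pump_flow = 0.14)
  expect_equal(protocol_infusion_rate(p2, 60), 0.07)
  expect_equal(protocol_infusion_rate(p2, 70), 30 * 0.14 / 70)
})

test_that("pooled TTR sums the channel isotopologues", {
  e <- tibble::tibble(
    time = 10, analyte = c("phe", "phe", "phe", "tyr", "tyr", "tyr"),
    isotopologue = c("d8", "d7", "d5", "d2", "d7", "d6"),
    ttr = c(0.05, 0.005, 0.01, 0.04, 0.003, 0.001)
  )
  expect_equal(pooled_ttr(e, "phe_d8d7")$ttr, 0.055)
  expect_equal(pooled_ttr(e, "tyr_d7d6")$ttr, 0.004)
  expect_equal(pooled_ttr(e, "phe_all")$ttr, 0.065)
  expect_equal(pooled_ttr(e, "phe_d5")$ttr, 0.01)
  expect_equal(pooled_ttr(e, "tyr_d2")$ttr, 0.04)
})

test_that("pooled TTR is additive and permutation-invariant", {
  set.seed(41)
  for (i in 1:20) {
    v <- runif(3, 0, 0.1)
    e <- tibble::tibble(time = 1, analyte = "phe",
                        isotopologue = sample(c("d5", "d7", "d8")),
                        ttr = v)
    expect_equal(pooled_ttr(e, "phe_all")$ttr, sum(v))
  }
})

test_that("pooled TTR refuses missing isotopologues, naming the channel", {
  e <- tibble::tibble(time = 10, analyte = "phe",
                      isotopologue = "d8", ttr = 0.05)
  expect_error(pooled_ttr(e, "phe_d8d7"), "phe_d8d7")
  e2 <- tibble::tibble(time = 10, analyte = "phe",
                       isotopologue = c("d8", "d7"), ttr = c(0.05, NA))
  expect_error(pooled_ttr(e2, "phe_d8d7"), "missing")
  expect_error(pooled_ttr(e, "nope"), "unknown channel")
})

test_that("background correction subtracts the -150 sample and drops it", {
  e <- tibble::tibble(
    time = c(-150, -60, 10), analyte = "phe",
    isotopologue = "d8", ttr = c(0.0002, 0.0502, 0.0602)
  )
  out <- correct_background(e)
  expect_equal(out$time, c(-60, 10))
  expect_equal(out$ttr, c(0.05, 0.06))
  expect_error(correct_background(dplyr::filter(e, time > 0)),
               "no background")
})

test_that("meal spec enforces the labelling ratio range", {
  expect_error(meal_spec(d5_to_tracee_ratio_r = 0), "0, 1")
  expect_error(meal_spec(d5_to_tracee_ratio_r = 1.2), "0, 1")
  expect_error(meal_spec(total_phe_ingested = -5), "positive")
  expect_s3_class(meal_spec(), "meal_spec")
})

test_that("study grid is strictly increasing and spans the design", {
  g <- study_grid()
  expect_true(all(diff(g) > 0))
  expect_equal(range(g), c(-150, 360))
  expect_true(all(c(-60, -30, 10, 360) %in% g))
})
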