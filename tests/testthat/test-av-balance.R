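test_that("net balance follows Fick across the bed", {
  expect_equal(net_balance(60, 55, flow = 0.3, lean_mass = 50), 0.03)
  expect_equal(net_balance(55, 55, flow = 0.3, lean_mass = 50), 0)
  expect_equal(net_balance(60, 55, mode = "difference"), 5)
  expect_error(net_balance(60, 55, flow = NULL, lean_mass = 50), "flow")
  expect_error(net_balance(60, 55, flow = NA, lean_mass = 50), "flow")
  expect_error(net_balance(60, 55, flow = 0.3, lean_mass = -1), "lean_mass")
})

test_that("fractional extraction matches its tracer-balance definition", {
  # oracle: (Ca Ea - Cv Ev) / (Ca Ea)
  oracle <- (60 * 0.055 - 57 * 0.050) / (60 * 0.055)
  expect_equal(fractional_extraction(60, 0.055, 57, 0.050), oracle,
               tolerance = 1e-12)
  expect_equal(round(oracle, 5), 0.13636)
  expect_equal(fractional_extraction(60, 0.05, 60, 0.05), 0)
  expect_equal(fractional_extraction(60, 0.05, 80, 0), 1)
  expect_error(fractional_extraction(0, 0.05, 60, 0.05), "Ca\\*Ea")
})

test_that("fractional extraction is scale invariant and bounded", {
  base <- fractional_extraction(60, 0.055, 57, 0.050)
  for (s in c(0.1, 3)) {
    expect_equal(fractional_extraction(60 * s, 0.055 * s, 57 * s, 0.050 * s),
                 base, tolerance = 1e-12)
  }
  set.seed(7)
  for (i in 1:50) {
    ca <- runif(1, 40, 80); ea <- runif(1, 0.02, 0.08)
    cv <- runif(1, 0, ca); ev <- runif(1, 0, ea)
    fe <- fractional_extraction(ca, ea, cv, ev)
    expect_gte(fe, 0)
    expect_lte(fe, 1)
  }
})

test_that("uptake and release close the two-pool balance", {
  fe <- fractional_extraction(60, 0.055, 57, 0.050)
  up <- uptake_rate(fe, 60, 0.35, 55)
  expect_equal(round(up, 5), 0.05207)
  expect_equal(uptake_rate(0, 60, 0.35, 55), 0)
  expect_equal(round(uptake_rate(1, 60, 0.35, 55), 5), 0.38182)
  expect_equal(round(release_rate(0.05207, 0.01909), 5), 0.03298)
  expect_equal(release_rate(0.05, 0.05), 0)
  expect_equal(release_rate(0, -0.02), 0.02) # fasting net release
})

test_that("uptake - net_balance - release is exactly zero on random inputs", {
  set.seed(13)
  for (i in 1:200) {
    ca <- runif(1, 40, 90); cv <- runif(1, 30, 90)
    ea <- runif(1, 0.02, 0.09); ev <- runif(1, 0.005, ea)
    fl <- runif(1, 0.2, 0.7); lm <- runif(1, 45, 80)
    nb <- net_balance(ca, cv, fl, lm)
    up <- uptake_rate(fractional_extraction(ca, ea, cv, ev), ca, fl, lm)
    rel <- release_rate(up, nb)
    expect_identical(up - nb - rel, 0)
  }
})

test_that("av pipeline reproduces per-timepoint balances for both analytes", {
  art <- tibble::tibble(time = rep(c(10, 20), 2),
                        analyte = rep(c("phe", "tyr"), each = 2),
                        concentration = c(60, 66, 50, 52))
  ven <- dplyr::mutate(art, concentration = concentration - c(5, 6, 2, 2))
  fl <- tibble::tibble(time = c(10, 20), flow = c(0.4, 0.5))
  out <- av_balance(art, ven, flow = fl, lean_mass = 50)
  expect_s3_class(out, "av_balance_result")
  phe <- dplyr::filter(out, analyte == "phe")
  expect_equal(phe$net_balance, c(5 * 0.4 / 50, 6 * 0.5 / 50))
  # identical series: all-zero balance
  out0 <- av_balance(art, art, flow = fl, lean_mass = 50)
  expect_true(all(out0$net_balance == 0))
})

test_that("av pipeline interpolates flow to sample times", {
  art <- tibble::tibble(time = c(10, 30), analyte = "phe",
                        concentration = c(60, 60))
  ven <- dplyr::mutate(art, concentration = 55)
  fl <- tibble::tibble(time = c(0, 40), flow = c(0.4, 0.8))
  out <- av_balance(art, ven, flow = fl, lean_mass = 50)
  expect_equal(out$flow, c(0.5, 0.7)) # linear in time
})

test_that("av pipeline flags misaligned grids and missing flow", {
  art <- tibble::tibble(time = c(10, 20), analyte = "phe",
                        concentration = c(60, 66))
  ven <- tibble::tibble(time = c(10, 25), analyte = "phe",
                        concentration = c(55, 60))
  expect_error(av_balance(art, ven, flow = tibble::tibble(time = 10, flow = 0.4),
                          lean_mass = 50), "misaligned.*2[05]")
  expect_error(av_balance(art, art[1:2, ], flow = NULL, lean_mass = 50),
               "flow")
})

test_that("difference mode yields concentration gradients without uptake", {
  art <- tibble::tibble(time = c(10, 20), analyte = "phe",
                        concentration = c(60, 66))
  ven <- dplyr::mutate(art, concentration = concentration - 5)
  out <- av_balance(art, ven, mode = "difference")
  expect_equal(out$net_balance, c(5, 5))
  expect_true(all(is.na(out$uptake)))
  expect_true(all(is.na(out$release)))
  expect_identical(attr(out, "units"), "umol/L")
})
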