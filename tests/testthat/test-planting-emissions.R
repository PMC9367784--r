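test_that("annual feed demand reproduces the herd mass balance", {
  # 10 million head: 20 kg/d silage -> 7.30e7 t/a; 9 kg/d common corn -> 3.29e7 t/a
  expect_equal(annual_feed_demand(20, 1e7, 365), 7.30e10)
  expect_equal(annual_feed_demand(9, 1e7, 365), 3.285e10)
  expect_equal(annual_feed_demand(0, 1e7, 365), 0)
  expect_error(annual_feed_demand(-1, 1e7, 365), "non-negative")
})

test_that("straw balance carries both straw-total conventions", {
  b <- straw_balance(3.285e10, 0.0988, 0.8575)
  # normalized total: retained fates (feed + burn) rescaled to sum to 1
  expect_equal(b$total_straw_normalized, 3.285e10 * 0.9563 / 0.0988)
  expect_equal(b$total_straw_normalized / 1e10, 31.80, tolerance = 1e-3)
  # feed-share total: demand / feed fraction
  expect_equal(b$total_straw_feed_share, 3.285e10 / 0.0988)
  expect_equal(b$total_straw_feed_share / 1e10, 33.25, tolerance = 1e-3)
  expect_gte(b$total_straw_normalized, b$annual_feed_demand)
  expect_gte(b$total_straw_feed_share, b$annual_feed_demand)

  # all straw used as feed: both totals collapse to the demand
  b1 <- straw_balance(5e9, 1.0, 0.0)
  expect_equal(b1$total_straw_normalized, 5e9)
  expect_equal(b1$total_straw_feed_share, 5e9)

  expect_error(straw_balance(1e9, 0, 0.5), "straw_feed_fraction")
  expect_error(straw_balance(1e9, 0.5, 0.6), "at most 1")
})

test_that("corn-planting CO2 matches the reported per-model values", {
  expect_equal(corn_planting_co2(7.30e10, 1.50), 10.95e10)
  expect_equal(corn_planting_co2(3.285e10 * 0.9563 / 0.0988, 1.50) / 1e10,
               47.69, tolerance = 1e-3)
  expect_equal(corn_planting_co2(0, 1.50), 0)
})

test_that("fertilizer N input follows area x rate x N-content composition", {
  n_ne <- fertilizer_nitrogen_input(70.66e5, 679.33, 0.3105, 0.5363, 0.2841)
  expect_equal(n_ne, 70.66e5 * 679.33 * (0.3105 + 0.5363 * 0.2841))
  expect_equal(n_ne, 2.2219e9, tolerance = 1e-3)
  n_ec <- fertilizer_nitrogen_input(9.01e5, 679.33, 0.3105, 0.5363, 0.2841)
  expect_equal(n_ec, 2.833e8, tolerance = 1e-3)
  expect_equal(fertilizer_nitrogen_input(0, 679.33, 0.3105, 0.5363, 0.2841), 0)
})

test_that("soil N2O combines direct and indirect pathways additively", {
  # composite factor 0.013375 x 44/28 x 265 = 5.5697 kg CO2-eq per kg N
  expect_equal(soil_n2o(1e6, 0.0105, 0.01, 0.1, 0.0075, 0.25, 265),
               1e6 * 0.013375 * 44 / 28 * 265)
  n_ne <- fertilizer_nitrogen_input(70.66e5, 679.33, 0.3105, 0.5363, 0.2841)
  expect_equal(soil_n2o(n_ne, 0.0105, 0.01, 0.1, 0.0075, 0.25, 265) / 1e10,
               1.2375, tolerance = 1e-3)
  expect_equal(soil_n2o(0, 0.0105, 0.01, 0.1, 0.0075, 0.25, 265), 0)

  # with loss fractions 0 only the direct term remains
  set.seed(41)
  for (i in 1:20) {
    tn <- rdraw(); efd <- rdraw(1, 0, 0.1); efv <- rdraw(1, 0, 0.1)
    efl <- rdraw(1, 0, 0.1); fg <- runif(1); fl <- runif(1)
    direct_only <- soil_n2o(tn, efd, efv, 0, efl, 0, 265)
    expect_equal(direct_only, tn * efd * 44 / 28 * 265)
    full <- soil_n2o(tn, efd, efv, fg, efl, fl, 265)
    vol_term <- soil_n2o(tn, 0, efv, fg, 0, 0, 265)
    leach_term <- soil_n2o(tn, 0, 0, 0, efl, fl, 265)
    expect_gte(vol_term, 0)
    expect_gte(leach_term, 0)
    expect_equal(full, direct_only + vol_term + leach_term)
  }
})

test_that("manure-application N2O: replication and corrected paths", {
  ref <- reference_scenarios()
  ec_rep <- manure_application_n2o(ref$ec, "replication")
  ne_rep <- manure_application_n2o(ref$nonec, "replication")
  # as-reported values 49.53 / 22.29 t (reproduced to the source's rounding)
  expect_equal(ec_rep / 1e3, 49.53, tolerance = 1e-3)
  expect_equal(ne_rep / 1e3, 22.29, tolerance = 1e-3)
  # the non-EC value is exactly the EC value scaled by its 45% return rate
  expect_equal(ne_rep / ec_rep, 0.45)

  # corrected path: herd N excretion basis with the standard N2O GWP
  nex <- n_excretion_annual(0.41, 319)
  comp <- (0.0105 + 0.01 * 0.2 + 0.0075 * 0.25) * 44 / 28
  expect_equal(manure_application_n2o(ref$ec, "corrected"),
               1e7 * nex * 1.0 * comp * 265)
  expect_equal(manure_application_n2o(ref$ec, "corrected") / 1e9, 2.858,
               tolerance = 1e-3)
  expect_error(manure_application_n2o(ref$ec, "bogus"))
})

test_that("feed-production CO2 exists only in the ecological-cycle system", {
  expect_equal(feed_production_co2(7.30e10, 0.0102), 7.446e8)
  expect_equal(feed_production_co2(7.30e10, 0.0102) / 1e10, 0.07,
               tolerance = 0.07)
  expect_equal(feed_production_co2(0, 0.0102), 0)
  expect_equal(feed_production_co2(1e10, 0.01), 1e8)
  ref <- reference_scenarios()
  expect_equal(scenario_feed_production_co2(ref$ec), 7.446e8)
  expect_error(scenario_feed_production_co2(ref$nonec), "non-EC")
})

test_that("straw-burning emissions reproduce the per-gas values", {
  f <- emission_factor_set(); g <- gwp_set()
  straw <- 3.285e10 / 0.0988  # feed-share straw total
  burn <- straw_burning_emissions(straw, 0.8575, 0.1, f, g)
  burned <- straw * 0.8575 * 0.1
  expect_equal(burn$co2, burned * 1.39)
  expect_equal(burn$co2 / 1e10, 3.96, tolerance = 1e-3)
  expect_equal(burn$n2o, burned * 7e-5 * 265)
  expect_equal(burn$n2o / 1e10, 0.05, tolerance = 0.06)
  # CH4 computes 0.175e7 t; the reported 0.18 is that value rounded up
  expect_equal(burn$ch4, burned * 2.19e-3 * 28)
  expect_equal(burn$ch4 / 1e9, 1.748, tolerance = 1e-3)
  expect_equal(burn$total, burn$co2 + burn$ch4 + burn$n2o)

  z <- straw_burning_emissions(0, 0.8575, 0.1, f, g)
  expect_equal(unlist(z), c(co2 = 0, ch4 = 0, n2o = 0, total = 0))

  ref <- reference_scenarios()
  expect_error(scenario_straw_burning(ref$ec), "EC scenario")
  expect_equal(scenario_straw_burning(ref$nonec)$co2, burn$co2)
})

test_that("planting emissions are homogeneous of degree 1 in activity", {
  set.seed(99)
  for (i in 1:25) {
    k <- runif(1, 0.1, 10)
    m <- rdraw(); ef <- rdraw(1, 0, 2)
    expect_equal(corn_planting_co2(k * m, ef), k * corn_planting_co2(m, ef))
    expect_equal(feed_production_co2(k * m, ef), k * feed_production_co2(m, ef))
    tn <- rdraw()
    expect_equal(soil_n2o(k * tn, 0.0105, 0.01, 0.1, 0.0075, 0.25, 265),
                 k * soil_n2o(tn, 0.0105, 0.01, 0.1, 0.0075, 0.25, 265))
    fs <- emission_factor_set(); gs <- gwp_set()
    b1 <- straw_burning_emissions(m, 0.8, 0.1, fs, gs)
    bk <- straw_burning_emissions(k * m, 0.8, 0.1, fs, gs)
    expect_equal(bk$total, k * b1$total)
  }
})

test_that("planting formulas agree with independent oracles on random draws", {
  set.seed(7)
  for (i in 1:100) {
    q <- rdraw(); na <- rdraw(); d <- rdraw(1, 1, 366)
    expect_rel_equal(annual_feed_demand(q, na, d),
                     oracle_feed_demand(q, na, d))

    fd <- rdraw(); rf <- runif(1, 0.01, 0.5); rb <- runif(1, 0, 0.5)
    b <- straw_balance(fd, rf, rb)
    expect_rel_equal(b$total_straw_normalized,
                     oracle_straw_normalized(fd, rf, rb))
    expect_rel_equal(b$total_straw_feed_share, oracle_straw_feed_share(fd, rf))

    m <- rdraw(); ef <- rdraw(1, 0, 3)
    expect_rel_equal(corn_planting_co2(m, ef), oracle_corn_co2(m, ef))
    expect_rel_equal(feed_production_co2(m, ef), oracle_feed_co2(m, ef))

    area <- rdraw(); qsn <- rdraw(); rnf <- runif(1); rcf <- runif(1)
    wc <- runif(1)
    expect_rel_equal(fertilizer_nitrogen_input(area, qsn, rnf, rcf, wc),
                     oracle_tnf(area, qsn, rnf, rcf, wc))

    tn <- rdraw(); efd <- rdraw(1, 0, 0.1); efv <- rdraw(1, 0, 0.1)
    efl <- rdraw(1, 0, 0.1); fg <- runif(1); fl <- runif(1); gwp <- rdraw(1, 1, 300)
    expect_rel_equal(soil_n2o(tn, efd, efv, fg, efl, fl, gwp),
                     oracle_soil_n2o(tn, efd, efv, fg, efl, fl, gwp))

    straw <- rdraw(); g <- runif(1, 0, 1)
    fs <- emission_factor_set(ef_burn_co2 = rdraw(1, 0, 2),
                              ef_burn_ch4 = rdraw(1, 0, 0.01),
                              ef_burn_n2o = rdraw(1, 0, 0.001))
    gs <- gwp_set(gwp_ch4 = rdraw(1, 1, 100), gwp_n2o = rdraw(1, 1, 400))
    bb <- straw_burning_emissions(straw, rb, g, fs, gs)
    expect_rel_equal(bb$co2, oracle_burn_gas(straw, rb, g, fs$ef_burn_co2, 1))
    expect_rel_equal(bb$ch4,
                     oracle_burn_gas(straw, rb, g, fs$ef_burn_ch4, gs$gwp_ch4))
    expect_rel_equal(bb$n2o,
                     oracle_burn_gas(straw, rb, g, fs$ef_burn_n2o, gs$gwp_n2o))
  }
})
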