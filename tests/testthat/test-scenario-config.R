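test_that("reference scenarios carry the documented parameterization", {
  ref <- reference_scenarios()
  ec <- ref$ec; ne <- ref$nonec

  expect_equal(ec$herd$herd_size, 1e7)
  expect_equal(ec$herd$live_weight, 319)
  expect_equal(ec$herd$enteric_ef, 65)
  expect_equal(ne$herd$enteric_ef, 65)
  expect_equal(ec$herd$fattening_days, 365)
  expect_equal(ec$herd$manure_per_head_day * 365, 8030)

  expect_equal(ec$planting$feed_intake_per_head_day, 20)
  expect_equal(ne$planting$feed_intake_per_head_day, 9)
  expect_equal(ec$planting$planting_area, 9.01e5)
  expect_equal(ne$planting$planting_area, 70.66e5)
  expect_equal(ne$planting$straw_feed_fraction, 0.0988)
  expect_equal(ne$planting$straw_burn_fraction, 0.8575)
  expect_identical(ec$planting$straw_burn_fraction, 0)

  expect_equal(ec$manure$return_rate, 1.00)
  expect_equal(ne$manure$return_rate, 0.45)
  expect_equal(ec$manure$vs_rate, 6.8)
  expect_equal(ne$manure$vs_rate, 10.8)
  expect_equal(ec$manure$ms_fraction, 0.28)
  expect_equal(ne$manure$ms_fraction, 0.29)
  expect_equal(ec$manure$mm_ch4_ef, 1.05)
  expect_equal(ne$manure$mm_ch4_ef, 2.05)
  expect_equal(ec$manure$mm_n2o_direct_ef, 0.005)
  expect_equal(ne$manure$mm_n2o_direct_ef, 0.01)
  expect_equal(ec$manure$f_gas, 0.30)
  expect_equal(ne$manure$f_gas, 0.45)
  expect_equal(ec$manure$f_leach, 0.035)
  expect_equal(ne$manure$f_leach, 0.02)

  expect_equal(ec$gwp$gwp_ch4, 28)
  expect_equal(ec$gwp$gwp_n2o, 265)
  expect_equal(ec$gwp$gwp_n2o_manure_application, 273)

  # both pass validation with zero violations
  expect_length(scenario_violations(ec), 0)
  expect_length(scenario_violations(ne), 0)
})

test_that("packaged fixture files load to the reference scenarios", {
  ec <- load_scenario(system.file("extdata", "ec_reference.yaml",
                                  package = "cattleGHG"))
  ne <- load_scenario(system.file("extdata", "nonec_reference.yaml",
                                  package = "cattleGHG"))
  expect_equal(ec$planting$feed_intake_per_head_day, 20)
  expect_equal(ne$planting$straw_burn_fraction, 0.8575)
  expect_equal(ec$overrides$n_fertilizer, 2.1e9)
  ref <- reference_scenarios()
  expect_identical(unclass(ec), unclass(ref$ec))
  expect_identical(unclass(ne), unclass(ref$nonec))
})

test_that("scenario write-then-load round trip is exact", {
  specs <- c(reference_scenarios(),
             list(gen_ec = generate_scenario(generation_ranges("EC"), seed = 11),
                  gen_ne = generate_scenario(generation_ranges("non-EC"),
                                             seed = 12)))
  for (s in specs) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_scenario(s, path)
    expect_identical(unclass(load_scenario(path)), unclass(s),
                     label = paste("round trip of", s$name))
  }
})

test_that("validation rejects out-of-range and structurally wrong configs", {
  ref <- reference_scenarios()

  bad <- ref$nonec
  bad$manure$return_rate <- 1.5
  expect_error(validate_scenario(bad), "return_rate")

  bad <- ref$nonec
  bad$planting$straw_feed_fraction <- 0.5
  bad$planting$straw_burn_fraction <- 0.6
  expect_error(validate_scenario(bad), "sum to at most 1")

  bad <- ref$ec
  bad$planting$straw_burn_fraction <- 0.1
  expect_error(validate_scenario(bad), "EC scenario")

  bad <- ref$nonec
  bad$planting$straw_burn_fraction <- 0
  expect_error(validate_scenario(bad), "non-EC scenario")

  bad <- ref$ec
  bad$herd$enteric_ef <- -1
  bad$manure$ms_fraction <- 2
  # all violations reported together
  err <- tryCatch(validate_scenario(bad), error = conditionMessage)
  expect_match(err, "enteric_ef")
  expect_match(err, "ms_fraction")

  expect_error(scenario_spec("x", "EC", ref$ec$herd, ref$ec$planting,
                             ref$ec$manure, overrides = list(bogus = 1)),
               "unknown override")
})

test_that("loader reports offending keys and fills factor defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")

  writeLines(c("name: t", "model_kind: EC", "herd: {herd_size: 1}",
               "planting: {feed_intake_per_head_day: 1, planting_area: 1}",
               "manure: {return_rate: 1, vs_rate: 1, ms_fraction: 0.2,",
               "  mm_ch4_ef: 1, mm_n2o_direct_ef: 0.01, f_gas: 0.1,",
               "  f_leach: 0.1}",
               "bogus_key: 1"), path)
  expect_error(load_scenario(path), "bogus_key")

  writeLines(c("name: t", "model_kind: EC",
               "herd: {herd_size: 1, not_a_field: 2}",
               "planting: {feed_intake_per_head_day: 1, planting_area: 1}",
               "manure: {return_rate: 1, vs_rate: 1, ms_fraction: 0.2,",
               "  mm_ch4_ef: 1, mm_n2o_direct_ef: 0.01, f_gas: 0.1,",
               "  f_leach: 0.1}"), path)
  expect_error(load_scenario(path), "not_a_field")

  writeLines(c("name: t", "model_kind: EC"), path)
  expect_error(load_scenario(path), "herd")

  expect_error(load_scenario("no/such/file.yaml"), "not found")

  # omitted factors/gwp blocks take the reference defaults
  writeLines(c("name: t", "model_kind: EC",
               "herd: {herd_size: 1}",
               "planting: {feed_intake_per_head_day: 1, planting_area: 1}",
               "manure: {return_rate: 1, vs_rate: 1, ms_fraction: 0.2,",
               "  mm_ch4_ef: 1, mm_n2o_direct_ef: 0.01, f_gas: 0.1,",
               "  f_leach: 0.1}"), path)
  s <- load_scenario(path)
  expect_equal(s$factors$ef_farm_corn, 1.50)
  expect_equal(s$factors$ef_burn_ch4, 2.19e-3)
  expect_equal(s$gwp$gwp_n2o, 265)
})

test_that("parameter glossary maps each symbol to exactly one live field", {
  gl <- parameter_glossary()
  expect_false(any(duplicated(gl$symbol)))
  expect_false(any(duplicated(gl$field)))
  ref <- reference_scenarios()
  for (f in gl$field) {
    expect_true(is.numeric(cattleGHG:::scenario_get(ref$ec, f)),
                label = paste("EC field", f))
    expect_true(is.numeric(cattleGHG:::scenario_get(ref$nonec, f)),
                label = paste("non-EC field", f))
  }
  # every numeric scenario field is covered by a glossary entry
  blocks <- c("herd", "planting", "manure", "factors", "gwp")
  fields <- unlist(lapply(blocks, function(b) {
    nm <- names(ref$ec[[b]])
    paste0(b, ".", nm[!vapply(ref$ec[[b]], is.logical, logical(1))])
  }))
  expect_setequal(setdiff(fields, gl$field),
                  "gwp.gwp_n2o_manure_application")  # replication-only constant
})
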