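# Independently coded single-expression arithmetic oracles for every
# emission formula. These never call package internals; each is the formula
# written out once, used to cross-check the implementation on random draws.

oracle_feed_demand <- function(q, na, d) q * na * d

oracle_straw_normalized <- function(fd, rf, rb) fd * (rf + rb) / rf

oracle_straw_feed_share <- function(fd, rf) fd / rf

oracle_corn_co2 <- function(m, ef) m * ef

oracle_tnf <- function(area, qsn, rnf, rcf, wc) area * qsn * (rnf + rcf * wc)

oracle_soil_n2o <- function(tn, efd, efv, fg, efl, fl, gwp) {
  tn * (efd + efv * fg + efl * fl) * 44 / 28 * gwp
}

oracle_feed_co2 <- function(qs, ef) qs * ef

oracle_burn_gas <- function(straw, rb, g, ef, gwp) straw * rb * g * ef * gwp

oracle_enteric <- function(na, ef, gwp) na * ef * gwp

oracle_vs <- function(rate, w) rate * w / 1000 * 365

oracle_mm_ch4 <- function(na, vs, ms, ef, gwp) na * vs * ms * ef * gwp

oracle_nex <- function(rate, w) rate * w / 1000 * 365

oracle_mm_n2o_direct <- function(na, nex, ms, ef, gwp) {
  na * nex * ms * ef * 44 / 28 * gwp
}

oracle_mm_n2o_vol <- function(na, nex, ms, fgas, ef, gwp) {
  na * nex * ms * fgas * ef * 44 / 28 * gwp
}

oracle_mm_n2o_leach <- function(na, nex, ms, fleach, ef, gwp) {
  na * nex * ms * fleach * ef * 44 / 28 * gwp
}

# random positive draws used by the oracle-equivalence property tests
rdraw <- function(n = 1, lo = 1e-4, hi = 1e4) runif(n, lo, hi)

expect_rel_equal <- function(actual, expected, rel_tol = 1e-12) {
  denom <- pmax(abs(expected), .Machine$double.xmin)
  expect_true(all(abs(actual - expected) / denom < rel_tol),
              label = paste0("relative error vs oracle (max ",
                             format(max(abs(actual - expected) / denom)), ")"))
}
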