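#' CH4 from enteric fermentation, in CO2-eq
#'
#' Tier-1: one fixed CH4 factor per head per year. The same factor is used
#' regardless of diet; a feed-dependent (gross-energy/Ym) Tier-2 model is
#' deliberately out of scope.
#'
#' @param herd_size Head of cattle (head/a).
#' @param enteric_ef Enteric CH4 factor (kg CH4/head/a).
#' @param gwp_ch4 CH4 100-year GWP.
#' @return CO2-eq (kg/a).
#' @examples
#' enteric_ch4(1e7, 65, 28) / 1e10  # 1.82e7 t CO2-eq
#' @export
enteric_ch4 <- function(herd_size, enteric_ef, gwp_ch4) {
  check_nonneg(herd_size = herd_size, enteric_ef = enteric_ef,
               gwp_ch4 = gwp_ch4)
  herd_size * enteric_ef * gwp_ch4
}

#' Annual volatile-solids excretion per head
#'
#' @param vs_rate VS excretion rate (kg VS/(1000 kg live mass)/d).
#' @param live_weight Live weight (kg).
#' @return VS per head per year (kg/head/a).
#' @export
volatile_solids_annual <- function(vs_rate, live_weight) {
  check_nonneg(vs_rate = vs_rate, live_weight = live_weight)
  vs_rate * live_weight / 1000 * 365
}

#' CH4 from manure management, in CO2-eq
#'
#' @param herd_size Head of cattle (head).
#' @param vs_annual Annual VS excretion per head (kg/head/a), from
#'   [volatile_solids_annual()].
#' @param ms_fraction Fraction of annual VS handled in the managed system.
#' @param mm_ch4_ef Manure-management CH4 factor (kg CH4/kg VS).
#' @param gwp_ch4 CH4 100-year GWP.
#' @return CO2-eq (kg/a).
#' @export
manure_mgmt_ch4 <- function(herd_size, vs_annual, ms_fraction, mm_ch4_ef,
                            gwp_ch4) {
  check_nonneg(herd_size = herd_size, vs_annual = vs_annual,
               ms_fraction = ms_fraction, mm_ch4_ef = mm_ch4_ef,
               gwp_ch4 = gwp_ch4)
  if (ms_fraction > 1) stop("'ms_fraction' must be <= 1", call. = FALSE)
  herd_size * vs_annual * ms_fraction * mm_ch4_ef * gwp_ch4
}

#' Annual nitrogen excretion per head
#'
#' @param n_rate N excretion rate (kg N/(1000 kg live mass)/d).
#' @param live_weight Live weight (kg).
#' @return N per head per year (kg N/head/a).
#' @export
n_excretion_annual <- function(n_rate, live_weight) {
  check_nonneg(n_rate = n_rate, live_weight = live_weight)
  n_rate * live_weight / 1000 * 365
}

#' N2O from manure management, in CO2-eq, by pathway
#'
#' Managed N is herd_size x per-head annual N excretion x the managed
#' fraction. Direct emission applies the management system's direct N2O-N
#' factor; the indirect pathways apply the volatilized (f_gas) and leached
#' (f_leach) shares of managed N to their respective indirect factors.
#' Every pathway converts N2O-N to N2O by 44/28 and to CO2-eq by the N2O
#' GWP.
#'
#' @param herd_size Head of cattle (head).
#' @param nex Annual N excretion per head (kg N/head/a), from
#'   [n_excretion_annual()].
#' @param manure A [manure_spec()].
#' @param factors An [emission_factor_set()].
#' @param gwp_n2o N2O 100-year GWP.
#' @return A list of class `manure_n2o_breakdown` with `direct`,
#'   `indirect_volatilization`, `indirect_leaching` and `total`
#'   (CO2-eq kg/a).
#' @export
manure_mgmt_n2o <- function(herd_size, nex, manure, factors, gwp_n2o) {
  check_nonneg(herd_size = herd_size, nex = nex, gwp_n2o = gwp_n2o)
  managed_n <- herd_size * nex * manure$ms_fraction
  k <- N2O_N_TO_N2O * gwp_n2o
  out <- list(
    direct = managed_n * manure$mm_n2o_direct_ef * k,
    indirect_volatilization = managed_n * manure$f_gas *
      factors$ef_mm_idn_vol * k,
    indirect_leaching = managed_n * manure$f_leach *
      factors$ef_mm_idn_leach * k)
  out$total <- out$direct + out$indirect_volatilization + out$indirect_leaching
  structure(out, class = "manure_n2o_breakdown")
}
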