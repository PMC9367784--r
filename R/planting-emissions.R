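check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
      stop("'", nm, "' must be a single non-negative finite number",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# N2O-N -> N2O mass conversion, kept as an exact rational
N2O_N_TO_N2O <- 44 / 28

#' Annual roughage feed demand of the herd
#'
#' @param intake_per_head_day Daily corn roughage intake (kg/head/d).
#' @param herd_size Head of cattle (head).
#' @param days Feeding days per year (d/a).
#' @return Feed mass demanded per year (kg/a).
#' @examples
#' annual_feed_demand(20, 1e7, 365) / 1e10  # 7.30e10 kg = 7.30e7 t silage
#' @export
annual_feed_demand <- function(intake_per_head_day, herd_size, days = 365) {
  check_nonneg(intake_per_head_day = intake_per_head_day,
               herd_size = herd_size, days = days)
  intake_per_head_day * herd_size * days
}

#' Partition the regional straw resource behind a feed demand
#'
#' The feed demand pins down the total straw resource through the share of
#' straw that goes to feed. Two totals are carried because the inventory's
#' processes are calibrated against different conventions: the *normalized*
#' total rescales the retained fates (feed + burning) to sum to one, while
#' the *feed-share* total divides the demand by the feed share alone.
#' Corn-planting CO2 for a conventional scenario consumes the normalized
#' total; straw-burning emissions consume the feed-share total.
#'
#' @param feed_demand Annual straw-as-feed demand (kg/a).
#' @param feed_fraction Share of the straw resource used as feed (0, 1].
#' @param burn_fraction Share open-burned.
#' @return A list of class `straw_balance` with `annual_feed_demand`,
#'   `total_straw_normalized` and `total_straw_feed_share` (all kg/a).
#' @examples
#' b <- straw_balance(3.285e10, 0.0988, 0.8575)
#' b$total_straw_normalized / 1e10   # 31.80e10 kg
#' b$total_straw_feed_share / 1e10   # 33.25e10 kg
#' @export
straw_balance <- function(feed_demand, feed_fraction, burn_fraction) {
  check_nonneg(feed_demand = feed_demand, feed_fraction = feed_fraction,
               burn_fraction = burn_fraction)
  if (feed_fraction == 0) {
    stop("straw feed fraction is 0: the straw total is undefined; ",
         "set planting.straw_feed_fraction to the share of straw used as feed",
         call. = FALSE)
  }
  if (feed_fraction + burn_fraction > 1 + 1e-9) {
    stop("straw feed and burn fractions must sum to at most 1", call. = FALSE)
  }
  structure(
    list(annual_feed_demand = feed_demand,
         total_straw_normalized =
           feed_demand * (feed_fraction + burn_fraction) / feed_fraction,
         total_straw_feed_share = feed_demand / feed_fraction),
    class = "straw_balance")
}

#' CO2 from growing the corn feed crop
#'
#' @param corn_mass Corn (or corn straw resource) grown per year (kg/a).
#'   An EC scenario uses its annual silage feed demand; a non-EC scenario
#'   uses the normalized straw total from [straw_balance()].
#' @param ef_farm_corn Farming CO2 factor (t CO2/t corn).
#' @return CO2 (kg/a).
#' @export
corn_planting_co2 <- function(corn_mass, ef_farm_corn) {
  check_nonneg(corn_mass = corn_mass, ef_farm_corn = ef_farm_corn)
  corn_mass * ef_farm_corn
}

#' Annual nitrogen input from chemical fertilizer
#'
#' Total fertilizer mass applied over the planting area, reduced to N mass
#' through the straight-N share plus the compound share times its N content.
#'
#' @param area Planting area (hm2).
#' @param application_rate Fertilizer application rate (kg/hm2/a).
#' @param n_fert_share Straight-N fertilizer share (fraction).
#' @param compound_share Compound fertilizer share (fraction).
#' @param compound_n_content N content of compound fertilizer (fraction).
#' @return N applied per year (kg N/a).
#' @export
fertilizer_nitrogen_input <- function(area, application_rate, n_fert_share,
                                      compound_share, compound_n_content) {
  check_nonneg(area = area, application_rate = application_rate,
               n_fert_share = n_fert_share, compound_share = compound_share,
               compound_n_content = compound_n_content)
  area * application_rate * (n_fert_share + compound_share * compound_n_content)
}

#' Soil N2O from applied nitrogen, in CO2-eq
#'
#' Direct emission at the application site plus the two indirect pathways:
#' re-deposition of volatilized NH3-N/NOx-N and leaching/runoff. The N2O-N
#' total is converted to N2O by 44/28 and to CO2-eq by the N2O GWP.
#'
#' @param n_input Applied N (kg N/a).
#' @param ef_direct Direct N2O-N factor (t/t).
#' @param ef_vol Indirect N2O-N factor for volatilized N (t/t).
#' @param f_gas Volatilized fraction of applied N.
#' @param ef_leach Indirect N2O-N factor for leached N (t/t).
#' @param f_leach Leached fraction of applied N.
#' @param gwp_n2o N2O 100-year GWP.
#' @return CO2-eq (kg/a).
#' @export
soil_n2o <- function(n_input, ef_direct, ef_vol, f_gas, ef_leach, f_leach,
                     gwp_n2o) {
  check_nonneg(n_input = n_input, ef_direct = ef_direct, ef_vol = ef_vol,
               f_gas = f_gas, ef_leach = ef_leach, f_leach = f_leach,
               gwp_n2o = gwp_n2o)
  n_input * (ef_direct + ef_vol * f_gas + ef_leach * f_leach) *
    N2O_N_TO_N2O * gwp_n2o
}

#' N2O from field application of manure, in CO2-eq
#'
#' Two computation paths are provided. `"replication"` reproduces the
#' reference results: the applied-N activity is the per-head annual manure
#' mass (manure_per_head_day x 365, i.e. 8030 kg on the reference herd)
#' times the return rate — a per-head mass basis, not herd N — and the
#' conversion uses the scenario's dedicated manure-application GWP (273).
#' `"corrected"` applies the factor set uniformly: herd N excretion
#' (herd_size x annual N per head) times the return rate, with the standard
#' N2O GWP (265). Both paths share the composite soil factor
#' (ef_n_direct + ef_n_vol_indirect x f_gas_manure +
#' ef_n_leach_indirect x f_leach_soil) x 44/28.
#'
#' @param spec A `ghg_scenario`.
#' @param mode `"replication"` or `"corrected"`.
#' @return CO2-eq (kg/a).
#' @export
manure_application_n2o <- function(spec, mode = c("replication", "corrected")) {
  mode <- match.arg(mode)
  f <- spec$factors
  composite <- (f$ef_n_direct + f$ef_n_vol_indirect * f$f_gas_manure +
                  f$ef_n_leach_indirect * f$f_leach_soil) * N2O_N_TO_N2O
  if (mode == "replication") {
    tnm <- spec$herd$manure_per_head_day * 365 * spec$manure$return_rate
    tnm * composite * spec$gwp$gwp_n2o_manure_application
  } else {
    nex <- n_excretion_annual(spec$herd$n_excretion_rate,
                              spec$herd$live_weight)
    tnm <- spec$herd$herd_size * nex * spec$manure$return_rate
    tnm * composite * spec$gwp$gwp_n2o
  }
}

#' CO2 from processing silage corn into feed
#'
#' Only an ecological-cycle system processes its own silage; a conventional
#' scenario has no feed-production process.
#'
#' @param silage_mass Annual silage feed demand (kg/a).
#' @param ef_feed_corn Feed-processing CO2 factor (t CO2/t silage).
#' @return CO2 (kg/a).
#' @export
feed_production_co2 <- function(silage_mass, ef_feed_corn) {
  check_nonneg(silage_mass = silage_mass, ef_feed_corn = ef_feed_corn)
  silage_mass * ef_feed_corn
}

#' Open-burning emissions of the straw resource, in CO2-eq
#'
#' The burned mass is straw_mass x burn_fraction x combustion factor G; per
#' gas, the burned mass times the gas's emission factor, with CH4 and N2O
#' converted to CO2-eq by their GWPs. Applies only to a conventional
#' scenario; `straw_mass` is the feed-share straw total from
#' [straw_balance()].
#'
#' @param straw_mass Straw resource subject to burning (kg/a).
#' @param burn_fraction Fraction open-burned.
#' @param combustion_factor Dimensionless burning emission factor G.
#' @param factors An [emission_factor_set()].
#' @param gwp A [gwp_set()].
#' @return A list with `co2`, `ch4`, `n2o` (CO2-eq kg/a) and their `total`.
#' @export
straw_burning_emissions <- function(straw_mass, burn_fraction,
                                    combustion_factor, factors, gwp) {
  check_nonneg(straw_mass = straw_mass, burn_fraction = burn_fraction,
               combustion_factor = combustion_factor)
  burned <- straw_mass * burn_fraction * combustion_factor
  out <- list(co2 = burned * factors$ef_burn_co2,
              ch4 = burned * factors$ef_burn_ch4 * gwp$gwp_ch4,
              n2o = burned * factors$ef_burn_n2o * gwp$gwp_n2o)
  out$total <- out$co2 + out$ch4 + out$n2o
  out
}
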