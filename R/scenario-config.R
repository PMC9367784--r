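#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% group_by summarise mutate arrange bind_rows
#' @importFrom stats quantile runif rnorm sd setNames median
#' @importFrom utils modifyList write.csv read.csv
NULL

# Canonical internal unit is kg per year for every mass; conversion to the
# reporting unit (1e7 t/a) happens only in report writers and print methods.

#' Herd description for one breeding scenario
#'
#' @param herd_size Head of cattle kept per year (head/a).
#' @param live_weight Average live weight (kg); the IPCC default for beef
#'   cattle in this system is 319 kg.
#' @param fattening_days Days in one fattening cycle (d/a); 365 for a
#'   year-round intensive system.
#' @param enteric_ef Tier-1 enteric-fermentation CH4 factor
#'   (kg CH4/head/a).
#' @param n_excretion_rate Default N excretion rate per 1000 kg live mass
#'   (kg N/(1000 kg)/d).
#' @param manure_per_head_day Manure (dung + urine) excreted per head
#'   (kg/d); 22.0 kg/d gives the 8030 kg annual per-head mass used by the
#'   as-reported manure-application pathway.
#' @return A list of class `herd_spec`.
#' @export
herd_spec <- function(herd_size = 1e7, live_weight = 319, fattening_days = 365,
                      enteric_ef = 65, n_excretion_rate = 0.41,
                      manure_per_head_day = 22.0) {
  structure(
    list(herd_size = herd_size, live_weight = live_weight,
         fattening_days = fattening_days, enteric_ef = enteric_ef,
         n_excretion_rate = n_excretion_rate,
         manure_per_head_day = manure_per_head_day),
    class = "herd_spec")
}

#' Feed-crop planting description for one breeding scenario
#'
#' @param feed_intake_per_head_day Roughage corn intake (kg/head/d): whole-plant
#'   silage corn in the ecological-cycle system, common corn in the
#'   conventional one.
#' @param planting_area Corn planting area (hm2).
#' @param fertilizer_application_rate Total chemical fertilizer applied per
#'   unit area (kg/hm2/a).
#' @param n_fertilizer_share Share of applied fertilizer that is straight N
#'   fertilizer (fraction).
#' @param compound_fertilizer_share Share that is compound fertilizer
#'   (fraction).
#' @param compound_n_content N mass content of compound fertilizer (fraction).
#' @param straw_feed_fraction Fraction of the regional corn straw resource
#'   used as feed.
#' @param straw_burn_fraction Fraction open-burned (household burning plus
#'   waste incineration); 0 in an ecological-cycle scenario.
#' @param is_silage Whether the roughage is whole-plant silage corn.
#' @return A list of class `planting_spec`.
#' @export
planting_spec <- function(feed_intake_per_head_day, planting_area,
                          fertilizer_application_rate = 679.33,
                          n_fertilizer_share = 0.3105,
                          compound_fertilizer_share = 0.5363,
                          compound_n_content = 0.2841,
                          straw_feed_fraction = 1.0,
                          straw_burn_fraction = 0.0,
                          is_silage = FALSE) {
  structure(
    list(feed_intake_per_head_day = feed_intake_per_head_day,
         planting_area = planting_area,
         fertilizer_application_rate = fertilizer_application_rate,
         n_fertilizer_share = n_fertilizer_share,
         compound_fertilizer_share = compound_fertilizer_share,
         compound_n_content = compound_n_content,
         straw_feed_fraction = straw_feed_fraction,
         straw_burn_fraction = straw_burn_fraction,
         is_silage = is_silage),
    class = "planting_spec")
}

#' Manure handling description for one breeding scenario
#'
#' @param return_rate Fraction of manure entering the planting system as
#'   fertilizer (1.0 with full field return, 0.45 under conventional
#'   composting/discharge).
#' @param vs_rate Volatile-solids excretion rate (kg VS/(1000 kg live mass)/d).
#' @param ms_fraction Fraction of annual VS (and N) handled in the managed
#'   manure system.
#' @param mm_ch4_ef Manure-management CH4 factor (kg CH4/kg VS).
#' @param mm_n2o_direct_ef Direct manure-management N2O factor
#'   (kg N2O-N/kg N).
#' @param f_gas Fraction of managed manure N volatilized as NH3-N/NOx-N.
#' @param f_leach Fraction of managed manure N lost to leaching and runoff.
#' @return A list of class `manure_spec`.
#' @export
manure_spec <- function(return_rate, vs_rate, ms_fraction, mm_ch4_ef,
                        mm_n2o_direct_ef, f_gas, f_leach) {
  structure(
    list(return_rate = return_rate, vs_rate = vs_rate,
         ms_fraction = ms_fraction, mm_ch4_ef = mm_ch4_ef,
         mm_n2o_direct_ef = mm_n2o_direct_ef, f_gas = f_gas,
         f_leach = f_leach),
    class = "manure_spec")
}

#' Emission factors and loss fractions shared by both scenarios
#'
#' Defaults are the coefficient set of the reference parameterization
#' (IPCC-2019-refinement style factors plus regional straw/fertilizer
#' coefficients).
#'
#' @param ef_farm_corn CO2 from growing corn feed grain (t CO2/t corn).
#' @param ef_feed_corn CO2 from processing silage into feed (t CO2/t silage).
#' @param ef_n_direct Direct soil N2O factor for applied N (t N2O-N/t N);
#'   used for both chemical fertilizer and applied manure N.
#' @param ef_n_vol_indirect Indirect N2O factor for atmospheric re-deposition
#'   of volatilized N (t N2O-N/t N).
#' @param ef_n_leach_indirect Indirect N2O factor for leached/runoff N
#'   (t N2O-N/t N).
#' @param f_gas_fert Volatilized fraction of applied fertilizer N.
#' @param f_gas_manure Volatilized fraction of field-applied manure N.
#' @param f_leach_soil Leached fraction of applied N (fertilizer and manure).
#' @param burn_combustion_factor Dimensionless open-burning emission factor G.
#' @param ef_burn_co2,ef_burn_ch4,ef_burn_n2o Gas emitted per kg of straw
#'   actually combusted (kg gas/kg straw).
#' @param ef_mm_idn_vol Indirect manure-management N2O factor for volatilized
#'   N (kg N2O-N/kg N).
#' @param ef_mm_idn_leach Indirect manure-management N2O factor for leached N
#'   (kg N2O-N/kg N).
#' @return A list of class `emission_factor_set`.
#' @export
emission_factor_set <- function(ef_farm_corn = 1.50, ef_feed_corn = 0.0102,
                                ef_n_direct = 0.0105,
                                ef_n_vol_indirect = 0.01,
                                ef_n_leach_indirect = 0.0075,
                                f_gas_fert = 0.1, f_gas_manure = 0.2,
                                f_leach_soil = 0.25,
                                burn_combustion_factor = 0.1,
                                ef_burn_co2 = 1.39, ef_burn_ch4 = 2.19e-3,
                                ef_burn_n2o = 7e-5,
                                ef_mm_idn_vol = 0.010,
                                ef_mm_idn_leach = 0.011) {
  structure(
    list(ef_farm_corn = ef_farm_corn, ef_feed_corn = ef_feed_corn,
         ef_n_direct = ef_n_direct, ef_n_vol_indirect = ef_n_vol_indirect,
         ef_n_leach_indirect = ef_n_leach_indirect,
         f_gas_fert = f_gas_fert, f_gas_manure = f_gas_manure,
         f_leach_soil = f_leach_soil,
         burn_combustion_factor = burn_combustion_factor,
         ef_burn_co2 = ef_burn_co2, ef_burn_ch4 = ef_burn_ch4,
         ef_burn_n2o = ef_burn_n2o, ef_mm_idn_vol = ef_mm_idn_vol,
         ef_mm_idn_leach = ef_mm_idn_leach),
    class = "emission_factor_set")
}

#' 100-year global-warming potentials
#'
#' @param gwp_ch4 CO2-eq per unit CH4 (AR5 value 28).
#' @param gwp_n2o CO2-eq per unit N2O (AR5 value 265).
#' @param gwp_n2o_manure_application CO2-eq per unit N2O used only by the
#'   as-reported (replication-mode) manure-application pathway, where the
#'   reference results are reproducible only with the AR6 value 273.
#' @return A list of class `gwp_set`.
#' @export
gwp_set <- function(gwp_ch4 = 28, gwp_n2o = 265,
                    gwp_n2o_manure_application = 273) {
  structure(
    list(gwp_ch4 = gwp_ch4, gwp_n2o = gwp_n2o,
         gwp_n2o_manure_application = gwp_n2o_manure_application),
    class = "gwp_set")
}

#' Assemble a breeding-model scenario
#'
#' A scenario is the unit of analysis: one breeding model (ecological-cycle
#' `"EC"` or conventional `"non-EC"`) with its herd, planting, manure and
#' coefficient blocks. Structural rules follow the two system boundaries:
#' an EC scenario burns no straw and includes a silage feed-production
#' process; a non-EC scenario burns straw and has no feed-production process.
#'
#' @param name Scenario label.
#' @param model_kind `"EC"` or `"non-EC"`.
#' @param herd A [herd_spec()].
#' @param planting A [planting_spec()].
#' @param manure A [manure_spec()].
#' @param factors An [emission_factor_set()].
#' @param gwp A [gwp_set()].
#' @param overrides Optional named list of as-reported per-process
#'   CO2-eq overrides (kg/a), keyed by process id; applied only in
#'   replication mode.
#' @param validate Validate invariants (default TRUE).
#' @return A list of class `ghg_scenario`.
#' @export
scenario_spec <- function(name, model_kind = c("EC", "non-EC"), herd, planting,
                          manure, factors = emission_factor_set(),
                          gwp = gwp_set(), overrides = list(),
                          validate = TRUE) {
  model_kind <- match.arg(model_kind)
  spec <- structure(
    list(name = name, model_kind = model_kind, herd = herd,
         planting = planting, manure = manure, factors = factors, gwp = gwp,
         overrides = overrides),
    class = "ghg_scenario")
  if (validate) validate_scenario(spec)
  spec
}

process_ids <- function() {
  c("corn_planting", "n_fertilizer", "manure_application", "feed_production",
    "straw_burning", "enteric_fermentation", "manure_management")
}

#' Validate a scenario against its invariants
#'
#' Checks sign and range constraints on every block and the structural
#' constraints tied to the model kind. All violations are collected and
#' reported together.
#'
#' @param spec A `ghg_scenario`.
#' @return Invisibly `TRUE`; errors with the full violation list otherwise.
#' @export
validate_scenario <- function(spec) {
  v <- scenario_violations(spec)
  if (length(v) > 0) {
    stop("invalid scenario '", spec$name, "':\n  - ",
         paste(v, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

#' List invariant violations of a scenario without erroring
#'
#' @param spec A `ghg_scenario`.
#' @return Character vector of violation messages (empty if valid).
#' @export
scenario_violations <- function(spec) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

  for (f in names(spec$herd)) {
    chk(num(spec$herd[[f]]) && spec$herd[[f]] >= 0,
        paste0("herd.", f, " must be a non-negative number"))
  }
  p <- spec$planting
  for (f in setdiff(names(p), "is_silage")) {
    chk(num(p[[f]]) && p[[f]] >= 0,
        paste0("planting.", f, " must be a non-negative number"))
  }
  fracs <- c("n_fertilizer_share", "compound_fertilizer_share",
             "compound_n_content", "straw_feed_fraction",
             "straw_burn_fraction")
  for (f in fracs) {
    chk(num(p[[f]]) && p[[f]] <= 1, paste0("planting.", f, " must be <= 1"))
  }
  if (num(p$straw_feed_fraction) && num(p$straw_burn_fraction)) {
    chk(p$straw_feed_fraction + p$straw_burn_fraction <= 1 + 1e-9,
        "planting straw fractions must sum to at most 1")
  }
  m <- spec$manure
  for (f in names(m)) {
    chk(num(m[[f]]) && m[[f]] >= 0,
        paste0("manure.", f, " must be a non-negative number"))
  }
  for (f in c("return_rate", "ms_fraction", "f_gas", "f_leach")) {
    chk(num(m[[f]]) && m[[f]] <= 1, paste0("manure.", f, " must be <= 1"))
  }
  for (f in names(spec$factors)) {
    chk(num(spec$factors[[f]]) && spec$factors[[f]] >= 0,
        paste0("factors.", f, " must be a non-negative number"))
  }
  for (f in names(spec$gwp)) {
    chk(num(spec$gwp[[f]]) && spec$gwp[[f]] > 0,
        paste0("gwp.", f, " must be a positive number"))
  }
  if (spec$model_kind == "EC") {
    chk(isTRUE(p$straw_burn_fraction == 0),
        "EC scenario must have planting.straw_burn_fraction = 0")
  } else {
    chk(num(p$straw_burn_fraction) && p$straw_burn_fraction > 0,
        "non-EC scenario must have planting.straw_burn_fraction > 0")
  }
  if (length(spec$overrides) > 0) {
    chk(!is.null(names(spec$overrides)) && all(nzchar(names(spec$overrides))),
        "overrides must be a named list keyed by process id")
    bad <- setdiff(names(spec$overrides), process_ids())
    chk(length(bad) == 0,
        paste0("unknown override process id: ", paste(bad, collapse = ", ")))
  }
  v
}

block_builders <- function() {
  list(herd = herd_spec, planting = planting_spec, manure = manure_spec,
       factors = emission_factor_set, gwp = gwp_set)
}

#' Load a scenario from a YAML (or JSON) configuration file
#'
#' Keys are snake_case and mirror the constructor arguments; omitted
#' `factors` and `gwp` entries are filled with their defaults. Unknown keys
#' are a format error naming the offending key; invariant violations are
#' collected and reported together. A machine-readable schema of the file
#' layout ships as `inst/extdata/scenario-schema.json`.
#'
#' @param path Path to a scenario file.
#' @return A validated `ghg_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop("cannot parse scenario file '", path,
                                      "': ", conditionMessage(e),
                                      call. = FALSE))
  }
  scenario_from_list(raw, where = path)
}

scenario_from_list <- function(raw, where = "config") {
  if (!is.list(raw)) stop("scenario config must be a key-value mapping: ",
                          where, call. = FALSE)
  top_known <- c("name", "model_kind", "herd", "planting", "manure",
                 "factors", "gwp", "overrides")
  bad <- setdiff(names(raw), top_known)
  if (length(bad) > 0) {
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (req in c("name", "model_kind", "herd", "planting", "manure")) {
    if (is.null(raw[[req]])) {
      stop("missing required key '", req, "' in ", where, call. = FALSE)
    }
  }
  builders <- block_builders()
  blocks <- list()
  for (b in names(builders)) {
    given <- raw[[b]]
    if (is.null(given)) given <- list()
    known <- names(formals(builders[[b]]))
    bad <- setdiff(names(given), known)
    if (length(bad) > 0) {
      stop("unknown key(s) under '", b, "' in ", where, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    # YAML reads whole numbers as integers; the canonical type is double
    given <- lapply(given, function(x) if (is.integer(x)) as.double(x) else x)
    blocks[[b]] <- do.call(builders[[b]], given)
  }
  ov <- raw$overrides
  if (is.null(ov)) ov <- list()
  scenario_spec(name = raw$name, model_kind = raw$model_kind,
                herd = blocks$herd, planting = blocks$planting,
                manure = blocks$manure, factors = blocks$factors,
                gwp = blocks$gwp, overrides = lapply(ov, as.numeric))
}

#' Write a scenario to a YAML configuration file
#'
#' Numbers are serialized at full double precision so that a write-then-load
#' round trip reproduces the scenario exactly.
#'
#' @param spec A `ghg_scenario`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_scenario <- function(spec, path) {
  x <- list(name = spec$name, model_kind = spec$model_kind,
            herd = unclass(spec$herd), planting = unclass(spec$planting),
            manure = unclass(spec$manure), factors = unclass(spec$factors),
            gwp = unclass(spec$gwp))
  if (length(spec$overrides) > 0) x$overrides <- spec$overrides
  # shortest decimal representation that round-trips the double exactly
  num_handler <- function(n) {
    if (n == round(n) && abs(n) < 2^53) {
      return(structure(sprintf("%.0f", n), class = "verbatim"))
    }
    for (d in 15:17) {
      s <- sprintf("%.*g", d, n)
      if (as.numeric(s) == n) break
    }
    # YAML 1.1 only reads exponent notation with a dotted mantissa
    if (grepl("e", s, fixed = TRUE) &&
          !grepl(".", sub("e.*$", "", s), fixed = TRUE)) {
      s <- sub("e", ".0e", s, fixed = TRUE)
    }
    structure(s, class = "verbatim")
  }
  yaml::write_yaml(x, path, handlers = list(numeric = num_handler))
  invisible(path)
}

#' The two reference scenarios
#'
#' Returns the fully parameterized ecological-cycle and conventional
#' scenarios for the 10-million-head corn-belt beef system: silage corn at
#' 20 kg/head/d with 100% manure field return and no straw burning (EC)
#' versus common corn at 9 kg/head/d with 45% manure return and 85.75% of
#' the straw resource open-burned (non-EC). The EC scenario carries one
#' as-reported override: its N-fertilizer N2O process is pinned to
#' 2.1e9 kg CO2-eq/a in replication mode because the reported value is not
#' derivable from the coefficient set (the recomputed value, used in
#' corrected mode, is about 1.58e9 kg/a).
#'
#' @return Named list with elements `ec` and `nonec`, each a `ghg_scenario`.
#' @export
reference_scenarios <- function() {
  herd <- herd_spec(herd_size = 1e7, live_weight = 319, fattening_days = 365,
                    enteric_ef = 65, n_excretion_rate = 0.41,
                    manure_per_head_day = 22.0)
  ec <- scenario_spec(
    name = "ec_reference", model_kind = "EC", herd = herd,
    planting = planting_spec(
      feed_intake_per_head_day = 20, planting_area = 9.01e5,
      straw_feed_fraction = 1.0, straw_burn_fraction = 0.0,
      is_silage = TRUE),
    manure = manure_spec(return_rate = 1.00, vs_rate = 6.8,
                         ms_fraction = 0.28, mm_ch4_ef = 1.05,
                         mm_n2o_direct_ef = 0.005, f_gas = 0.30,
                         f_leach = 0.035),
    overrides = list(n_fertilizer = 2.1e9))
  nonec <- scenario_spec(
    name = "nonec_reference", model_kind = "non-EC", herd = herd,
    planting = planting_spec(
      feed_intake_per_head_day = 9, planting_area = 70.66e5,
      straw_feed_fraction = 0.0988, straw_burn_fraction = 0.8575,
      is_silage = FALSE),
    manure = manure_spec(return_rate = 0.45, vs_rate = 10.8,
                         ms_fraction = 0.29, mm_ch4_ef = 2.05,
                         mm_n2o_direct_ef = 0.01, f_gas = 0.45,
                         f_leach = 0.02))
  list(ec = ec, nonec = nonec)
}

#' Glossary mapping conventional parameter symbols to scenario fields
#'
#' One row per coefficient of the reference parameterization, linking the
#' symbol used in IPCC-style inventory notation to the dot-addressed
#' scenario field holding it (fields shared by both scenarios map once).
#'
#' @return A tibble with columns `symbol`, `field`, `unit`.
#' @export
parameter_glossary <- function() {
  tibble::tribble(
    ~symbol,               ~field,                                    ~unit,
    "Na",                  "herd.herd_size",                          "head/a",
    "Wdefault",            "herd.live_weight",                        "kg",
    "efEF",                "herd.enteric_ef",                         "kg/head/a",
    "Nrate",               "herd.n_excretion_rate",                   "kg/(1000 kg)/d",
    "QF",                  "herd.manure_per_head_day",                "kg/d",
    "Qi",                  "planting.feed_intake_per_head_day",       "kg/head/d",
    "Tfat",                "herd.fattening_days",                     "d/a",
    "A",                   "planting.planting_area",                  "hm2",
    "Rreturn",             "manure.return_rate",                      "1",
    "QSN",                 "planting.fertilizer_application_rate",    "kg/hm2/a",
    "RNF",                 "planting.n_fertilizer_share",             "1",
    "RCF",                 "planting.compound_fertilizer_share",      "1",
    "wc",                  "planting.compound_n_content",             "1",
    "Rfeed",               "planting.straw_feed_fraction",            "1",
    "Rburn",               "planting.straw_burn_fraction",            "1",
    "VSrate",              "manure.vs_rate",                          "kg/(1000 kg)/d",
    "MS",                  "manure.ms_fraction",                      "1",
    "efMMC",               "manure.mm_ch4_ef",                        "kg/kg",
    "efMMDN",              "manure.mm_n2o_direct_ef",                 "kg/kg",
    "FGAS_mm",             "manure.f_gas",                            "1",
    "FLEACH_mm",           "manure.f_leach",                          "1",
    "effarm-corn",         "factors.ef_farm_corn",                    "t/t",
    "effeed-corn",         "factors.ef_feed_corn",                    "t/t",
    "efND",                "factors.ef_n_direct",                     "t/t",
    "efNH",                "factors.ef_n_vol_indirect",               "t/t",
    "efNL",                "factors.ef_n_leach_indirect",             "t/t",
    "FGAS",                "factors.f_gas_fert",                      "1",
    "FGASM",               "factors.f_gas_manure",                    "1",
    "FL",                  "factors.f_leach_soil",                    "1",
    "G",                   "factors.burn_combustion_factor",          "1",
    "efburn-CO2",          "factors.ef_burn_co2",                     "kg/kg",
    "efburn-CH4",          "factors.ef_burn_ch4",                     "kg/kg",
    "efburn-N2O",          "factors.ef_burn_n2o",                     "kg/kg",
    "efMMIDN-volatilize",  "factors.ef_mm_idn_vol",                   "kg/kg",
    "efMMIDN-leach",       "factors.ef_mm_idn_leach",                 "kg/kg",
    "GWPCH4",              "gwp.gwp_ch4",                             "1",
    "GWPN2O",              "gwp.gwp_n2o",                             "1")
}

#' @export
print.ghg_scenario <- function(x, ...) {
  cat("<ghg_scenario> ", x$name, " [", x$model_kind, "]\n", sep = "")
  cat("  herd: ", format(x$herd$herd_size, big.mark = ","),
      " head x ", x$herd$live_weight, " kg, enteric EF ",
      x$herd$enteric_ef, " kg CH4/head/a\n", sep = "")
  cat("  feed: ", x$planting$feed_intake_per_head_day, " kg/head/d (",
      if (isTRUE(x$planting$is_silage)) "silage" else "common corn",
      "), area ", format(x$planting$planting_area, big.mark = ","),
      " hm2\n", sep = "")
  cat("  manure return ", x$manure$return_rate * 100, "%, straw burned ",
      x$planting$straw_burn_fraction * 100, "%\n", sep = "")
  if (length(x$overrides) > 0) {
    cat("  as-reported overrides:", paste(names(x$overrides), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# dot-path access used by sensitivity and Monte-Carlo machinery
scenario_get <- function(spec, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- spec
  for (p in parts) {
    if (is.null(x[[p]])) stop("unknown parameter path: ", path, call. = FALSE)
    x <- x[[p]]
  }
  x
}

scenario_set <- function(spec, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    if (is.null(spec[[parts]])) stop("unknown parameter path: ", path,
                                     call. = FALSE)
    spec[[parts]] <- value
    return(spec)
  }
  if (is.null(spec[[parts[1]]]) || is.null(spec[[parts[1]]][[parts[2]]])) {
    stop("unknown parameter path: ", path, call. = FALSE)
  }
  spec[[parts[1]]][[parts[2]]] <- value
  spec
}
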