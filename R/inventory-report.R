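# display rounding: half-away-from-zero, as inventory tables are printed
round_display <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

KG_PER_1E7_T <- 1e10

#' Silage feed-production CO2 for a scenario
#'
#' Structural wrapper around [feed_production_co2()]: the feed-production
#' process exists only in an ecological-cycle scenario.
#'
#' @param spec A `ghg_scenario` of kind `"EC"`.
#' @return CO2 (kg/a).
#' @export
scenario_feed_production_co2 <- function(spec) {
  if (spec$model_kind != "EC") {
    stop("feed production is not a process of a non-EC scenario", call. = FALSE)
  }
  silage <- annual_feed_demand(spec$planting$feed_intake_per_head_day,
                               spec$herd$herd_size, spec$herd$fattening_days)
  feed_production_co2(silage, spec$factors$ef_feed_corn)
}

#' Straw-burning emissions for a scenario
#'
#' Structural wrapper around [straw_burning_emissions()]: open burning
#' exists only in a non-ecological-cycle scenario. The activity mass is the
#' feed-share straw total of the scenario's [straw_balance()].
#'
#' @param spec A `ghg_scenario` of kind `"non-EC"`.
#' @return A list with `co2`, `ch4`, `n2o`, `total` (CO2-eq kg/a).
#' @export
scenario_straw_burning <- function(spec) {
  if (spec$model_kind != "non-EC") {
    stop("straw burning is not a process of an EC scenario", call. = FALSE)
  }
  feed <- annual_feed_demand(spec$planting$feed_intake_per_head_day,
                             spec$herd$herd_size, spec$herd$fattening_days)
  bal <- straw_balance(feed, spec$planting$straw_feed_fraction,
                       spec$planting$straw_burn_fraction)
  straw_burning_emissions(bal$total_straw_feed_share,
                          spec$planting$straw_burn_fraction,
                          spec$factors$burn_combustion_factor,
                          spec$factors, spec$gwp)
}

#' Build the full process-by-gas emission inventory of a scenario
#'
#' Runs every process applicable to the scenario's model kind (an EC
#' scenario has feed production and no straw burning; a non-EC scenario the
#' reverse) and assembles one CO2-eq record per (process, gas) pair.
#' In `"replication"` mode any as-reported process overrides carried by the
#' scenario replace the recomputed value (flagged in the output), and the
#' manure-application pathway uses its as-reported per-head basis and GWP;
#' `"corrected"` mode ignores overrides and applies the factor set
#' uniformly.
#'
#' @param spec A `ghg_scenario`.
#' @param mode `"replication"` or `"corrected"`.
#' @return A list of class `inventory_report`: `scenario`, `model_kind`,
#'   `mode`, `emissions` (tibble: process, gas, industry, co2eq_kg,
#'   override), `total_kg`.
#' @examples
#' inv <- build_inventory(reference_scenarios()$ec)
#' inv$total_kg / 1e10  # total in 1e7 t CO2-eq/a
#' @export
build_inventory <- function(spec, mode = c("replication", "corrected")) {
  mode <- match.arg(mode)
  validate_scenario(spec)
  h <- spec$herd; p <- spec$planting; m <- spec$manure
  f <- spec$factors; g <- spec$gwp

  feed <- annual_feed_demand(p$feed_intake_per_head_day, h$herd_size,
                             h$fattening_days)
  rows <- list()
  add <- function(process, gas, industry, co2eq) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      process = process, gas = gas, industry = industry, co2eq_kg = co2eq,
      override = FALSE)
  }

  # planting industry
  if (spec$model_kind == "EC") {
    corn_mass <- feed
  } else {
    corn_mass <- straw_balance(feed, p$straw_feed_fraction,
                               p$straw_burn_fraction)$total_straw_normalized
  }
  add("corn_planting", "CO2", "planting",
      corn_planting_co2(corn_mass, f$ef_farm_corn))

  n_in <- fertilizer_nitrogen_input(p$planting_area,
                                    p$fertilizer_application_rate,
                                    p$n_fertilizer_share,
                                    p$compound_fertilizer_share,
                                    p$compound_n_content)
  add("n_fertilizer", "N2O", "planting",
      soil_n2o(n_in, f$ef_n_direct, f$ef_n_vol_indirect, f$f_gas_fert,
               f$ef_n_leach_indirect, f$f_leach_soil, g$gwp_n2o))

  add("manure_application", "N2O", "planting",
      manure_application_n2o(spec, mode))

  if (spec$model_kind == "EC") {
    add("feed_production", "CO2", "planting",
        scenario_feed_production_co2(spec))
  } else {
    burn <- scenario_straw_burning(spec)
    add("straw_burning", "CO2", "planting", burn$co2)
    add("straw_burning", "CH4", "planting", burn$ch4)
    add("straw_burning", "N2O", "planting", burn$n2o)
  }

  # breeding industry
  add("enteric_fermentation", "CH4", "breeding",
      enteric_ch4(h$herd_size, h$enteric_ef, g$gwp_ch4))
  vs <- volatile_solids_annual(m$vs_rate, h$live_weight)
  add("manure_management", "CH4", "breeding",
      manure_mgmt_ch4(h$herd_size, vs, m$ms_fraction, m$mm_ch4_ef, g$gwp_ch4))
  nex <- n_excretion_annual(h$n_excretion_rate, h$live_weight)
  add("manure_management", "N2O", "breeding",
      manure_mgmt_n2o(h$herd_size, nex, m, f, g$gwp_n2o)$total)

  emissions <- dplyr::bind_rows(rows)

  if (mode == "replication" && length(spec$overrides) > 0) {
    for (pid in names(spec$overrides)) {
      idx <- which(emissions$process == pid)
      if (length(idx) == 0) next  # override for a process absent in this kind
      if (length(idx) > 1) {
        stop("override for multi-gas process '", pid, "' is ambiguous",
             call. = FALSE)
      }
      emissions$co2eq_kg[idx] <- spec$overrides[[pid]]
      emissions$override[idx] <- TRUE
    }
  }

  structure(
    list(scenario = spec$name, model_kind = spec$model_kind, mode = mode,
         emissions = emissions, total_kg = sum(emissions$co2eq_kg)),
    class = "inventory_report")
}

#' Per-process table of an inventory with shares
#'
#' @param report An `inventory_report`.
#' @return Tibble: industry, process, gas, co2eq_kg, co2eq_1e7_t (display
#'   rounded), share, override.
#' @export
process_table <- function(report) {
  e <- report$emissions
  total <- report$total_kg
  dplyr::mutate(e,
                co2eq_1e7_t = round_display(.data$co2eq_kg / KG_PER_1E7_T),
                share = if (total > 0) .data$co2eq_kg / total else 0)[
    , c("industry", "process", "gas", "co2eq_kg", "co2eq_1e7_t", "share",
        "override")]
}

#' Per-gas totals of an inventory with shares
#'
#' Regroups the same process entries by gas; by construction the gas totals
#' re-partition the inventory total exactly.
#'
#' @param report An `inventory_report`.
#' @return Tibble: gas, co2eq_kg, co2eq_1e7_t, share.
#' @export
gas_totals <- function(report) {
  total <- report$total_kg
  out <- report$emissions %>%
    dplyr::group_by(.data$gas) %>%
    dplyr::summarise(co2eq_kg = sum(.data$co2eq_kg), .groups = "drop") %>%
    dplyr::arrange(match(.data$gas, c("CO2", "CH4", "N2O")))
  dplyr::mutate(out,
                co2eq_1e7_t = round_display(.data$co2eq_kg / KG_PER_1E7_T),
                share = if (total > 0) .data$co2eq_kg / total else 0)
}

#' Per-industry subtotals of an inventory with shares
#'
#' @param report An `inventory_report`.
#' @return Tibble: industry, co2eq_kg, co2eq_1e7_t, share.
#' @export
industry_totals <- function(report) {
  total <- report$total_kg
  out <- report$emissions %>%
    dplyr::group_by(.data$industry) %>%
    dplyr::summarise(co2eq_kg = sum(.data$co2eq_kg), .groups = "drop") %>%
    dplyr::arrange(match(.data$industry, c("planting", "breeding")))
  dplyr::mutate(out,
                co2eq_1e7_t = round_display(.data$co2eq_kg / KG_PER_1E7_T),
                share = if (total > 0) .data$co2eq_kg / total else 0)
}

#' Compare two inventories (reduction table)
#'
#' Differences are `b - a` elementwise (conventionally: conventional model
#' minus ecological-cycle model, so positive values are the reduction the
#' EC system achieves). Processes absent from one scenario count as zero
#' there; negative differences (EC emits more, e.g. feed production) are
#' reported signed.
#'
#' @param a,b `inventory_report` objects built in the same mode.
#' @return A list of class `inventory_comparison`: `process` (tibble of
#'   per-process-gas differences), `gas` (per-gas differences), `total_kg`.
#' @export
compare_inventories <- function(a, b) {
  if (a$mode != b$mode) {
    stop("cannot compare inventories built in different modes: ",
         a$mode, " vs ", b$mode, call. = FALSE)
  }
  key <- function(e) paste(e$process, e$gas, sep = ":")
  ea <- a$emissions; eb <- b$emissions
  keys <- union(key(ea), key(eb))
  lookup <- function(e, k) {
    i <- match(k, key(e))
    ifelse(is.na(i), 0, e$co2eq_kg[i])
  }
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  ind <- ifelse(parts[, 1] %in% c("enteric_fermentation", "manure_management"),
                "breeding", "planting")
  proc <- tibble::tibble(
    industry = ind, process = parts[, 1], gas = parts[, 2],
    a_kg = lookup(ea, keys), b_kg = lookup(eb, keys)) %>%
    dplyr::mutate(diff_kg = .data$b_kg - .data$a_kg,
                  diff_1e7_t = round_display(.data$diff_kg / KG_PER_1E7_T)) %>%
    dplyr::arrange(match(.data$process, process_ids()),
                   match(.data$gas, c("CO2", "CH4", "N2O")))
  gas <- proc %>%
    dplyr::group_by(.data$gas) %>%
    dplyr::summarise(a_kg = sum(.data$a_kg), b_kg = sum(.data$b_kg),
                     diff_kg = sum(.data$diff_kg), .groups = "drop") %>%
    dplyr::mutate(diff_1e7_t = round_display(.data$diff_kg / KG_PER_1E7_T)) %>%
    dplyr::arrange(match(.data$gas, c("CO2", "CH4", "N2O")))
  structure(
    list(a = a$scenario, b = b$scenario, mode = a$mode, process = proc,
         gas = gas, total_kg = b$total_kg - a$total_kg),
    class = "inventory_comparison")
}

#' Write an inventory report to CSV or JSON
#'
#' CSV emits the process table and the gas/industry subtotal rows in one
#' flat file: a `section` column distinguishes `process`, `gas`, `industry`
#' and `total` rows; display values are in 1e7 t/a rounded to 2 decimals
#' alongside full-precision kg/a, with scenario/mode metadata on every row.
#' JSON serializes the report so that [read_report()] round-trips to an
#' equal object.
#'
#' @param report An `inventory_report`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- list(scenario = report$scenario, model_kind = report$model_kind,
              mode = report$mode,
              emissions = as.data.frame(report$emissions),
              total_kg = report$total_kg)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  pt <- process_table(report)
  gt <- gas_totals(report)
  it <- industry_totals(report)
  rows <- rbind(
    data.frame(section = "process", industry = pt$industry,
               process = pt$process, gas = pt$gas, co2eq_kg = pt$co2eq_kg,
               co2eq_1e7_t = pt$co2eq_1e7_t, share = pt$share,
               override = pt$override),
    data.frame(section = "gas", industry = "", process = "", gas = gt$gas,
               co2eq_kg = gt$co2eq_kg, co2eq_1e7_t = gt$co2eq_1e7_t,
               share = gt$share, override = FALSE),
    data.frame(section = "industry", industry = it$industry, process = "",
               gas = "", co2eq_kg = it$co2eq_kg,
               co2eq_1e7_t = it$co2eq_1e7_t, share = it$share,
               override = FALSE),
    data.frame(section = "total", industry = "", process = "", gas = "",
               co2eq_kg = report$total_kg,
               co2eq_1e7_t = round_display(report$total_kg / KG_PER_1E7_T),
               share = 1, override = FALSE))
  rows$scenario <- report$scenario
  rows$mode <- report$mode
  ok <- tryCatch({
    write.csv(rows, path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write report to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read a JSON inventory report written by [write_report()]
#'
#' @param path Path to a JSON report.
#' @return An `inventory_report` equal to the one written.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(scenario = x$scenario, model_kind = x$model_kind, mode = x$mode,
         emissions = tibble::as_tibble(x$emissions),
         total_kg = x$total_kg),
    class = "inventory_report")
}

#' @export
print.inventory_report <- function(x, ...) {
  cat("<inventory_report> ", x$scenario, " [", x$model_kind, ", ",
      x$mode, " mode]\n", sep = "")
  pt <- process_table(x)
  df <- data.frame(
    process = paste0(pt$process, ifelse(pt$override, "*", "")),
    gas = pt$gas,
    `CO2eq_1e7_t` = sprintf("%.2f", pt$co2eq_1e7_t),
    share = sprintf("%.2f%%", 100 * pt$share))
  print(df, row.names = FALSE)
  cat(sprintf("total: %.2f x 1e7 t CO2-eq/a\n", x$total_kg / KG_PER_1E7_T))
  if (any(pt$override)) cat("(* as-reported override applied)\n")
  invisible(x)
}

#' @export
print.inventory_comparison <- function(x, ...) {
  cat("<inventory_comparison> ", x$b, " - ", x$a, " [", x$mode, " mode]\n",
      sep = "")
  df <- data.frame(process = x$process$process, gas = x$process$gas,
                   diff_1e7_t = sprintf("%.2f", x$process$diff_1e7_t))
  print(df, row.names = FALSE)
  cat(sprintf("total difference: %.2f x 1e7 t CO2-eq/a\n",
              x$total_kg / KG_PER_1E7_T))
  invisible(x)
}
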