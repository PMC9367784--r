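# fields that are fractions: Monte-Carlo draws are truncated to [0, 1] here
FRACTION_FIELDS <- c(
  "planting.n_fertilizer_share", "planting.compound_fertilizer_share",
  "planting.compound_n_content", "planting.straw_feed_fraction",
  "planting.straw_burn_fraction", "manure.return_rate", "manure.ms_fraction",
  "manure.f_gas", "manure.f_leach", "factors.f_gas_fert",
  "factors.f_gas_manure", "factors.f_leach_soil")

#' Extract one scalar output from an inventory report
#'
#' @param report An `inventory_report`.
#' @param output `"total"`, a gas name (`"CO2"`, `"CH4"`, `"N2O"`), an
#'   industry (`"planting"`, `"breeding"`), or a process id (summed over
#'   its gases).
#' @return CO2-eq (kg/a).
#' @export
inventory_output <- function(report, output = "total") {
  e <- report$emissions
  if (output == "total") return(report$total_kg)
  if (output %in% c("CO2", "CH4", "N2O")) {
    return(sum(e$co2eq_kg[e$gas == output]))
  }
  if (output %in% c("planting", "breeding")) {
    return(sum(e$co2eq_kg[e$industry == output]))
  }
  if (output %in% e$process) return(sum(e$co2eq_kg[e$process == output]))
  stop("unknown output id: ", output, call. = FALSE)
}

#' One-at-a-time elasticity of an inventory output to a parameter
#'
#' Central-difference elasticity (dE/E)/(dp/p) around the scenario value:
#' the parameter is moved to (1 - delta)p and (1 + delta)p, the inventory
#' rebuilt each time, and the normalized slope returned. For an output
#' linear in the parameter the elasticity equals the parameter-driven
#' share of that output, so the inventory's own shares are a cross-check.
#'
#' @param spec A `ghg_scenario`.
#' @param parameter Dot-addressed field, e.g. `"factors.ef_farm_corn"`.
#' @param relative_delta Relative perturbation in (0, 0.5].
#' @param output Output id as in [inventory_output()].
#' @param mode Inventory mode.
#' @return Dimensionless elasticity.
#' @examples
#' oat_elasticity(reference_scenarios()$ec, "herd.enteric_ef",
#'                output = "enteric_fermentation")  # exactly 1
#' @export
oat_elasticity <- function(spec, parameter, relative_delta = 0.1,
                           output = "total",
                           mode = c("replication", "corrected")) {
  mode <- match.arg(mode)
  if (!is.numeric(relative_delta) || relative_delta <= 0 ||
        relative_delta > 0.5) {
    stop("'relative_delta' must be in (0, 0.5]", call. = FALSE)
  }
  p0 <- scenario_get(spec, parameter)
  if (!is.numeric(p0) || length(p0) != 1) {
    stop("parameter '", parameter, "' is not a scalar numeric", call. = FALSE)
  }
  if (p0 == 0) {
    stop("parameter '", parameter,
         "' is 0: a relative elasticity is undefined", call. = FALSE)
  }
  e0 <- inventory_output(build_inventory(spec, mode), output)
  if (e0 == 0) {
    stop("output '", output, "' is 0 at the scenario value: ",
         "elasticity is undefined", call. = FALSE)
  }
  build_at <- function(p) {
    s <- scenario_set(spec, parameter, p)
    inventory_output(build_inventory(s, mode), output)
  }
  e_hi <- build_at(p0 * (1 + relative_delta))
  e_lo <- build_at(p0 * (1 - relative_delta))
  ((e_hi - e_lo) / e0) / (2 * relative_delta)
}

#' Describe a parameter's uncertainty distribution
#'
#' @param path Dot-addressed scenario field.
#' @param kind `"uniform"`, `"triangular"` or `"normal"` (truncated at 0;
#'   fraction-valued fields are additionally truncated to [0, 1]).
#' @param ... Distribution parameters: `min`/`max` (uniform), `min`/`mode`/
#'   `max` (triangular), `mean`/`sd` (normal).
#' @param units Free-text unit annotation.
#' @return A list of class `param_dist`.
#' @export
param_dist <- function(path, kind = c("uniform", "triangular", "normal"), ...,
                       units = "") {
  kind <- match.arg(kind)
  args <- list(...)
  need <- switch(kind, uniform = c("min", "max"),
                 triangular = c("min", "mode", "max"),
                 normal = c("mean", "sd"))
  missing <- setdiff(need, names(args))
  if (length(missing) > 0) {
    stop(kind, " distribution for '", path, "' needs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (kind %in% c("uniform", "triangular") && args$min > args$max) {
    stop("empty interval for '", path, "': min > max", call. = FALSE)
  }
  structure(list(path = path, kind = kind, args = args[need], units = units),
            class = "param_dist")
}

sample_dist <- function(d, n) {
  a <- d$args
  x <- switch(d$kind,
    uniform = runif(n, a$min, a$max),
    triangular = {
      # inverse-CDF triangular sample
      u <- runif(n)
      fc <- if (a$max > a$min) (a$mode - a$min) / (a$max - a$min) else 0
      ifelse(u < fc,
             a$min + sqrt(u * (a$max - a$min) * (a$mode - a$min)),
             a$max - sqrt((1 - u) * (a$max - a$min) * (a$max - a$mode)))
    },
    normal = rnorm(n, a$mean, a$sd))
  x <- pmax(x, 0)
  if (d$path %in% FRACTION_FIELDS) x <- pmin(x, 1)
  x
}

#' Default perturbation set for a scenario
#'
#' A plus/minus 20 percent uniform band on every emission factor and loss
#' fraction of the coefficient set, plus the surveyed roughage-intake range
#' (8 to 10 kg/head/d) on the feed intake of a conventional scenario. GWPs
#' are left fixed by default but can be added as further [param_dist()]
#' entries.
#'
#' @param spec A `ghg_scenario`.
#' @param factor_band Half-width of the relative band on factors.
#' @return List of `param_dist`.
#' @export
default_distributions <- function(spec, factor_band = 0.2) {
  dists <- lapply(names(spec$factors), function(f) {
    v <- spec$factors[[f]]
    param_dist(paste0("factors.", f), "uniform",
               min = v * (1 - factor_band), max = v * (1 + factor_band))
  })
  if (spec$model_kind == "non-EC") {
    dists <- c(dists, list(param_dist("planting.feed_intake_per_head_day",
                                      "uniform", min = 8, max = 10,
                                      units = "kg/head/d")))
  }
  dists
}

#' Load a perturbation set from a YAML file
#'
#' The file is a list of entries with keys `path`, `kind`, the distribution
#' parameters, and optional `units` — the same config dialect as scenario
#' files.
#'
#' @param path YAML file path.
#' @return List of `param_dist`.
#' @export
load_distributions <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) {
    extra <- x[setdiff(names(x), c("path", "kind", "units"))]
    do.call(param_dist, c(list(path = x$path, kind = x$kind,
                               units = if (is.null(x$units)) "" else x$units),
                          extra))
  })
}

#' Monte-Carlo uncertainty propagation through the inventory
#'
#' Draws `n` parameter vectors from the given distributions with a seeded
#' generator (plain independent sampling, no variance-reduction, for
#' auditability), rebuilds the inventory for each draw, and summarizes the
#' total, per-gas and per-process outputs. Identical
#' (spec, dists, n, seed) inputs give an identical summary.
#'
#' @param spec A `ghg_scenario`.
#' @param dists List of [param_dist()]; default [default_distributions()].
#' @param n Number of draws (>= 1).
#' @param seed Integer RNG seed.
#' @param mode Inventory mode.
#' @param outputs Output ids to summarize (default: total, the three gases,
#'   and every process of the scenario).
#' @return A list of class `uncertainty_summary`: `summary` (tibble with
#'   mean, sd, 2.5/50/97.5 percentiles per output), `n`, `seed`, `mode`.
#' @export
monte_carlo <- function(spec, dists = default_distributions(spec), n = 1000,
                        seed = 1, mode = c("replication", "corrected"),
                        outputs = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  n <- as.integer(n)
  # resolve every path before sampling so a bad path fails fast
  for (d in dists) scenario_get(spec, d$path)
  if (is.null(outputs)) {
    base <- build_inventory(spec, mode)
    outputs <- c("total", "CO2", "CH4", "N2O", unique(base$emissions$process))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  draws <- vapply(dists, sample_dist, numeric(n), n = n)
  if (n == 1) draws <- matrix(draws, nrow = 1)

  vals <- matrix(NA_real_, nrow = n, ncol = length(outputs),
                 dimnames = list(NULL, outputs))
  for (i in seq_len(n)) {
    s <- spec
    for (j in seq_along(dists)) {
      s <- scenario_set(s, dists[[j]]$path, draws[i, j])
    }
    rep_i <- build_inventory(s, mode)
    vals[i, ] <- vapply(outputs, inventory_output, numeric(1),
                        report = rep_i)
  }
  qs <- apply(vals, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  summary <- tibble::tibble(
    output = outputs,
    mean = unname(colMeans(vals)),
    sd = unname(apply(vals, 2, sd)),
    p2.5 = unname(qs[1, ]), p50 = unname(qs[2, ]), p97.5 = unname(qs[3, ]))
  structure(list(summary = summary, n = n, seed = seed, mode = mode),
            class = "uncertainty_summary")
}

#' Write an uncertainty summary to CSV or JSON
#'
#' @param x An `uncertainty_summary`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_uncertainty <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- as.data.frame(x$summary)
    df$n <- x$n; df$seed <- x$seed; df$mode <- x$mode
    write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(summary = as.data.frame(x$summary), n = x$n, seed = x$seed,
           mode = x$mode),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @export
print.uncertainty_summary <- function(x, ...) {
  cat("<uncertainty_summary> n =", x$n, ", seed =", x$seed, ", mode =",
      x$mode, "\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
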