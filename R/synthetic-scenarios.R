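#' Sampling ranges for the synthetic-scenario generator
#'
#' Returns one closed sampling interval per scenario field. Defaults span
#' plausible intensive beef-fattening systems: herd size is sampled
#' log-uniformly over 1e4 to 1e7 head so linearity holds across scales;
#' feed-intake ranges follow the surveyed roughage band (8 to 10 kg/head/d
#' of common corn; silage systems 15 to 25 around the nominal 20); all
#' other intervals bracket the reference coefficients. A generated
#' conventional scenario keeps straw_feed_fraction + straw_burn_fraction
#' equal to the two retained straw fates (0.9563) by sampling the feed
#' share and assigning the complement to burning. With `pin = TRUE` every
#' interval collapses to the reference value, so the generator reproduces
#' the reference scenarios exactly (including the EC as-reported override).
#'
#' @param model_kind `"EC"` or `"non-EC"`.
#' @param pin Pin all intervals to the reference parameterization.
#' @return A list of class `generation_ranges`: `model_kind`, `ranges`
#'   (named list of c(lo, hi)), `log_sampled` (fields sampled on log scale),
#'   `overrides`.
#' @export
generation_ranges <- function(model_kind = c("EC", "non-EC"), pin = FALSE) {
  model_kind <- match.arg(model_kind)
  ref <- if (model_kind == "EC") reference_scenarios()$ec
         else reference_scenarios()$nonec

  if (pin) {
    fields <- c(
      paste0("herd.", names(ref$herd)),
      paste0("planting.", setdiff(names(ref$planting), "is_silage")),
      paste0("manure.", names(ref$manure)),
      paste0("factors.", names(ref$factors)),
      paste0("gwp.", names(ref$gwp)))
    ranges <- lapply(fields, function(f) rep(scenario_get(ref, f), 2))
    names(ranges) <- fields
    return(structure(list(model_kind = model_kind, ranges = ranges,
                          log_sampled = character(), overrides = ref$overrides),
                     class = "generation_ranges"))
  }

  band <- function(path, width = 0.2) {
    v <- scenario_get(ref, path)
    r <- c(v * (1 - width), v * (1 + width))
    names(r) <- NULL
    r
  }
  intake <- if (model_kind == "EC") c(15, 25) else c(8, 10)
  ranges <- list(
    herd.herd_size = c(1e4, 1e7),
    herd.live_weight = c(250, 450),
    herd.fattening_days = c(365, 365),
    herd.enteric_ef = c(50, 80),
    herd.n_excretion_rate = c(0.3, 0.5),
    herd.manure_per_head_day = c(15, 30),
    planting.feed_intake_per_head_day = intake,
    planting.planting_area = band("planting.planting_area", 0.5),
    planting.fertilizer_application_rate = c(400, 900),
    planting.n_fertilizer_share = c(0.2, 0.4),
    planting.compound_fertilizer_share = c(0.4, 0.6),
    planting.compound_n_content = c(0.2, 0.35),
    manure.vs_rate = c(5, 12),
    manure.ms_fraction = c(0.2, 0.4),
    manure.mm_ch4_ef = c(0.5, 2.5),
    manure.mm_n2o_direct_ef = c(0.002, 0.015),
    manure.f_gas = c(0.2, 0.5),
    manure.f_leach = c(0.01, 0.05))
  ranges$manure.return_rate <- if (model_kind == "EC") c(0.9, 1.0)
                               else c(0.3, 0.6)
  if (model_kind == "EC") {
    ranges$planting.straw_feed_fraction <- c(1, 1)
    ranges$planting.straw_burn_fraction <- c(0, 0)
  } else {
    # complement (0.9563 - feed share) goes to burning
    ranges$planting.straw_feed_fraction <- c(0.05, 0.5)
  }
  for (f in names(ref$factors)) {
    ranges[[paste0("factors.", f)]] <- band(paste0("factors.", f))
  }
  structure(list(model_kind = model_kind, ranges = ranges,
                 log_sampled = "herd.herd_size", overrides = list()),
            class = "generation_ranges")
}

check_ranges <- function(ranges) {
  for (f in names(ranges$ranges)) {
    r <- ranges$ranges[[f]]
    if (!is.numeric(r) || length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      stop("invalid interval for '", f, "': need finite c(lo, hi), lo <= hi",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Generate one structurally valid random scenario
#'
#' Samples every field uniformly inside its interval (log-uniformly for
#' fields listed in `log_sampled`), enforces the structural constraints of
#' the model kind, and validates the result. Deterministic under a fixed
#' seed.
#'
#' @param ranges A [generation_ranges()].
#' @param seed Integer seed (optional; uses the current RNG state if NULL).
#' @param name Scenario name.
#' @return A validated `ghg_scenario`.
#' @export
generate_scenario <- function(ranges, seed = NULL, name = "synthetic") {
  check_ranges(ranges)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(seed)
  }
  draw <- function(f) {
    r <- ranges$ranges[[f]]
    if (f %in% ranges$log_sampled) {
      if (r[1] <= 0) stop("log-sampled interval for '", f,
                          "' must be positive", call. = FALSE)
      exp(runif(1, log(r[1]), log(r[2])))
    } else {
      runif(1, r[1], r[2])
    }
  }
  vals <- lapply(names(ranges$ranges), draw)
  names(vals) <- names(ranges$ranges)

  if (ranges$model_kind == "non-EC" &&
        is.null(ranges$ranges$planting.straw_burn_fraction)) {
    vals$planting.straw_burn_fraction <-
      0.9563 - vals$planting.straw_feed_fraction
  }
  block <- function(prefix, builder, extra = list()) {
    keys <- grep(paste0("^", prefix, "\\."), names(vals), value = TRUE)
    args <- vals[keys]
    names(args) <- sub(paste0("^", prefix, "\\."), "", keys)
    do.call(builder, c(args, extra))
  }
  scenario_spec(
    name = name, model_kind = ranges$model_kind,
    herd = block("herd", herd_spec),
    planting = block("planting", planting_spec,
                     list(is_silage = ranges$model_kind == "EC")),
    manure = block("manure", manure_spec),
    factors = block("factors", emission_factor_set),
    gwp = block("gwp", gwp_set),
    overrides = ranges$overrides)
}

#' Generate a suite of scenario files with a manifest
#'
#' Writes `n` scenario YAML files plus `manifest.json` recording the master
#' seed, per-file seeds and the sampling ranges. Repeated calls with the
#' same arguments produce byte-identical files.
#'
#' @param n Number of scenarios (>= 1).
#' @param ranges A [generation_ranges()].
#' @param seed Master integer seed; scenario i uses seed + i.
#' @param dir Output directory (created if missing).
#' @return Character vector of scenario file paths, invisibly; the manifest
#'   sits alongside them.
#' @export
generate_suite <- function(n, ranges = generation_ranges("EC"), seed = 1,
                           dir = ".") {
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  n <- as.integer(n)
  check_ranges(ranges)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(n)
  seeds <- seed + seq_len(n)
  for (i in seq_len(n)) {
    nm <- sprintf("synthetic_%s_%03d", tolower(gsub("-", "", ranges$model_kind)),
                  i)
    s <- generate_scenario(ranges, seed = seeds[i], name = nm)
    files[i] <- file.path(dir, paste0(nm, ".yaml"))
    write_scenario(s, files[i])
  }
  manifest <- list(
    model_kind = ranges$model_kind, n = n, master_seed = seed,
    scenario_seeds = seeds, files = basename(files),
    ranges = ranges$ranges, log_sampled = ranges$log_sampled)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
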