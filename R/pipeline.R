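#' Configure an end-to-end synthetic pipeline run
#'
#' Bundles every input of [run_pipeline()]: the synthetic-data blocks
#' (layout, rotation mix, years, site count, generator truth, weather
#' settings), the analysis settings (climate windows, model
#' specifications), the area-sampling settings, the scenario inputs, and
#' the seeds. Validation happens up front so a bad configuration fails
#' before any stage runs.
#'
#' @param layout A [region_layout()].
#' @param mix A [rotation_mix()].
#' @param years Raster years (>= 3 consecutive).
#' @param n_sites Number of SOC sites.
#' @param truth A [generative_params()].
#' @param months_back Months of weather history per site (>= 36).
#' @param windows A [climate_windows()].
#' @param model_specs Named list of [soc_model_spec()]s to fit.
#' @param sample_n Points sampled per region for area estimation.
#' @param region_areas Tibble `region`, `total_area_ha`, or `NULL` to
#'   skip implied areas.
#' @param scc Social cost of carbon (USD per t C).
#' @param seed Master seed; per-stage seeds are derived from it.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(layout, mix, years, n_sites = 500,
                            truth = generative_params(),
                            months_back = 36,
                            windows = climate_windows(),
                            model_specs = list(
                              groups = soc_model_spec(
                                weather = FALSE, texture = FALSE,
                                month_fe = FALSE
                              ),
                              per_year = soc_model_spec(
                                rotation_encoding = "continuous_years",
                                weather = FALSE, texture = FALSE,
                                month_fe = FALSE
                              )
                            ),
                            sample_n = 40000,
                            region_areas = NULL,
                            scc = 678,
                            seed = 1) {
  stopifnot(inherits(layout, "region_layout"))
  if (!inherits(mix, "rotation_mix")) abort("`mix` must be a rotation_mix().")
  stopifnot(inherits(truth, "generative_params"))
  if (months_back < 36) abort("`months_back` must be >= 36.")
  if (!length(model_specs) || is.null(names(model_specs))) {
    abort("`model_specs` must be a named list of soc_model_spec() objects.")
  }
  for (ms in model_specs) stopifnot(inherits(ms, "soc_model_spec"))
  if (!is.null(region_areas) &&
      !all(c("region", "total_area_ha") %in% names(region_areas))) {
    abort("`region_areas` needs columns `region`, `total_area_ha`.")
  }
  structure(
    list(
      layout = layout, mix = mix, years = sort(as.integer(years)),
      n_sites = as.integer(n_sites), truth = truth,
      months_back = as.integer(months_back), windows = windows,
      model_specs = model_specs, sample_n = as.integer(sample_n),
      region_areas = region_areas, scc = scc, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

stage_seed <- function(seed, stage) {
  # small fixed offsets keep every stage's stream independent of the others
  offsets <- c(rasters = 11L, sites = 23L, weather = 37L, soc = 53L,
               sampling = 71L)
  (seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order: generate rasters -> place
#' sites -> simulate weather -> build climate features -> extract crop
#' sequences -> simulate SOC stocks -> group summaries and Welch tests ->
#' regression fits and percent effects -> area sampling -> conversion
#' scenarios -> valuation. All stage outputs are written under `out_dir`
#' (CSV tables, ASCII-grid rasters, YAML truth and manifest); rerunning
#' with the same configuration reproduces them bit for bit.
#'
#' Scenario inputs are taken from the run itself: baseline group means
#' from the group summaries, percent effects from base-group-specific
#' refits of the first model spec, and areas from the sampled rotation
#' proportions times `region_areas` (stage skipped when `region_areas`
#' is `NULL`).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#'
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "rasters"), showWarnings = FALSE)
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  gen <- generate_crop_rasters(
    config$layout, config$years, config$mix,
    seed = stage_seed(config$seed, "rasters")
  )
  for (yr in names(gen$rasters)) {
    write_ascii_grid(gen$rasters[[yr]],
                     file.path(out_dir, "rasters", paste0("crops_", yr, ".asc")))
  }
  write_rotsoc_table(gen$truth, file.path(out_dir, "rotation_truth.csv"))
  note("rasters: %d years, %d regions", length(gen$rasters),
       nrow(config$layout$regions))

  sites <- generate_sites(
    config$n_sites, config$layout, gen$rasters,
    seed = stage_seed(config$seed, "sites")
  )
  write_rotsoc_table(sites, file.path(out_dir, "sites.csv"))
  note("sites: %d rows", nrow(sites))

  weather <- generate_weather(
    sites, months_back = config$months_back,
    seed = stage_seed(config$seed, "weather")
  )
  write_rotsoc_table(weather, file.path(out_dir, "weather.csv"))
  note("weather: %d rows", nrow(weather))

  features <- compute_climate_features(weather, config$windows)
  write_rotsoc_table(features, file.path(out_dir, "climate_features.csv"))
  note("climate features: %d rows", nrow(features))

  sequences <- build_sequences(sites, gen$rasters)
  write_rotsoc_table(sequences, file.path(out_dir, "sequences.csv"))
  note("sequences: %d rows (%d excluded)", nrow(sequences),
       sum(sequences$rotation_group == "excluded"))

  soc <- generate_soc(
    sites, sequences, features, config$truth,
    seed = stage_seed(config$seed, "soc")
  )
  write_rotsoc_table(soc, file.path(out_dir, "soc_sites.csv"))

  summaries <- group_summaries(soc)
  write_rotsoc_table(summaries, file.path(out_dir, "group_summaries.csv"))
  welch <- welch_group_tests(soc)
  write_rotsoc_table(welch, file.path(out_dir, "welch_tests.csv"))
  note("summaries: %d groups x layers; welch: %d contrasts",
       nrow(summaries), nrow(welch))

  fits <- purrr::imap(config$model_specs, function(ms, nm) {
    f <- fit_soc_model(soc, ms, features = features)
    write_rotsoc_table(tidy(f), file.path(out_dir, paste0("fit_", nm, ".csv")))
    write_rotsoc_table(
      percent_effects(f),
      file.path(out_dir, paste0("percent_effects_", nm, ".csv"))
    )
    f
  })
  note("fits: %s", paste(names(fits), collapse = ", "))

  samples <- sample_points_by_region(
    gen$rasters, config$layout, config$sample_n,
    seed = stage_seed(config$seed, "sampling")
  )
  proportions <- rotation_proportions(samples)
  frequency <- planting_frequency(samples)
  write_rotsoc_table(proportions, file.path(out_dir, "area_proportions.csv"))
  write_rotsoc_table(frequency, file.path(out_dir, "planting_frequency.csv"))
  note("area sampling: %d points/region", config$sample_n)

  scenario_results <- NULL
  valuation <- NULL
  if (!is.null(config$region_areas)) {
    areas <- estimate_group_area(proportions, config$region_areas)
    areas_tbl <- tibble::tibble(
      state = areas$region, from_group = areas$pattern,
      area_ha = areas$implied_area
    )
    areas_tbl <- areas_tbl[areas_tbl$from_group %in% c("0c", "1c", "2c"), ]
    gm <- summaries[summaries$layer == "0-100" &
                      summaries$rotation_group %in% c("0c", "1c", "2c", "3c"), ]
    group_means <- tibble::tibble(group = gm$rotation_group, mean_soc = gm$mean)
    # pairwise effects from base-group-specific refits of the first spec
    base_spec <- config$model_specs[[1]]
    effects <- purrr::map_dfr(c("0c", "1c", "2c"), function(bg) {
      ms <- base_spec
      ms$base_group <- bg
      ms$rotation_encoding <- "group_dummies"
      f <- fit_soc_model(soc, ms, features = features)
      pe <- percent_effects(f)
      to <- sub("^rotation_group", "", pe$term)
      keep <- corn_years_of_group(to) > corn_years_of_group(bg)
      tibble::tibble(
        from_group = bg, to_group = to[keep],
        pct_effect = pe$pct_effect[keep] / 100
      )
    })
    write_rotsoc_table(effects, file.path(out_dir, "conversion_effects.csv"))
    defs <- effects[, c("from_group", "to_group")]
    scenario_results <- run_scenarios(areas_tbl, group_means, effects, defs)
    write_rotsoc_table(scenario_results,
                       file.path(out_dir, "scenario_results.csv"))
    max_policy <- tibble::tibble(
      from_group = c("0c", "1c", "2c"), to_group = "3c"
    )
    total <- aggregate_policy(scenario_results, max_policy)
    valuation <- monetize(total, config$scc)
    write_rotsoc_table(valuation, file.path(out_dir, "valuation.csv"))
    note("scenarios: %d rows; max-policy total %.1f million Mg C",
         nrow(scenario_results), total / 1e6)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rotsoc")),
    seed = config$seed,
    stage_seeds = as.list(purrr::map_int(
      setNames(
        c("rasters", "sites", "weather", "soc", "sampling"),
        c("rasters", "sites", "weather", "soc", "sampling")
      ),
      ~ as.integer(stage_seed(config$seed, .x))
    )),
    config_hash = rlang::hash(config),
    years = config$years,
    n_sites = config$n_sites,
    sample_n = config$sample_n,
    rows = list(
      sites = nrow(sites), weather = nrow(weather),
      sequences = nrow(sequences), features = nrow(features)
    )
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  truth_out <- config$truth
  truth_out$group_log_effects <- as.list(truth_out$group_log_effects)
  yaml::write_yaml(
    lapply(unclass(truth_out), function(v) if (is.numeric(v)) unname(v) else v),
    file.path(out_dir, "generative_truth.yaml")
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(
    rasters = gen$rasters, truth = gen$truth, sites = sites,
    weather = weather, features = features, sequences = sequences,
    soc = soc, summaries = summaries, welch = welch, fits = fits,
    samples = samples, proportions = proportions, frequency = frequency,
    scenarios = scenario_results, valuation = valuation,
    manifest = manifest
  ))
}
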