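#' Pipeline run configuration
#'
#' Bundles everything one reproducible end-to-end run needs: generator
#' settings, the prey visual system, the scenario list, the depths at
#' which to evaluate camouflage, dark-adaptation settings and the output
#' directory. All randomness flows from the single `seed`, split
#' deterministically per stage.
#'
#' @param seed Top-level integer seed; required.
#' @param output_dir Directory for the report bundle.
#' @param depths_m Depths at which light fields are built (default
#'   `c(7, 15)`, the study depths).
#' @param generator A [generator_config()]; defaults to
#'   `generator_config(seed = seed)`.
#' @param observer A [visual_system()]; defaults to the triplefin.
#' @param scenarios Non-empty list of [scenario_spec()]s; defaults to
#'   [default_scenarios()] with the generator's shade fraction.
#' @param n_draws Simulation draws for the decay-fit credible intervals.
#' @param dark Named list of overrides passed to
#'   [make_dark_adaptation_series()] (e.g. `slope`, `gamma_shape`).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(seed, output_dir = tempfile("retroshine_run_"),
                       depths_m = c(7, 15), generator = NULL,
                       observer = NULL, scenarios = NULL,
                       n_draws = 10000, dark = list()) {
  if (missing(seed)) stop("run_config: seed is required")
  if (is.null(generator)) generator <- generator_config(seed = seed)
  if (is.null(observer)) observer <- triplefin_visual_system()
  if (is.null(scenarios))
    scenarios <- default_scenarios(generator$shade_fraction)
  if (!length(scenarios)) stop("run_config: scenarios must be non-empty")
  stopifnot(inherits(generator, "generator_config"),
            inherits(observer, "visual_system"),
            all(vapply(scenarios, inherits, logical(1), "scenario_spec")))
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 depths_m = depths_m, generator = generator,
                 observer = observer, scenarios = scenarios,
                 n_draws = n_draws, dark = dark),
            class = "run_config")
}

#' Average component spectra across individuals
#'
#' Wavelength-wise mean of each component over a list of individuals,
#' mirroring the averaging of the three field fish before contrast
#' modelling.
#'
#' @param comp_list List of [eyeshine_components()] objects.
#' @return A pooled [eyeshine_components()] with `individual_id`
#'   `"pooled"`.
#' @export
pool_components <- function(comp_list) {
  stopifnot(length(comp_list) >= 1)
  avg <- function(name) {
    vals <- sapply(comp_list, function(cc) cc[[name]]$value)
    ref <- comp_list[[1]][[name]]
    new_spct(ref$wl, rowMeans(vals), ref$kind)
  }
  eyeshine_components(sar_narrow = avg("sar_narrow"),
                      sar_broad = avg("sar_broad"), pet = avg("pet"),
                      iris = avg("iris"), model_pupil = avg("model_pupil"),
                      individual_id = "pooled")
}

.write_components_csv <- function(comp_list, path) {
  rows <- lapply(comp_list, function(cc) {
    do.call(rbind, lapply(
      c("sar_narrow", "sar_broad", "pet", "iris", "model_pupil"),
      function(nm) data.frame(individual_id = cc$individual_id,
                              component = nm,
                              wavelength_nm = cc[[nm]]$wl,
                              value = sprintf("%.17g", cc[[nm]]$value))))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate - decompose - reconstruct - contrast as one
#' reproducible run: builds a light field per depth, simulates individuals
#' and their field measurement sets (individual 1 at the first depth, the
#' rest at the second, as in the field reconstruction data set), decomposes
#' each measurement set back into component spectra, scores the
#' reconstruction with the log10-ratio match for pupil and iris under both
#' exposures, evaluates every scenario at every depth with pooled mean
#' components (chromatic JND and absolute achromatic Michelson contrast for
#' natural and model pupil against the iris), computes the pairwise
#' skin-patch contrast distribution, and fits the dark-adaptation decay.
#'
#' The bundle written to `cfg$output_dir` contains `components.csv`,
#' `recon.json`, `table2.csv` (one row per scenario x depth),
#' `skin_contrasts.csv`, `darkfit.json` and `manifest.json` (seed, config
#' hash, package version). Two runs with the same seed produce identical
#' bundles.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory results (`components`,
#'   `recon`, `table2`, `skin_contrasts`, `darkfit`, `paths`).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- cfg$generator
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("run_all: stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  lfs <- stage("lightfield", lapply(cfg$depths_m, function(d) {
    g <- gen; g$depth_m <- d; make_lightfield(g)
  }))
  names(lfs) <- paste0("d", cfg$depths_m)

  ids <- sprintf("ind%d", seq_len(gen$n_individuals))
  true_comps <- stage("individuals",
                      lapply(ids, function(id) make_individual(gen, id)))
  # individual 1 at the first depth, the remainder at the last
  depth_of <- c(1L, rep(length(lfs), max(0, length(ids) - 1L)))
  meas <- stage("measurements", Map(function(id, k)
    make_field_measurements(gen, true_comps[[match(id, ids)]], lfs[[k]]),
    ids, depth_of))

  comps <- stage("decompose", Map(function(ms, id)
    decompose_individual(ms, id), meas, ids))

  recon <- stage("reconstruct", {
    rows <- list()
    for (i in seq_along(ids)) {
      lf <- lfs[[depth_of[i]]]
      for (expo in c("exposed", "shaded")) {
        p_pred <- predict_pupil_radiance(comps[[i]], lf, expo)
        i_pred <- predict_iris_radiance(comps[[i]], lf, expo)
        p_meas <- find_measurement(meas[[i]], "pupil", expo,
                                   individual_id = ids[i])
        i_meas <- find_measurement(meas[[i]], "iris", expo,
                                   individual_id = ids[i])
        rows[[length(rows) + 1L]] <- list(
          individual_id = ids[i], depth_m = lf$depth_m, exposure = expo,
          match_pupil = log_ratio_match(p_pred, p_meas),
          match_iris = log_ratio_match(i_pred, i_meas))
      }
    }
    list(per_fish = rows,
         mean_match_pupil_exposed = mean(vapply(
           rows, function(r) if (r$exposure == "exposed") r$match_pupil
           else NA_real_, numeric(1)), na.rm = TRUE),
         mean_match_pupil_shaded = mean(vapply(
           rows, function(r) if (r$exposure == "shaded") r$match_pupil
           else NA_real_, numeric(1)), na.rm = TRUE),
         mean_match_iris_exposed = mean(vapply(
           rows, function(r) if (r$exposure == "exposed") r$match_iris
           else NA_real_, numeric(1)), na.rm = TRUE),
         mean_match_iris_shaded = mean(vapply(
           rows, function(r) if (r$exposure == "shaded") r$match_iris
           else NA_real_, numeric(1)), na.rm = TRUE))
  })

  pooled <- stage("pool", pool_components(comps))

  table2 <- stage("contrast", {
    rows <- list()
    for (lf in lfs) for (sc in cfg$scenarios) {
      res <- run_scenario(pooled, lf, sc, cfg$observer)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$name, depth_m = lf$depth_m,
        jnd_natural = res$natural$chromatic_jnd,
        jnd_model = res$model$chromatic_jnd,
        michelson_natural = res$natural$achromatic_michelson,
        michelson_model = res$model$achromatic_michelson)
    }
    do.call(rbind, rows)
  })

  skin <- stage("skin", {
    rows <- list()
    for (i in seq_along(ids)) {
      lf <- lfs[[depth_of[i]]]
      patches <- skin_reflectances(meas[[i]], ids[i])
      cm <- skin_patch_contrasts(patches, lf, cfg$observer)
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = ids[i], depth_m = lf$depth_m,
        pair = seq_along(cm), contrast = cm)
    }
    do.call(rbind, rows)
  })

  dark_args <- utils::modifyList(
    list(seed = stage_seed(cfg$seed, "dark")), cfg$dark)
  series <- stage("dark_series",
                  do.call(make_dark_adaptation_series, dark_args))
  dfit <- stage("dark_fit",
                fit_dark_adaptation(series, n_draws = cfg$n_draws,
                                    seed = stage_seed(cfg$seed, "draws")))

  paths <- list(
    components = file.path(cfg$output_dir, "components.csv"),
    recon = file.path(cfg$output_dir, "recon.json"),
    table2 = file.path(cfg$output_dir, "table2.csv"),
    skin = file.path(cfg$output_dir, "skin_contrasts.csv"),
    darkfit = file.path(cfg$output_dir, "darkfit.json"),
    manifest = file.path(cfg$output_dir, "manifest.json"))

  .write_components_csv(comps, paths$components)
  jsonlite::write_json(recon, paths$recon, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(table2, paths$table2, row.names = FALSE, quote = FALSE)
  utils::write.csv(skin, paths$skin, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    coef_time = dfit$coef_time,
    percent_change_per_min = dfit$percent_change_per_min,
    r_squared = dfit$r_squared,
    n_draws = dfit$n_draws,
    coefficients = cbind(term = rownames(dfit$coefficients),
                         dfit$coefficients)),
    paths$darkfit, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # the echoed config (and its hash) must not depend on where the bundle
  # lands, so the output path is excluded
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg),
                                           c("observer", "output_dir"))],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg_file <- file.path(cfg$output_dir, "config_echo.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   package_version = as.character(
                     utils::packageVersion("retroshine")),
                   rng = "Mersenne-Twister/Inversion",
                   files = vapply(paths[names(paths) != "manifest"],
                                  basename, character(1)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  message(sprintf("run_all: bundle written to %s", cfg$output_dir))
  invisible(list(components = comps, pooled = pooled, recon = recon,
                 table2 = table2, skin_contrasts = skin, darkfit = dfit,
                 lightfields = lfs, measurements = meas, paths = paths))
}

#' Run the pipeline from a YAML configuration file
#'
#' Thin wrapper over [run_config()] + [run_all()]. The YAML file may set
#' `seed` (required), `output_dir`, `depths_m`, `n_draws`, any
#' [generator_config()] field under `generator:`, and dark-adaptation
#' overrides under `dark:`.
#'
#' @param path Path to a YAML config file.
#' @return See [run_all()].
#' @export
retroshine_run <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("retroshine_run: config must set a seed")
  gen_args <- c(y$generator, list(seed = y$seed))
  gen_args <- gen_args[!duplicated(names(gen_args))]
  cfg <- run_config(
    seed = y$seed,
    output_dir = if (is.null(y$output_dir)) tempfile("retroshine_run_")
                 else y$output_dir,
    depths_m = if (is.null(y$depths_m)) c(7, 15) else unlist(y$depths_m),
    generator = do.call(generator_config, gen_args),
    n_draws = if (is.null(y$n_draws)) 10000 else y$n_draws,
    dark = if (is.null(y$dark)) list() else y$dark)
  run_all(cfg)
}
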