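#' Assemble an end-to-end run configuration
#'
#' A run configuration bundles the synthetic landscape, the virtual
#' community, the data-hygiene settings (thinning edge, test fraction), the
#' model settings (all defaulting to the published choices: convergence
#' 1e-6, 500 iterations, 30% test data, hinge features above 15 presences),
#' the scenarios, and one named seed per stochastic stage so that no stage
#' perturbs another's stream.
#'
#' Scenarios are named multipliers on the landscape's change field: the
#' future stack for scenario `s` is `current + multiplier_s * delta`. The
#' defaults emulate a stronger and a milder emission pathway.
#'
#' @param landscape a [landscape_config()].
#' @param species list of [species_spec()] objects, or `NULL` to build
#'   [default_community()] with `n_species` members.
#' @param n_species community size when `species` is `NULL`.
#' @param n_occurrences raw occurrence records drawn per species.
#' @param bias_strength sampling-bias weight ratio (see [sampling_bias()]).
#' @param thin_edge_km thinning-grid edge.
#' @param test_fraction test partition fraction.
#' @param scenarios named numeric vector of delta multipliers.
#' @param maxent list of model settings: `beta_scale`, `convergence`,
#'   `max_iter`, `background_size`, `hinge_knot_count`.
#' @param run_sensitivity run the per-species severity experiment?
#' @param seeds named list of integer seeds: `occurrences`, `thin`,
#'   `split`, `background`.
#' @param output_dir directory for artifact files, or `NULL` to skip
#'   writing.
#' @return An object of class `nc_run_config`.
#' @export
run_config <- function(landscape = landscape_config(),
                       species = NULL, n_species = 5,
                       n_occurrences = 300, bias_strength = 10,
                       thin_edge_km = 10, test_fraction = 0.3,
                       scenarios = c(a2 = 1, b2 = 0.7),
                       maxent = list(), run_sensitivity = TRUE,
                       seeds = list(occurrences = 11L, thin = 12L,
                                    split = 13L, background = 14L),
                       output_dir = NULL) {
  maxent <- utils::modifyList(
    list(beta_scale = 1, convergence = 1e-6, max_iter = 500,
         background_size = 10000, hinge_knot_count = 5),
    maxent
  )
  structure(
    list(landscape = landscape, species = species, n_species = n_species,
         n_occurrences = n_occurrences, bias_strength = bias_strength,
         thin_edge_km = thin_edge_km, test_fraction = test_fraction,
         scenarios = scenarios, maxent = maxent,
         run_sensitivity = run_sensitivity, seeds = seeds,
         output_dir = output_dir),
    class = "nc_run_config"
  )
}

#' Validate a run configuration
#'
#' Non-mutating check of a configuration: reports missing fields, range
#' violations and duplicate scenario labels without raising.
#'
#' @param config an [run_config()] (or any list shaped like one).
#' @return A tibble with columns `field` and `problem`; zero rows when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  problems <- list()
  note <- function(field, problem) {
    problems[[length(problems) + 1]] <<- tibble::tibble(field = field,
                                                        problem = problem)
  }
  if (!inherits(config$landscape, "nc_landscape_config")) {
    note("landscape", "not a landscape_config()")
  }
  if (is.null(config$species) &&
      (is.null(config$n_species) || config$n_species < 1)) {
    note("n_species", "must be >= 1 when no species list is given")
  }
  if (is.null(config$n_occurrences) || config$n_occurrences < 1) {
    note("n_occurrences", "must be >= 1")
  }
  if (is.null(config$thin_edge_km) || config$thin_edge_km <= 0) {
    note("thin_edge_km", "must be > 0")
  }
  if (is.null(config$test_fraction) || config$test_fraction <= 0 ||
      config$test_fraction >= 1) {
    note("test_fraction", "must be in (0, 1)")
  }
  if (is.null(config$scenarios) || length(config$scenarios) == 0 ||
      is.null(names(config$scenarios)) || any(names(config$scenarios) == "")) {
    note("scenarios", "must be a named vector of delta multipliers")
  } else if (anyDuplicated(names(config$scenarios))) {
    note("scenarios", "duplicate scenario labels")
  }
  for (s in c("occurrences", "thin", "split", "background")) {
    if (is.null(config$seeds[[s]]) || !is.numeric(config$seeds[[s]])) {
      note(paste0("seeds$", s), "missing or non-numeric seed")
    }
  }
  mx <- config$maxent
  if (is.null(mx$convergence) || mx$convergence <= 0) {
    note("maxent$convergence", "must be > 0")
  }
  if (is.null(mx$max_iter) || mx$max_iter < 1) {
    note("maxent$max_iter", "must be >= 1")
  }
  if (is.null(mx$background_size) || mx$background_size < 10) {
    note("maxent$background_size", "must be >= 10")
  }
  if (length(problems) == 0) {
    tibble::tibble(field = character(), problem = character())
  } else {
    dplyr::bind_rows(problems)
  }
}

#' Read and write run configurations as YAML
#'
#' @param config an [run_config()].
#' @param path file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` an [run_config()] (landscape re-validated).
#' @export
write_run_config <- function(config, path) {
  doc <- unclass(config)
  doc$landscape <- unclass(doc$landscape)
  doc$landscape$correlation <- as.vector(doc$landscape$correlation)
  doc$scenarios <- as.list(doc$scenarios)
  doc$species <- NULL  # species specs are code, not config
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  ls <- doc$landscape
  landscape <- landscape_config(
    nrow = ls$nrow, ncol = ls$ncol, cell_km = ls$cell_km,
    n_climate = ls$n_climate, n_veg = ls$n_veg,
    autocorr_km = ls$autocorr_km,
    correlation = matrix(ls$correlation,
                         ls$n_climate + ls$n_veg, ls$n_climate + ls$n_veg),
    gradient = ls$gradient, noise_amplitude = ls$noise_amplitude,
    delta = ls$delta, delta_gradient = ls$delta_gradient,
    calibration_frac = ls$calibration_frac, buffer_frac = ls$buffer_frac,
    seed = ls$seed
  )
  run_config(
    landscape = landscape, n_species = doc$n_species,
    n_occurrences = doc$n_occurrences, bias_strength = doc$bias_strength,
    thin_edge_km = doc$thin_edge_km, test_fraction = doc$test_fraction,
    scenarios = unlist(doc$scenarios), maxent = doc$maxent,
    run_sensitivity = doc$run_sensitivity, seeds = doc$seeds,
    output_dir = doc$output_dir
  )
}

scenario_landscape <- function(landscape, multiplier) {
  ls <- landscape
  ls$delta <- ls$delta * multiplier
  ls
}

#' Run the full projection pipeline on a synthetic world
#'
#' Executes the complete analysis: generate the landscape, sample biased
#' occurrences per species, thin to the grid, split train/test, restrict to
#' the calibration extent, fit the niche model, evaluate train/test AUC,
#' select the threshold, project the current and each scenario's future
#' stack, derive full- and no-dispersal ranges, trends and centroid shifts,
#' stack richness, sum net suitability change, run the severity experiment,
#' and compute the cross-species summaries. Every stage draws from its own
#' named seed stream, so identical configurations reproduce identical
#' output byte for byte.
#'
#' @param config an [run_config()]; validation failures abort before any
#'   computation.
#' @param quiet suppress per-stage progress messages?
#' @return A list: `reports` (per-scenario Table-1-schema tibbles, merged
#'   in `table1`), `accuracy`, `summary`, `richness` (per period/scenario),
#'   `net_change`, `sensitivity`, `truth`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  problems <- validate_config(config)
  if (nrow(problems) > 0) {
    abort(paste0("invalid configuration:\n",
                 paste(" -", problems$field, ":", problems$problem,
                       collapse = "\n")),
          class = "nc_config_error")
  }
  say <- function(...) if (!quiet) message(...)
  mx <- config$maxent

  env_current <- generate_env_stack(config$landscape, "current")
  futures <- lapply(config$scenarios, function(mult) {
    generate_env_stack(scenario_landscape(config$landscape, mult), "future")
  })
  specs <- config$species %||% default_community(config$landscape,
                                                 config$n_species)
  names(specs) <- vapply(specs, function(s) s$id, character(1))
  bias <- sampling_bias(env_current, config$bias_strength)
  truth <- truth_set(specs, env_current, futures[[1]])

  reports <- setNames(vector("list", length(config$scenarios)),
                      names(config$scenarios))
  accuracy <- list(); sensitivity <- list()
  current_maps <- list(); future_maps <- lapply(futures, function(x) list())
  current_ranges <- list()
  bcs_ranges <- lapply(futures, function(x) list())
  wcs_ranges <- lapply(futures, function(x) list())

  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    say("species ", sp$id)
    occ <- sample_occurrences(sp, env_current, bias = bias,
                              n = config$n_occurrences,
                              seed = config$seeds$occurrences + si)
    thinned <- suppressWarnings(
      thin_to_grid(occ, config$thin_edge_km, seed = config$seeds$thin + si))
    parts <- split_train_test(thinned, config$test_fraction,
                              seed = config$seeds$split + si)
    calib <- restrict_to_calibration(parts$train, env_current)
    say("  records raw/thinned/train/test: ", nrow(occ), "/", nrow(thinned),
        "/", nrow(calib$occurrences), "/", nrow(parts$test))
    model <- fit_species_model(
      calib$occurrences, env_current,
      hinge_knot_count = mx$hinge_knot_count, beta_scale = mx$beta_scale,
      convergence = mx$convergence, max_iter = mx$max_iter,
      background_size = mx$background_size,
      seed = config$seeds$background + si
    )
    map0 <- project(model, env_current)
    bg_scores <- map0$logistic[model$background]
    thr <- select_threshold(score_occurrences(map0, calib$occurrences),
                            bg_scores)
    acc <- accuracy_report(map0, calib$occurrences, parts$test, bg_scores)
    ref <- truth$occupancy_current[[si]]
    r0 <- binarize(map0, thr$threshold)
    agreement <- compare_reference_range(r0, ref)
    accuracy[[sp$id]] <- dplyr::bind_cols(
      tibble::tibble(species = sp$id, n_train = nrow(calib$occurrences),
                     n_test = nrow(parts$test), threshold = thr$threshold),
      acc, agreement
    )
    current_maps[[sp$id]] <- map0
    current_ranges[[sp$id]] <- r0
    for (sc in names(futures)) {
      map1 <- project(model, futures[[sc]])
      r1 <- binarize(map1, thr$threshold)
      future_maps[[sc]][[sp$id]] <- map1
      bcs_ranges[[sc]][[sp$id]] <- r1
      wcs_ranges[[sc]][[sp$id]] <- wcs_range(r0, r1)
      reports[[sc]] <- dplyr::bind_rows(
        reports[[sc]],
        species_report(sp$id, r0, r1, type = sp$type, order = sp$group)
      )
    }
    if (isTRUE(config$run_sensitivity)) {
      sensitivity[[sp$id]] <- severity_experiment(
        calib$occurrences, env_current, futures[[1]],
        hinge_knot_count = mx$hinge_knot_count, beta_scale = mx$beta_scale,
        convergence = mx$convergence, max_iter = mx$max_iter,
        background_size = mx$background_size,
        seed = config$seeds$background + si
      )
    }
  }

  # the merged table carries the first scenario's centroid shift, as the
  # published table does; later scenarios contribute their ratio columns
  schemas <- lapply(names(reports), function(sc) {
    reports_to_table1_schema(reports[[sc]], sc)
  })
  schemas[-1] <- lapply(schemas[-1], function(s) {
    s[, !names(s) %in% c("shift_km", "shift_bearing_deg"), drop = FALSE]
  })
  table1 <- Reduce(function(a, b) {
    dplyr::left_join(a, b, by = c("species", "order", "type", "area_2000"))
  }, schemas)
  summary <- summarize_reports(table1, scenarios = names(reports))
  richness <- c(
    list(current = stack_richness(current_ranges)),
    setNames(lapply(names(futures), function(sc) {
      stack_richness(bcs_ranges[[sc]])
    }), paste0("bcs_", names(futures))),
    setNames(lapply(names(futures), function(sc) {
      stack_richness(wcs_ranges[[sc]])
    }), paste0("wcs_", names(futures)))
  )
  net_change <- lapply(future_maps, function(fm) {
    net_suitability_change(current_maps, fm)
  })
  out <- list(
    reports = reports, table1 = table1,
    accuracy = dplyr::bind_rows(accuracy),
    summary = summary, richness = richness, net_change = net_change,
    sensitivity = if (length(sensitivity) > 0) dplyr::bind_rows(sensitivity),
    truth = truth,
    ranges = list(current = current_ranges, bcs = bcs_ranges,
                  wcs = wcs_ranges),
    manifest = list(scenarios = config$scenarios, seeds = config$seeds,
                    maxent = config$maxent,
                    n_species = length(specs),
                    grid = c(config$landscape$nrow, config$landscape$ncol),
                    cell_km = config$landscape$cell_km)
  )
  if (!is.null(config$output_dir)) {
    write_pipeline_outputs(out, config$output_dir, env_current$cell_km)
  }
  out
}

write_pipeline_outputs <- function(result, dir, cell_km) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$table1, file.path(dir, "table1_pipeline.csv"))
  readr::write_csv(result$accuracy, file.path(dir, "accuracy.csv"))
  if (!is.null(result$sensitivity)) {
    readr::write_csv(result$sensitivity, file.path(dir, "table2_pipeline.csv"))
  }
  summary_doc <- result$summary
  summary_doc$contingency <- lapply(summary_doc$contingency, function(ct) {
    ct$table <- as.vector(ct$table)
    ct
  })
  jsonlite::write_json(summary_doc, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (nm in names(result$richness)) {
    write_ascii_grid(result$richness[[nm]],
                     file.path(dir, paste0("richness_", nm, ".asc")), cell_km)
  }
  for (nm in names(result$net_change)) {
    write_ascii_grid(result$net_change[[nm]],
                     file.path(dir, paste0("net_change_", nm, ".asc")),
                     cell_km)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
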