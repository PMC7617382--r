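#' Default pipeline configuration
#'
#' The full set of pipeline knobs with their defaults; [validate_config()]
#' merges user values into this structure and rejects unknown keys, so this
#' function doubles as the configuration reference.
#'
#' @return A nested list of class `"memland_config"`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    out_dir = "memland_out",
    recording = NULL,   # path to a recording directory; default: simulate stage output
    convention = "pm1",
    simulate = list(n_regions = 8, coupling_scale = 0.45,
                    structure_noise = 0.05, density = 0.6,
                    n_samples = 20000, neurons_per_region = 20, snr = 20,
                    method = "metropolis"),
    preprocess = list(n_rois = 64, n_clusters = 8, threshold_z = 0,
                      linkage = "average"),
    fit = list(method = "auto", learning_rate = 0.1, tolerance = 1e-4,
               max_iter = 20000, exact_limit = 15),
    evaluate = list(sf_thresholds = c(0.01, 0.3), split_half = TRUE),
    dynamics = list(n_steps = 1e5, burn_in = 30000, thin = 1),
    thermo = list(engine = "exact", t_max = 2, t_min = 0.05, t_step = 0.05,
                  n_steps = 1e6, burn_in = 30000, thin = 500, scale = 0.1),
    resect = list(engine = "exact")
  ), class = "memland_config")
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a JSON file path, a nested list, or `NULL` (pure defaults).
#' Unknown keys, type mismatches and out-of-range values are all collected
#' and reported together in a single error.
#'
#' @param config Path to a JSON config file, a list, or `NULL`.
#' @return The normalized `"memland_config"` (defaults filled in).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (nzchar(trimws(txt))) {
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
    } else list()
  }
  if (is.null(config)) config <- list()
  if (inherits(config, "memland_config")) config <- unclass(config)
  stopifnot(is.list(config))
  def <- unclass(default_config())
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)
  merged <- def
  for (key in names(config)) {
    if (!key %in% names(def)) {
      note(paste0("unknown config key: '", key, "'"))
      next
    }
    if (is.list(def[[key]])) {
      sub <- config[[key]]
      if (!is.list(sub)) {
        note(paste0("'", key, "' must be a table of settings"))
        next
      }
      for (k2 in names(sub)) {
        if (!k2 %in% names(def[[key]])) {
          note(paste0("unknown config key: '", key, ".", k2, "'"))
        } else {
          merged[[key]][[k2]] <- sub[[k2]]
        }
      }
    } else {
      merged[[key]] <- config[[key]]
    }
  }
  chk_num <- function(path, value, lower = -Inf, positive = FALSE) {
    if (!is.numeric(value) || length(value) < 1 || anyNA(value)) {
      note(paste0("'", path, "' must be numeric"))
    } else if (positive && any(value <= 0)) {
      note(paste0("'", path, "' must be positive"))
    } else if (any(value < lower)) {
      note(paste0("'", path, "' must be >= ", lower))
    }
  }
  chk_num("seed", merged$seed)
  if (!merged$convention %in% c("pm1", "01")) {
    note("'convention' must be \"pm1\" or \"01\"")
  }
  chk_num("simulate.n_regions", merged$simulate$n_regions, lower = 2)
  chk_num("simulate.coupling_scale", merged$simulate$coupling_scale, positive = TRUE)
  chk_num("simulate.structure_noise", merged$simulate$structure_noise, lower = 0)
  chk_num("simulate.n_samples", merged$simulate$n_samples, lower = 0)
  chk_num("simulate.snr", merged$simulate$snr, positive = TRUE)
  chk_num("preprocess.n_rois", merged$preprocess$n_rois, lower = 1)
  chk_num("preprocess.n_clusters", merged$preprocess$n_clusters, lower = 2)
  chk_num("preprocess.threshold_z", merged$preprocess$threshold_z)
  chk_num("fit.learning_rate", merged$fit$learning_rate, positive = TRUE)
  chk_num("fit.tolerance", merged$fit$tolerance, positive = TRUE)
  chk_num("fit.max_iter", merged$fit$max_iter, lower = 1)
  chk_num("dynamics.n_steps", merged$dynamics$n_steps, positive = TRUE)
  chk_num("dynamics.burn_in", merged$dynamics$burn_in, lower = 0)
  chk_num("thermo.t_max", merged$thermo$t_max, positive = TRUE)
  chk_num("thermo.t_min", merged$thermo$t_min, positive = TRUE)
  chk_num("thermo.t_step", merged$thermo$t_step, positive = TRUE)
  chk_num("thermo.n_steps", merged$thermo$n_steps, positive = TRUE)
  chk_num("thermo.scale", merged$thermo$scale, positive = TRUE)
  if (!merged$thermo$engine %in% c("exact", "mcmc")) {
    note("'thermo.engine' must be \"exact\" or \"mcmc\"")
  }
  if (!merged$resect$engine %in% c("exact", "mcmc")) {
    note("'resect.engine' must be \"exact\" or \"mcmc\"")
  }
  if (length(errors)) {
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  structure(merged, class = "memland_config")
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

require_input <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing input '", path, "' - run stage '", producer, "' first",
         call. = FALSE)
  }
  path
}

write_manifest <- function(dir, stage, params, inputs = character(0)) {
  manifest <- list(
    stage = stage,
    package = "memland",
    version = as.character(utils::packageVersion("memland")),
    parameters = params,
    inputs = if (length(inputs)) {
      stats::setNames(as.list(unname(tools::md5sum(inputs))),
                      basename(inputs))
    } else list()
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
}

recording_path <- function(config) {
  if (!is.null(config$recording)) config$recording
  else file.path(config$out_dir, "simulate", "recording")
}

#' Run one pipeline stage (or the end-to-end demo)
#'
#' Orchestrates the analysis as file-based stages under
#' `config$out_dir/<stage>/`, each with a `manifest.json` recording every
#' parameter actually used (defaults included), the input file checksums
#' and the package version.  All numerics in the CSV outputs are written at
#' full precision, so two runs with the same configuration and seed produce
#' byte-identical outputs.
#'
#' Stages: `simulate` (ground truth + recording), `preprocess` (ROIs,
#' functional clusters, binarization), `fit`, `evaluate`
#' (multi-information, state probabilities, structure-function),
#' `landscape`, `dynamics` (empirical vs Metropolis basin transitions),
#' `thermo`, `resect`, and `demo` (all of the above in order).
#'
#' @param stage Stage name.
#' @param config A config file path, list, or `NULL` for defaults; see
#'   [validate_config()].
#' @return The stage's main result object, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "preprocess", "fit", "evaluate",
                                "landscape", "dynamics", "thermo", "resect",
                                "demo"),
                      config = NULL) {
  stage <- match.arg(stage)
  config <- validate_config(config)
  if (stage == "demo") {
    for (s in c("simulate", "preprocess", "fit", "evaluate", "landscape",
                "dynamics", "thermo", "resect")) {
      run_stage(s, config)
    }
    return(invisible(config))
  }
  switch(stage,
         simulate = stage_simulate(config),
         preprocess = stage_preprocess(config),
         fit = stage_fit(config),
         evaluate = stage_evaluate(config),
         landscape = stage_landscape(config),
         dynamics = stage_dynamics(config),
         thermo = stage_thermo(config),
         resect = stage_resect(config))
}

stage_simulate <- function(config) {
  d <- stage_dir(config, "simulate")
  p <- config$simulate
  gt <- make_ground_truth(p$n_regions, coupling_scale = p$coupling_scale,
                          structure_noise = p$structure_noise,
                          density = p$density,
                          seed = child_seed(config$seed, 1),
                          convention = config$convention)
  states <- sample_states(gt, p$n_samples, method = p$method,
                          seed = child_seed(config$seed, 2))
  rec <- states_to_traces(states, neurons_per_region = p$neurons_per_region,
                          snr = p$snr, seed = child_seed(config$seed, 3),
                          ground_truth = gt)
  write_recording(rec, file.path(d, "recording"))
  write_manifest(d, "simulate", c(p, list(seed = config$seed,
                                          convention = config$convention)))
  invisible(rec)
}

stage_preprocess <- function(config) {
  d <- stage_dir(config, "preprocess")
  p <- config$preprocess
  rec_dir <- recording_path(config)
  require_input(file.path(rec_dir, "neurons.csv"), "simulate")
  rec <- read_recording(rec_dir)
  rois <- spatial_kmeans(rec$neuron_positions, rec$traces,
                         n_rois = min(p$n_rois, nrow(rec$traces)),
                         seed = child_seed(config$seed, 4))
  cl <- functional_clusters(rois, n_clusters = p$n_clusters,
                            linkage = p$linkage)
  raster <- binarize(cl, threshold_z = p$threshold_z,
                     convention = config$convention)
  write_matrix_csv(cl$traces, file.path(d, "cluster_traces.csv"),
                   col_names = paste0("t_", seq_len(ncol(cl$traces)) - 1))
  write_matrix_csv(raster$states, file.path(d, "raster.csv"),
                   col_names = paste0("c", seq_len(ncol(raster$states))))
  jsonlite::write_json(list(convention = raster$convention,
                            threshold_z = raster$threshold_z),
                       file.path(d, "raster_meta.json"), auto_unbox = TRUE,
                       digits = I(17))
  utils::write.csv(data.frame(roi_id = seq_len(rois$n_rois),
                              cluster_id = cl$cluster_of_roi),
                   file.path(d, "cluster_assignment.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(neuron_id = seq_along(rois$roi_of_neuron),
                              roi_id = rois$roi_of_neuron),
                   file.path(d, "roi_assignment.csv"), row.names = FALSE,
                   quote = FALSE)
  write_manifest(d, "preprocess",
                 c(p, list(seed = config$seed,
                           convention = config$convention)),
                 inputs = file.path(rec_dir, "neurons.csv"))
  invisible(raster)
}

read_stage_raster <- function(config) {
  d <- file.path(config$out_dir, "preprocess")
  require_input(file.path(d, "raster.csv"), "preprocess")
  meta <- jsonlite::read_json(file.path(d, "raster_meta.json"),
                              simplifyVector = TRUE)
  st <- read_matrix_csv(file.path(d, "raster.csv"), has_header = TRUE)
  dimnames(st) <- NULL
  binary_raster(st, meta$convention,
                if (is.null(meta$threshold_z)) NA_real_ else meta$threshold_z)
}

read_stage_model <- function(config) {
  f <- require_input(file.path(config$out_dir, "fit", "params.json"), "fit")
  g <- jsonlite::read_json(f, simplifyVector = TRUE)
  mem_model(g$h, g$J, convention = g$convention)
}

stage_fit <- function(config) {
  d <- stage_dir(config, "fit")
  p <- config$fit
  raster <- read_stage_raster(config)
  fit <- fit_mem(raster, method = p$method,
                 learning_rate = p$learning_rate, tolerance = p$tolerance,
                 max_iter = p$max_iter, exact_limit = p$exact_limit)
  jsonlite::write_json(list(convention = fit$convention, h = fit$h,
                            J = fit$J),
                       file.path(d, "params.json"), auto_unbox = TRUE,
                       digits = I(17), matrix = "rowmajor")
  jsonlite::write_json(list(method = fit$method, iterations = fit$iterations,
                            converged = fit$converged,
                            max_moment_error = fit$max_moment_error,
                            error_trace = fit$error_trace),
                       file.path(d, "fit_report.json"), auto_unbox = TRUE,
                       digits = I(17))
  write_manifest(d, "fit", c(p, list(seed = config$seed)),
                 inputs = file.path(config$out_dir, "preprocess", "raster.csv"))
  invisible(fit)
}

stage_evaluate <- function(config) {
  d <- stage_dir(config, "evaluate")
  raster <- read_stage_raster(config)
  model <- read_stage_model(config)
  report <- list()
  if (model$n_units <= 20) {
    mi <- suppressWarnings(multi_information(raster, model))
    report$multi_information <- mi[c("S1", "S2", "SN", "I2", "IN", "r",
                                     "r_defined")]
    spc <- state_probability_comparison(raster, model)
    write_matrix_csv(as.matrix(spc[, c("state", "empirical_p", "model_p",
                                       "n_active")]),
                     file.path(d, "state_probabilities.csv"),
                     col_names = c("state", "empirical_p", "model_p",
                                   "n_active"))
  }
  rec_dir <- recording_path(config)
  if (file.exists(file.path(rec_dir, "structural.csv"))) {
    rec <- read_recording(rec_dir)
    pre <- file.path(config$out_dir, "preprocess")
    roi_assign <- utils::read.csv(file.path(pre, "roi_assignment.csv"))
    cl_assign <- utils::read.csv(file.path(pre, "cluster_assignment.csv"))
    roi_region <- vapply(sort(unique(roi_assign$roi_id)), function(a) {
      majority_label(rec$region_of_neuron[roi_assign$roi_id == a])
    }, 0L)
    agg <- aggregate_structural(rec$ground_truth$structural, roi_region,
                                cl_assign$cluster_id, model$n_units)
    sf <- structure_function(model, agg, score = "absJ",
                             thresholds = config$evaluate$sf_thresholds)
    report$structure_function <- sf[c("pearson", "spearman",
                                      "auc_by_threshold")]
    for (i in seq_along(sf$roc_curves)) {
      if (!is.null(sf$roc_curves[[i]])) {
        write_matrix_csv(as.matrix(sf$roc_curves[[i]]),
                         file.path(d, paste0("roc_", sf$thresholds[i], ".csv")),
                         col_names = c("FPR", "TPR"))
      }
    }
  }
  if (isTRUE(config$evaluate$split_half) && nrow(raster$states) >= 4) {
    sh <- split_half(raster, seed = child_seed(config$seed, 5),
                     tolerance = config$fit$tolerance,
                     max_iter = config$fit$max_iter)
    report$split_half <- sh[c("corr_J", "corr_h", "corr_state_p")]
  }
  jsonlite::write_json(report, file.path(d, "evaluation.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  write_manifest(d, "evaluate",
                 c(config$evaluate, list(seed = config$seed)),
                 inputs = file.path(config$out_dir, "fit", "params.json"))
  invisible(report)
}

stage_landscape <- function(config) {
  d <- stage_dir(config, "landscape")
  model <- read_stage_model(config)
  ls <- energy_landscape(model)
  bits <- index_to_state(0:(2^model$n_units - 1), model$n_units, "01")
  tab <- cbind(state_index = 0:(2^model$n_units - 1),
               energy = ls$energies, basin_label = ls$basin_of_state)
  utils::write.table(
    data.frame(state_index = tab[, 1],
               state_bits = apply(bits, 1, paste, collapse = ""),
               energy = format_full(ls$energies),
               basin_label = ls$basin_of_state),
    file.path(d, "landscape.csv"), sep = ",", quote = FALSE,
    row.names = FALSE)
  dg <- if (length(ls$minima) >= 1) disconnectivity(ls) else NULL
  summ <- landscape_summary(ls, dg)
  utils::write.csv(summ, file.path(d, "minima.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(dg)) {
    jsonlite::write_json(dg$merge_tree, file.path(d, "merge_tree.json"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  write_manifest(d, "landscape", list(seed = config$seed),
                 inputs = file.path(config$out_dir, "fit", "params.json"))
  invisible(ls)
}

stage_dynamics <- function(config) {
  d <- stage_dir(config, "dynamics")
  p <- config$dynamics
  raster <- read_stage_raster(config)
  model <- read_stage_model(config)
  ls <- energy_landscape(model)
  emp_lab <- basin_trajectory(raster, ls)
  walk <- mcmc_walk(model, n_steps = p$n_steps, burn_in = p$burn_in,
                    thin = p$thin, seed = child_seed(config$seed, 6))
  sim_lab <- basin_trajectory(walk, ls)
  basin_set <- sort(unique(c(emp_lab, sim_lab)))
  emp <- transition_stats(emp_lab, basin_set)
  sim <- transition_stats(sim_lab, basin_set)
  cmp <- compare_transitions(emp, sim)
  dwell <- dwell_size_relation(emp, ls)
  for (nm in c("freq", "p_out", "p_in")) {
    write_matrix_csv(emp[[nm]], file.path(d, paste0("empirical_", nm, ".csv")),
                     col_names = colnames(emp[[nm]]))
    write_matrix_csv(sim[[nm]], file.path(d, paste0("simulated_", nm, ".csv")),
                     col_names = colnames(sim[[nm]]))
  }
  utils::write.csv(cmp$table, file.path(d, "transition_comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    comparison = cmp[c("slope", "intercept", "r_squared", "p_value",
                       "reliable")],
    dwell_size = dwell[c("intercept", "slope", "r_squared", "reliable")],
    acceptance_rate = walk$acceptance_rate),
    file.path(d, "dynamics.json"), auto_unbox = TRUE, digits = I(17),
    pretty = TRUE)
  write_manifest(d, "dynamics", c(p, list(seed = config$seed)),
                 inputs = file.path(config$out_dir, "fit", "params.json"))
  invisible(cmp)
}

thermo_grid <- function(p) seq(p$t_max, p$t_min, by = -p$t_step)

stage_thermo <- function(config) {
  d <- stage_dir(config, "thermo")
  p <- config$thermo
  model <- read_stage_model(config)
  grid <- thermo_grid(p)
  curve <- if (p$engine == "exact") {
    thermo_exact(model, grid)
  } else {
    annealed_sweep(model, grid, n_steps = p$n_steps, burn_in = p$burn_in,
                   thin = p$thin, seed = child_seed(config$seed, 7),
                   scale = p$scale)
  }
  write_matrix_csv(cbind(T = curve$temperatures, C = curve$C,
                         chi = curve$chi, M_mean = curve$M_mean),
                   file.path(d, "thermo_curve.csv"),
                   col_names = c("T", "C", "chi", "M_mean"))
  tr <- locate_transition(curve)
  jsonlite::write_json(tr, file.path(d, "transition.json"),
                       auto_unbox = TRUE, digits = I(17))
  write_manifest(d, "thermo", c(p, list(seed = config$seed)),
                 inputs = file.path(config$out_dir, "fit", "params.json"))
  invisible(curve)
}

stage_resect <- function(config) {
  d <- stage_dir(config, "resect")
  p <- config$resect
  model <- read_stage_model(config)
  tp <- config$thermo
  scan <- resection_scan(model, thermo_grid(tp), engine = p$engine,
                         seed = child_seed(config$seed, 8),
                         scale = tp$scale, n_steps = tp$n_steps,
                         burn_in = tp$burn_in, thin = tp$thin)
  tab <- scan$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], format_full)
  utils::write.table(tab, file.path(d, "resection.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    cor_strength_dTc = scan$cor_strength_dTc,
    cor_strength_dTc_spearman = scan$cor_strength_dTc_spearman),
    file.path(d, "resection_summary.json"), auto_unbox = TRUE, digits = I(17))
  write_manifest(d, "resect", c(p, list(seed = config$seed)),
                 inputs = file.path(config$out_dir, "fit", "params.json"))
  invisible(scan)
}
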