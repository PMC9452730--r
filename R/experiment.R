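# Orchestration: reproducible end-to-end experiments
# (synth -> preprocess -> train -> neurofeedback -> stats), model-bundle
# persistence and fixture generation.

#' Persist / load a trained classifier bundle
#'
#' The bundle is a directory holding the mask and effect map as NIfTI
#' images plus a YAML file with the weights, bias, selected voxels,
#' standardisation constants and class coding.
#'
#' @param model An \code{nf_model}.
#' @param path Bundle directory.
#' @param affine Voxel-to-world transform for the NIfTI images
#'   (default identity scaled by 3 mm).
#' @return \code{write_model} returns \code{path} invisibly;
#'   \code{read_model} returns an \code{nf_model}.
#' @export
write_model <- function(model, path, affine = sim_grid(dim(model$mask))$affine) {
  stopifnot(inherits(model, "nf_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  mask_img <- RNifti::asNifti(array(as.numeric(model$mask),
                                    dim = dim(model$mask)))
  mask_img <- RNifti::`sform<-`(mask_img, structure(affine, code = 2L))
  RNifti::writeNifti(mask_img, file.path(path, "mask.nii.gz"))
  emap <- array(0, dim = dim(model$mask))
  emap[model$voxel_index] <- model$effect
  e_img <- RNifti::asNifti(emap)
  e_img <- RNifti::`sform<-`(e_img, structure(affine, code = 2L))
  RNifti::writeNifti(e_img, file.path(path, "effect_map.nii.gz"))
  yaml::write_yaml(list(
    weights = as.list(model$weights), bias = model$bias,
    selected = as.list(model$selected),
    standardise = list(mu = as.list(model$standardise$mu),
                       sd = as.list(model$standardise$sd)),
    fraction = model$fraction, cost = model$cost,
    class_coding = as.list(model$class_coding)),
    file.path(path, "model.yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  mask_img <- RNifti::readNifti(file.path(path, "mask.nii.gz"))
  mask <- array(as.numeric(mask_img) > 0.5, dim = dim(mask_img))
  e_img <- RNifti::readNifti(file.path(path, "effect_map.nii.gz"))
  meta <- yaml::read_yaml(file.path(path, "model.yaml"))
  vidx <- which(as.vector(mask))
  structure(list(weights = as.numeric(unlist(meta$weights)),
                 bias = meta$bias,
                 effect = array(as.numeric(e_img), dim = dim(mask))[vidx],
                 selected = as.integer(unlist(meta$selected)),
                 mask = mask, voxel_index = vidx,
                 standardise = list(mu = as.numeric(unlist(meta$standardise$mu)),
                                    sd = as.numeric(unlist(meta$standardise$sd))),
                 fraction = meta$fraction, cost = meta$cost,
                 class_coding = unlist(meta$class_coding)),
            class = "nf_model")
}

#' Experiment configuration
#'
#' Defaults reproduce the study conditions: TR 2 s, 210-volume runs, a
#' tutor trained from 4 runs, 7 patients, 4 training days of 4 runs.
#'
#' @param seed Master seed; every random draw in the experiment derives
#'   from it.
#' @param grid_dim Simulation grid (default 20 x 24 x 20 at 3 mm).
#' @param tr,n_discard,offline_fwhm_mm,online_fwhm_mm Acquisition and
#'   preprocessing settings.
#' @param tutor List: \code{n_runs}, \code{amplitude}, \code{noise_sigma},
#'   \code{ar1}, \code{drift}.
#' @param patients List: \code{n}, \code{fidelity}, \code{learning_rate},
#'   \code{amplitude}, \code{noise_sigma}, \code{ar1}, \code{drift}.
#' @param model List: \code{mask_fraction}, \code{select_fraction},
#'   \code{cost}, \code{label_shift}.
#' @param protocol List: \code{days}, \code{runs_per_day}.
#' @return A list of class \code{nf_experiment_config}.
#' @export
experiment_config <- function(seed = 1,
                              grid_dim = c(20L, 24L, 20L),
                              tr = 2, n_discard = 10,
                              offline_fwhm_mm = 8, online_fwhm_mm = 6,
                              tutor = list(),
                              patients = list(),
                              model = list(),
                              protocol = list()) {
  tutor <- utils::modifyList(list(n_runs = 4, amplitude = 30,
                                  noise_sigma = 1, ar1 = 0.3, drift = 0.5),
                             tutor)
  patients <- utils::modifyList(list(n = 7, fidelity = 0.3,
                                     learning_rate = 0.1, amplitude = 30,
                                     noise_sigma = 1, ar1 = 0.3,
                                     drift = 0.5),
                                patients)
  model <- utils::modifyList(list(mask_fraction = 0.5,
                                  select_fraction = 0.05, cost = 1,
                                  label_shift = 0),
                             model)
  protocol <- utils::modifyList(list(days = 4, runs_per_day = 4), protocol)
  cfg <- list(seed = seed, grid_dim = as.integer(grid_dim), tr = tr,
              n_discard = n_discard, offline_fwhm_mm = offline_fwhm_mm,
              online_fwhm_mm = online_fwhm_mm, tutor = tutor,
              patients = patients, model = model, protocol = protocol)
  class(cfg) <- "nf_experiment_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  required <- c("seed", "grid_dim", "tr", "n_discard", "offline_fwhm_mm",
                "online_fwhm_mm", "tutor", "patients", "model", "protocol")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("invalid experiment config: missing field(s) ",
         paste(missing, collapse = ", "))
  if (is.null(cfg$tutor$n_runs) || cfg$tutor$n_runs < 2)
    stop("invalid experiment config: field 'tutor$n_runs' must be >= 2")
  if (is.null(cfg$patients$n) || cfg$patients$n < 1)
    stop("invalid experiment config: field 'patients$n' must be >= 1")
  if (is.null(cfg$seed)) stop("invalid experiment config: field 'seed'")
  invisible(cfg)
}

# Polynomial rolling hash (mod 2^31 - 1) of a serialised R object, as a
# hex string; used for the reproducibility manifest.
config_hash <- function(object) {
  raw <- serialize(object, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Train the tutor classifier under a configuration
#'
#' Simulates the tutor's training runs, discards the initial volumes,
#' smooths, masks, extracts detrended task features, cross-validates
#' (leave-one-run-out) and fits the final effect-map model on all runs.
#'
#' @param cfg An \code{nf_experiment_config}.
#' @param template Optional pre-built \code{nf_template}.
#' @return List with \code{model}, \code{cv} (an \code{nf_cv_report}),
#'   \code{mask}, \code{template}, \code{paradigm}.
#' @export
train_tutor_classifier <- function(cfg, template = NULL) {
  stopifnot(inherits(cfg, "nf_experiment_config"))
  grid <- sim_grid(cfg$grid_dim)
  if (is.null(template)) template <- tutor_template(grid)
  paradigm <- build_paradigm(tr = cfg$tr)
  tutor <- tutor_profile(template, amplitude = cfg$tutor$amplitude,
                         noise_sigma = cfg$tutor$noise_sigma,
                         ar1_coefficient = cfg$tutor$ar1,
                         drift_amplitude = cfg$tutor$drift)
  identity_params <- norm_params(diag(4), grid$dim, grid$affine,
                                 smoothing_fwhm_mm = cfg$offline_fwhm_mm,
                                 voxel_mm = grid$voxel_mm)
  runs <- lapply(seq_len(cfg$tutor$n_runs), function(r) {
    run <- simulate_run(paradigm, tutor, session = 1,
                        seed = derive_seed(cfg$seed, 101, r))
    run <- discard_initial(run, cfg$n_discard)
    normalize_run(run, identity_params)
  })
  mean_vol <- Reduce(`+`, lapply(runs, function(r) apply(r$data, 1:3, mean))) /
    length(runs)
  mask <- make_mask(mean_vol, cfg$model$mask_fraction)
  features <- extract_features(runs, mask,
                               label_shift = cfg$model$label_shift)
  cv <- cross_validate(features, fraction = cfg$model$select_fraction,
                       cost = cfg$model$cost)
  model <- train_effect_map_model(features,
                                  fraction = cfg$model$select_fraction,
                                  cost = cfg$model$cost)
  list(model = model, cv = cv, mask = mask, template = template,
       paradigm = paradigm, tutor = tutor)
}

#' Run a full end-to-end experiment
#'
#' Trains the tutor classifier, simulates the neurofeedback protocol for
#' every patient, aggregates the accuracy table and computes the group
#' statistics report. When \code{out_dir} is given, all artifacts (model
#' bundle, per-run outcome logs, accuracy table, statistics, manifest
#' with a config hash) are written there; rerunning with the same config
#' reproduces the same numeric-output hash.
#'
#' @param cfg An \code{nf_experiment_config}.
#' @param out_dir Optional artifact directory.
#' @return A list of class \code{nf_experiment}: \code{cv},
#'   \code{model}, \code{logs} (per patient), \code{accuracy_table},
#'   \code{report}, \code{manifest}.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  validate_config(cfg)
  trained <- train_tutor_classifier(cfg)
  logs <- lapply(seq_len(cfg$patients$n), function(i) {
    prof <- patient_profile(trained$template,
                            pattern_fidelity = cfg$patients$fidelity,
                            learning_rate = cfg$patients$learning_rate,
                            seed = derive_seed(cfg$seed, 201, i),
                            amplitude = cfg$patients$amplitude,
                            noise_sigma = cfg$patients$noise_sigma,
                            ar1_coefficient = cfg$patients$ar1,
                            drift_amplitude = cfg$patients$drift)
    run_protocol(prof, trained$model, trained$paradigm,
                 days = cfg$protocol$days,
                 runs_per_day = cfg$protocol$runs_per_day,
                 seed = derive_seed(cfg$seed, 301, i),
                 smoothing_fwhm_mm = cfg$online_fwhm_mm,
                 voxel_mm = sim_grid(cfg$grid_dim)$voxel_mm)
  })
  acc <- do.call(rbind, lapply(logs, function(l) as.vector(t(l$accuracy))))
  table <- accuracy_table(acc, runs_per_day = cfg$protocol$runs_per_day)
  report <- stats_report(table)
  manifest <- list(package_version = as.character(utils::packageVersion("rtnf")),
                   config_hash = config_hash(cfg),
                   output_hash = config_hash(list(acc = acc,
                                                  cv = trained$cv$folds)))
  result <- structure(list(cv = trained$cv, model = trained$model,
                           logs = logs, accuracy_table = table,
                           report = report, manifest = manifest,
                           config = cfg),
                      class = "nf_experiment")
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_model(result$model, file.path(out_dir, "model"),
              affine = sim_grid(result$config$grid_dim)$affine)
  acc <- result$accuracy_table$runs
  utils::write.table(
    data.frame(participant = seq_len(nrow(acc)), acc, check.names = FALSE),
    file.path(out_dir, "accuracy.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  for (i in seq_along(result$logs)) {
    log <- result$logs[[i]]
    for (k in seq_along(log$results))
      utils::write.table(log$results[[k]]$outcomes,
                         file.path(out_dir,
                                   sprintf("patient%02d_run%02d.tsv", i, k)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report_json <- list(
    day_summary = result$report$day_summary,
    day4_ztest = if (!is.null(result$report$day4_ztest))
      list(z = unname(result$report$day4_ztest$statistic),
           p = result$report$day4_ztest$p.value),
    wilcoxon = lapply(result$report$wilcoxon, function(ht)
      if (!is.null(ht)) list(W = unname(ht$statistic), p = ht$p.value)),
    slopes_run = as.numeric(result$report$slopes_run),
    slopes_session = as.numeric(result$report$slopes_session))
  jsonlite::write_json(report_json, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  yaml::write_yaml(result$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Generate the standard test fixtures
#'
#' Three small, fully reproducible datasets: a pair of well-separated
#' Gaussian clouds for the SVM, a single-informative-voxel feature set,
#' and a tutor template plus a 7-patient cohort of subject profiles.
#' Regeneration under the same seed is byte-identical.
#'
#' @param seed Integer seed.
#' @param grid_dim Grid for the cohort fixture (small by default).
#' @return A list with \code{clouds} (\code{x}, \code{y}),
#'   \code{single_voxel} (\code{x}, \code{y}, \code{informative}),
#'   \code{cohort} (\code{template}, \code{patients}).
#' @export
make_fixtures <- function(seed = 1, grid_dim = c(10L, 12L, 10L)) {
  clouds <- with_seed(derive_seed(seed, 1), {
    n <- 40
    x <- rbind(matrix(stats::rnorm(n * 5, mean = 2), ncol = 5),
               matrix(stats::rnorm(n * 5, mean = -2), ncol = 5))
    list(x = x, y = factor(rep(c("HAPPY", "MOTOR"), each = n),
                           levels = c("HAPPY", "MOTOR")))
  })
  single <- with_seed(derive_seed(seed, 2), {
    n <- 60; v <- 200; informative <- 17L
    x <- matrix(stats::rnorm(n * v), ncol = v)
    y <- factor(rep(c("HAPPY", "MOTOR"), length.out = n),
                levels = c("HAPPY", "MOTOR"))
    x[, informative] <- x[, informative] + ifelse(y == "HAPPY", 1.5, -1.5)
    list(x = x, y = y, informative = informative)
  })
  template <- tutor_template(sim_grid(grid_dim))
  patients <- lapply(seq_len(7), function(i)
    patient_profile(template, pattern_fidelity = 0.3, learning_rate = 0.1,
                    seed = derive_seed(seed, 3, i)))
  list(clouds = clouds, single_voxel = single,
       cohort = list(template = template, patients = patients))
}
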