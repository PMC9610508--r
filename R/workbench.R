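#' Experiment configuration profiles
#'
#' Bundles geometry, coils, scan, physics, dataset, architecture and
#' training schedule into one serializable object. Two profiles ship:
#'
#' * `"paper"` — the full torso-scale configuration: 50x28x24 cm body, 1 cm
#'   simulation / 2 cm reconstruction grids, 256-position scan trimmed to
#'   206, 3000 one-object + 15000 two-object cases (66,000 samples), the
#'   full-width network. Generating and training at this scale is a
#'   multi-day CPU job; the profile exists so the full recipe is explicit
#'   and runnable.
#' * `"desk"` — a reduced 24x12x12 cm body with a 64-position scan trimmed
#'   to 48, 4-8 cm perturbations, 600 one-object + 600 two-object cases
#'   (3,600 samples) and a narrow block plan. The same pipeline end to end,
#'   sized for a CPU.
#'
#' @param profile `"paper"` or `"desk"`.
#' @param seed master seed recorded in the config; stages derive named
#'   sub-seeds from it (placement, noise, split, init).
#' @return an `experiment_config`.
#' @export
experiment_config <- function(profile = c("desk", "paper"), seed = 1) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    body <- c(50, 28, 24)
    cfg <- list(
      profile = profile, seed = seed,
      body_extent_cm = body, fine_voxel_cm = 1, coarse_voxel_cm = 2,
      exciter = list(n_wires = 11, pitch_cm = 6, length_cm = 60,
                     y_center_cm = body[2] / 2, z_cm = -6),
      receivers = list(z_cm = body[3] + 6, wide_lobe_cm = 12,
                       narrow_lobe_cm = 4, height_cm = body[2]),
      scan = scan_config(positions = 256, trim = 25),
      # gain from calibrate_signal_gain(): max |S_Diff| of a centred 8 cm
      # insulating reference cuboid maps to 1
      physics = physics_params(frequency_hz = 1.5e6, signal_gain = 8.7969e-8),
      dataset = dataset_config(cases_1obj = 3000, cases_2obj = 15000,
                               length_range_cm = c(6, 10), snr_db = 60),
      split = c(train = 0.65, test = 0.25, val = 0.10),
      arch = arch_spec(input_shape = c(6, 206), output_units = 4200,
                       init = "paper"),
      schedule = training_schedule())
  } else {
    body <- c(24, 12, 12)
    cfg <- list(
      profile = profile, seed = seed,
      body_extent_cm = body, fine_voxel_cm = 1, coarse_voxel_cm = 2,
      exciter = list(n_wires = 11, pitch_cm = 6, length_cm = 30,
                     y_center_cm = body[2] / 2, z_cm = -2),
      receivers = list(z_cm = body[3] + 2, wide_lobe_cm = 8,
                       narrow_lobe_cm = 3, height_cm = body[2]),
      scan = scan_config(positions = 64, trim = 8),
      # gain from calibrate_signal_gain() with a 6 cm reference cuboid
      physics = physics_params(frequency_hz = 1.5e6, signal_gain = 1.8253e-7),
      dataset = dataset_config(cases_1obj = 600, cases_2obj = 600,
                               length_range_cm = c(4, 8), snr_db = 60),
      split = c(train = 0.65, test = 0.25, val = 0.10),
      arch = arch_spec(input_shape = c(6, 48), output_units = 432,
                       stem_filters = 16,
                       block_plan = list(
                         list(type = "residual", filters = 16),
                         list(type = "bottleneck", filters = 32),
                         list(type = "residual", filters = 32)),
                       dense_units = 512, init = "scaled"),
      schedule = training_schedule(epochs1 = 15, epochs2 = 30,
                                   lr_patience = 5))
  }
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> profile '%s': body %gx%gx%g cm, scan %d->%d positions, %d samples\n",
              x$profile, x$body_extent_cm[1], x$body_extent_cm[2],
              x$body_extent_cm[3], x$scan$positions, x$scan$kept,
              dataset_sample_count(x$dataset)))
  invisible(x)
}

#' Build the coil set of a configuration
#'
#' @param config an `experiment_config`.
#' @return list with `exciter` and `receivers` (list of 6 `coil_spec`s).
#' @export
config_coils <- function(config) {
  ex <- config$exciter
  rx <- config$receivers
  list(exciter = undulator_coil(ex$n_wires, ex$pitch_cm, ex$length_cm,
                                ex$y_center_cm, ex$z_cm),
       receivers = receiver_array(rx$height_cm, rx$z_cm,
                                  rx$wide_lobe_cm, rx$narrow_lobe_cm))
}

#' Build the fine simulation grid and scan caches of a configuration
#'
#' @param config an `experiment_config`.
#' @return a `scan_cache` on the fine grid.
#' @export
config_caches <- function(config) {
  grid <- make_body_grid(config$body_extent_cm, config$fine_voxel_cm)
  scan_caches(grid, config_coils(config), config$scan, config$physics)
}

#' Run the full reduced-scale learning experiment
#'
#' One call reproduces the whole study at the configuration's scale:
#' generate the dataset (fine-grid simulation, noise, differential signals,
#' coarse targets), split by geometric case, fit the standardizer on the
#' training split only, train the residual network with the two-phase Huber
#' schedule, and evaluate on the held-out test split plus the two synthetic
#' robustness cases.
#'
#' @param config an `experiment_config` (use the `"desk"` profile unless you
#'   have days of CPU).
#' @param seed master seed overriding the config's.
#' @param caches optional prebuilt `scan_cache`.
#' @param verbose print progress.
#' @return list with the trained `model`, `dataset`, `split`, test-set
#'   `report` (a `metrics_report`), `special` (per-case metrics of the two
#'   robustness cases) and the `config`.
#' @export
run_experiment <- function(config = experiment_config("desk"), seed = NULL,
                           caches = NULL, verbose = FALSE) {
  if (!is.null(seed)) config$seed <- seed
  seed <- config$seed
  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg) if (verbose) message(sprintf("[%6.1fs] %s",
                                                      proc.time()[["elapsed"]] - t0, msg))
  if (is.null(caches)) {
    stage("precomputing coil potential caches")
    caches <- config_caches(config)
  }
  stage("generating dataset")
  ds <- generate_dataset(caches, config$dataset, config$physics, seed = seed,
                         progress = verbose)
  split <- split_dataset(ds$manifest, config$split,
                         seed = derive_seed(seed, "split"))
  tr <- split == "train"; va <- split == "val"; te <- split == "test"
  std <- fit_standardizer(ds$signals[tr, , drop = FALSE])
  xt <- apply_standardizer(std, ds$signals[tr, , drop = FALSE])
  xv <- apply_standardizer(std, ds$signals[va, , drop = FALSE])
  stage(sprintf("training on %d samples (val %d)", sum(tr), sum(va)))
  set.seed(derive_seed(seed, "init"))
  model <- build_model(config$arch)
  model <- train_two_phase(model, xt, ds$targets[tr, , drop = FALSE],
                           xv, ds$targets[va, , drop = FALSE],
                           schedule = config$schedule, std = std,
                           verbose = verbose)
  stage(sprintf("evaluating on %d test samples", sum(te)))
  report <- evaluate_model(model, ds$signals[te, , drop = FALSE],
                           ds$targets[te, , drop = FALSE])
  stage("simulating special robustness cases")
  set.seed(derive_seed(seed, "special"))
  specials <- make_special_cases(caches, config$dataset, config$physics,
                                 max_extent_cm = special_extent(config),
                                 edge_cm = special_edge(config))
  special <- lapply(specials, function(sc) {
    pred <- reconstruct(model, sc$signal)$vectors[1, ]
    list(label = sc$label, target = sc$target, prediction = pred,
         metrics = c(mae = mae(sc$target, pred), mse = mse(sc$target, pred),
                     cc = as.numeric(pearson_cc(sc$target, pred)),
                     ssim = ssim(sc$target, pred)))
  })
  stage("done")
  list(model = model, dataset = ds, split = split, report = report,
       special = special, config = config, caches = caches)
}

# special-case dimensions scale with the profile: at torso scale the overlap
# union spans 13 cm from two 8 cm cuboids; the desk body uses 6 cm cuboids
# with a 9 cm union
special_edge <- function(config) if (config$profile == "paper") 8 else 6
special_extent <- function(config) if (config$profile == "paper") 13 else 9

## ---- persistence / export ------------------------------------------------

#' Write a scan signal as CSV (one row per receiver)
#' @param signal a `scan_signal`.
#' @param path output file.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "scan_signal"))
  utils::write.table(signal$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a scan signal from CSV
#' @param path CSV with one row per receiver.
#' @param kind signal kind label.
#' @export
read_signal_csv <- function(path, kind = "S_Diff") {
  scan_signal(as.matrix(utils::read.table(path, sep = ",", header = FALSE)),
              kind = kind)
}

#' Save / load a dataset container
#'
#' The container is a single RDS file holding signals, targets, manifest and
#' provenance (seed, noise level, grids); a JSON sidecar carries the
#' manifest for external tools.
#'
#' @param ds a `mit_dataset`.
#' @param path output `.rds` path.
#' @param json_manifest also write `<path>.manifest.json`.
#' @export
save_dataset <- function(ds, path, json_manifest = TRUE) {
  stopifnot(inherits(ds, "mit_dataset"))
  saveRDS(ds, path)
  if (json_manifest) {
    m <- as.data.frame(ds$manifest)
    jsonlite::write_json(list(seed = ds$seed, snr_db = ds$snr_db,
                              n_samples = nrow(ds$signals), manifest = m),
                         paste0(path, ".manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)

#' Save / load a trained model checkpoint
#'
#' The checkpoint embeds the architecture spec, all weights and batch-norm
#' statistics, the training history and the standardizer, so inference
#' reproduces exactly.
#'
#' @param model a `mit_model`.
#' @param path `.rds` path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mit_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Export a metrics report as CSV and JSON
#'
#' @param report a `metrics_report`.
#' @param path_prefix files `<prefix>.csv` (per-sample) and `<prefix>.json`
#'   (means) are written.
#' @export
export_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "metrics_report"))
  utils::write.csv(report$per_sample, paste0(path_prefix, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(report$means), paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}

#' Run record with config hash for provenance
#'
#' @param config an `experiment_config`.
#' @param stages named numeric vector of per-stage wall times (seconds).
#' @param artifacts named character vector of artifact paths.
#' @return a `run_record` list.
#' @export
run_record <- function(config, stages = numeric(0), artifacts = character(0)) {
  structure(list(config_hash = config_hash(config),
                 seed = config$seed, profile = config$profile,
                 package_version = as.character(utils::packageVersion("mitnet")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 stages = as.list(stages), artifacts = as.list(artifacts)),
            class = "run_record")
}

#' Stable hash of a configuration
#' @param config any serializable object.
#' @return md5 hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(config, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

#' Plot ground truth and reconstruction as z-slice montages
#'
#' One row per volume (truth on top, reconstruction below), one panel per z
#' slice, shared `[0, 1]` grey scale.
#'
#' @param truth,pred `conductivity_grid`s on the same coarse grid.
#' @param file optional PNG path; plots to the active device when `NULL`.
#' @export
plot_slices <- function(truth, pred, file = NULL) {
  stopifnot(identical(truth$grid$shape, pred$grid$shape))
  nz <- truth$grid$shape[3]
  if (!is.null(file)) grDevices::png(file, width = 160 * nz, height = 340)
  op <- graphics::par(mfrow = c(2, nz), mar = c(0.5, 0.5, 1.2, 0.5))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  gray <- grDevices::gray.colors(64, start = 0, end = 1)
  for (row in list(truth = truth, pred = pred)) {
    for (z in seq_len(nz)) {
      graphics::image(row$sigma[, , z], zlim = c(0, 1), col = gray,
                      axes = FALSE, main = sprintf("z=%d", z), cex.main = 0.8)
    }
  }
  invisible(NULL)
}
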