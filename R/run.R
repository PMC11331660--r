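# Run orchestration: a validated configuration object, scale presets, and
# a driver that executes one training arm over a list of seeds and writes
# metrics, history, and a reproducibility manifest.

#' Scale presets for detector, trainer, federated, and synthesizer settings
#'
#' `full` embeds the full-scale recipes (500 Hz / 10 s records, 100-epoch
#' training with patience 10, 30 federated rounds of 20 local epochs,
#' 2000-epoch GAN with patience 100, Adam 1e-4, batches 256 and 64); `tiny`
#' and `small` shrink the problem so every arm runs on one CPU in minutes.
#'
#' @param scale `"tiny"`, `"small"`, or `"full"`
#' @return named list of sub-configurations
#' @export
scale_preset <- function(scale = c("tiny", "small", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(det = detector_config(),
         train = train_config(epochs = 100L, patience = 10L, lr = 1e-4,
                              batch_size = 256L),
         federated = federated_config(rounds = 30L, local_epochs = 20L,
                                      local_patience = 5L),
         synth = synth_config(samples = 5000L, fs = 500,
                              gen_channels = c(256L, 128L, 64L),
                              critic_channels = c(64L, 128L, 256L),
                              epochs = 2000L, patience = 100L,
                              batch_size = 64L),
         sim_fs = 500, sim_duration = 10)
  } else {
    ep <- if (scale == "tiny") 10L else 20L
    list(det = detector_config(leads = 12L, input_samples = 313L,
                               width_multiplier = 1 / 8),
         train = train_config(epochs = ep, patience = 4L, lr = 1e-3,
                              batch_size = 32L),
         federated = federated_config(rounds = 3L, local_epochs = 4L,
                                      local_patience = 2L, lr = 1e-3,
                                      batch_size = 32L),
         synth = synth_config(samples = 313L, fs = 125,
                              gen_channels = c(32L, 16L, 8L),
                              critic_channels = c(8L, 16L, 32L),
                              epochs = if (scale == "tiny") 12L else 30L,
                              patience = 6L, batch_size = 16L),
         sim_fs = 125, sim_duration = 2.504)
  }
}

#' Run configuration
#'
#' @param arm `"supervised"`, `"federated"`, `"finetune"`, or `"continual"`
#' @param scale a [scale_preset()] name
#' @param order site ordering for sequential arms
#' @param seeds nonempty integer vector; the arm runs once per seed and the
#'   manifest reports per-seed metrics with mean and SD
#' @param algorithm federated flavour (federated arm only)
#' @param output_dir directory for metrics, history, and manifest
#' @param scenario_scale scenario preset for the built-in simulator
#' @return an object of class `run_config`
#' @export
run_config <- function(arm = c("supervised", "federated", "finetune",
                               "continual"),
                       scale = c("tiny", "small", "full"),
                       order = c("small_to_large", "large_to_small"),
                       seeds = 1L, algorithm = c("fedavg", "fedprox"),
                       output_dir = tempfile("cardiocl-run-"),
                       scenario_scale = NULL) {
  arm <- match.arg(arm); scale <- match.arg(scale)
  order <- match.arg(order); algorithm <- match.arg(algorithm)
  if (length(seeds) < 1) stop("seeds must be nonempty")
  if (is.null(scenario_scale))
    scenario_scale <- if (scale == "full") "fourdb" else scale
  structure(list(arm = arm, scale = scale, order = order,
                 seeds = as.integer(seeds), algorithm = algorithm,
                 output_dir = output_dir, scenario_scale = scenario_scale),
            class = "run_config")
}

# simulate, preprocess, and split the scenario's four sites
build_scenario_sites <- function(config, preset, seed) {
  sc <- default_multicenter_scenario(config$scenario_scale,
                                     fs = preset$sim_fs,
                                     duration = preset$sim_duration)
  sites <- lapply(seq_along(sc$profiles), function(i) {
    s <- simulate_site(sc$profiles[[i]], sc$config,
                       seed = derive_seed(seed, paste0("scenario", i)),
                       site_id = sc$site_ids[i])
    s <- preprocess_site(s, low = 0.5, high = 40)
    split_dataset(s, seed = derive_seed(seed, paste0("split", i)),
                  stratify = TRUE)
  })
  sites
}

#' Execute a configured run over its seeds
#'
#' For each seed: simulates the multicenter scenario, runs the configured
#' arm, and records final per-site test AUROCs plus the arm's own artifacts
#' (selection history for the continual arm, round metrics for the
#' federated arm). Writes a JSON manifest with per-seed metrics and their
#' mean and SD to `output_dir`.
#'
#' @param config a [run_config()]
#' @return the manifest, invisibly (also written to
#'   `file.path(config$output_dir, "manifest.json")`)
#' @export
run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$arm == "continual" || config$arm == "finetune") {
    # sequential arms need >= 2 sites; the built-in scenario always has 4
  }
  preset <- scale_preset(config$scale)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "metrics.jsonl")
  per_seed <- list()
  for (seed in config$seeds) {
    sites <- build_scenario_sites(config, preset, seed)
    ordered <- order_sites(sites, config$order)
    out <- switch(config$arm,
      supervised = {
        res <- train_supervised(sites, preset$det, preset$train, seed = seed,
                                log_path = log_path)
        list(det = res$det)
      },
      federated = {
        res <- run_federated(sites, preset$det, preset$federated,
                             algorithm = config$algorithm, seed = seed,
                             log_path = log_path)
        list(det = res$det, extra = list(best_round = res$best_round))
      },
      finetune = {
        res <- run_finetuning(ordered, preset$det, preset$train, seed = seed,
                              log_path = log_path)
        list(det = res$det,
             extra = list(forgetting = forgetting_trajectory(res$stage_metrics)))
      },
      continual = {
        sel_cfg <- selection_config(train = preset$train,
                                    max_decay_steps = 3L)
        res <- run_multicenter(ordered, sel_cfg, preset$det, preset$synth,
                               seed = seed, log_path = log_path)
        hist_path <- file.path(config$output_dir,
                               sprintf("selection-history-seed%d.json", seed))
        jsonlite::write_json(
          lapply(unclass(res$history), function(e)
            e[c("site_id", "chosen", "p_star")]),
          hist_path, auto_unbox = TRUE, pretty = TRUE)
        list(det = res$det, extra = list(history = res$history))
      })
    site_metrics <- Filter(Negate(is.null), lapply(sites, function(s) {
      recs <- partition_records(s, "test")
      if (length(unique(vapply(recs, function(r) r$label, integer(1)))) < 2) {
        warning("test partition of ", s$site_id,
                " is single-class; site skipped in the weighted metric")
        return(NULL)
      }
      ev <- evaluate_detector(out$det, recs)
      list(site_id = s$site_id, n = s$size_n, auroc = ev$auroc)
    }))
    per_seed[[as.character(seed)]] <- list(
      seed = seed,
      test_auroc = stats::setNames(
        vapply(site_metrics, function(m) m$auroc, numeric(1)),
        vapply(site_metrics, function(m) m$site_id, character(1))),
      weighted_test_auroc = weighted_auroc(site_metrics))
  }
  overall <- vapply(per_seed, function(p) p$weighted_test_auroc, numeric(1))
  manifest <- list(
    arm = config$arm, scale = config$scale, order = config$order,
    seeds = config$seeds,
    per_seed = per_seed,
    weighted_test_auroc_mean = mean(overall),
    weighted_test_auroc_sd = if (length(overall) > 1) stats::sd(overall) else 0,
    config_hash = content_hash(unclass(config)))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
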