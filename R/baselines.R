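# Training arms used as comparators: federated averaging (FedAvg), its
# proximally regularized variant (FedProx), and sequential finetuning.
# Supervised training lives in train.R; every arm consumes identical
# preprocessed site datasets.

#' Federated configuration
#'
#' Defaults follow the full-scale recipe: 30 rounds of 20 local epochs with
#' local patience 5; desk-scale runs shrink them.
#'
#' @param rounds communication rounds
#' @param local_epochs local training epochs per round
#' @param local_patience local early-stopping patience
#' @param mu FedProx proximal coefficient (`>= 0`; 0 reduces to FedAvg's
#'   local objective)
#' @param lr Adam learning rate
#' @param batch_size local minibatch size
#' @return an object of class `federated_config`
#' @export
federated_config <- function(rounds = 30L, local_epochs = 20L,
                             local_patience = 5L, mu = 0.01, lr = 1e-4,
                             batch_size = 256L) {
  stopifnot(rounds >= 1, local_epochs >= 1, mu >= 0)
  structure(list(rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 local_patience = as.integer(local_patience),
                 mu = mu, lr = lr, batch_size = as.integer(batch_size)),
            class = "federated_config")
}

#' Size-weighted federated parameter average
#'
#' `w = sum_k (n_k / n) w_k` element-wise, `n = sum_k n_k`.
#'
#' @param client_params list of parameter trees (or flat vectors) with
#'   identical index spaces
#' @param client_sizes positive record counts `n_k`
#' @return averaged parameters in the same form as the inputs
#' @export
fedavg_aggregate <- function(client_params, client_sizes) {
  stopifnot(length(client_params) == length(client_sizes),
            all(client_sizes > 0))
  flats <- lapply(client_params, function(p)
    if (is.list(p)) flatten_params(p) else as.numeric(p))
  npar <- unique(lengths(flats))
  if (length(npar) != 1) stop("client parameter index spaces do not match")
  w <- client_sizes / sum(client_sizes)
  agg <- numeric(npar)
  for (k in seq_along(flats)) agg <- agg + w[k] * flats[[k]]
  if (is.list(client_params[[1]])) unflatten_params(agg, client_params[[1]])
  else agg
}

#' FedProx local objective
#'
#' `base_loss + (mu / 2) * || w_local - w_global ||_2^2`.
#'
#' @param base_loss scalar local loss
#' @param w_local,w_global parameter trees or flat vectors with identical
#'   index spaces
#' @param mu proximal coefficient
#' @return scalar penalized loss
#' @export
fedprox_local_loss <- function(base_loss, w_local, w_global, mu) {
  fl <- if (is.list(w_local)) flatten_params(w_local) else as.numeric(w_local)
  fg <- if (is.list(w_global)) flatten_params(w_global) else as.numeric(w_global)
  if (length(fl) != length(fg)) stop("parameter index spaces do not match")
  base_loss + mu / 2 * sum((fl - fg)^2)
}

# weighted average of buffer trees (batch-norm running stats travel with
# the parameters in aggregation)
aggregate_buffers <- function(client_buffers, client_sizes) {
  w <- client_sizes / sum(client_sizes)
  flats <- lapply(client_buffers, flatten_params)
  agg <- numeric(length(flats[[1]]))
  for (k in seq_along(flats)) agg <- agg + w[k] * flats[[k]]
  unflatten_params(agg, client_buffers[[1]])
}

#' Federated training across sites
#'
#' Per round: broadcast the global model, train locally on every site (20
#' epochs, early stop on local validation AUROC), aggregate by
#' [fedavg_aggregate()]. Returns the round whose aggregate maximizes the
#' size-weighted validation AUROC across sites.
#'
#' @param sites list of split [site_dataset()] objects
#' @param det_config a [detector_config()]
#' @param config a [federated_config()]
#' @param algorithm `"fedavg"` or `"fedprox"`
#' @param seed integer seed
#' @param log_path optional JSON-lines log
#' @return list with `det` (best aggregate), `round_metrics` (data.frame of
#'   per-round weighted validation AUROC), `best_round`
#' @export
run_federated <- function(sites, det_config, config = federated_config(),
                          algorithm = c("fedavg", "fedprox"), seed = 0L,
                          log_path = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(length(sites) >= 1)
  det <- build_detector(det_config, seed = derive_seed(seed, "federated"))
  sizes <- vapply(sites, function(s) length(s$partitions$train), numeric(1))
  local_cfg <- train_config(epochs = config$local_epochs,
                            patience = config$local_patience,
                            lr = config$lr, batch_size = config$batch_size)
  best <- list(metric = -Inf, theta = flatten_params(det$params),
               buffers = det$buffers, round = 0L)
  round_metrics <- data.frame(round = integer(0), weighted_val_auroc = numeric(0))
  for (rd in seq_len(config$rounds)) {
    client_params <- list(); client_buffers <- list()
    theta_global <- flatten_params(det$params)
    for (k in seq_along(sites)) {
      local <- det
      pen <- if (algorithm == "fedprox")
        penalty_fedprox(config$mu, theta_global) else penalty_none()
      res <- train_detector(local, sites[[k]], local_cfg, pen,
                            seed = derive_seed(seed, paste0("r", rd, "c", k)),
                            log_path = log_path,
                            log_tag = paste0(algorithm, "-r", rd, "-",
                                             sites[[k]]$site_id))
      client_params[[k]] <- res$det$params
      client_buffers[[k]] <- res$det$buffers
    }
    det$params <- fedavg_aggregate(client_params, sizes)
    det$buffers <- aggregate_buffers(client_buffers, sizes)
    sm <- lapply(seq_along(sites), function(k) {
      ev <- evaluate_detector(det, partition_records(sites[[k]], "val"))
      list(site_id = sites[[k]]$site_id, n = sites[[k]]$size_n,
           auroc = ev$auroc)
    })
    wm <- weighted_auroc(sm)
    round_metrics <- rbind(round_metrics,
                           data.frame(round = rd, weighted_val_auroc = wm))
    log_metric(log_path, list(tag = paste0(algorithm, "-round"), round = rd,
                              weighted_val_auroc = wm))
    if (wm > best$metric)
      best <- list(metric = wm, theta = flatten_params(det$params),
                   buffers = det$buffers, round = rd)
  }
  det$params <- unflatten_params(best$theta, det$params)
  det$buffers <- best$buffers
  list(det = det, round_metrics = round_metrics, best_round = best$round,
       best_weighted_val_auroc = best$metric)
}

#' Sequential finetuning across an ordered list of sites
#'
#' Trains on each site in turn with no regularization toward earlier sites,
#' logging every site's validation AUROC after every stage - the trajectory
#' whose per-site drop quantifies catastrophic forgetting.
#'
#' @param sites ordered list (>= 2) of split [site_dataset()] objects
#' @param det_config a [detector_config()]
#' @param config a [train_config()]
#' @param seed integer seed
#' @param log_path optional JSON-lines log
#' @return list with `det` (final model), `stage_metrics` (stages x sites
#'   matrix of validation AUROCs), `order` (site ids)
#' @export
run_finetuning <- function(sites, det_config, config = train_config(),
                           seed = 0L, log_path = NULL) {
  if (length(sites) < 2) stop("run_finetuning needs at least 2 sites")
  det <- build_detector(det_config, seed = derive_seed(seed, "finetune"))
  ids <- vapply(sites, function(s) s$site_id, character(1))
  stage_metrics <- matrix(NA_real_, length(sites), length(sites),
                          dimnames = list(stage = ids, site = ids))
  for (k in seq_along(sites)) {
    res <- train_detector(det, sites[[k]], config, penalty_none(),
                          seed = derive_seed(seed, paste0("stage", k)),
                          log_path = log_path,
                          log_tag = paste0("finetune-", ids[k]))
    det <- res$det
    for (j in seq_along(sites)) {
      ev <- evaluate_detector(det, partition_records(sites[[j]], "val"))
      stage_metrics[k, j] <- ev$auroc
      log_metric(log_path, list(tag = "finetune-stage", stage = ids[k],
                                site = ids[j], val_auroc = ev$auroc))
    }
  }
  list(det = det, stage_metrics = stage_metrics, order = ids)
}
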