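# On-line continual-learning method selection: finetune baseline, candidate
# training with continual hyperparameter decay, evaluation on accumulated
# synthetic (fake) data, selection, and the multicenter driver chaining
# institutions in a chosen order.

#' Selection configuration
#'
#' @param candidates ordered method candidates; ties in the fake-data score
#'   break toward the earlier candidate
#' @param lambda_init initial importance hyperparameter (maximal stability)
#' @param temperature distillation temperature for LwF
#' @param alpha decay factor applied to `lambda` when the current-site
#'   validation AUROC misses the reference threshold, `0 < alpha < 1`
#' @param delta performance drop margin in the reference threshold
#' @param reference_mode threshold formula: `"drop_margin"` uses
#'   `(1 - delta) * p_star` (the literal published formula, inert at
#'   `delta = 0.95`); `"fraction_retained"` uses `delta * p_star` (the
#'   reading under which the decay loop is active). Both are available
#'   because the published text is internally inconsistent about them.
#' @param max_decay_steps bound on decay iterations
#' @param train a [train_config()] for all candidate/baseline training
#' @param fake_cap maximum fake records synthesized per site
#' @return an object of class `selection_config`
#' @export
selection_config <- function(candidates = c("LwF", "EWC", "MAS"),
                             lambda_init = 1, temperature = 10,
                             alpha = 0.9, delta = 0.95,
                             reference_mode = c("drop_margin",
                                                "fraction_retained"),
                             max_decay_steps = 20L,
                             train = train_config(),
                             fake_cap = 2000L) {
  reference_mode <- match.arg(reference_mode)
  stopifnot(alpha > 0, alpha < 1, delta >= 0, delta <= 1,
            max_decay_steps >= 1, length(candidates) >= 1,
            all(candidates %in% c("LwF", "EWC", "MAS")))
  structure(list(candidates = candidates, lambda_init = lambda_init,
                 temperature = temperature, alpha = alpha, delta = delta,
                 reference_mode = reference_mode,
                 max_decay_steps = as.integer(max_decay_steps),
                 train = train, fake_cap = as.integer(fake_cap)),
            class = "selection_config")
}

reference_threshold <- function(config, p_star) {
  switch(config$reference_mode,
         drop_margin = (1 - config$delta) * p_star,
         fraction_retained = config$delta * p_star)
}

#' Finetune the previous model on a site without any regularization
#'
#' Step 1 of the selection algorithm: establishes the baseline performance
#' `p_star` that the candidate methods' thresholds refer to.
#'
#' @param det_prev the previous institution's selected `detector`
#' @param site a split [site_dataset()]
#' @param config a [selection_config()]
#' @param seed integer seed
#' @param log_path optional JSON-lines log
#' @return a `train_result` (its `best_val_metric` is `p_star`)
#' @export
finetune_baseline <- function(det_prev, site, config, seed = 0L,
                              log_path = NULL) {
  train_detector(det_prev, site, config$train, penalty_none(), seed = seed,
                 log_path = log_path, log_tag = "finetune-baseline")
}

method_penalty <- function(method_id, state, lambda, config) {
  switch(method_id,
         LwF = penalty_lwf(lambda, config$temperature, state$old_model),
         EWC = {
           if (is.null(state$fisher)) stop("no Fisher weights in state")
           penalty_quadratic(lambda, state$fisher, state$theta_old)
         },
         MAS = {
           if (is.null(state$omega)) stop("no MAS weights in state")
           penalty_quadratic(lambda, state$omega, state$theta_old)
         },
         stop("unknown method_id: ", method_id))
}

#' Train one continual-learning candidate with hyperparameter decay
#'
#' Step 2 of the selection algorithm. `lambda` starts at `lambda_init`
#' (maximal stability). The model is trained from the previous parameters
#' with the candidate's penalty; if the resulting validation AUROC falls
#' below the reference threshold, `lambda` is multiplied by `alpha` and
#' training restarts from the previous parameters, up to `max_decay_steps`
#' attempts (then the best attempt so far is returned with the trace marked
#' exhausted). Afterwards the method state is refreshed on the current
#' site: new parameter snapshot, re-estimated Fisher/MAS weights, final
#' `lambda`.
#'
#' @param det_prev the previous institution's selected `detector`
#' @param site a split [site_dataset()]
#' @param method_id `"LwF"`, `"EWC"`, or `"MAS"`
#' @param prev_state a [method_state()] from the previous institution
#' @param p_star baseline performance from [finetune_baseline()]
#' @param config a [selection_config()]
#' @param seed integer seed (the same seed as the baseline makes a
#'   zero-strength penalty reproduce it bitwise)
#' @param importance_samples records used to refresh importance weights
#' @param log_path optional JSON-lines log
#' @return list with `result` (a `train_result` whose `decay_trace` is a
#'   data.frame of `(lambda, val_metric)` rows) and `state` (refreshed
#'   [method_state()])
#' @export
train_with_method <- function(det_prev, site, method_id, prev_state, p_star,
                              config, seed = 0L, importance_samples = 64L,
                              log_path = NULL) {
  stopifnot(inherits(prev_state, "method_state"))
  threshold <- reference_threshold(config, p_star)
  lambda <- config$lambda_init
  trace <- data.frame(lambda = numeric(0), val_metric = numeric(0))
  best <- NULL
  exhausted <- TRUE
  for (step in seq_len(config$max_decay_steps)) {
    pen <- method_penalty(method_id, prev_state, lambda, config)
    res <- train_detector(det_prev, site, config$train, pen, seed = seed,
                          log_path = log_path,
                          log_tag = paste0(method_id, "-lambda-", signif(lambda, 4)))
    trace <- rbind(trace, data.frame(lambda = lambda,
                                     val_metric = res$best_val_metric))
    if (is.null(best) || res$best_val_metric > best$best_val_metric)
      best <- res
    if (res$best_val_metric >= threshold) {
      best <- res
      exhausted <- FALSE
      break
    }
    lambda <- config$alpha * lambda
  }
  best$decay_trace <- trace
  attr(best$decay_trace, "exhausted") <- exhausted
  final_lambda <- trace$lambda[nrow(trace)]
  theta_new <- flatten_params(best$det$params)
  state <- method_state(
    theta_old = theta_new,
    fisher = estimate_fisher(best$det, site, importance_samples, seed),
    omega = estimate_mas_importance(best$det, site, importance_samples, seed),
    lambda = final_lambda, temperature = config$temperature,
    old_model = best$det, method_id = method_id)
  list(result = best, state = state)
}

#' Weighted-average AUROC of a model on accumulated fake datasets
#'
#' Step 3 of the selection algorithm: candidates are compared on the
#' synthetic data accumulated from all previous institutions, weighting each
#' fake set by its size. Single-class fake sets are skipped with a warning.
#'
#' @param det a `detector`
#' @param fake_sets nonempty list of fake datasets (see
#'   [generate_fake_dataset()])
#' @return weighted average AUROC
#' @export
evaluate_on_fake <- function(det, fake_sets) {
  stopifnot(length(fake_sets) >= 1)
  metrics <- list()
  for (fs in fake_sets) {
    labels <- vapply(fs$records, function(r) r$label, integer(1))
    if (length(unique(labels)) < 2) {
      warning("fake set from ", fs$source_site,
              " has a single class; skipped")
      next
    }
    ev <- evaluate_detector(det, fs$records)
    metrics[[length(metrics) + 1L]] <-
      list(site_id = fs$source_site, n = length(fs$records), auroc = ev$auroc)
  }
  if (length(metrics) == 0) stop("all fake sets were single-class")
  weighted_auroc(metrics)
}

#' Select the best-performing candidate by fake-data score
#'
#' Argmax over candidates of the fake-data score; exact ties break toward
#' the earliest entry (the candidate order of the configuration).
#'
#' @param results named list (in candidate order) of entries with fields
#'   `result` (a `train_result`) and `fake_score`
#' @return list with `method_id`, `det`, `fake_score`
#' @export
select_method <- function(results) {
  stopifnot(length(results) >= 1)
  scores <- vapply(results, function(r) r$fake_score, numeric(1))
  k <- which.max(scores) # first maximum = earliest candidate on ties
  list(method_id = names(results)[k], det = results[[k]]$result$det,
       fake_score = scores[[k]])
}

#' Order sites by dataset size
#'
#' @param sites list of [site_dataset()] objects
#' @param order `"small_to_large"` or `"large_to_small"`; equal sizes break
#'   by `site_id` (lexicographic, stable)
#' @return reordered list
#' @export
order_sites <- function(sites, order = c("small_to_large", "large_to_small")) {
  order <- match.arg(order)
  sizes <- vapply(sites, function(s) s$size_n, numeric(1))
  ids <- vapply(sites, function(s) s$site_id, character(1))
  o <- order(sizes, ids, decreasing = c(order == "large_to_small", FALSE),
             method = "radix")
  sites[o]
}

## ---- multicenter driver ----------------------------------------------------

#' Run the continual-learning framework across an ordered list of sites
#'
#' The first institution trains a fresh supervised model (there is nothing
#' to preserve), trains the waveform synthesizer on its data, and emits a
#' fake dataset. Every later institution runs the selection algorithm
#' (baseline finetune, per-candidate decay training, fake-data evaluation,
#' selection) against the accumulated fake sets, then warm-starts the
#' synthesizer on its own data and appends its fake set. The only objects
#' passed between institutions are the selected parameters, the method
#' state, the synthesizer state, and the fake sets - never raw records
#' (asserted on every hand-off).
#'
#' @param sites ordered list (>= 2) of split [site_dataset()] objects
#' @param config a [selection_config()]
#' @param det_config a [detector_config()]
#' @param synth_config a [synth_config()]
#' @param seed integer seed
#' @param importance_samples records for importance estimation per site
#' @param log_path optional JSON-lines log
#' @return list with `det` (final selected detector), `history` (class
#'   `selection_history`), and `handoff` (the final hand-off archive)
#' @export
run_multicenter <- function(sites, config, det_config, synth_config,
                            seed = 0L, importance_samples = 64L,
                            log_path = NULL) {
  if (length(sites) < 2) stop("run_multicenter needs at least 2 sites")
  all_real_ids <- unlist(lapply(sites, function(s)
    vapply(s$records, function(r) r$record_id, character(1))))
  history <- list()
  # --- institution 1: plain supervised training + synthesizer
  s1 <- sites[[1]]
  res1 <- train_supervised(s1, det_config, config$train,
                           seed = derive_seed(seed, "site1"),
                           log_path = log_path)
  det <- res1$det
  synth <- train_synthesizer(s1, synth_config, init = NULL,
                             seed = derive_seed(seed, "gan-site1"),
                             log_path = log_path)
  fake_sets <- list(make_site_fake(synth, s1, config$fake_cap,
                                   derive_seed(seed, "fake-site1")))
  state <- method_state(
    theta_old = flatten_params(det$params),
    fisher = estimate_fisher(det, s1, importance_samples, seed),
    omega = estimate_mas_importance(det, s1, importance_samples, seed),
    lambda = config$lambda_init, temperature = config$temperature,
    old_model = det)
  history[[1]] <- list(site_id = s1$site_id, chosen = "supervised",
                       p_star = res1$best_val_metric,
                       fake_scores = NULL, lambdas = NULL,
                       checkpoint = list(theta = flatten_params(det$params),
                                         buffers = det$buffers))
  handoff <- make_handoff(det, state, synth, fake_sets, all_real_ids)
  # --- institutions 2..K: selection algorithm
  for (k in 2:length(sites)) {
    sk <- sites[[k]]
    sseed <- derive_seed(seed, paste0("site", k))
    base <- finetune_baseline(det, sk, config, seed = sseed,
                              log_path = log_path)
    p_star <- base$best_val_metric
    results <- list()
    for (m in config$candidates) {
      tr <- train_with_method(det, sk, m, state, p_star, config,
                              seed = sseed,
                              importance_samples = importance_samples,
                              log_path = log_path)
      tr$fake_score <- evaluate_on_fake(tr$result$det, fake_sets)
      results[[m]] <- tr
    }
    sel <- select_method(results)
    det <- sel$det
    state <- results[[sel$method_id]]$state
    state$old_model <- det
    synth <- train_synthesizer(sk, synth_config, init = synth,
                               seed = derive_seed(seed, paste0("gan-site", k)),
                               log_path = log_path)
    fake_sets[[length(fake_sets) + 1L]] <-
      make_site_fake(synth, sk, config$fake_cap,
                     derive_seed(seed, paste0("fake-site", k)))
    history[[k]] <- list(
      site_id = sk$site_id, chosen = sel$method_id, p_star = p_star,
      fake_scores = vapply(results, function(r) r$fake_score, numeric(1)),
      lambdas = vapply(results, function(r)
        r$result$decay_trace$lambda[nrow(r$result$decay_trace)], numeric(1)),
      checkpoint = list(theta = flatten_params(det$params),
                        buffers = det$buffers))
    handoff <- make_handoff(det, state, synth, fake_sets, all_real_ids)
  }
  structure(list(det = det,
                 history = structure(history, class = "selection_history"),
                 handoff = handoff),
            class = "multicenter_result")
}

# synthesize a fake dataset matching a site's training prevalence, capped
make_site_fake <- function(synth, site, cap, seed) {
  train_recs <- partition_records(site, "train")
  labels <- vapply(train_recs, function(r) r$label, integer(1))
  n_fake <- min(length(train_recs), cap)
  n1 <- round(n_fake * mean(labels))
  n_per_group <- c(`0` = n_fake - n1, `1` = n1)
  pools <- list(
    `0` = lapply(train_recs[labels == 0L], function(r)
      list(age = r$age, sex = r$sex)),
    `1` = lapply(train_recs[labels == 1L], function(r)
      list(age = r$age, sex = r$sex)))
  generate_fake_dataset(synth, pools, n_per_group, seed,
                        source_site = site$site_id)
}

#' Build and validate an inter-site hand-off archive
#'
#' @param det selected `detector`
#' @param state a [method_state()]
#' @param synth a synthesizer state
#' @param fake_sets list of fake datasets
#' @param real_ids character vector of all real record ids (for the privacy
#'   assertion)
#' @return a `handoff` list with a manifest of content hashes
#' @export
make_handoff <- function(det, state, synth, fake_sets, real_ids) {
  h <- structure(list(theta = flatten_params(det$params),
                      det_config = det$config,
                      method_state = state,
                      synth_state = synth,
                      fake_sets = fake_sets),
                 class = "handoff")
  h$manifest <- list(
    fields = setdiff(names(h), "manifest"),
    n_fake_sets = length(fake_sets),
    hashes = list(theta = content_hash(h$theta),
                  synth = content_hash(lapply(synth$groups, function(g)
                    g$gen_params))))
  assert_handoff_private(h, real_ids)
  h
}

#' Assert that a hand-off archive carries no raw records
#'
#' Structural privacy check: the archive may contain only model parameters,
#' method state, synthesizer state, fake sets, and a manifest; every record
#' inside the fake sets must be flagged synthetic and must not reuse any
#' real record id.
#'
#' @param handoff a `handoff` archive
#' @param real_ids character vector of all real record ids
#' @return TRUE invisibly; stops on violation
#' @export
assert_handoff_private <- function(handoff, real_ids) {
  allowed <- c("theta", "det_config", "method_state", "synth_state",
               "fake_sets", "manifest")
  extra <- setdiff(names(handoff), allowed)
  if (length(extra) > 0)
    stop("hand-off archive has unexpected fields: ",
         paste(extra, collapse = ", "))
  for (fs in handoff$fake_sets) {
    if (!isTRUE(fs$synthetic)) stop("fake set not flagged synthetic")
    ids <- vapply(fs$records, function(r) r$record_id, character(1))
    clash <- intersect(ids, real_ids)
    if (length(clash) > 0)
      stop("fake set reuses real record ids: ",
           paste(utils::head(clash, 3), collapse = ", "))
  }
  invisible(TRUE)
}

#' Save a hand-off archive to disk
#'
#' Writes the archive as an RDS payload plus a JSON manifest with content
#' hashes, the institution-to-institution transfer format.
#'
#' @param handoff a `handoff` archive
#' @param path output directory
#' @return invisibly, `path`
#' @export
write_handoff <- function(handoff, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(handoff[setdiff(names(handoff), "manifest")],
          file.path(path, "handoff.rds"))
  jsonlite::write_json(handoff$manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Retrospective per-stage validation trajectory of a multicenter run
#'
#' Rebuilds each stage's selected model from the checkpoints stored in the
#' selection history and evaluates it on every site's validation partition.
#' This is an analysis-time convenience over already-exchanged model
#' checkpoints; the training loop itself never touches other sites' data.
#'
#' @param result a [run_multicenter()] result
#' @param sites the site list the run was trained on (training order)
#' @return stages x sites matrix of validation AUROCs
#' @export
multicenter_trajectory <- function(result, sites) {
  stopifnot(inherits(result, "multicenter_result"))
  det <- result$det
  ids <- vapply(sites, function(s) s$site_id, character(1))
  m <- matrix(NA_real_, length(result$history), length(sites),
              dimnames = list(stage = vapply(result$history,
                                             function(e) e$site_id,
                                             character(1)),
                              site = ids))
  for (k in seq_along(result$history)) {
    ck <- result$history[[k]]$checkpoint
    det$params <- unflatten_params(ck$theta, det$params)
    det$buffers <- ck$buffers
    for (j in seq_along(sites)) {
      ev <- evaluate_detector(det, partition_records(sites[[j]], "val"))
      m[k, j] <- ev$auroc
    }
  }
  m
}

#' @export
print.selection_history <- function(x, ...) {
  for (e in x) {
    cat(sprintf("%s: %s (p* = %.3f)", e$site_id, e$chosen, e$p_star))
    if (!is.null(e$fake_scores))
      cat("  fake scores:",
          paste(sprintf("%s=%.3f", names(e$fake_scores), e$fake_scores),
                collapse = " "))
    cat("\n")
  }
  invisible(x)
}
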