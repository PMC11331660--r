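# Detector training: class-balanced cross-entropy, Adam, early stopping on
# validation AUROC, and a penalty hook through which the continual-learning
# and federated regularizers plug into the same loop.

#' Training configuration
#'
#' Defaults are the full-scale recipe (Adam, learning rate 1e-4, batch 256,
#' 100 epochs, patience 10); desk-scale runs shrink `epochs`, `patience`,
#' and `batch_size` proportionally.
#'
#' @param epochs maximum training epochs
#' @param patience early-stopping patience in epochs without validation
#'   AUROC improvement
#' @param lr Adam learning rate
#' @param batch_size minibatch size
#' @return an object of class `train_config`
#' @export
train_config <- function(epochs = 100L, patience = 10L, lr = 1e-4,
                         batch_size = 256L) {
  stopifnot(epochs >= 1, patience >= 1, lr > 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), patience = as.integer(patience),
                 lr = lr, batch_size = as.integer(batch_size)),
            class = "train_config")
}

#' Class-balanced cross-entropy loss
#'
#' Weighted sum `sum_i w_i * l_i` where `l_i` is record `i`'s cross-entropy
#' and `w_i = N / count(training labels equal to y_i)`. The class counts
#' come from the full training partition, not from the batch, so
#' single-class batches remain finite.
#'
#' @param logits n x l matrix of class scores (rows = records)
#' @param labels length-n 0-based class labels of the batch
#' @param train_labels labels of the full training partition (weight source)
#' @return scalar weighted loss
#' @export
balanced_ce_loss <- function(logits, labels, train_labels = labels) {
  stopifnot(nrow(logits) == length(labels))
  labels <- as.integer(labels)
  counts <- table(factor(train_labels, levels = sort(unique(train_labels))))
  if (any(!(labels %in% as.integer(names(counts)))))
    stop("batch contains a label absent from the training partition")
  N <- length(train_labels)
  w <- N / as.numeric(counts[as.character(labels)])
  p <- softmax_cols(t(logits))
  li <- -log(pmax(p[cbind(labels + 1L, seq_along(labels))], 1e-12))
  sum(w * li)
}

# class weights w_c = N / count_c from a training-partition label vector
class_weights <- function(train_labels, n_labels = 2L) {
  counts <- tabulate(train_labels + 1L, nbins = n_labels)
  if (any(counts == 0))
    stop("a class is absent from the training partition")
  length(train_labels) / counts
}

## ---- penalty hooks ---------------------------------------------------------

#' Penalty hooks for the training loop
#'
#' A penalty plugs an extra loss term (and its gradient) into
#' [train_detector()]: `penalty_none()` trains plainly;
#' `penalty_quadratic()` anchors parameters to a snapshot with per-parameter
#' weights (`lambda * sum_i w_i (theta_i - theta_old_i)^2`, the EWC/MAS
#' form); `penalty_lwf()` distills toward a frozen old model's tempered
#' outputs; `penalty_fedprox()` adds the federated proximal term
#' `(mu/2) ||theta - theta_global||^2`. A zero-strength penalty leaves the
#' training trajectory bitwise unchanged.
#'
#' @param lambda importance weight of the penalty
#' @param weights nonnegative per-parameter weights (quadratic)
#' @param theta_old,theta_global flat parameter snapshots
#' @param temperature distillation temperature (LwF)
#' @param old_model frozen `detector` providing distillation targets (LwF)
#' @param mu proximal coefficient (FedProx)
#' @return a penalty object consumed by [train_detector()]
#' @name penalties
NULL

#' @rdname penalties
#' @export
penalty_none <- function() list(type = "none")

#' @rdname penalties
#' @export
penalty_quadratic <- function(lambda, weights, theta_old) {
  stopifnot(length(weights) == length(theta_old), lambda >= 0)
  list(type = "quadratic", lambda = lambda, weights = weights,
       theta_old = theta_old)
}

#' @rdname penalties
#' @export
penalty_lwf <- function(lambda, temperature, old_model) {
  stopifnot(lambda >= 0, temperature > 0, inherits(old_model, "detector"))
  list(type = "lwf", lambda = lambda, temperature = temperature,
       old_model = old_model)
}

#' @rdname penalties
#' @export
penalty_fedprox <- function(mu, theta_global) {
  stopifnot(mu >= 0)
  list(type = "fedprox", mu = mu, theta_global = theta_global)
}

# flat-parameter gradient contribution of a penalty (NULL if none)
penalty_flat_grad <- function(penalty, theta) {
  switch(penalty$type,
         none = NULL,
         lwf = NULL,
         quadratic = 2 * penalty$lambda * penalty$weights *
           (theta - penalty$theta_old),
         fedprox = penalty$mu * (theta - penalty$theta_global),
         stop("unknown penalty type"))
}

penalty_flat_loss <- function(penalty, theta) {
  switch(penalty$type,
         none = 0, lwf = 0,
         quadratic = penalty$lambda *
           sum(penalty$weights * (theta - penalty$theta_old)^2),
         fedprox = penalty$mu / 2 * sum((theta - penalty$theta_global)^2))
}

## ---- evaluation ------------------------------------------------------------

#' Evaluate a detector on a list of records
#'
#' @param det a `detector`
#' @param records list of `ecg_record` objects (both classes present for
#'   AUROC)
#' @param batch_size evaluation batch size
#' @return list with `auroc`, `scores` (probability of class 1), `labels`
#' @export
evaluate_detector <- function(det, records, batch_size = 256L) {
  n <- length(records)
  scores <- numeric(n); labels <- integer(n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    b <- records_to_batch(records[idx])
    p <- predict_proba(det, b)
    scores[idx] <- p[, 2]
    labels[idx] <- b$y
  }
  list(auroc = auroc(scores, labels), scores = scores, labels = labels)
}

## ---- core loop -------------------------------------------------------------

#' Train a detector on one site
#'
#' Minimizes the class-balanced cross-entropy (plus an optional
#' [penalties] hook) with Adam on the site's training partition,
#' early-stopping on the validation partition's AUROC and returning the
#' best-validation checkpoint. Deterministic given `seed`; a fixed penalty
#' does not perturb the RNG stream, so a zero-strength penalty reproduces
#' plain training bitwise.
#'
#' @param det a `detector` (starting point; not modified)
#' @param site a split [site_dataset()]
#' @param config a [train_config()]
#' @param penalty a [penalties] hook
#' @param seed integer seed
#' @param log_path optional JSON-lines metrics log
#' @param log_tag tag recorded with each log line
#' @return a `train_result`: `det` (best checkpoint), `best_val_metric`,
#'   `best_epoch`, `epochs_run`
#' @export
train_detector <- function(det, site, config, penalty = penalty_none(),
                           seed = 0L, log_path = NULL, log_tag = "train") {
  stopifnot(inherits(det, "detector"), inherits(config, "train_config"),
            is.list(penalty), !is.null(penalty$type)) # force args before seeding
  if (is.null(site$partitions)) stop("site has no train/val/test partitions")
  train_recs <- partition_records(site, "train")
  val_recs <- partition_records(site, "val")
  if (length(train_recs) == 0 || length(val_recs) == 0)
    stop("empty train or validation partition")
  tb <- records_to_batch(train_recs)
  n <- length(train_recs)
  wts <- class_weights(tb$y, det$config$n_labels)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "train"))
  theta <- flatten_params(det$params)
  opt <- adam_init(length(theta))
  # the incoming model is the epoch-0 checkpoint candidate, so training
  # returns it unchanged when no epoch improves on it
  best <- list(metric = evaluate_detector(det, val_recs)$auroc,
               theta = theta, buffers = det$buffers, epoch = 0L)
  bad_epochs <- 0L; epochs_run <- 0L
  lwf <- penalty$type == "lwf"
  Tdist <- if (lwf) penalty$temperature else 1
  for (epoch in seq_len(config$epochs)) {
    epochs_run <- epoch
    perm <- sample.int(n)
    epoch_loss <- 0
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- perm[s:min(n, s + config$batch_size - 1L)]
      B <- length(idx)
      xw <- tb$xw[, , idx, drop = FALSE]
      xd <- tb$xd[, idx, drop = FALSE]
      y <- tb$y[idx]
      det$params <- unflatten_params(theta, det$params)
      fw <- detector_fwd(det, xw, xd, training = TRUE)
      det$buffers <- fw$buffers
      p <- softmax_cols(fw$logits)
      w <- wts[y + 1L]
      li <- -log(pmax(p[cbind(y + 1L, seq_len(B))], 1e-12))
      loss <- sum(w * li) / B
      glogits <- p * rep(w, each = det$config$n_labels)
      glogits[cbind(y + 1L, seq_len(B))] <-
        glogits[cbind(y + 1L, seq_len(B))] - w
      glogits <- glogits / B
      if (lwf) {
        fo <- detector_fwd(penalty$old_model, xw, xd, training = FALSE)
        po <- softmax_cols(fo$logits / Tdist)
        pn <- softmax_cols(fw$logits / Tdist)
        glogits <- glogits +
          penalty$lambda * (pn - po) / (Tdist * B)
        loss <- loss - penalty$lambda *
          sum(po * log(pmax(pn, 1e-12))) / B
      }
      bk <- detector_bwd(det, fw$caches, glogits)
      g <- flatten_params(bk$gparams)
      pg <- penalty_flat_grad(penalty, theta)
      if (!is.null(pg)) g <- g + pg
      loss <- loss + penalty_flat_loss(penalty, theta)
      st <- adam_step(theta, g, opt, lr = config$lr)
      theta <- st$theta; opt <- st$state
      epoch_loss <- epoch_loss + loss * B
    }
    det$params <- unflatten_params(theta, det$params)
    vm <- evaluate_detector(det, val_recs)$auroc
    log_metric(log_path, list(tag = log_tag, epoch = epoch,
                              loss = epoch_loss / n, val_auroc = vm))
    if (vm > best$metric) {
      best <- list(metric = vm, theta = theta, buffers = det$buffers,
                   epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs > config$patience) break
    }
  }
  det$params <- unflatten_params(best$theta, det$params)
  det$buffers <- best$buffers
  structure(list(det = det, best_val_metric = best$metric,
                 best_epoch = best$epoch, epochs_run = epochs_run,
                 decay_trace = NULL),
            class = "train_result")
}

#' Supervised training on one site or a merged set of sites
#'
#' Builds a fresh detector and trains it with the class-balanced
#' cross-entropy, selecting the epoch with the best validation AUROC.
#'
#' @param datasets a [site_dataset()] or list of them (merged; each must be
#'   split already, partitions are concatenated)
#' @param det_config a [detector_config()]
#' @param config a [train_config()]
#' @param seed integer seed
#' @param log_path optional JSON-lines metrics log
#' @return a `train_result` with fields `det`, `best_val_metric`,
#'   `epochs_run`
#' @export
train_supervised <- function(datasets, det_config, config = train_config(),
                             seed = 0L, log_path = NULL) {
  if (inherits(datasets, "site_dataset")) datasets <- list(datasets)
  merged <- merge_sites(datasets)
  det <- build_detector(det_config, seed = derive_seed(seed, "supervised"))
  train_detector(det, merged, config, penalty_none(), seed = seed,
                 log_path = log_path, log_tag = "supervised")
}

#' Merge several split site datasets into one (concatenating partitions)
#'
#' @param datasets list of split [site_dataset()] objects
#' @param site_id identifier of the merged dataset
#' @return a [site_dataset()] with merged partitions
#' @export
merge_sites <- function(datasets, site_id = "merged") {
  stopifnot(length(datasets) >= 1)
  records <- list(); parts <- list(train = integer(0), val = integer(0),
                                   test = integer(0))
  off <- 0L
  for (d in datasets) {
    if (is.null(d$partitions)) stop("merge_sites requires split datasets")
    records <- c(records, d$records)
    for (p in names(parts)) parts[[p]] <- c(parts[[p]], d$partitions[[p]] + off)
    off <- off + d$size_n
  }
  site_dataset(records, site_id, parts)
}
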