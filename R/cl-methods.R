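# Regularization-based continual-learning candidates: knowledge
# distillation (LwF), elastic weight consolidation (EWC, diagonal empirical
# Fisher), and memory-aware synapses (MAS).

#' Temperature distillation of a probability vector
#'
#' Raises each probability to `1/T` and renormalizes:
#' `out_i = p_i^(1/T) / sum_j p_j^(1/T)`. `T = 1` is the identity; large `T`
#' flattens toward the uniform distribution. Applied to a softmax output
#' this equals re-softmaxing the logits at temperature `T`.
#'
#' @param probs nonnegative vector summing to 1 (within 1e-6), or a matrix
#'   with one probability vector per row
#' @param temperature `T > 0`
#' @return distilled probabilities, same shape
#' @export
distill <- function(probs, temperature) {
  stopifnot(temperature > 0)
  if (is.matrix(probs)) return(t(apply(probs, 1, distill, temperature)))
  if (sum(probs) == 0) stop("cannot distill a zero vector")
  stopifnot(all(probs >= 0), abs(sum(probs) - 1) < 1e-6)
  q <- probs^(1 / temperature)
  q / sum(q)
}

#' Learning-without-Forgetting loss
#'
#' `L_new + lambda * mean_batch(-sum_i distill(y_o)^(i) log distill(yhat_o)^(i))`:
#' the new-task loss plus a distillation cross-entropy between the frozen
#' old model's recorded probabilities and the training model's current
#' probabilities, both tempered at `T`.
#'
#' @param new_task_loss scalar new-task loss
#' @param old_recorded matrix (rows = records) of the frozen previous
#'   model's probabilities on the current batch
#' @param old_current matrix of the training model's current probabilities
#'   on the same records
#' @param lambda old-task importance `lambda >= 0`
#' @param temperature distillation temperature
#' @return scalar total loss
#' @export
lwf_loss <- function(new_task_loss, old_recorded, old_current, lambda,
                     temperature) {
  if (is.vector(old_recorded)) old_recorded <- matrix(old_recorded, nrow = 1)
  if (is.vector(old_current)) old_current <- matrix(old_current, nrow = 1)
  if (nrow(old_recorded) != nrow(old_current))
    stop("recorded and current batches differ in size")
  po <- distill(old_recorded, temperature)
  pn <- distill(old_current, temperature)
  if (nrow(old_recorded) == 1) { po <- matrix(po, nrow = 1); pn <- matrix(pn, nrow = 1) }
  penalty <- mean(-rowSums(po * log(pmax(pn, 1e-12))))
  new_task_loss + lambda * penalty
}

## ---- model adapters --------------------------------------------------------
# The importance estimators work on any model exposing (1) flat parameters,
# (2) an output vector per record, and (3) flat parameter gradients given an
# output-space gradient. Detectors and small analytic toys share this
# interface, so estimator tests can use exact hand-checkable models.

#' Output vector of a model on one record
#' @param model a supported model (`detector` or `linear_logit`)
#' @param rec one record (an `ecg_record`, or for toys a list with `x`)
#' @return numeric output (pre-softmax scores)
#' @export
model_output <- function(model, rec) UseMethod("model_output")

#' Flat parameter gradient of `sum(output * gout)` on one record
#' @param model a supported model
#' @param rec one record
#' @param gout gradient in output space
#' @return numeric vector aligned with the model's flat parameters
#' @export
model_output_grad <- function(model, rec, gout) UseMethod("model_output_grad")

#' Flat parameter vector of a model
#' @param model a supported model
#' @return numeric vector
#' @export
model_flat_params <- function(model) UseMethod("model_flat_params")

#' @export
model_output.detector <- function(model, rec) {
  b <- records_to_batch(list(rec))
  fw <- detector_fwd(model, b$xw, b$xd, training = FALSE)
  as.numeric(fw$logits)
}

#' @export
model_output_grad.detector <- function(model, rec, gout) {
  b <- records_to_batch(list(rec))
  fw <- detector_fwd(model, b$xw, b$xd, training = FALSE, keep_cache = TRUE)
  bk <- detector_bwd(model, fw$caches, matrix(gout, ncol = 1))
  flatten_params(bk$gparams)
}

#' @export
model_flat_params.detector <- function(model) flatten_params(model$params)

#' Linear two-class toy model with scores `(0, theta . x)`
#'
#' A minimal analytic model for validating the importance estimators: the
#' positive-class probability is `sigmoid(theta . x)` and all gradients are
#' available in closed form.
#'
#' @param theta numeric parameter vector
#' @return an object of class `linear_logit`
#' @export
linear_logit <- function(theta) {
  structure(list(theta = as.numeric(theta)), class = "linear_logit")
}

#' @export
model_output.linear_logit <- function(model, rec) {
  c(0, sum(model$theta * rec$x))
}

#' @export
model_output_grad.linear_logit <- function(model, rec, gout) {
  gout[2] * rec$x
}

#' @export
model_flat_params.linear_logit <- function(model) model$theta

# label accessor shared by both record styles
record_label <- function(rec) {
  if (!is.null(rec$label)) rec$label else rec$y
}

## ---- importance estimators -------------------------------------------------

#' Diagonal empirical Fisher information
#'
#' `F_i = mean_k (d log p(y_k | x_k; theta) / d theta_i)^2` over `n_samples`
#' records sampled from `data`, using each record's ground-truth label.
#' Entries are nonnegative; large entries mark parameters whose perturbation
#' most changes the fitted likelihood.
#'
#' @param model a supported model (see [model_output()])
#' @param data list of records, or a split [site_dataset()] (train partition
#'   is used)
#' @param n_samples number of records to average over (default: all)
#' @param seed integer seed for the subsample
#' @return numeric vector of per-parameter weights
#' @export
estimate_fisher <- function(model, data, n_samples = NULL, seed = 0L) {
  recs <- importance_records(data, n_samples, seed)
  npar <- length(model_flat_params(model))
  F <- numeric(npar)
  for (rec in recs) {
    z <- model_output(model, rec)
    p <- exp(z - max(z)); p <- p / sum(p)
    y <- record_label(rec)
    gout <- -p; gout[y + 1L] <- gout[y + 1L] + 1 # d log p(y)/d z
    g <- model_output_grad(model, rec, gout)
    F <- F + g^2
  }
  F / length(recs)
}

#' Memory-aware-synapses importance weights
#'
#' `Omega_i = mean_k | d ||M(x_k; theta)||_2^2 / d theta_i |` where `M` is
#' the model's pre-softmax output vector. Records' labels are not used.
#'
#' @inheritParams estimate_fisher
#' @return numeric vector of per-parameter weights
#' @export
estimate_mas_importance <- function(model, data, n_samples = NULL, seed = 0L) {
  recs <- importance_records(data, n_samples, seed)
  npar <- length(model_flat_params(model))
  Om <- numeric(npar)
  for (rec in recs) {
    z <- model_output(model, rec)
    g <- model_output_grad(model, rec, 2 * z) # d ||z||^2 / d theta
    Om <- Om + abs(g)
  }
  Om / length(recs)
}

importance_records <- function(data, n_samples, seed) {
  recs <- if (inherits(data, "site_dataset")) {
    if (!is.null(data$partitions)) partition_records(data, "train")
    else data$records
  } else data
  if (length(recs) == 0) stop("no records to estimate importance from")
  if (!is.null(n_samples)) {
    if (n_samples <= 0) stop("n_samples must be positive")
    if (n_samples < length(recs)) {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(derive_seed(seed, "importance-sample"))
      recs <- recs[sort(sample.int(length(recs), n_samples))]
    }
  }
  recs
}

## ---- method state and penalties --------------------------------------------

#' State a continual-learning method carries between institutions
#'
#' Bundles everything the candidate regularizers need from the previous
#' institution: the old parameter snapshot, the Fisher and MAS importance
#' weights estimated there, the current importance hyperparameter `lambda`,
#' the distillation temperature, and a frozen copy of the old model (for
#' recording distillation targets on current inputs).
#'
#' @param theta_old flat parameter snapshot
#' @param fisher Fisher weights aligned with `theta_old` (EWC), or NULL
#' @param omega MAS weights aligned with `theta_old`, or NULL
#' @param lambda importance hyperparameter (`>= 0`)
#' @param temperature distillation temperature (`> 0`)
#' @param old_model frozen `detector` producing old-task outputs, or NULL
#' @param method_id optional label of the method that produced this state
#' @return an object of class `method_state`
#' @export
method_state <- function(theta_old, fisher = NULL, omega = NULL, lambda = 1,
                         temperature = 10, old_model = NULL,
                         method_id = NA_character_) {
  stopifnot(lambda >= 0, temperature > 0)
  if (!is.null(fisher) && length(fisher) != length(theta_old))
    stop("fisher weights do not match the parameter snapshot")
  if (!is.null(omega) && length(omega) != length(theta_old))
    stop("omega weights do not match the parameter snapshot")
  structure(list(theta_old = theta_old, fisher = fisher, omega = omega,
                 lambda = lambda, temperature = temperature,
                 old_model = old_model, method_id = method_id),
            class = "method_state")
}

#' Elastic-weight-consolidation penalty
#'
#' `lambda * sum_i F_i (theta_new_i - theta_old_i)^2`.
#'
#' @param theta_new flat parameter vector (or a `detector`)
#' @param state a [method_state()] with `fisher` present
#' @return scalar penalty
#' @export
ewc_penalty <- function(theta_new, state) {
  if (inherits(theta_new, "detector")) theta_new <- flatten_params(theta_new$params)
  if (is.null(state$fisher)) stop("state has no Fisher weights")
  if (length(theta_new) != length(state$theta_old))
    stop("parameter index spaces do not match")
  state$lambda * sum(state$fisher * (theta_new - state$theta_old)^2)
}

#' Memory-aware-synapses penalty
#'
#' `lambda * sum_i Omega_i (theta_new_i - theta_old_i)^2`; structurally the
#' EWC penalty with the Fisher weights replaced by MAS importances.
#'
#' @param theta_new flat parameter vector (or a `detector`)
#' @param state a [method_state()] with `omega` present
#' @return scalar penalty
#' @export
mas_penalty <- function(theta_new, state) {
  if (inherits(theta_new, "detector")) theta_new <- flatten_params(theta_new$params)
  if (is.null(state$omega)) stop("state has no MAS weights")
  if (length(theta_new) != length(state$theta_old))
    stop("parameter index spaces do not match")
  state$lambda * sum(state$omega * (theta_new - state$theta_old)^2)
}
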