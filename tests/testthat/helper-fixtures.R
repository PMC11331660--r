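# Shared fixtures, built in code and cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# a tiny preprocessed, split site (~90 records at 125 Hz / 313 samples)
tiny_site <- function(seed = 11, n = 90, site_id = "tsite",
                      prevalence = 0.5, ...) {
  key <- paste0("site-", seed, "-", n, "-", site_id, "-", prevalence)
  fixture(key, function() {
    sc <- sim_config(leads = 12L, fs = 125, duration = 2.504)
    prof <- site_profile(n = n, arrhythmia_prevalence = prevalence, ...)
    s <- simulate_site(prof, sc, seed = seed, site_id = site_id)
    s <- preprocess_site(s)
    split_dataset(s, seed = seed, stratify = TRUE)
  })
}

# detector configuration matching the tiny site
tiny_det_config <- function(multiplier = 1 / 8) {
  detector_config(leads = 12L, input_samples = 313L,
                  width_multiplier = multiplier)
}

tiny_train_config <- function(epochs = 6L) {
  train_config(epochs = epochs, patience = 3L, lr = 1e-3, batch_size = 32L)
}

tiny_synth_config <- function(epochs = 8L) {
  synth_config(samples = 313L, fs = 125, latent_dim = 8L,
               gen_channels = c(16L, 12L, 8L),
               critic_channels = c(8L, 12L, 16L),
               kernel = 9L, batch_size = 16L, epochs = epochs, patience = 4L)
}

# toy records for the importance-estimator oracles
toy_records <- function(theta_len, n, seed = 3) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    list(x = stats::rnorm(theta_len), y = sample(0:1, 1)))
}

# finite-difference gradient of f at theta
fd_grad <- function(f, theta, eps = 1e-6) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (f(tp) - f(tm)) / (2 * eps)
  }, numeric(1))
}

# hand-crafted critic whose input gradient has a closed form: kernel-1
# single-channel conv (large bias keeps leaky-ReLU linear) + unit read-out;
# grad_x = gain * w %o% d with ||w|| = ||d|| = 1, so ||grad_x|| = gain
unit_gradient_critic <- function(leads = 3L, samples = 32L, gain = 1) {
  cfg <- synth_config(samples = samples, leads = leads, fs = 125,
                      latent_dim = 4L, gen_channels = c(4L, 4L, 4L),
                      critic_channels = c(1L), kernel = 1L,
                      critic_strides = c(1L), phase_shuffle = 0L)
  p <- cardiocl:::critic_init(cfg)
  w <- rep(1 / sqrt(leads), leads)
  p$convs$conv1$W <- matrix(w, ncol = 1)
  p$convs$conv1$b <- 100
  d <- rep(1 / sqrt(samples), samples)
  p$dense$W <- matrix(d * gain, ncol = 1)
  p$dense$b <- 0
  list(params = p, config = cfg)
}
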