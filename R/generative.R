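# WGAN-GP waveform synthesizer: a WaveGAN-style 1D generator/critic pair
# trained per label group (with / without arrhythmia), with warm-start
# transfer between institutions and privacy-oriented fake-data construction
# (synthetic waveforms randomly paired with real demographic pairs).
#
# The critic contains no batch norm (a requirement of the gradient
# penalty), uses leaky-ReLU activations and phase shuffle; the generator
# uses nearest-neighbour upsampling + convolution stages and a tanh output,
# matching the [-1, 1] range of preprocessed records. The gradient-penalty
# parameter gradients are computed by an exact manual double-backward pass:
# with activation masks and shuffle shifts frozen, the critic's
# input-gradient map is linear in the activations, so differentiating the
# penalty through the backward pass reduces to a second (transposed)
# traversal of the same frozen graph.

#' Synthesizer configuration
#'
#' @param samples output waveform length in samples
#' @param leads channels (default 12)
#' @param fs sampling frequency attached to generated records
#' @param latent_dim latent dimension
#' @param gen_channels channel widths of the generator stages
#' @param critic_channels channel widths of the critic stages
#' @param kernel convolution kernel size
#' @param upsample per-stage upsampling factors (product >= samples /
#'   initial length)
#' @param critic_strides per-stage critic strides
#' @param phase_shuffle max phase-shuffle shift in samples (0 disables)
#' @param lr Adam learning rate
#' @param batch_size minibatch size
#' @param critic_steps critic updates per generator update
#' @param gp_weight gradient-penalty weight
#' @param epochs maximum training epochs
#' @param patience early-stop patience on the negative critic loss
#' @param alternation `"updates"` (critic_steps inner updates, the standard
#'   inner loop) or `"epochs"` (critic_steps whole epochs of critic
#'   training per generator epoch)
#' @return an object of class `synth_config`
#' @export
synth_config <- function(samples, leads = 12L, fs = 500,
                         latent_dim = 16L,
                         gen_channels = c(64L, 32L, 16L),
                         critic_channels = c(16L, 32L, 64L),
                         kernel = 9L, upsample = c(4L, 4L, 4L),
                         critic_strides = c(4L, 4L, 4L),
                         phase_shuffle = 2L,
                         lr = 1e-4, batch_size = 64L, critic_steps = 5L,
                         gp_weight = 10, epochs = 2000L, patience = 100L,
                         alternation = c("updates", "epochs")) {
  alternation <- match.arg(alternation)
  stopifnot(length(gen_channels) == length(upsample),
            length(critic_channels) == length(critic_strides),
            critic_steps >= 1, gp_weight >= 0, samples >= 16)
  structure(list(samples = as.integer(samples), leads = as.integer(leads),
                 fs = fs, latent_dim = as.integer(latent_dim),
                 gen_channels = as.integer(gen_channels),
                 critic_channels = as.integer(critic_channels),
                 kernel = as.integer(kernel),
                 upsample = as.integer(upsample),
                 critic_strides = as.integer(critic_strides),
                 phase_shuffle = as.integer(phase_shuffle),
                 lr = lr, batch_size = as.integer(batch_size),
                 critic_steps = as.integer(critic_steps),
                 gp_weight = gp_weight, epochs = as.integer(epochs),
                 patience = as.integer(patience), alternation = alternation),
            class = "synth_config")
}

## ---- generator --------------------------------------------------------------

gen_init <- function(cfg) {
  l0 <- ceiling(cfg$samples / prod(cfg$upsample))
  ch <- cfg$gen_channels
  n <- length(ch)
  convs <- vector("list", n)
  for (i in seq_len(n)) {
    cin <- ch[i]
    cout <- if (i < n) ch[i + 1] else cfg$leads
    convs[[i]] <- conv1d_init(cin, cfg$kernel, cout)
  }
  names(convs) <- paste0("conv", seq_len(n))
  list(dense = dense_init(cfg$latent_dim, ch[1] * l0), convs = convs)
}

gen_meta <- function(cfg) {
  l0 <- ceiling(cfg$samples / prod(cfg$upsample))
  list(l0 = as.integer(l0), gen_len = as.integer(l0 * prod(cfg$upsample)),
       crop_off = as.integer((l0 * prod(cfg$upsample) - cfg$samples) %/% 2))
}

upsample_fwd <- function(x, u) {
  if (u == 1) return(x)
  x[, rep(seq_len(dim(x)[2]), each = u), , drop = FALSE]
}

upsample_bwd <- function(gout, u, L) {
  if (u == 1) return(gout)
  d <- dim(gout)
  g <- gout
  dim(g) <- c(d[1], u, L, d[3])
  # sum over the repeated positions
  out <- g[, 1, , , drop = FALSE]
  for (j in 2:u) out <- out + g[, j, , , drop = FALSE]
  dim(out) <- c(d[1], L, d[3])
  out
}

gen_fwd <- function(params, cfg, z, keep_cache = TRUE) {
  meta <- gen_meta(cfg)
  N <- ncol(z)
  h0 <- dense_fwd(z, params$dense$W, params$dense$b)
  r0 <- relu_fwd(h0)
  x <- array(r0$out, c(cfg$gen_channels[1], meta$l0, N))
  n <- length(cfg$gen_channels)
  caches <- vector("list", n)
  lens <- integer(n)
  for (i in seq_len(n)) {
    Lin <- dim(x)[2]
    x <- upsample_fwd(x, cfg$upsample[i])
    cv <- conv1d_fwd(x, params$convs[[i]]$W, params$convs[[i]]$b,
                     cfg$kernel, 1L, cache = keep_cache)
    if (i < n) {
      rl <- relu_fwd(cv$out)
      x <- rl$out
      caches[[i]] <- list(conv = cv$cache, mask = rl$mask, Lin = Lin)
    } else {
      y <- tanh(cv$out)
      x <- y
      caches[[i]] <- list(conv = cv$cache, tanh_out = y, Lin = Lin)
    }
    lens[i] <- Lin
  }
  out <- x[, meta$crop_off + seq_len(cfg$samples), , drop = FALSE]
  list(out = out,
       cache = if (keep_cache) list(z = z, r0 = r0, meta = meta,
                                    caches = caches, full_len = dim(x)[2]))
}

gen_bwd <- function(params, cfg, cache, gout) {
  meta <- cache$meta
  N <- dim(gout)[3]
  n <- length(cfg$gen_channels)
  g <- array(0, c(cfg$leads, cache$full_len, N))
  g[, meta$crop_off + seq_len(cfg$samples), ] <- gout
  gconvs <- vector("list", n)
  for (i in n:1) {
    cc <- cache$caches[[i]]
    if (i == n) g <- g * (1 - cc$tanh_out^2) else g <- relu_bwd(g, cc$mask)
    cb <- conv1d_bwd(g, params$convs[[i]]$W, cc$conv)
    gconvs[[i]] <- list(W = cb$gW, b = cb$gb)
    g <- upsample_bwd(cb$gx, cfg$upsample[i], cc$Lin)
  }
  names(gconvs) <- names(params$convs)
  gh <- g
  dim(gh) <- c(cfg$gen_channels[1] * meta$l0, N)
  gh <- relu_bwd(gh, cache$r0$mask)
  gd <- dense_bwd(gh, cache$z, params$dense$W)
  list(dense = list(W = gd$gW, b = gd$gb), convs = gconvs)
}

## ---- critic -----------------------------------------------------------------

critic_init <- function(cfg) {
  ch <- cfg$critic_channels
  n <- length(ch)
  convs <- vector("list", n)
  L <- cfg$samples
  for (i in seq_len(n)) {
    cin <- if (i == 1) cfg$leads else ch[i - 1]
    convs[[i]] <- conv1d_init(cin, cfg$kernel, ch[i])
    L <- ceiling(L / cfg$critic_strides[i])
  }
  names(convs) <- paste0("conv", seq_len(n))
  list(convs = convs, dense = dense_init(ch[n] * L, 1L))
}

phase_shuffle_fwd <- function(x, shifts) {
  L <- dim(x)[2]
  for (i in seq_along(shifts)) {
    s <- shifts[i] %% L
    if (s != 0)
      x[, , i] <- x[, c((L - s + 1):L, 1:(L - s)), i] # circular right shift
  }
  x
}

phase_shuffle_bwd <- function(g, shifts) phase_shuffle_fwd(g, -shifts)

# Forward pass; shifts are drawn here (one per sample per shuffled layer)
# unless supplied. Returns per-sample scores and the frozen-graph cache.
critic_fwd <- function(params, cfg, x, shifts = NULL, keep_cache = TRUE) {
  n <- length(cfg$critic_channels)
  N <- dim(x)[3]
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    cv <- conv1d_fwd(x, params$convs[[i]]$W, params$convs[[i]]$b,
                     cfg$kernel, cfg$critic_strides[i], cache = keep_cache)
    rl <- lrelu_fwd(cv$out)
    x <- rl$out
    sh <- NULL
    if (cfg$phase_shuffle > 0 && i < n) {
      sh <- if (is.null(shifts)) {
        sample.int(2L * cfg$phase_shuffle + 1L, N, replace = TRUE) -
          cfg$phase_shuffle - 1L
      } else shifts[[i]]
      x <- phase_shuffle_fwd(x, sh)
    }
    caches[[i]] <- list(conv = cv$cache, mask = rl$mask, shifts = sh)
  }
  d <- dim(x)
  h <- x; dim(h) <- c(d[1] * d[2], N)
  score <- as.numeric(dense_fwd(h, params$dense$W, params$dense$b))
  list(score = score,
       cache = if (keep_cache) list(caches = caches, h = h, feat_dim = d))
}

# Backward from per-sample score gradients. Returns parameter gradients,
# input gradients, and the gradient arriving at each conv's output (needed
# by the penalty's double backward).
critic_bwd <- function(params, cfg, cache, gscore) {
  N <- length(gscore)
  gd <- dense_bwd(matrix(gscore, 1, N), cache$h, params$dense$W)
  g <- gd$gx
  dim(g) <- cache$feat_dim
  n <- length(cfg$critic_channels)
  gconvs <- vector("list", n)
  vs <- vector("list", n)
  for (i in n:1) {
    cc <- cache$caches[[i]]
    if (!is.null(cc$shifts)) g <- phase_shuffle_bwd(g, cc$shifts)
    g <- lrelu_bwd(g, cc$mask)
    vs[[i]] <- g # gradient at conv i's output
    cb <- conv1d_bwd(g, params$convs[[i]]$W, cc$conv)
    gconvs[[i]] <- list(W = cb$gW, b = cb$gb)
    g <- cb$gx
  }
  names(gconvs) <- names(params$convs)
  list(gparams = list(convs = gconvs, dense = list(W = gd$gW, b = gd$gb)),
       gx = g, vs = vs, gscore = gscore)
}

#' WGAN gradient penalty
#'
#' Draws per-sample interpolates `eps * x_real + (1 - eps) * x_fake` with
#' `eps ~ U(0, 1)` and returns the mean of
#' `(||grad_xhat critic(xhat)||_2 - 1)^2`. Zero exactly when every
#' interpolate's critic gradient has unit norm.
#'
#' @param critic list with `params` and `config` (a [synth_config()]), as
#'   stored per group in a synthesizer state
#' @param real_batch,fake_batch arrays (leads x samples x n), same shape
#' @param seed integer seed for the interpolation draws
#' @return scalar penalty
#' @export
gradient_penalty <- function(critic, real_batch, fake_batch, seed = 0L) {
  if (!identical(dim(real_batch), dim(fake_batch)))
    stop("real and fake batches differ in shape")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "gp"))
  xhat <- gp_interpolate(real_batch, fake_batch)
  gp_pass(critic$params, critic$config, xhat, want_grads = FALSE)$gp
}

gp_interpolate <- function(real_batch, fake_batch) {
  N <- dim(real_batch)[3]
  eps <- stats::runif(N)
  xhat <- real_batch
  for (i in seq_len(N))
    xhat[, , i] <- eps[i] * real_batch[, , i] + (1 - eps[i]) * fake_batch[, , i]
  xhat
}

# Penalty value and (optionally) its exact parameter gradients via the
# frozen-graph double backward described in the header comment.
gp_pass <- function(params, cfg, xhat, want_grads = TRUE) {
  N <- dim(xhat)[3]
  fw <- critic_fwd(params, cfg, xhat, keep_cache = TRUE)
  bk <- critic_bwd(params, cfg, fw$cache, rep(1, N))
  g <- bk$gx
  gm <- g; dim(gm) <- c(prod(dim(g)[1:2]), N)
  gn <- sqrt(colSums(gm^2))
  gp <- mean((gn - 1)^2)
  if (!want_grads) return(list(gp = gp))
  a <- 2 * (gn - 1) / pmax(gn, 1e-12) / N
  um <- sweep(gm, 2, a, `*`)
  u <- array(um, dim(g))
  # transposed traversal: push u forward through the frozen graph,
  # accumulating the bilinear weight terms against the cached backward
  # gradients vs[[i]]
  n <- length(cfg$critic_channels)
  gconvs <- vector("list", n)
  for (i in seq_len(n)) {
    cc <- fw$cache$caches[[i]]
    cv <- conv1d_fwd(u, params$convs[[i]]$W, 0 * params$convs[[i]]$b,
                     cfg$kernel, cfg$critic_strides[i], cache = TRUE)
    v <- bk$vs[[i]]
    vm <- v; dim(vm) <- c(dim(v)[1], prod(dim(v)[2:3]))
    gW <- cv$cache$Xc %*% t(vm)
    gconvs[[i]] <- list(W = gW, b = 0 * params$convs[[i]]$b)
    u <- cv$out * ifelse(cc$mask, 1, 0.2) # frozen leaky-ReLU mask
    if (!is.null(cc$shifts)) u <- phase_shuffle_fwd(u, cc$shifts)
  }
  names(gconvs) <- names(params$convs)
  d <- dim(u)
  uh <- u; dim(uh) <- c(d[1] * d[2], N)
  gWd <- uh %*% matrix(bk$gscore, N, 1)
  list(gp = gp,
       gparams = list(convs = gconvs,
                      dense = list(W = gWd, b = 0 * params$dense$b)))
}

#' Critic and generator losses of WGAN-GP
#'
#' `critic_loss = mean(critic_fake) - mean(critic_real) + gp_weight * gp`;
#' `generator_loss = -mean(critic_fake)`.
#'
#' @param critic_real,critic_fake per-sample critic scores
#' @param gp gradient-penalty value
#' @param gp_weight penalty weight
#' @return list with `critic_loss` and `generator_loss`
#' @export
wgan_gp_losses <- function(critic_real, critic_fake, gp, gp_weight = 10) {
  stopifnot(all(is.finite(critic_real)), all(is.finite(critic_fake)),
            is.finite(gp))
  list(critic_loss = mean(critic_fake) - mean(critic_real) + gp_weight * gp,
       generator_loss = -mean(critic_fake))
}

## ---- training ---------------------------------------------------------------

# one critic update on given real/fake batches; returns new params/opt and loss
critic_update <- function(gp_params, cfg, real, fake, opt, theta_skel) {
  N <- dim(real)[3]
  fr <- critic_fwd(gp_params, cfg, real, keep_cache = TRUE)
  br <- critic_bwd(gp_params, cfg, fr$cache, rep(-1 / N, N))
  ff <- critic_fwd(gp_params, cfg, fake, keep_cache = TRUE)
  bf <- critic_bwd(gp_params, cfg, ff$cache, rep(1 / N, N))
  xhat <- gp_interpolate(real, fake)
  gpres <- gp_pass(gp_params, cfg, xhat, want_grads = TRUE)
  g <- flatten_params(br$gparams) + flatten_params(bf$gparams) +
    cfg$gp_weight * flatten_params(gpres$gparams)
  theta <- flatten_params(gp_params)
  st <- adam_step(theta, g, opt, lr = cfg$lr)
  losses <- wgan_gp_losses(fr$score, ff$score, gpres$gp, cfg$gp_weight)
  list(params = unflatten_params(st$theta, theta_skel), opt = st$state,
       critic_loss = losses$critic_loss)
}

gen_update <- function(gen_params, critic_params, cfg, z, opt, theta_skel) {
  N <- ncol(z)
  gf <- gen_fwd(gen_params, cfg, z, keep_cache = TRUE)
  cf <- critic_fwd(critic_params, cfg, gf$out, keep_cache = TRUE)
  cb <- critic_bwd(critic_params, cfg, cf$cache, rep(-1 / N, N))
  gg <- gen_bwd(gen_params, cfg, gf$cache, cb$gx)
  theta <- flatten_params(gen_params)
  st <- adam_step(theta, flatten_params(gg), opt, lr = cfg$lr)
  list(params = unflatten_params(st$theta, theta_skel), opt = st$state,
       gen_loss = -mean(cf$score))
}

train_gan_group <- function(waves, cfg, init_group = NULL, seed = 0L,
                            log_path = NULL, tag = "gan") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, paste0("gan-", tag)))
  gen_params <- if (!is.null(init_group)) init_group$gen_params else gen_init(cfg)
  critic_params <- if (!is.null(init_group)) init_group$critic_params else critic_init(cfg)
  gopt <- adam_init(length(flatten_params(gen_params)))
  copt <- adam_init(length(flatten_params(critic_params)))
  n <- dim(waves)[3]
  bs <- min(cfg$batch_size, n)
  best_ncl <- Inf; bad <- 0L
  n_critic_updates <- 0L; n_gen_updates <- 0L
  ncl_trace <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    closses <- numeric(0)
    if (cfg$alternation == "updates") {
      n_batches <- max(1L, n %/% bs)
      for (b in seq_len(n_batches)) {
        for (s in seq_len(cfg$critic_steps)) {
          real <- waves[, , sample.int(n, bs, replace = bs > n), drop = FALSE]
          z <- matrix(stats::rnorm(cfg$latent_dim * bs), cfg$latent_dim, bs)
          fake <- gen_fwd(gen_params, cfg, z, keep_cache = FALSE)$out
          up <- critic_update(critic_params, cfg, real, fake, copt,
                              critic_params)
          critic_params <- up$params; copt <- up$opt
          closses <- c(closses, up$critic_loss)
          n_critic_updates <- n_critic_updates + 1L
        }
        z <- matrix(stats::rnorm(cfg$latent_dim * bs), cfg$latent_dim, bs)
        gu <- gen_update(gen_params, critic_params, cfg, z, gopt, gen_params)
        gen_params <- gu$params; gopt <- gu$opt
        n_gen_updates <- n_gen_updates + 1L
      }
    } else {
      # whole-epoch alternation: critic_steps critic epochs, 1 generator epoch
      for (ce in seq_len(cfg$critic_steps)) {
        real <- waves[, , sample.int(n, bs, replace = bs > n), drop = FALSE]
        z <- matrix(stats::rnorm(cfg$latent_dim * bs), cfg$latent_dim, bs)
        fake <- gen_fwd(gen_params, cfg, z, keep_cache = FALSE)$out
        up <- critic_update(critic_params, cfg, real, fake, copt,
                            critic_params)
        critic_params <- up$params; copt <- up$opt
        closses <- c(closses, up$critic_loss)
        n_critic_updates <- n_critic_updates + 1L
      }
      z <- matrix(stats::rnorm(cfg$latent_dim * bs), cfg$latent_dim, bs)
      gu <- gen_update(gen_params, critic_params, cfg, z, gopt, gen_params)
      gen_params <- gu$params; gopt <- gu$opt
      n_gen_updates <- n_gen_updates + 1L
    }
    ncl <- -mean(closses)
    ncl_trace <- c(ncl_trace, ncl)
    if (!is.finite(ncl)) stop("critic loss diverged (non-finite)")
    log_metric(log_path, list(tag = tag, epoch = epoch,
                              neg_critic_loss = ncl))
    if (ncl < best_ncl) { best_ncl <- ncl; bad <- 0L } else bad <- bad + 1L
    if (bad > cfg$patience) break
  }
  list(gen_params = gen_params, critic_params = critic_params,
       ncl_trace = ncl_trace,
       n_critic_updates = n_critic_updates, n_gen_updates = n_gen_updates)
}

#' Train the per-group waveform synthesizer on one site
#'
#' Trains one WGAN-GP per label group (records without / with arrhythmia)
#' on the site's training partition. If `init` is given, both groups
#' warm-start from the previous institution's synthesizer parameters.
#'
#' @param site a split [site_dataset()] with both label groups present in
#'   its training partition
#' @param config a [synth_config()]
#' @param init a previous synthesizer state for warm-start transfer, or NULL
#' @param seed integer seed
#' @param log_path optional JSON-lines log
#' @return an object of class `synthesizer_state` with per-group generator
#'   and critic parameters, training traces, and the provenance site chain
#' @export
train_synthesizer <- function(site, config, init = NULL, seed = 0L,
                              log_path = NULL) {
  stopifnot(inherits(config, "synth_config"))
  train_recs <- partition_records(site, "train")
  labels <- vapply(train_recs, function(r) r$label, integer(1))
  groups <- list()
  for (g in c(0L, 1L)) {
    recs <- train_recs[labels == g]
    if (length(recs) == 0)
      stop("label group ", g, " is empty in the training partition")
    waves <- records_to_batch(recs)$xw
    groups[[as.character(g)]] <-
      train_gan_group(waves, config,
                      init_group = if (!is.null(init))
                        init$groups[[as.character(g)]],
                      seed = derive_seed(seed, paste0("group", g)),
                      log_path = log_path,
                      tag = paste0("gan-", site$site_id, "-g", g))
  }
  provenance <- c(if (!is.null(init)) init$provenance, site$site_id)
  structure(list(groups = groups, config = config, provenance = provenance),
            class = "synthesizer_state")
}

#' Generate a fake dataset with randomly paired demographics
#'
#' Samples latent vectors per label group, synthesizes waveforms, and pairs
#' each with an (age, sex) pair drawn jointly (with replacement) from that
#' group's real demographic pool. The joint age-sex distribution of the
#' pool is preserved, while the waveform-demographics linkage is random and
#' never derived from any real record.
#'
#' @param state a [train_synthesizer()] result
#' @param demographics_pool named list (`"0"`, `"1"`) of lists of
#'   `list(age, sex)` pairs
#' @param n_per_group named integer vector (`"0"`, `"1"`) of records to
#'   generate per group
#' @param seed integer seed
#' @param source_site site id recorded as the fake set's origin
#' @return a `fake_dataset`: list of synthetic `ecg_record`s plus metadata
#' @export
generate_fake_dataset <- function(state, demographics_pool, n_per_group,
                                  seed = 0L, source_site = "unknown") {
  stopifnot(inherits(state, "synthesizer_state"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "fake"))
  cfg <- state$config
  records <- list()
  for (g in names(n_per_group)) {
    ng <- n_per_group[[g]]
    if (ng == 0) next
    pool <- demographics_pool[[g]]
    if (is.null(pool) || length(pool) == 0)
      stop("empty demographics pool for group ", g)
    z <- matrix(stats::rnorm(cfg$latent_dim * ng), cfg$latent_dim, ng)
    waves <- gen_fwd(state$groups[[g]]$gen_params, cfg, z,
                     keep_cache = FALSE)$out
    picks <- sample.int(length(pool), ng, replace = TRUE)
    for (i in seq_len(ng)) {
      dem <- pool[[picks[i]]]
      records[[length(records) + 1L]] <- ecg_record(
        waveform = matrix(waves[, , i], cfg$leads, cfg$samples),
        sampling_rate = cfg$fs, age = dem$age, sex = dem$sex,
        label = as.integer(g),
        record_id = sprintf("FAKE-%s-g%s-%05d", source_site, g, i),
        site_id = paste0("fake-", source_site))
    }
  }
  structure(list(records = records, source_site = source_site,
                 size = length(records), synthetic = TRUE),
            class = "fake_dataset")
}

#' Waveform diversity check against mode collapse
#'
#' Compares the standard deviation of per-record RMS amplitude across a set
#' of synthetic waveforms with the real data's; warns (never stops) when the
#' synthetic spread falls below 10 percent of the real spread.
#'
#' @param fake_records,real_records lists of `ecg_record`s
#' @return invisible list with both spreads and the ratio
#' @export
check_fake_diversity <- function(fake_records, real_records) {
  rms <- function(recs) vapply(recs, function(r) sqrt(mean(r$waveform^2)),
                               numeric(1))
  sf <- stats::sd(rms(fake_records)); sr <- stats::sd(rms(real_records))
  ratio <- if (sr > 0) sf / sr else NA_real_
  if (is.finite(ratio) && ratio < 0.1)
    warning("possible mode collapse: synthetic RMS spread is ",
            signif(ratio, 3), " of the real spread")
  invisible(list(fake_sd = sf, real_sd = sr, ratio = ratio))
}
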