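# Residual 1D-convolutional arrhythmia detector.
#
# The detector has three parts: a waveform trunk of 11 residual convolution
# blocks, a demographic MLP (age, sex -> 64 features), and a detection head
# on the concatenated representations. Each trunk block is
#   conv(k, stride, SAME) -> batch norm -> (+ shortcut) -> ReLU -> pool,
# where the shortcut is parameter-free (strided identity with zero channel
# padding) and the pool is an adaptive average pool to the block's target
# length. The head's two hidden dense layers carry batch norm. This
# convention is the unique one (over bias / batch-norm / shortcut /
# conv-count variants) under which the default configuration has exactly
# 6,631,234 trainable parameters, the published total for this architecture.

# Target output lengths of the 11 default blocks at 5000 input samples.
.default_block_lens <- c(1250L, 313L, 80L, 80L, 80L, 40L, 40L, 40L, 20L, 20L, 20L)

#' Detector configuration
#'
#' @param leads number of waveform channels (default 12)
#' @param input_samples waveform length in samples (default 5000 = 10 s at
#'   500 Hz)
#' @param width_multiplier positive scaling of all trunk channel widths;
#'   reduced widths (e.g. 1/8) give desk-scale models for tests
#' @param n_labels number of output classes (default 2)
#' @param use_batch_norm include batch-norm layers (default TRUE)
#' @param demo_widths hidden widths of the demographic MLP
#' @param head_widths hidden widths of the detection head
#' @return an object of class `detector_config`
#' @export
detector_config <- function(leads = 12L, input_samples = 5000L,
                            width_multiplier = 1, n_labels = 2L,
                            use_batch_norm = TRUE,
                            demo_widths = c(32L, 64L, 64L),
                            head_widths = c(512L, 256L)) {
  stopifnot(width_multiplier > 0, leads >= 1, input_samples >= 16)
  wm <- function(c) max(1L, as.integer(round(c * width_multiplier)))
  kernels <- c(11L, 7L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L)
  couts <- c(96L, 96L, 96L, 96L, 96L, 192L, 192L, 192L, 384L, 384L, 384L)
  strides <- c(2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)
  pools <- c(2L, 2L, 2L, 1L, 1L, 2L, 1L, 1L, 2L, 1L, 1L)
  couts <- vapply(couts, wm, integer(1))
  cins <- c(leads, couts[-11])
  # block output lengths: ceil(L/stride) then ceil(/pool); at the reference
  # input length the printed table lengths are authoritative (its third
  # block prints 80 where the rule gives 79) and are used verbatim.
  lens <- integer(11); L <- as.integer(input_samples)
  for (i in 1:11) {
    L <- ceiling(ceiling(L / strides[i]) / pools[i])
    lens[i] <- L
  }
  if (input_samples == 5000L) lens <- .default_block_lens
  blocks <- lapply(1:11, function(i) {
    list(kernel = kernels[i], cin = cins[i], cout = couts[i],
         stride = strides[i], out_len = lens[i], conv_count = 1L)
  })
  structure(list(leads = leads, input_samples = as.integer(input_samples),
                 width_multiplier = width_multiplier,
                 n_labels = as.integer(n_labels),
                 use_batch_norm = use_batch_norm,
                 demo_widths = as.integer(demo_widths),
                 head_widths = as.integer(head_widths),
                 blocks = blocks,
                 head_input = couts[11] * lens[11] + demo_widths[3]),
            class = "detector_config")
}

#' Expected intermediate output shapes of a detector configuration
#'
#' @param config a [detector_config()]
#' @return data.frame with one row per trunk block: channels and length
#' @export
detector_shapes <- function(config) {
  data.frame(block = 1:11,
             channels = vapply(config$blocks, function(b) b$cout, integer(1)),
             length = vapply(config$blocks, function(b) b$out_len, integer(1)))
}

#' Build an arrhythmia detector
#'
#' Initializes all trainable parameters (He-uniform) and batch-norm running
#' statistics. The forward map takes a waveform batch (leads x samples x n)
#' and a demographic batch (2 x n, rows = age/100 and sex in \{0,1\}) to
#' `n_labels` class scores.
#'
#' @param config a [detector_config()]
#' @param seed integer seed for parameter initialization
#' @return an object of class `detector`
#' @export
build_detector <- function(config, seed = 0L) {
  stopifnot(inherits(config, "detector_config"))
  # validate that the reference configuration realizes the published shapes
  if (config$input_samples == 5000L && config$width_multiplier == 1 &&
      config$leads == 12L) {
    sh <- detector_shapes(config)
    ref <- data.frame(block = 1:11,
                      channels = c(96L, 96L, 96L, 96L, 96L, 192L, 192L, 192L,
                                   384L, 384L, 384L),
                      length = .default_block_lens)
    if (!identical(sh, ref))
      stop("default configuration does not realize the reference shapes: ",
           paste(which(sh$channels != ref$channels | sh$length != ref$length),
                 collapse = ", "))
    if (config$head_input != 7744L)
      stop("default head input width is ", config$head_input, ", expected 7744")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "detector-init"))
  trunk <- lapply(config$blocks, function(b) {
    p <- list(conv = conv1d_init(b$cin, b$kernel, b$cout))
    if (config$use_batch_norm) p$bn <- bn_init(b$cout)
    p
  })
  dw <- config$demo_widths
  demo <- list(d1 = dense_init(2L, dw[1]), d2 = dense_init(dw[1], dw[2]),
               d3 = dense_init(dw[2], dw[3]))
  hw <- config$head_widths
  head <- list(d1 = dense_init(config$head_input, hw[1]),
               d2 = dense_init(hw[1], hw[2]),
               d3 = dense_init(hw[2], config$n_labels))
  if (config$use_batch_norm) {
    head$bn1 <- bn_init(hw[1])
    head$bn2 <- bn_init(hw[2])
  }
  buffers <- list(
    trunk = if (config$use_batch_norm)
      lapply(config$blocks, function(b) bn_buffers_init(b$cout)),
    head = if (config$use_batch_norm)
      list(bn1 = bn_buffers_init(hw[1]), bn2 = bn_buffers_init(hw[2])))
  # pooling operators are data-independent; precompute per block
  pools <- vector("list", 11); L <- config$input_samples
  for (i in 1:11) {
    b <- config$blocks[[i]]
    conv_out <- ceiling(L / b$stride)
    if (conv_out != b$out_len)
      pools[[i]] <- adaptive_pool_matrix(conv_out, b$out_len)
    L <- b$out_len
  }
  structure(list(config = config,
                 params = list(trunk = trunk, demo = demo, head = head),
                 buffers = buffers, pools = pools),
            class = "detector")
}

# save/restore the global RNG state so builders do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Count trainable parameters of a detector (or any parameter list)
#'
#' @param model a `detector`, or a nested list of numeric arrays
#' @param component for detectors: `"all"`, `"trunk"`, `"demo"`, `"head"`,
#'   or `"head_dense"` (the head's dense layers without batch norm)
#' @return integer count of trainable scalars
#' @export
count_parameters <- function(model, component = "all") {
  p <- if (inherits(model, "detector")) model$params else model
  if (inherits(model, "detector") && component != "all") {
    p <- switch(component,
                trunk = p$trunk, demo = p$demo, head = p$head,
                head_dense = p$head[c("d1", "d2", "d3")],
                stop("unknown component: ", component))
  }
  length(flatten_params(p))
}

## ---- forward / backward ---------------------------------------------------

# One residual block. Returns output, cache, updated bn buffers.
block_fwd <- function(x, bp, bspec, P, bnbuf, use_bn, training,
                      keep_cache = training) {
  cv <- conv1d_fwd(x, bp$conv$W, bp$conv$b, bspec$kernel, bspec$stride,
                   cache = keep_cache)
  y <- cv$out
  bnc <- NULL
  if (use_bn) {
    r <- bn_fwd(y, bp$bn$gamma, bp$bn$beta, bnbuf, training)
    y <- r$out; bnc <- r$cache; bnbuf <- r$buffers
  }
  # parameter-free shortcut: strided identity, zero-padded channels
  d <- dim(x)
  xs <- x[, seq(1L, d[2], by = bspec$stride), , drop = FALSE]
  if (bspec$cin < bspec$cout) {
    sc <- array(0, dim(y))
    sc[seq_len(bspec$cin), , ] <- xs
  } else sc <- xs
  z <- y + sc
  rl <- relu_fwd(z)
  out <- rl$out
  if (!is.null(P)) out <- pool_fwd(out, P)
  list(out = out, bnbuf = bnbuf,
       cache = list(conv = cv$cache, bn = bnc, mask = rl$mask,
                    pre_pool_len = dim(z)[2], in_dim = d))
}

block_bwd <- function(gout, bp, bspec, P, cache) {
  if (!is.null(P)) gout <- pool_bwd(gout, P, cache$pre_pool_len)
  gz <- relu_bwd(gout, cache$mask)
  # shortcut gradient
  gx_sc <- array(0, cache$in_dim)
  gsrc <- if (bspec$cin < bspec$cout) gz[seq_len(bspec$cin), , , drop = FALSE] else gz
  gx_sc[, seq(1L, cache$in_dim[2], by = bspec$stride), ] <- gsrc
  gparams <- list(conv = NULL)
  if (!is.null(cache$bn)) {
    bb <- bn_bwd(gz, bp$bn$gamma, cache$bn)
    gz <- bb$gx
    gparams$bn <- list(gamma = bb$ggamma, beta = bb$gbeta)
  }
  cb <- conv1d_bwd(gz, bp$conv$W, cache$conv)
  gparams$conv <- list(W = cb$gW, b = cb$gb)
  list(gx = cb$gx + gx_sc, gparams = gparams)
}

#' Low-level detector forward pass
#'
#' Runs the detector on a batch, returning pre-softmax class scores. In
#' training mode batch statistics drive the batch-norm layers (and the
#' returned `buffers` carry updated running statistics); in evaluation mode
#' the stored running statistics are used.
#'
#' @param det a `detector`
#' @param xw waveform array (leads x samples x n)
#' @param xd demographic matrix (2 x n: age/100, sex in \{0,1\})
#' @param training use batch statistics and keep backward caches
#' @param keep_cache keep backward caches even in evaluation mode
#' @return list with `logits` (n_labels x n), `caches`, `buffers`
#' @export
detector_fwd <- function(det, xw, xd, training = FALSE,
                         keep_cache = training) {
  cfg <- det$config
  stopifnot(dim(xw)[1] == cfg$leads, dim(xw)[2] == cfg$input_samples,
            nrow(xd) == 2, dim(xw)[3] == ncol(xd))
  use_bn <- cfg$use_batch_norm
  caches <- list(trunk = vector("list", 11))
  x <- xw
  for (i in 1:11) {
    r <- block_fwd(x, det$params$trunk[[i]], cfg$blocks[[i]], det$pools[[i]],
                   if (use_bn) det$buffers$trunk[[i]], use_bn, training,
                   keep_cache)
    x <- r$out
    caches$trunk[[i]] <- r$cache
    if (use_bn) det$buffers$trunk[[i]] <- r$bnbuf
  }
  n <- dim(x)[3]
  flat <- x; dim(flat) <- c(dim(x)[1] * dim(x)[2], n)
  # demographic branch: dense-ReLU x3
  dm <- det$params$demo
  a1 <- dense_fwd(xd, dm$d1$W, dm$d1$b); r1 <- relu_fwd(a1)
  a2 <- dense_fwd(r1$out, dm$d2$W, dm$d2$b); r2 <- relu_fwd(a2)
  a3 <- dense_fwd(r2$out, dm$d3$W, dm$d3$b); r3 <- relu_fwd(a3)
  caches$demo <- list(xd = xd, r1 = r1, r2 = r2, r3 = r3)
  h <- rbind(flat, r3$out)
  hd <- det$params$head
  b1 <- dense_fwd(h, hd$d1$W, hd$d1$b)
  if (use_bn) {
    rb1 <- bn_fwd(b1, hd$bn1$gamma, hd$bn1$beta, det$buffers$head$bn1, training)
    b1 <- rb1$out; det$buffers$head$bn1 <- rb1$buffers
  } else rb1 <- NULL
  hr1 <- relu_fwd(b1)
  b2 <- dense_fwd(hr1$out, hd$d2$W, hd$d2$b)
  if (use_bn) {
    rb2 <- bn_fwd(b2, hd$bn2$gamma, hd$bn2$beta, det$buffers$head$bn2, training)
    b2 <- rb2$out; det$buffers$head$bn2 <- rb2$buffers
  } else rb2 <- NULL
  hr2 <- relu_fwd(b2)
  logits <- dense_fwd(hr2$out, hd$d3$W, hd$d3$b)
  caches$head <- list(h = h, bn1 = if (use_bn) rb1$cache, hr1 = hr1,
                      bn2 = if (use_bn) rb2$cache, hr2 = hr2,
                      trunk_dim = dim(x))
  list(logits = logits, caches = caches, buffers = det$buffers)
}

#' Low-level detector backward pass
#'
#' Backpropagates a gradient in logit space through a forward pass's caches.
#'
#' @param det the `detector` used in the forward pass
#' @param caches caches from [detector_fwd()] (training or `keep_cache`)
#' @param glogits gradient w.r.t. the logits (n_labels x n)
#' @return list with `gparams` (gradient tree aligned with `det$params`),
#'   `gx_wave`, `gx_demo`
#' @export
detector_bwd <- function(det, caches, glogits) {
  cfg <- det$config; use_bn <- cfg$use_batch_norm
  hd <- det$params$head; hc <- caches$head
  g3 <- dense_bwd(glogits, hc$hr2$out, hd$d3$W)
  g <- relu_bwd(g3$gx, hc$hr2$mask)
  ghead <- list(d3 = list(W = g3$gW, b = g3$gb))
  if (use_bn) {
    bb <- bn_bwd(g, hd$bn2$gamma, hc$bn2)
    g <- bb$gx
    ghead$bn2 <- list(gamma = bb$ggamma, beta = bb$gbeta)
  }
  g2 <- dense_bwd(g, hc$hr1$out, hd$d2$W)
  g <- relu_bwd(g2$gx, hc$hr1$mask)
  ghead$d2 <- list(W = g2$gW, b = g2$gb)
  if (use_bn) {
    bb <- bn_bwd(g, hd$bn1$gamma, hc$bn1)
    g <- bb$gx
    ghead$bn1 <- list(gamma = bb$ggamma, beta = bb$gbeta)
  }
  g1 <- dense_bwd(g, hc$h, hd$d1$W)
  ghead$d1 <- list(W = g1$gW, b = g1$gb)
  td <- hc$trunk_dim
  nt <- td[1] * td[2]
  gtrunk_flat <- g1$gx[seq_len(nt), , drop = FALSE]
  gdemo_in <- g1$gx[(nt + 1):nrow(g1$gx), , drop = FALSE]
  # demographic branch backward
  dm <- det$params$demo; dc <- caches$demo
  g <- relu_bwd(gdemo_in, dc$r3$mask)
  gd3 <- dense_bwd(g, dc$r2$out, dm$d3$W)
  g <- relu_bwd(gd3$gx, dc$r2$mask)
  gd2 <- dense_bwd(g, dc$r1$out, dm$d2$W)
  g <- relu_bwd(gd2$gx, dc$r1$mask)
  gd1 <- dense_bwd(g, dc$xd, dm$d1$W)
  gdemo <- list(d1 = list(W = gd1$gW, b = gd1$gb),
                d2 = list(W = gd2$gW, b = gd2$gb),
                d3 = list(W = gd3$gW, b = gd3$gb))
  # trunk backward
  gx <- array(gtrunk_flat, td)
  gtrunk <- vector("list", 11)
  for (i in 11:1) {
    r <- block_bwd(gx, det$params$trunk[[i]], cfg$blocks[[i]], det$pools[[i]],
                   caches$trunk[[i]])
    gx <- r$gx
    gtrunk[[i]] <- r$gparams
  }
  gparams <- reorder_like(list(trunk = gtrunk, demo = gdemo, head = ghead),
                          det$params)
  list(gparams = gparams, gx_wave = gx, gx_demo = gd1$gx)
}

#' Class probabilities for a batch of records
#'
#' Runs the detector in evaluation mode (batch-norm running statistics) and
#' applies a softmax to the class scores.
#'
#' @param model a `detector`
#' @param batch list with `xw` (leads x samples x n waveform array) and `xd`
#'   (2 x n demographic matrix: age/100 and sex in \{0,1\}), as produced by
#'   [records_to_batch()]
#' @return n x n_labels matrix of probabilities; rows sum to 1
#' @export
predict_proba <- function(model, batch) {
  stopifnot(inherits(model, "detector"))
  fw <- detector_fwd(model, batch$xw, batch$xd, training = FALSE)
  t(softmax_cols(fw$logits))
}

#' Assemble ECG records into a detector input batch
#'
#' @param records list of `ecg_record` objects
#' @return list with waveform array `xw` (leads x samples x n), demographic
#'   matrix `xd` (2 x n; age/100 and sex male=1/female=0), label vector `y`
#' @export
records_to_batch <- function(records) {
  stopifnot(length(records) >= 1)
  C <- nrow(records[[1]]$waveform); L <- ncol(records[[1]]$waveform)
  n <- length(records)
  xw <- array(0, c(C, L, n))
  xd <- matrix(0, 2, n)
  y <- integer(n)
  for (i in seq_len(n)) {
    r <- records[[i]]
    xw[, , i] <- r$waveform
    xd[1, i] <- r$age / 100
    xd[2, i] <- if (identical(r$sex, "male")) 1 else 0
    y[i] <- r$label
  }
  list(xw = xw, xd = xd, y = y)
}

#' Save and load detector checkpoints
#'
#' A checkpoint is a single RDS archive holding the configuration, all named
#' parameter groups, the batch-norm running statistics, and free-form
#' training metadata (e.g. site history and seeds). Round-trips are
#' bit-stable: the reloaded detector's flat parameter vector is identical to
#' the saved one.
#'
#' @param det a `detector`
#' @param path file path of the checkpoint archive
#' @param metadata optional list stored alongside the model
#' @return `save_detector` returns `path` invisibly; `load_detector` returns
#'   the `detector` with the metadata in attribute `"metadata"`
#' @export
save_detector <- function(det, path, metadata = list()) {
  stopifnot(inherits(det, "detector"))
  saveRDS(list(config = det$config, params = det$params,
               buffers = det$buffers, metadata = metadata), path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  ck <- readRDS(path)
  det <- build_detector(ck$config, seed = 0L)
  det$params <- ck$params
  det$buffers <- ck$buffers
  attr(det, "metadata") <- ck$metadata
  det
}
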