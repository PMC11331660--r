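test_that("default detector reproduces the published architecture exactly", {
  cfg <- detector_config()
  det <- build_detector(cfg, seed = 1)
  expect_equal(count_parameters(det), 6631234L)
  sh <- detector_shapes(cfg)
  expect_equal(sh$channels, c(96L, 96L, 96L, 96L, 96L, 192L, 192L, 192L,
                              384L, 384L, 384L))
  expect_equal(sh$length, c(1250L, 313L, 80L, 80L, 80L, 40L, 40L, 40L,
                            20L, 20L, 20L))
  expect_equal(cfg$head_input, 7744L) # 384 * 20 + 64
})

test_that("component parameter counts match the dense-layer hand sums", {
  det <- build_detector(detector_config(), seed = 1)
  # demographic MLP 2->32->64->64 with biases
  expect_equal(count_parameters(det, "demo"),
               (2 * 32 + 32) + (32 * 64 + 64) + (64 * 64 + 64))
  expect_equal(count_parameters(det, "demo"), 6368L)
  # head dense stack 7744->512->256->2 with biases
  expect_equal(count_parameters(det, "head_dense"),
               (7744 * 512 + 512) + (512 * 256 + 256) + (256 * 2 + 2))
  expect_equal(count_parameters(det, "head_dense"), 4097282L)
  # independent recomputation: sum over parameter groups of element counts
  total <- sum(rapply(det$params, length, how = "unlist"))
  expect_equal(total, count_parameters(det))
})

test_that("halving trunk widths shrinks conv parameters about fourfold", {
  full <- build_detector(detector_config(), seed = 1)
  half <- build_detector(detector_config(width_multiplier = 0.5), seed = 1)
  conv_count <- function(det) sum(rapply(lapply(det$params$trunk,
                                                function(b) b$conv["W"]),
                                         length, how = "unlist"))
  ratio <- conv_count(full) / conv_count(half)
  expect_gt(ratio, 3.5); expect_lt(ratio, 4.5)
})

test_that("default detector forward realizes the printed output shape", {
  det <- build_detector(detector_config(), seed = 2)
  xw <- array(rnorm(12 * 5000 * 4), c(12, 5000, 4))
  xd <- matrix(runif(8), 2, 4)
  fw <- detector_fwd(det, xw, xd)
  expect_equal(dim(fw$logits), c(2L, 4L))
})

test_that("tiny detector builds and runs forward quickly", {
  cfg <- detector_config(input_samples = 625L, width_multiplier = 1 / 8)
  det <- build_detector(cfg, seed = 3)
  t0 <- Sys.time()
  fw <- detector_fwd(det, array(rnorm(12 * 625 * 2), c(12, 625, 2)),
                     matrix(runif(4), 2, 2))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(dim(fw$logits), c(2L, 2L))
})

test_that("predict_proba returns normalized, deterministic probabilities", {
  det <- build_detector(tiny_det_config(), seed = 4)
  set.seed(10)
  xw <- array(rnorm(12 * 313 * 6), c(12, 313, 6))
  xw[, , 6] <- xw[, , 1] # duplicated record
  xd <- matrix(runif(12), 2, 6); xd[, 6] <- xd[, 1]
  p <- predict_proba(det, list(xw = xw, xd = xd))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p[6, ], p[1, ])
})

test_that("random-weights detector is near-symmetric on random input", {
  # batch statistics center the hidden activations, which is what makes the
  # symmetry-of-initialization bound hold for an untrained network
  det <- build_detector(tiny_det_config(), seed = 5)
  set.seed(11)
  fw <- detector_fwd(det, array(rnorm(12 * 313 * 256), c(12, 313, 256)),
                     matrix(runif(512), 2, 256), training = TRUE)
  p <- t(cardiocl:::softmax_cols(fw$logits))
  expect_gt(mean(p[, 2]), 0.2)
  expect_lt(mean(p[, 2]), 0.8)
})

test_that("detector backward matches finite differences", {
  cfg <- detector_config(leads = 3L, input_samples = 64L,
                         width_multiplier = 1 / 24)
  det <- build_detector(cfg, seed = 6)
  set.seed(12)
  xw <- array(rnorm(3 * 64 * 2), c(3, 64, 2))
  xd <- matrix(runif(4), 2, 2)
  y <- c(1L, 0L)
  lossfn <- function(theta) {
    d <- det; d$params <- unflatten_params(theta, det$params)
    fw <- detector_fwd(d, xw, xd, training = TRUE)
    p <- cardiocl:::softmax_cols(fw$logits)
    -sum(log(p[cbind(y + 1, 1:2)]))
  }
  fw <- detector_fwd(det, xw, xd, training = TRUE)
  p <- cardiocl:::softmax_cols(fw$logits)
  gl <- p; gl[cbind(y + 1, 1:2)] <- gl[cbind(y + 1, 1:2)] - 1
  ga <- flatten_params(detector_bwd(det, fw$caches, gl)$gparams)
  theta <- flatten_params(det$params)
  idx <- sample(length(theta), 40)
  gfd <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + 1e-5
    tm <- theta; tm[i] <- tm[i] - 1e-5
    (lossfn(tp) - lossfn(tm)) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(gfd - ga[idx])), 1e-4)
})

test_that("checkpoints round-trip bit-stably with metadata", {
  det <- build_detector(tiny_det_config(), seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_detector(det, path, metadata = list(sites = c("a", "b"), seed = 8))
  back <- load_detector(path)
  expect_identical(flatten_params(back$params), flatten_params(det$params))
  expect_identical(back$buffers, det$buffers)
  expect_equal(attr(back, "metadata")$sites, c("a", "b"))
  # the reloaded model predicts identically
  set.seed(13)
  b <- list(xw = array(rnorm(12 * 313 * 3), c(12, 313, 3)),
            xd = matrix(runif(6), 2, 3))
  expect_identical(predict_proba(det, b), predict_proba(back, b))
})
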