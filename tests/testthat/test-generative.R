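test_that("gradient_penalty is exact on closed-form critics", {
  set.seed(41)
  x <- array(rnorm(3 * 32 * 5), c(3, 32, 5))
  y <- array(rnorm(3 * 32 * 5), c(3, 32, 5))
  cr1 <- unit_gradient_critic(gain = 1)
  expect_equal(gradient_penalty(cr1, x, y, seed = 2), 0, tolerance = 1e-12)
  # constant critic: zero gradient, penalty (0 - 1)^2 = 1
  cr0 <- unit_gradient_critic()
  cr0$params$convs$conv1$W[] <- 0
  cr0$params$dense$W[] <- 0
  expect_equal(gradient_penalty(cr0, x, y, seed = 3), 1)
  # gain-3 critic: gradient norm 3 everywhere, penalty (3 - 1)^2 = 4
  cr3 <- unit_gradient_critic(gain = 3)
  expect_equal(gradient_penalty(cr3, x, y, seed = 4), 4, tolerance = 1e-10)
  expect_error(gradient_penalty(cr1, x, y[, , 1:2]), "differ in shape")
})

test_that("gradient_penalty is nonnegative for arbitrary critics", {
  set.seed(42)
  cfg <- tiny_synth_config()
  p <- critic_init(cfg)
  x <- array(rnorm(12 * 313 * 4), c(12, 313, 4))
  gp <- gradient_penalty(list(params = p, config = cfg), x,
                         x + rnorm(length(x), sd = 0.3), seed = 5)
  expect_gte(gp, 0)
})

test_that("penalty parameter gradients match finite differences", {
  set.seed(43)
  cfg <- synth_config(samples = 48, leads = 2L, fs = 125, latent_dim = 4L,
                      gen_channels = c(4L, 4L, 4L),
                      critic_channels = c(3L, 4L), kernel = 5L,
                      upsample = c(4L, 4L, 3L), critic_strides = c(4L, 4L),
                      phase_shuffle = 0L)
  params <- critic_init(cfg)
  xhat <- array(rnorm(2 * 48 * 3), c(2, 48, 3))
  r <- cardiocl:::gp_pass(params, cfg, xhat, want_grads = TRUE)
  theta <- flatten_params(params)
  ga <- flatten_params(r$gparams)
  gp_of <- function(th) {
    cardiocl:::gp_pass(unflatten_params(th, params), cfg, xhat,
                       want_grads = FALSE)$gp
  }
  set.seed(44)
  idx <- sample(length(theta), 30)
  gfd <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + 1e-5
    tm <- theta; tm[i] <- tm[i] - 1e-5
    (gp_of(tp) - gp_of(tm)) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(gfd - ga[idx])), 1e-6)
})

test_that("wgan_gp_losses follows the closed-form expressions", {
  sym <- wgan_gp_losses(c(1, 2), c(1, 2), gp = 0)
  expect_equal(sym$critic_loss, 0)
  l <- wgan_gp_losses(critic_real = c(0.5, 1.5), critic_fake = c(-2, 0),
                      gp = 0.5, gp_weight = 10)
  expect_equal(l$critic_loss, -1 - 1 + 5)
  expect_equal(l$generator_loss, 1)
  # generator loss ignores real scores entirely
  l2 <- wgan_gp_losses(critic_real = c(99, -99), critic_fake = c(-2, 0),
                       gp = 0.1)
  expect_equal(l2$generator_loss, l$generator_loss)
})

test_that("synthesizer training runs, logs the 5:1 update ratio, stays finite", {
  site <- tiny_site(seed = 55, n = 60)
  cfg <- tiny_synth_config(6L)
  st <- train_synthesizer(site, cfg, seed = 1)
  for (g in c("0", "1")) {
    gr <- st$groups[[g]]
    expect_true(all(is.finite(gr$ncl_trace)))
    expect_equal(gr$n_critic_updates, 5L * gr$n_gen_updates)
  }
  expect_equal(st$provenance, site$site_id)
  # an all-negative site cannot train the arrhythmia group
  neg <- tiny_site(seed = 56, n = 40, prevalence = 0.001)
  labels <- vapply(partition_records(neg, "train"), function(r) r$label,
                   integer(1))
  skip_if(any(labels == 1L)) # seed guard: group must actually be empty
  expect_error(train_synthesizer(neg, cfg, seed = 1), "group 1")
})

test_that("warm starts begin closer to convergence than cold starts", {
  site <- tiny_site(seed = 57, n = 50)
  cfg <- tiny_synth_config(10L)
  donor <- train_synthesizer(site, cfg, seed = 2)
  short <- tiny_synth_config(2L)
  closer <- 0
  for (s in 1:3) {
    cold <- train_synthesizer(site, short, init = NULL, seed = 100 + s)
    warm <- train_synthesizer(site, short, init = donor, seed = 100 + s)
    target <- min(donor$groups[["0"]]$ncl_trace)
    d_cold <- abs(cold$groups[["0"]]$ncl_trace[1] - target)
    d_warm <- abs(warm$groups[["0"]]$ncl_trace[1] - target)
    closer <- closer + (d_warm < d_cold)
  }
  expect_gte(closer, 2)
})

test_that("fake datasets preserve prevalence and randomize pairings", {
  site <- tiny_site(seed = 58, n = 50)
  cfg <- tiny_synth_config(3L)
  st <- train_synthesizer(site, cfg, seed = 3)
  # group sizes (35, 15) keep prevalence 0.3 at n = 50
  pool <- list(`0` = list(list(age = 40, sex = "male"),
                          list(age = 60, sex = "female"),
                          list(age = 80, sex = "female")),
               `1` = list(list(age = 55, sex = "male")))
  fd <- generate_fake_dataset(st, pool, c(`0` = 35L, `1` = 15L), seed = 4,
                              source_site = "src")
  labels <- vapply(fd$records, function(r) r$label, integer(1))
  expect_equal(mean(labels), 0.3)
  expect_equal(fd$size, 50L)
  # degenerate pool: every group-1 record carries the single pair
  g1 <- fd$records[labels == 1]
  expect_true(all(vapply(g1, function(r) r$age == 55 && r$sex == "male",
                         logical(1))))
  # different seeds: same pool distribution, different pairings
  big0 <- c(`0` = 300L, `1` = 0L)
  fa <- generate_fake_dataset(st, pool, big0, seed = 10, source_site = "src")
  fb <- generate_fake_dataset(st, pool, big0, seed = 11, source_site = "src")
  counts <- function(f) table(factor(vapply(f$records, function(r) r$age,
                                            integer(1)), c(40, 60, 80)))
  expect_gt(stats::chisq.test(rbind(counts(fa), counts(fb)))$p.value, 0.01)
  ages_a <- vapply(fa$records, function(r) r$age, integer(1))
  ages_b <- vapply(fb$records, function(r) r$age, integer(1))
  expect_false(identical(ages_a, ages_b))
  expect_error(generate_fake_dataset(st, list(`0` = list()), c(`0` = 5L)),
               "empty demographics pool")
})

test_that("large fake sets reproduce the joint demographic distribution", {
  site <- tiny_site(seed = 59, n = 40)
  st <- train_synthesizer(site, tiny_synth_config(2L), seed = 5)
  pairs <- list(list(age = 30, sex = "male"), list(age = 30, sex = "female"),
                list(age = 70, sex = "male"), list(age = 70, sex = "female"))
  probs <- c(0.4, 0.1, 0.2, 0.3)
  pool <- list(`0` = pairs[rep(1:4, round(100 * probs))])
  fd <- generate_fake_dataset(st, pool, c(`0` = 2000L), seed = 6,
                              source_site = "j")
  key <- vapply(fd$records, function(r) paste(r$age, r$sex), character(1))
  obs <- table(factor(key, vapply(pairs, function(p)
    paste(p$age, p$sex), character(1))))
  expect_gt(stats::chisq.test(obs, p = probs)$p.value, 0.01)
})

test_that("fake record ids never collide with real ids", {
  site <- tiny_site(seed = 60, n = 40)
  st <- train_synthesizer(site, tiny_synth_config(2L), seed = 7)
  fd <- cardiocl:::make_site_fake(st, site, cap = 30L, seed = 8)
  real_ids <- vapply(site$records, function(r) r$record_id, character(1))
  fake_ids <- vapply(fd$records, function(r) r$record_id, character(1))
  expect_length(intersect(real_ids, fake_ids), 0)
  expect_true(fd$synthetic)
  expect_equal(fd$size, 30L)
})

test_that("diversity check warns only on collapsed spreads", {
  site <- tiny_site(seed = 61, n = 30)
  recs <- site$records
  collapsed <- lapply(recs, function(r) { r$waveform <- r$waveform * 0 + 0.5; r })
  expect_warning(check_fake_diversity(collapsed, recs), "mode collapse")
  expect_silent(check_fake_diversity(recs, recs))
})
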