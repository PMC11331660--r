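test_that("simulated records are deterministic under seed", {
  sc <- sim_config(leads = 12L, fs = 125, duration = 2.504)
  prof <- site_profile(n = 10)
  r1 <- simulate_record(prof, sc, 1L, seed = 99)
  r2 <- simulate_record(prof, sc, 1L, seed = 99)
  expect_identical(r1$waveform, r2$waveform)
  expect_identical(r1$age, r2$age)
  s1 <- simulate_site(prof, sc, seed = 3, site_id = "d")
  s2 <- simulate_site(prof, sc, seed = 3, site_id = "d")
  expect_identical(records_to_batch(s1$records)$xw,
                   records_to_batch(s2$records)$xw)
})

test_that("noise-free normal records are strictly periodic", {
  sc <- sim_config(leads = 12L, fs = 250, duration = 4)
  prof <- site_profile(n = 1, wander_amp = 0, noise_sd = 0,
                       rr_cv_normal = 1e-9, rr_cv_arrhythmia = 0.25)
  rec <- simulate_record(prof, sc, 0L, seed = 1)
  x <- rec$waveform[6, ] # a strong QRS-projection lead
  lag <- round(0.8 * 250) # RR interval in samples
  n <- length(x) - lag
  ac <- stats::cor(x[1:n], x[(lag + 1):(lag + n)])
  expect_gt(ac, 0.99)
})

test_that("arrhythmia records show higher inter-peak interval variability", {
  skip_if_not_installed("pracma")
  sc <- sim_config(leads = 12L, fs = 125, duration = 10)
  prof <- site_profile(n = 1, wander_amp = 0.02, noise_sd = 0.02)
  # quantile threshold is robust to single-sample amplitude outliers
  peak_cv <- function(rec) {
    x <- rec$waveform[6, ]
    pk <- pracma::findpeaks(x, minpeakdistance = 25,
                            minpeakheight = 0.5 * stats::quantile(x, 0.999))
    iv <- diff(sort(pk[, 2]))
    stats::sd(iv) / mean(iv)
  }
  wins <- 0
  for (i in 1:100) {
    cv0 <- peak_cv(simulate_record(prof, sc, 0L, seed = 1000 + i))
    cv1 <- peak_cv(simulate_record(prof, sc, 1L, seed = 2000 + i))
    wins <- wins + (cv1 > cv0)
  }
  expect_gte(wins, 95)
})

test_that("site statistics converge to the cohort profile", {
  sc <- sim_config(leads = 2L, fs = 25, duration = 2.56)
  # published non-IID cohort rows used as profiles (site 1 and site 4)
  rows <- list(list(n = 5305, age = 51.71, sd = 14.98, male = 0.1913,
                    prev = 0.5048),
               list(n = 5624, age = 68.14, sd = 13.47, male = 0.8007,
                    prev = 0.6305))
  for (row in rows) {
    prof <- site_profile(n = row$n, age_mean = row$age, age_sd = row$sd,
                         male_fraction = row$male,
                         arrhythmia_prevalence = row$prev)
    s <- simulate_site(prof, sc, seed = 17, site_id = "conv")
    ages <- vapply(s$records, function(r) r$age, integer(1))
    males <- mean(vapply(s$records, function(r) r$sex == "male", logical(1)))
    prev <- mean(vapply(s$records, function(r) r$label, integer(1)))
    se_age <- row$sd / sqrt(row$n)
    expect_lt(abs(mean(ages) - row$age), 3 * se_age + 0.5) # 0.5: rounding+clip
    expect_lt(abs(males - row$male),
              3 * sqrt(row$male * (1 - row$male) / row$n))
    expect_lt(abs(prev - row$prev),
              3 * sqrt(row$prev * (1 - row$prev) / row$n))
  }
})

test_that("zero prevalence yields all-negative labels", {
  sc <- sim_config(leads = 2L, fs = 25, duration = 2.56)
  s <- simulate_site(site_profile(n = 200, arrhythmia_prevalence = 0), sc,
                     seed = 2)
  expect_true(all(vapply(s$records, function(r) r$label, integer(1)) == 0L))
})

test_that("multicenter scenarios encode the intended heterogeneity", {
  for (scale in c("tiny", "small", "fourdb")) {
    sc <- default_multicenter_scenario(scale)
    expect_length(sc$profiles, 4)
    ns <- vapply(sc$profiles, function(p) p$n, integer(1))
    expect_equal(anyDuplicated(ns), 0L)
    for (p in sc$profiles) expect_s3_class(p, "site_profile")
  }
  prevs <- vapply(default_multicenter_scenario("fourdb")$profiles,
                  function(p) p$arrhythmia_prevalence, numeric(1))
  expect_equal(sort(prevs), sort(c(0.8201, 0.5612, 0.8321, 0.8775)))
  # exactly one low-prevalence outlier site
  expect_equal(sum(prevs < 0.7), 1L)
})

test_that("generated records pass preprocessing unchanged in shape", {
  sc <- default_multicenter_scenario("tiny")
  s <- simulate_site(sc$profiles[[2]], sc$config, seed = 4, site_id = "pp")
  pp <- preprocess_site(s)
  expect_equal(pp$size_n, s$size_n) # ages were clipped to [18, 100]
  expect_equal(dim(pp$records[[1]]$waveform), dim(s$records[[1]]$waveform))
  rng <- range(vapply(pp$records, function(r) range(r$waveform), numeric(2)))
  expect_gte(rng[1], -1); expect_lte(rng[2], 1)
})

test_that("the label signal is linearly learnable from RR variability", {
  skip_if_not_installed("pracma")
  # 10-second records give ~12 beats, enough intervals for a stable CV
  sc <- sim_config(leads = 12L, fs = 125, duration = 10)
  site <- simulate_site(site_profile(n = 120, arrhythmia_prevalence = 0.5),
                        sc, seed = 77, site_id = "learn")
  site <- preprocess_site(site)
  rrcv <- vapply(site$records, function(r) {
    x <- r$waveform[6, ]
    pk <- pracma::findpeaks(x, minpeakheight = 0.45 * max(abs(x)),
                            minpeakdistance = 30)
    if (is.null(pk) || nrow(pk) < 3) return(0)
    iv <- diff(sort(pk[, 2]))
    stats::sd(iv) / mean(iv)
  }, numeric(1))
  y <- vapply(site$records, function(r) r$label, integer(1))
  fit <- stats::glm(y ~ rrcv, family = stats::binomial())
  expect_gt(auroc(stats::fitted(fit), y), 0.8)
})
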