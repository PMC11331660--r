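make_records <- function(ages, sexes = NULL, labels = NULL, fs = 125,
                         samples = 32) {
  n <- length(ages)
  if (is.null(sexes)) sexes <- rep(c("male", "female"), length.out = n)
  if (is.null(labels)) labels <- rep(0:1, length.out = n)
  lapply(seq_len(n), function(i)
    ecg_record(matrix(rnorm(2 * samples), 2, samples), fs, ages[i],
               sexes[i], labels[i], sprintf("r%03d", i)))
}

test_that("filter_by_age keeps inclusive bounds and preserves order", {
  recs <- make_records(c(17, 18, 100, 101))
  kept <- filter_by_age(recs, 18, 100)
  expect_equal(vapply(kept, function(r) r$age, integer(1)), c(18L, 100L))
  expect_equal(filter_by_age(list(), 18, 100), list())
  expect_error(filter_by_age(recs, 50, 40), "min_age")
  # brute-force oracle on random ages
  set.seed(9)
  ages <- sample(0:120, 1000, replace = TRUE)
  recs <- make_records(ages, samples = 4)
  kept <- filter_by_age(recs, 18, 100)
  brute <- recs[ages >= 18 & ages <= 100]
  expect_identical(vapply(kept, function(r) r$record_id, character(1)),
                   vapply(brute, function(r) r$record_id, character(1)))
})

test_that("bandpass_filter removes DC, passes 10 Hz, attenuates 60 Hz", {
  fs <- 500; t <- seq(0, 20, by = 1 / fs)[-1]
  const <- matrix(3, 2, length(t))
  out <- bandpass_filter(const, 0.5, 40, 5, fs)
  expect_lt(max(abs(rowMeans(out))), 1e-3)
  rms <- function(x) sqrt(mean(x^2))
  s10 <- matrix(sin(2 * pi * 10 * t), 1)
  o10 <- bandpass_filter(s10, 0.5, 40, 5, fs)
  expect_lt(abs(rms(o10) - rms(s10)) / rms(s10), 0.05)
  s60 <- matrix(sin(2 * pi * 60 * t), 1)
  o60 <- bandpass_filter(s60, 0.5, 40, 5, fs)
  expect_lt(rms(o60), 0.2 * rms(s60))
  expect_error(bandpass_filter(s10, 0.5, 260, 5, fs), "Nyquist")
})

test_that("bandpass_filter agrees with the analytic zero-phase response", {
  # |H(f)|^2 of the forward-backward Butterworth evaluated on the unit circle
  fs <- 500
  bf <- signal::butter(5, c(0.5, 40) / (fs / 2), type = "pass")
  gain2 <- function(f) {
    z <- exp(-2i * pi * f / fs)
    abs(sum(bf$b * z^(0:(length(bf$b) - 1))) /
        sum(bf$a * z^(0:(length(bf$a) - 1))))^2
  }
  t <- seq(0, 20, by = 1 / fs)[-1]
  L <- length(t)
  mid <- seq(floor(L * 0.4), floor(L * 0.6)) # steady-state window
  for (f in c(10, 60)) {
    x <- matrix(sin(2 * pi * f * t), 1)
    y <- bandpass_filter(x, 0.5, 40, 5, fs)
    ratio <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
    expect_equal(ratio, gain2(f), tolerance = 0.01)
  }
})

test_that("bandpass_filter is linear", {
  set.seed(4)
  x <- matrix(rnorm(500), 2); y <- matrix(rnorm(500), 2)
  lhs <- bandpass_filter(2 * x - 3 * y, 0.5, 40, 5, 125)
  rhs <- 2 * bandpass_filter(x, 0.5, 40, 5, 125) -
    3 * bandpass_filter(y, 0.5, 40, 5, 125)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
})

test_that("minmax_scale maps the record onto [-1, 1]", {
  x <- matrix(c(-2, 0, 1, 2), 2)
  out <- minmax_scale(x)
  expect_equal(range(out), c(-1, 1))
  expect_equal(out[x == 0], 0)
  x2 <- matrix(c(0, 1, 2, 4), 2)
  out2 <- minmax_scale(x2)
  expect_equal(range(out2), c(-1, 1))
  expect_equal(out2[x2 == 2], 0)
  expect_equal(minmax_scale(matrix(5, 3, 4)), matrix(0, 3, 4))
  # always within [-1, 1], endpoints attained for non-constant input
  set.seed(5)
  for (rep in 1:10) {
    w <- matrix(rnorm(40, sd = 10^runif(1, -2, 2)), 4)
    s <- minmax_scale(w)
    expect_equal(range(s), c(-1, 1))
  }
  # per-lead variant scales each lead independently
  pl <- minmax_scale(matrix(c(0, 1, 0, 10), 2, 2, byrow = TRUE), per_lead = TRUE)
  expect_equal(range(pl[1, ]), c(-1, 1))
  expect_equal(range(pl[2, ]), c(-1, 1))
})

test_that("split_dataset produces 8:1:1 sizes, is deterministic, conserves", {
  recs <- make_records(rep(50, 10))
  d <- site_dataset(recs, "s")
  sp <- split_dataset(d, seed = 1)
  expect_equal(lengths(sp$partitions), c(train = 8L, val = 1L, test = 1L))
  sp2 <- split_dataset(d, seed = 1)
  expect_identical(sp$partitions, sp2$partitions)
  d97 <- site_dataset(make_records(rep(40, 97), samples = 4), "s97")
  sp97 <- split_dataset(d97, seed = 2)
  expect_equal(lengths(sp97$partitions), c(train = 79L, val = 9L, test = 9L))
  all_idx <- sort(unname(unlist(sp97$partitions)))
  expect_equal(all_idx, 1:97)
  expect_error(split_dataset(site_dataset(make_records(rep(30, 5),
                                                       samples = 4), "x"),
                             ratios = c(1, 1, 1), seed = 1), NA)
})

test_that("generate_noniid_sites partitions exactly and mixes groups", {
  set.seed(6)
  ages <- c(sample(20:59, 200, TRUE), sample(60:95, 200, TRUE))
  sexes <- rep(rep(c("male", "female"), each = 100), 2)
  recs <- make_records(ages, sexes, samples = 4)
  d <- site_dataset(recs, "all")
  for (seed in c(1, 7, 23)) {
    sites <- generate_noniid_sites(d, seed = seed)
    expect_length(sites, 4)
    expect_equal(vapply(sites, function(s) s$size_n, integer(1)),
                 rep(100L, 4)) # 7x10 own + 3x10 foreign
    ids <- sort(unlist(lapply(sites, function(s)
      vapply(s$records, function(r) r$record_id, character(1)))))
    expect_equal(ids, sort(vapply(recs, function(r) r$record_id,
                                  character(1))))
    # every site contains all four demographic groups
    for (s in sites) {
      g <- vapply(s$records, function(r)
        paste0(r$age >= 60, r$sex), character(1))
      expect_equal(length(unique(g)), 4)
    }
  }
  small <- site_dataset(make_records(c(20:24, 61:69), samples = 4), "small")
  expect_error(generate_noniid_sites(small, seed = 1), "cannot form")
})

test_that("WFDB round trip preserves waveforms and drops bad metadata", {
  sc <- sim_config(leads = 3L, fs = 125, duration = 1)
  prof <- site_profile(n = 3)
  d <- simulate_site(prof, sc, seed = 5, site_id = "wf")
  path <- withr::local_tempdir()
  write_wfdb_dataset(d, path)
  back <- read_wfdb_dataset(path)
  expect_equal(back$size_n, 3)
  expect_equal(attr(back, "dropped"), 0L)
  for (i in 1:3) {
    orig <- d$records[[i]]
    got <- back$records[[which(vapply(back$records, function(r) r$record_id,
                                      character(1)) == orig$record_id)]]
    expect_lt(max(abs(got$waveform - orig$waveform)), 1e-3)
    expect_equal(got$age, orig$age)
    expect_equal(got$sex, orig$sex)
    expect_equal(got$label, orig$label)
  }
  # corrupt one demographics row -> record dropped and counted
  demo <- read.csv(file.path(path, "demographics.csv"))
  demo$age[2] <- NA
  write.csv(demo, file.path(path, "demographics.csv"), row.names = FALSE)
  back2 <- read_wfdb_dataset(path)
  expect_equal(back2$size_n, 2)
  expect_equal(attr(back2, "dropped"), 1L)
  expect_error(read_wfdb_dataset(withr::local_tempdir()), "no WFDB headers")
})
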