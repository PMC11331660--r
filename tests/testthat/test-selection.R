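test_that("order_sites sorts by size with stable id tie-break", {
  mk <- function(n, id) {
    recs <- lapply(seq_len(n), function(i)
      ecg_record(matrix(0, 1, 4), 125, 50, "male", 0L,
                 paste0(id, "-", i), id))
    site_dataset(recs, id)
  }
  sites <- list(mk(5, "a"), mk(3, "b"), mk(9, "c"))
  expect_equal(vapply(order_sites(sites, "small_to_large"),
                      function(s) s$size_n, integer(1)), c(3L, 5L, 9L))
  expect_equal(vapply(order_sites(sites, "large_to_small"),
                      function(s) s$size_n, integer(1)), c(9L, 5L, 3L))
  ties <- list(mk(4, "zz"), mk(4, "aa"))
  expect_equal(vapply(order_sites(ties, "small_to_large"),
                      function(s) s$site_id, character(1)), c("aa", "zz"))
})

test_that("select_method returns the fake-score argmax with ordered ties", {
  wrap <- function(score) list(result = list(det = score), fake_score = score)
  res <- list(LwF = wrap(0.70), EWC = wrap(0.80), MAS = wrap(0.75))
  expect_equal(select_method(res)$method_id, "EWC")
  expect_equal(select_method(res["MAS"])$method_id, "MAS")
  tie <- list(LwF = wrap(0.75), EWC = wrap(0.70), MAS = wrap(0.75))
  expect_equal(select_method(tie)$method_id, "LwF")
})

test_that("reference threshold follows the configured reading", {
  cfg_dm <- selection_config(train = tiny_train_config())
  expect_equal(cardiocl:::reference_threshold(cfg_dm, 0.9), 0.05 * 0.9)
  cfg_fr <- selection_config(reference_mode = "fraction_retained",
                             train = tiny_train_config())
  expect_equal(cardiocl:::reference_threshold(cfg_fr, 0.9), 0.95 * 0.9)
})

test_that("lambda decays geometrically until the step bound when unreachable", {
  site <- tiny_site()
  det0 <- train_supervised(site, tiny_det_config(), tiny_train_config(2L),
                           seed = 3)$det
  th <- flatten_params(det0$params)
  st <- method_state(theta_old = th, fisher = rep(1e-4, length(th)),
                     omega = rep(1e-4, length(th)), old_model = det0)
  cfg <- selection_config(reference_mode = "fraction_retained", delta = 1,
                          max_decay_steps = 4L,
                          train = tiny_train_config(2L))
  # p_star above 1 makes the threshold unattainable for any AUROC
  out <- train_with_method(det0, site, "EWC", st, p_star = 1.02,
                           config = cfg, seed = 3,
                           importance_samples = 8L)
  expect_equal(out$result$decay_trace$lambda, c(1, 0.9, 0.81, 0.729))
  expect_true(attr(out$result$decay_trace, "exhausted"))
  # reachable threshold under the drop-margin default: single attempt
  cfg2 <- selection_config(max_decay_steps = 4L,
                           train = tiny_train_config(2L))
  out2 <- train_with_method(det0, site, "EWC", st, p_star = 0.9,
                            config = cfg2, seed = 3,
                            importance_samples = 8L)
  expect_equal(nrow(out2$result$decay_trace), 1L)
  expect_equal(out2$result$decay_trace$lambda, 1)
})

test_that("a zero lambda_init reproduces the finetune baseline bitwise", {
  site <- tiny_site()
  det0 <- train_supervised(site, tiny_det_config(), tiny_train_config(2L),
                           seed = 4)$det
  th <- flatten_params(det0$params)
  st <- method_state(theta_old = th, fisher = abs(rnorm(length(th))),
                     omega = abs(rnorm(length(th))), old_model = det0)
  cfg <- selection_config(lambda_init = 0, max_decay_steps = 2L,
                          train = tiny_train_config(3L))
  base <- finetune_baseline(det0, site, cfg, seed = 8)
  for (m in c("LwF", "EWC", "MAS")) {
    out <- train_with_method(det0, site, m, st, p_star = base$best_val_metric,
                             config = cfg, seed = 8, importance_samples = 4L)
    expect_identical(flatten_params(out$result$det$params),
                     flatten_params(base$det$params))
  }
  expect_error(train_with_method(det0, site, "XYZ", st, 0.5, cfg, 1),
               "unknown method_id")
})

test_that("evaluate_on_fake averages by size and skips single-class sets", {
  site <- tiny_site()
  det <- train_supervised(site, tiny_det_config(), tiny_train_config(3L),
                          seed = 5)$det
  recs <- partition_records(site, "train")
  fake1 <- structure(list(records = recs[1:30], source_site = "f1",
                          size = 30, synthetic = TRUE),
                     class = "fake_dataset")
  expect_equal(evaluate_on_fake(det, list(fake1)),
               evaluate_detector(det, recs[1:30])$auroc)
  labels <- vapply(recs, function(r) r$label, integer(1))
  ones <- recs[labels == 1][1:5]
  fake_bad <- structure(list(records = ones, source_site = "bad",
                             size = 5, synthetic = TRUE),
                        class = "fake_dataset")
  expect_warning(v <- evaluate_on_fake(det, list(fake1, fake_bad)),
                 "single class")
  expect_equal(v, evaluate_detector(det, recs[1:30])$auroc)
  expect_error(suppressWarnings(evaluate_on_fake(det, list(fake_bad))),
               "single-class")
})

test_that("the multicenter driver selects per site and keeps hand-offs clean", {
  sc <- strong_shift_scenario("tiny")
  sites <- lapply(1:2, function(i) {
    s <- simulate_site(sc$profiles[[i]], sc$config, seed = 50 + i,
                       site_id = sc$site_ids[i])
    split_dataset(preprocess_site(s), seed = i, stratify = TRUE)
  })
  cfg <- selection_config(train = tiny_train_config(3L),
                          max_decay_steps = 2L)
  mc <- run_multicenter(sites, cfg, tiny_det_config(), tiny_synth_config(4L),
                        seed = 60, importance_samples = 8L)
  expect_length(mc$history, 2)
  expect_equal(mc$history[[1]]$chosen, "supervised")
  expect_true(mc$history[[2]]$chosen %in% c("LwF", "EWC", "MAS"))
  # exactly one selection entry carries candidate scores
  expect_null(mc$history[[1]]$fake_scores)
  expect_length(mc$history[[2]]$fake_scores, 3)
  # selection optimality re-verified post hoc from the history
  expect_equal(unname(mc$history[[2]]$fake_scores[mc$history[[2]]$chosen]),
               max(mc$history[[2]]$fake_scores))
  # privacy assertion on the final hand-off
  real_ids <- unlist(lapply(sites, function(s)
    vapply(s$records, function(r) r$record_id, character(1))))
  expect_true(assert_handoff_private(mc$handoff, real_ids))
  expect_setequal(setdiff(names(mc$handoff), "manifest"),
                  c("theta", "det_config", "method_state", "synth_state",
                    "fake_sets"))
  # a poisoned archive fails the assertion
  bad <- mc$handoff
  bad$raw_records <- sites[[1]]$records[1]
  expect_error(assert_handoff_private(bad, real_ids), "unexpected fields")
  # trajectory is computable from stored checkpoints
  traj <- multicenter_trajectory(mc, sites)
  expect_equal(dim(traj), c(2L, 2L))
  expect_true(all(traj >= 0 & traj <= 1))
  expect_error(run_multicenter(sites[1], cfg, tiny_det_config(),
                               tiny_synth_config(4L)), "at least 2")
})

test_that("training never touches other sites' real records", {
  sc <- strong_shift_scenario("tiny")
  sites <- lapply(1:2, function(i) {
    s <- simulate_site(sc$profiles[[i]], sc$config, seed = 70 + i,
                       site_id = sc$site_ids[i])
    split_dataset(preprocess_site(s), seed = i, stratify = TRUE)
  })
  assign(".cardiocl_access_log", character(0), envir = globalenv())
  suppressMessages(trace("records_to_batch",
                         where = asNamespace("cardiocl"), print = FALSE,
                         tracer = quote(assign(
                           ".cardiocl_access_log",
                           c(get(".cardiocl_access_log", envir = globalenv()),
                             unique(vapply(records, function(r) r$site_id,
                                           character(1)))),
                           envir = globalenv()))))
  on.exit({
    suppressMessages(untrace("records_to_batch",
                             where = asNamespace("cardiocl")))
    rm(".cardiocl_access_log", envir = globalenv())
  }, add = TRUE)
  cfg <- selection_config(train = tiny_train_config(2L),
                          max_decay_steps = 1L)
  invisible(run_multicenter(sites, cfg, tiny_det_config(),
                            tiny_synth_config(3L), seed = 71,
                            importance_samples = 4L))
  log <- get(".cardiocl_access_log", envir = globalenv())
  # once the second site starts, the first site's real records never recur
  first_b <- match(sites[[2]]$site_id, log)
  expect_false(any(log[first_b:length(log)] == sites[[1]]$site_id))
})
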