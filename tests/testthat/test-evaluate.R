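test_that("detection depth is the first positive decision", {
  expect_equal(detection_depth(c(1, 1.5, 2, 2.5), c(0, 0, 1, 1)), 2)
  expect_equal(detection_depth(c(1, 1.5, 2), c(1, 0, 0)), 1)
  expect_true(is.na(detection_depth(c(1, 1.5, 2), c(0, 0, 0))))
  expect_error(detection_depth(c(2, 1, 3), c(0, 0, 1)), "increasing")
})

test_that("detection is monotone: adding a positive never deepens it", {
  set.seed(20)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    depths <- cumsum(runif(n, 0.1, 1))
    dec <- rbinom(n, 1, 0.2)
    base <- detection_depth(depths, dec)
    j <- sample(n, 1)
    dec2 <- dec
    dec2[j] <- 1
    flipped <- detection_depth(depths, dec2)
    expect_true(flipped <= ifelse(is.na(base), Inf, base))
  }
})

test_that("never-detected sequences get the worst-late sentinel", {
  res <- detection_result(c(1, 1.5, 2), c(0, 0, 0), bone_strike_depth = 10,
                          forewarning = 5, insertion_id = "x")
  expect_false(res$detected)
  expect_equal(res$signed_error, 5)
  res2 <- detection_result(c(1, 1.5, 2), c(0, 1, 1), bone_strike_depth = 10)
  expect_true(res2$detected)
  expect_equal(res2$signed_error, 1.5 - 5)
})

test_that("error summaries match direct arithmetic", {
  s <- summarize_errors(c(-1, 2, 3))
  expect_equal(s$average_error, 4 / 3, tolerance = 1e-12)
  expect_equal(s$mae, 2)
  expect_equal(s$rmse, sqrt(14 / 3), tolerance = 1e-12)
  z <- summarize_errors(rep(0, 5))
  expect_equal(c(z$average_error, z$mae, z$rmse), c(0, 0, 0))
  one <- summarize_errors(-3.2)
  expect_equal(c(one$average_error, one$mae, one$rmse), c(-3.2, 3.2, 3.2))
  expect_error(summarize_errors(numeric(0)), "nonempty")
})

test_that("rmse >= mae >= |average| on arbitrary error sets", {
  set.seed(21)
  for (i in 1:30) {
    e <- rnorm(sample(2:50, 1), sd = runif(1, 0.1, 20))
    s <- summarize_errors(e)
    expect_gte(s$mae, abs(s$average_error))
    expect_gte(s$rmse + 1e-12, s$mae)
  }
})

test_that("the random-guess baseline reproduces its closed-form values", {
  b40 <- random_guess_baseline(40, 0.5, 5)
  expect_equal(b40$n, 81)
  expect_equal(b40$average_error, -15, tolerance = 1e-12)
  expect_equal(round(b40$mae, 2), 15.68)
  expect_equal(round(b40$rmse, 2), 19.02)
  b10 <- random_guess_baseline(10, 0.5, 5)
  expect_equal(b10$average_error, 0, tolerance = 1e-12)
  expect_equal(b10$mae, 55 / 21, tolerance = 1e-12)
  expect_equal(b10$rmse, sqrt(192.5 / 21), tolerance = 1e-12)
  degenerate <- random_guess_baseline(0, 0.5, 0)
  expect_equal(c(degenerate$average_error, degenerate$mae, degenerate$rmse),
               c(0, 0, 0))
  expect_error(random_guess_baseline(40, 0), "increment")
})

test_that("the baseline agrees with Monte-Carlo sampling within 3 sds", {
  cand <- random_guess_errors(40, 0.5, 5)
  set.seed(22)
  draws <- sample(cand, 1e6, replace = TRUE)
  se <- sd(draws) / sqrt(1e6)
  b <- random_guess_baseline(40, 0.5, 5)
  expect_lt(abs(mean(draws) - b$average_error), 3 * se)
  se_abs <- sd(abs(draws)) / sqrt(1e6)
  expect_lt(abs(mean(abs(draws)) - b$mae), 3 * se_abs)
})

test_that("error histograms center bins on integer errors", {
  h <- error_histogram(c(-0.4, 0.3, 1.6, 2.1, 2.4, 2.6))
  expect_equal(h$center, 0:3)
  expect_equal(h$count, c(2L, 0L, 3L, 1L))
  expect_equal(attr(error_histogram(c(1.9, 2.1, 2.2, -7)), "mode"), 2)
})

test_that("experiments are reproducible end to end from their seeds", {
  cfg <- fast_config(strike_depth_range = c(9, 12), seed = 61)
  ds <- generate_dataset(cfg, 5, c(train = 3, test = 2, validation = 0))
  run <- function() {
    run_experiment(ds, "subsequence_force_ffts", multiprobe = 2,
                   classifier = classifier_config("random_forest", ntree = 60),
                   regime = "split", n_train_sequences = 4,
                   n_eval_sequences = 4, seed = 62)
  }
  a <- run()
  b <- run()
  expect_identical(a$table_row, b$table_row)
  expect_identical(a$results, b$results)
  expect_equal(a$summary$n, 2 * 4)
  expect_true(all(c("classifier", "feature_set", "multiprobe", "regime",
                    "avg_error", "mae", "rmse") %in% names(a$table_row)))
})

test_that("logo evaluation scores every training insertion with its own model", {
  cfg <- fast_config(strike_depth_range = c(9, 12), seed = 63)
  ds <- generate_dataset(cfg, 4, c(train = 3, test = 1, validation = 0))
  ex <- run_experiment(ds, "subsequence_force_ffts", multiprobe = 2,
                       classifier = classifier_config("random_forest",
                                                      ntree = 60),
                       regime = "logo", n_train_sequences = 3,
                       n_eval_sequences = 2, seed = 64)
  train_ids <- names(ds$split_assignment)[ds$split_assignment == "train"]
  expect_setequal(unique(ex$results$insertion_id), train_ids)
  expect_equal(nrow(ex$results), length(train_ids) * 2)
})

test_that("learning curves report one row per grid point with fold bands", {
  cfg <- fast_config(strike_depth_range = c(8, 10), seed = 65)
  ds <- generate_dataset(cfg, 4, c(train = 4, test = 0, validation = 0))
  lc <- learning_curve(ds, sequence_grid = c(2, 3),
                       feature_set = "subsequence_force_ffts",
                       multiprobe = 2,
                       classifier = classifier_config("random_forest",
                                                      ntree = 50),
                       folds = 4, seed = 66)
  expect_equal(nrow(lc), 2)
  expect_equal(lc$n_sequences, c(2, 3))
  expect_equal(lc$n_train_examples, round(c(8, 12) * 3 / 4))
  expect_true(all(is.finite(lc$validation_mean)))
  expect_true(all(lc$train_mean <= lc$validation_mean))
  expect_error(
    learning_curve(ds, sequence_grid = 1, folds = 50,
                   feature_set = "subsequence_force_ffts",
                   classifier = classifier_config("random_forest",
                                                  ntree = 50)),
    "fold count")
})

test_that("the directionality protocol separates high-contrast geometry", {
  mech <- mechanical_params(delta_k = 1, length_scale = 4,
                            onset_distance = 10)
  cfg <- fast_config(mechanics = mech, sensors = quiet_sensors(), seed = 67)
  dset <- generate_directionality_set(cfg, offsets = c(1, 4, 8),
                                      n_per_condition = 30, seed = 68)
  dp <- directionality_protocol(dset, seed = 69)
  expect_equal(dp$per_offset$offset, c(1, 4, 8))
  expect_gte(dp$overall, 0.99)
  expect_identical(directionality_protocol(dset, seed = 69)$overall,
                   dp$overall)
  small <- generate_directionality_set(cfg, offsets = 1,
                                       n_per_condition = 10, seed = 70)
  expect_error(directionality_protocol(small), "fewer than")
})
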