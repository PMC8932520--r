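acq <- acquisition_spec()
spec <- feature_set_spec("subsequence_force_ffts")

# Toy linearly separable windows: feature 1 tracks distance exactly.
toy_windows <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  dist_close <- runif(n_per_class, 0.5, 4.5)
  dist_far <- runif(n_per_class, 6, 20)
  distances <- c(dist_close, dist_far)
  X <- cbind(distances + rnorm(2 * n_per_class, 0, 0.05),
             rnorm(2 * n_per_class))
  colnames(X) <- c("f1", "f2")
  list(X = X, distances = distances,
       groups = rep(c("g1", "g2"), n_per_class))
}

test_that("a linear SVM separates a separable toy problem perfectly", {
  tw <- toy_windows()
  fit <- fit_detector(tw$X, tw$distances, tw$groups,
                      classifier_config("linear_svm"), "split")
  expect_equal(decide(fit, tw$X), binary_label(tw$distances))
})

test_that("single-class training sets are rejected with the missing class named", {
  tw <- toy_windows()
  far_only <- tw$distances > 5
  expect_error(
    fit_detector(tw$X[far_only, ], tw$distances[far_only],
                 tw$groups[far_only], classifier_config("linear_svm"),
                 "split"),
    "class '1'")
})

test_that("window layout mismatches are rejected at decision time", {
  tw <- toy_windows()
  fit <- fit_detector(tw$X, tw$distances, tw$groups,
                      classifier_config("random_forest", ntree = 50), "split")
  expect_error(decide(fit, tw$X[, 1, drop = FALSE]), "layout mismatch")
})

test_that("logo fits one model per insertion and needs at least two", {
  tw <- toy_windows()
  fits <- fit_detector(tw$X, tw$distances, tw$groups,
                       classifier_config("linear_svm"), "logo")
  expect_named(fits, c("g1", "g2"))
  expect_s3_class(fits$g1, "detector_fit")
  one <- tw$groups == "g1"
  expect_error(
    fit_detector(tw$X[one, ], tw$distances[one], tw$groups[one],
                 classifier_config("linear_svm"), "logo"),
    "at least 2")
})

test_that("all three families are deterministic given data and seed", {
  tw <- toy_windows(seed = 3)
  for (family in c("linear_svm", "random_forest", "gb_distance_regressor")) {
    cfg <- classifier_config(family, seed = 11, ntree = 50, nrounds = 30)
    a <- decide(fit_detector(tw$X, tw$distances, tw$groups, cfg, "split"),
                tw$X)
    b <- decide(fit_detector(tw$X, tw$distances, tw$groups, cfg, "split"),
                tw$X)
    expect_identical(a, b)
  }
})

test_that("the distance regressor thresholds its prediction inclusively", {
  tw <- toy_windows(n_per_class = 100, seed = 5)
  cfg <- classifier_config("gb_distance_regressor", nrounds = 50)
  fit <- fit_detector(tw$X, tw$distances, tw$groups, cfg, "split")
  pred <- predict(fit$model, tw$X)
  expect_identical(decide(fit, tw$X), as.integer(pred <= 5))
  # predictions should recover distance well enough to classify correctly
  expect_gt(mean(as.integer(pred <= 5) == binary_label(tw$distances)), 0.95)
})

test_that("held-out balanced accuracy is high under a sharp 5 mm stiffness onset", {
  mech <- mechanical_params(onset_distance = 5, onset_form = "step")
  cfg <- fast_config(mechanics = mech, sensors = quiet_sensors(),
                     strike_depth_range = c(10, 14), seed = 41)
  ds <- generate_dataset(cfg, 6, c(train = 4, test = 2, validation = 0))
  feats <- lapply(ds$insertions, featurize_insertion, spec = spec,
                  acquisition = acq)
  pool <- function(ids, n_seq, seed) {
    out <- lapply(feats[ids], function(f) {
      seqs <- sample_sequences(f, n_seq, seed = seed)
      ws <- lapply(seqs, compile_multiprobe, N = 2)
      list(X = do.call(rbind, lapply(ws, `[[`, "X")),
           d = unlist(lapply(ws, `[[`, "distances")))
    })
    list(X = do.call(rbind, lapply(out, `[[`, "X")),
         d = unlist(lapply(out, `[[`, "d")))
  }
  train_ids <- names(ds$split_assignment)[ds$split_assignment == "train"]
  test_ids <- names(ds$split_assignment)[ds$split_assignment == "test"]
  tr <- pool(train_ids, 5, seed = 7)
  te <- pool(test_ids, 3, seed = 8)
  y_true <- binary_label(te$d)
  for (family in c("linear_svm", "random_forest", "gb_distance_regressor")) {
    fit <- fit_detector(tr$X, tr$d, rep("x", length(tr$d)),
                        classifier_config(family, ntree = 100, nrounds = 60),
                        "split")
    y_hat <- decide(fit, te$X)
    bal_acc <- mean(c(mean(y_hat[y_true == 1] == 1),
                      mean(y_hat[y_true == 0] == 0)))
    expect_gt(bal_acc, 0.95)
  }
})

test_that("the null generator produces no depth leakage in decisions", {
  mech <- mechanical_params(delta_k = 0)
  cfg <- fast_config(mechanics = mech, strike_depth_range = c(10, 14),
                     seed = 51)
  ds <- generate_dataset(cfg, 6, c(train = 4, test = 2, validation = 0))
  ex <- run_experiment(ds, spec, multiprobe = 2,
                       classifier = classifier_config("random_forest",
                                                      ntree = 100),
                       regime = "split", n_train_sequences = 5,
                       n_eval_sequences = 5, seed = 52)
  # recompute per-depth decisions on test insertions and compare positive
  # rates near vs far from bone: they should be statistically similar
  feats <- lapply(ds$insertions, featurize_insertion, spec = spec,
                  acquisition = acq)
  train_ids <- names(ds$split_assignment)[ds$split_assignment == "train"]
  pool <- do.call(rbind, lapply(feats[train_ids], function(f) {
    s <- sample_sequences(f, 5, seed = 53)
    do.call(rbind, lapply(s, function(q) {
      w <- compile_multiprobe(q, 2)
      cbind(w$X, d = w$distances)
    }))
  }))
  fit <- fit_detector(pool[, -ncol(pool)], pool[, "d"],
                      rep("x", nrow(pool)),
                      classifier_config("random_forest", ntree = 100), "split")
  test_ids <- names(ds$split_assignment)[ds$split_assignment == "test"]
  rates <- unlist(lapply(feats[test_ids], function(f) {
    s <- sample_sequences(f, 5, seed = 54)
    unlist(lapply(s, function(q) {
      w <- compile_multiprobe(q, 2)
      dec <- decide(fit, w$X)
      c(near = mean(dec[w$distances <= 5]), far = mean(dec[w$distances > 5]))
    }))
  }))
  near <- mean(rates[grepl("near", names(rates))])
  far <- mean(rates[grepl("far", names(rates))])
  expect_lt(abs(near - far), 0.2)
})
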