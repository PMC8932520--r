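#' Classifier configuration
#'
#' Three detector families are supported. `linear_svm` and `random_forest`
#' are trained on binary close-to-bone labels (distance within
#' `decision_threshold` of bone, inclusive); `gb_distance_regressor` is a
#' gradient-boosted regressor trained on the raw distance-from-bone labels
#' whose prediction is thresholded at `decision_threshold` mm to reach a
#' binary decision. Features are standardized (train-set mean/sd) for the
#' SVM by default; tree ensembles are scale-invariant and left
#' unstandardized. Hyperparameters are library defaults with fixed seeds.
#'
#' @param family `"linear_svm"`, `"random_forest"`, or
#'   `"gb_distance_regressor"`.
#' @param decision_threshold Forewarning margin in mm (default 5).
#' @param standardize Standardize features with train-set mean/sd; defaults
#'   to `TRUE` for the SVM, `FALSE` otherwise.
#' @param seed Integer seed for the stochastic learners.
#' @param cost SVM soft-margin cost.
#' @param ntree Random-forest tree count.
#' @param nrounds,max_depth,eta Gradient-boosting rounds, tree depth, and
#'   learning rate.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(family = c("linear_svm", "random_forest",
                                         "gb_distance_regressor"),
                              decision_threshold = 5.0,
                              standardize = NULL,
                              seed = 1L,
                              cost = 1, ntree = 300L,
                              nrounds = 150L, max_depth = 4L, eta = 0.1) {
  family <- match.arg(family)
  stopifnot(decision_threshold > 0)
  if (is.null(standardize)) standardize <- family == "linear_svm"
  structure(
    list(family = family,
         label_mode = if (family == "gb_distance_regressor") "distance"
                      else "binary",
         decision_threshold = decision_threshold,
         standardize = standardize, seed = as.integer(seed),
         cost = cost, ntree = as.integer(ntree),
         nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
         eta = eta),
    class = "classifier_config"
  )
}

# Fit one model on a window matrix; distances are the raw mm labels.
fit_single <- function(X, distances, config) {
  stopifnot(nrow(X) == length(distances))
  center <- scale_ <- NULL
  if (config$standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(sweep(X, 2, center, "-"), 2, scale_, "/")
  }
  model <- with_seed(config$seed, switch(
    config$family,
    linear_svm = {
      y <- factor(binary_label(distances, config$decision_threshold),
                  levels = c(0, 1))
      check_both_classes(y)
      e1071::svm(x = X, y = y, kernel = "linear", cost = config$cost,
                 scale = FALSE)
    },
    random_forest = {
      y <- factor(binary_label(distances, config$decision_threshold),
                  levels = c(0, 1))
      check_both_classes(y)
      randomForest::randomForest(x = X, y = y, ntree = config$ntree)
    },
    gb_distance_regressor = {
      xgboost::xgboost(
        x = X, y = distances,
        objective = "reg:squarederror", nrounds = config$nrounds,
        max_depth = config$max_depth, learning_rate = config$eta,
        nthreads = 1, verbosity = 0, seed = config$seed
      )
    }
  ))
  structure(list(model = model, config = config, center = center,
                 scale = scale_, n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "detector_fit")
}

check_both_classes <- function(y) {
  missing <- setdiff(levels(y), as.character(unique(y)))
  if (length(missing)) {
    stop("training set contains no windows of class '", missing[1],
         "'; both close-to-bone classes are required")
  }
  invisible(y)
}

#' Fit bone-proximity detectors
#'
#' Under the `split` regime, fits one model on all supplied windows (the
#' caller passes the training-split insertions). Under the `logo`
#' (leave-one-group-out) regime, fits one model per insertion, each trained
#' on the windows of every other insertion; the held-out insertion is then
#' evaluated with its own model via [decide()]. Group integrity — no window
#' from an evaluation insertion contributing to the model that scores it —
#' is structural under both regimes.
#'
#' @param X Window matrix (rows = multiprobe windows).
#' @param distances Distance-from-bone label per row, mm.
#' @param groups Insertion id per row.
#' @param config A [classifier_config()].
#' @param regime `"split"` or `"logo"`.
#' @return For `split`, a single `detector_fit`; for `logo`, a named list of
#'   `detector_fit` objects keyed by the held-out insertion id.
#' @export
fit_detector <- function(X, distances, groups, config,
                         regime = c("split", "logo")) {
  regime <- match.arg(regime)
  stopifnot(nrow(X) == length(distances), length(groups) == length(distances))
  if (regime == "split") {
    return(fit_single(X, distances, config))
  }
  ids <- unique(groups)
  if (length(ids) < 2) stop("logo regime needs at least 2 insertions")
  fits <- lapply(ids, function(id) {
    keep <- groups != id
    fit_single(X[keep, , drop = FALSE], distances[keep], config)
  })
  setNames(fits, ids)
}

#' Binary close-to-bone decisions for windows
#'
#' Binary families return their class decision directly; the distance
#' regressor returns 1 iff the predicted distance is at most the decision
#' threshold (inclusive, mirroring the binary labelling convention).
#'
#' @param fit A `detector_fit` from [fit_detector()].
#' @param X Window matrix with the training layout.
#' @return Integer vector of 0/1 decisions.
#' @export
decide <- function(fit, X) {
  stopifnot(inherits(fit, "detector_fit"))
  if (ncol(X) != fit$n_features) {
    stop("window layout mismatch: model expects ", fit$n_features,
         " features, got ", ncol(X))
  }
  if (fit$config$standardize) {
    X <- sweep(sweep(X, 2, fit$center, "-"), 2, fit$scale, "/")
  }
  if (fit$config$family == "gb_distance_regressor") {
    pred <- predict(fit$model, X)
    as.integer(pred <= fit$config$decision_threshold)
  } else {
    as.integer(as.character(predict(fit$model, X)))
  }
}
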