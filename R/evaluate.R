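#' Detection depth of a decision sequence
#'
#' The needle depth of the first probe event classified as close to bone
#' becomes the detection depth for the whole insertion; `NA` when no depth
#' is classified positive.
#'
#' @param depths Strictly increasing needle depths, mm.
#' @param decisions 0/1 decision per depth, in the same order.
#' @return Detection depth in mm, or `NA_real_`.
#' @examples
#' detection_depth(c(1, 1.5, 2, 2.5), c(0, 0, 1, 1))  # 2
#' @export
detection_depth <- function(depths, decisions) {
  stopifnot(length(depths) == length(decisions))
  if (length(depths) > 1 && any(diff(depths) <= 0)) {
    stop("depths must be strictly increasing")
  }
  hit <- which(decisions == 1)
  if (!length(hit)) NA_real_ else depths[hit[1]]
}

#' Signed detection error for one evaluated sequence
#'
#' The threshold depth is `bone_strike_depth - forewarning`; the signed
#' error is `detection_depth - threshold_depth`. Negative errors mean the
#' alarm fired early (further from bone than the forewarning margin),
#' positive errors late. A sequence with no positive decision is assigned
#' the worst-late sentinel `+forewarning` (equivalent to detecting at bone
#' strike) and flagged `detected = FALSE`.
#'
#' @param depths,decisions As in [detection_depth()].
#' @param bone_strike_depth Ground-truth strike depth, mm.
#' @param forewarning Forewarning margin, mm (default 5).
#' @param insertion_id Identifier carried into the result.
#' @return A one-row data frame: `insertion_id`, `detection_depth`,
#'   `threshold_depth`, `signed_error`, `detected`.
#' @export
detection_result <- function(depths, decisions, bone_strike_depth,
                             forewarning = 5.0, insertion_id = NA_character_) {
  dd <- detection_depth(depths, decisions)
  threshold_depth <- bone_strike_depth - forewarning
  detected <- !is.na(dd)
  data.frame(
    insertion_id = insertion_id,
    detection_depth = dd,
    threshold_depth = threshold_depth,
    signed_error = if (detected) dd - threshold_depth else forewarning,
    detected = detected,
    stringsAsFactors = FALSE
  )
}

#' Summarize signed detection errors
#'
#' @param errors Nonempty numeric vector of signed errors, mm.
#' @return An `error_summary`: list with `average_error` (mean, signaling
#'   early/late bias), `mae` (mean absolute error), `rmse` (root mean square
#'   error, emphasizing extremes), and `n`.
#' @examples
#' summarize_errors(c(-1, 2, 3))
#' @export
summarize_errors <- function(errors) {
  if (!length(errors)) stop("errors must be nonempty")
  structure(
    list(average_error = mean(errors),
         mae = mean(abs(errors)),
         rmse = sqrt(mean(errors^2)),
         n = length(errors)),
    class = "error_summary"
  )
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("average error %.2f mm, MAE %.2f mm, RMSE %.2f mm (n = %d)\n",
              x$average_error, x$mae, x$rmse, x$n))
  invisible(x)
}

#' Histogram of signed detection errors
#'
#' Bins of width `binwidth` centered on integer multiples of `binwidth`
#' (the granularity at which detection-error clusters are read off).
#'
#' @param errors Numeric vector of signed errors, mm.
#' @param binwidth Bin width, mm (default 1).
#' @return A data frame of `center` and `count`, with the modal bin center
#'   in attribute `"mode"` (ties broken toward the smallest center).
#' @export
error_histogram <- function(errors, binwidth = 1) {
  if (!length(errors)) stop("errors must be nonempty")
  stopifnot(binwidth > 0)
  centers_of <- binwidth * round(errors / binwidth)
  lev <- seq(min(centers_of), max(centers_of), by = binwidth)
  counts <- as.integer(table(factor(centers_of, levels = lev)))
  out <- data.frame(center = lev, count = counts)
  attr(out, "mode") <- lev[which.max(counts)]
  out
}

#' Candidate signed errors of uniform random guessing
#'
#' Enumerates the candidate detection depths `0, increment, ...,
#' insertion_length` (inclusive endpoints) and returns the signed error of
#' each relative to the threshold depth `insertion_length - forewarning`.
#'
#' @param insertion_length Theoretical insertion length, mm.
#' @param increment Candidate grid spacing, mm.
#' @param forewarning Forewarning margin, mm.
#' @return Numeric vector of candidate signed errors.
#' @export
random_guess_errors <- function(insertion_length, increment = 0.5,
                                forewarning = 5.0) {
  if (increment <= 0) stop("increment must be > 0")
  if (insertion_length < 0) stop("insertion_length must be >= 0")
  candidates <- seq(0, insertion_length, by = increment)
  if (utils::tail(candidates, 1) < insertion_length) {
    candidates <- c(candidates, insertion_length)
  }
  candidates - (insertion_length - forewarning)
}

#' Closed-form random-guess baseline
#'
#' Error measures of a guesser that picks the detection depth uniformly
#' from the candidate grid of a theoretical insertion. For the canonical
#' 40 mm insertion probed every 0.5 mm with 5 mm forewarning this gives an
#' average error of -15.00 mm, MAE 15.68 mm, and RMSE 19.02 mm over the
#' 81-candidate grid — the floor any useful detector must beat.
#'
#' @inheritParams random_guess_errors
#' @return An `error_summary`.
#' @examples
#' random_guess_baseline(40, 0.5, 5)
#' @export
random_guess_baseline <- function(insertion_length, increment = 0.5,
                                  forewarning = 5.0) {
  summarize_errors(random_guess_errors(insertion_length, increment,
                                       forewarning))
}

# Resolve a classifier argument (config object or family name) to a config.
as_classifier_config <- function(classifier, seed) {
  if (inherits(classifier, "classifier_config")) return(classifier)
  classifier_config(family = classifier, seed = seed)
}

# Stack multiprobe windows over sampled sequences of several insertions.
build_window_pool <- function(feats_list, n_sequences, multiprobe, padding) {
  pools <- lapply(feats_list, function(feats) {
    seqs <- sample_sequences(feats, n_sequences)
    ws <- lapply(seqs, compile_multiprobe, N = multiprobe, padding = padding)
    list(X = do.call(rbind, lapply(ws, `[[`, "X")),
         distances = unlist(lapply(ws, `[[`, "distances")),
         group = feats$insertion_id)
  })
  list(X = do.call(rbind, lapply(pools, `[[`, "X")),
       distances = unlist(lapply(pools, `[[`, "distances")),
       groups = unlist(lapply(pools, function(p) rep(p$group, length(p$distances)))))
}

#' Run a full detection experiment
#'
#' Composes the complete pipeline: featurize every probe event, sample
#' single-replicate sequences, compile multiprobe windows, fit the
#' requested detector under the requested regime, score each evaluation
#' sequence with the first-positive detection rule, and summarize the
#' signed errors. Under the `split` regime the detector trains on the
#' train-split insertions and is evaluated on the test split; under `logo`
#' each train-split insertion is evaluated by the model trained on the
#' other eleven.
#'
#' @param dataset An [insertion_dataset()].
#' @param feature_set Feature-set name or [feature_set_spec()].
#' @param multiprobe Window length `N` (default 3).
#' @param classifier Family name or [classifier_config()].
#' @param regime `"split"` or `"logo"`.
#' @param n_train_sequences Sequences sampled per training insertion
#'   (default 10).
#' @param n_eval_sequences Sequences sampled per evaluation insertion
#'   (default 10; each yields one detection error).
#' @param forewarning Forewarning margin, mm (default 5).
#' @param padding Multiprobe padding rule (see [compile_multiprobe()]).
#' @param seed Seed governing all sampling and fitting.
#' @return A list with `results` (one row per evaluated sequence),
#'   `summary` (an `error_summary`), and `table_row` (one-row data frame of
#'   configuration and the three error measures).
#' @export
run_experiment <- function(dataset,
                           feature_set = "subsequence_force_ffts",
                           multiprobe = 3L,
                           classifier = "random_forest",
                           regime = c("split", "logo"),
                           n_train_sequences = 10L,
                           n_eval_sequences = 10L,
                           forewarning = 5.0,
                           padding = "repeat_first",
                           seed = 1L) {
  regime <- match.arg(regime)
  spec <- if (inherits(feature_set, "feature_set_spec")) feature_set
          else feature_set_spec(feature_set)
  config <- as_classifier_config(classifier, seed = derive_seed(seed, 17))
  split <- dataset$split_assignment
  train_ids <- names(split)[split == "train"]
  eval_ids <- if (regime == "split") names(split)[split == "test"] else train_ids
  if (!length(train_ids)) stop("dataset has no training insertions")
  if (!length(eval_ids)) stop("dataset has no evaluation insertions")

  with_seed(seed, {
    feats <- lapply(dataset$insertions[union(train_ids, eval_ids)],
                    featurize_insertion, spec = spec,
                    acquisition = dataset$acquisition)
    pool <- build_window_pool(feats[train_ids], n_train_sequences,
                              multiprobe, padding)
    fits <- fit_detector(pool$X, pool$distances, pool$groups, config, regime)
    results <- do.call(rbind, lapply(eval_ids, function(id) {
      fit <- if (regime == "split") fits else fits[[id]]
      seqs <- sample_sequences(feats[[id]], n_eval_sequences)
      do.call(rbind, lapply(seq_along(seqs), function(s) {
        w <- compile_multiprobe(seqs[[s]], N = multiprobe, padding = padding)
        res <- detection_result(w$depths, decide(fit, w$X),
                                bone_strike_depth = seqs[[s]]$bone_strike_depth,
                                forewarning = forewarning, insertion_id = id)
        res$sequence <- s
        res
      }))
    }))
    summary <- summarize_errors(results$signed_error)
    list(
      results = results,
      summary = summary,
      table_row = data.frame(
        classifier = config$family, feature_set = spec$name,
        multiprobe = as.integer(multiprobe), regime = regime,
        avg_error = summary$average_error, mae = summary$mae,
        rmse = summary$rmse, stringsAsFactors = FALSE
      )
    )
  })
}

#' Learning curve over the number of sampled sequences
#'
#' Sweeps the number of sequences sampled per training insertion and, at
#' each grid point, runs k-fold cross-validation with whole sequences as
#' the fold unit (so windows from one sequence never straddle a fold
#' boundary). The error at each fold is the mean absolute detection error
#' over the fold's sequences; the curve reports mean and sd across folds
#' for both the training and the validation side.
#'
#' @param dataset An [insertion_dataset()] (train split is used).
#' @param sequence_grid Numbers of sequences per insertion to sweep.
#' @param feature_set,multiprobe,classifier,forewarning,padding As in
#'   [run_experiment()].
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for sampling and fold assignment.
#' @return A data frame with one row per grid point: `n_sequences`,
#'   `n_train_examples` (sequences per training fold), `train_mean`,
#'   `train_sd`, `validation_mean`, `validation_sd`.
#' @export
learning_curve <- function(dataset, sequence_grid = c(2, 5, 10),
                           feature_set = "raw_union_stats",
                           multiprobe = 3L,
                           classifier = "random_forest",
                           folds = 5L, forewarning = 5.0,
                           padding = "repeat_first", seed = 1L) {
  if (!length(sequence_grid)) stop("sequence_grid must be nonempty")
  spec <- if (inherits(feature_set, "feature_set_spec")) feature_set
          else feature_set_spec(feature_set)
  config <- as_classifier_config(classifier, seed = derive_seed(seed, 29))
  split <- dataset$split_assignment
  train_ids <- names(split)[split == "train"]
  if (!length(train_ids)) stop("dataset has no training insertions")

  with_seed(seed, {
    feats <- lapply(dataset$insertions[train_ids], featurize_insertion,
                    spec = spec, acquisition = dataset$acquisition)
    n_max <- max(sequence_grid)
    all_seqs <- unlist(lapply(feats, sample_sequences, n_sequences = n_max),
                       recursive = FALSE)
    seq_rank <- rep(seq_len(n_max), times = length(feats))
    rows <- lapply(sort(sequence_grid), function(n_seq) {
      seqs <- all_seqs[seq_rank <= n_seq]
      if (folds > length(seqs)) {
        stop("fold count (", folds, ") exceeds sequence count (",
             length(seqs), ")")
      }
      fold_of <- sample(rep_len(seq_len(folds), length(seqs)))
      ws <- lapply(seqs, compile_multiprobe, N = multiprobe, padding = padding)
      per_fold <- vapply(seq_len(folds), function(f) {
        tr <- which(fold_of != f)
        te <- which(fold_of == f)
        fit <- fit_single(
          do.call(rbind, lapply(ws[tr], `[[`, "X")),
          unlist(lapply(ws[tr], `[[`, "distances")), config)
        seq_abs_error <- function(i) {
          res <- detection_result(ws[[i]]$depths, decide(fit, ws[[i]]$X),
                                  seqs[[i]]$bone_strike_depth, forewarning)
          abs(res$signed_error)
        }
        c(train = mean(vapply(tr, seq_abs_error, numeric(1))),
          validation = mean(vapply(te, seq_abs_error, numeric(1))))
      }, c(train = 0, validation = 0))
      data.frame(
        n_sequences = n_seq,
        n_train_examples = round(length(seqs) * (folds - 1) / folds),
        train_mean = mean(per_fold["train", ]),
        train_sd = sd(per_fold["train", ]),
        validation_mean = mean(per_fold["validation", ]),
        validation_sd = sd(per_fold["validation", ])
      )
    })
    do.call(rbind, rows)
  })
}

#' Perpendicular-vs-parallel directionality protocol
#'
#' For each offset from the hard interface, trains a linear SVM on the raw
#' concatenated force+displacement series to separate perpendicular from
#' parallel probe events: `n_balanced` events per condition (parallel
#' events drawn at random from the pool), scored by k-fold cross-validation
#' accuracy, repeated with fresh random selections and fold splits, and
#' averaged. Reports per-offset and overall mean accuracy.
#'
#' @param dirset A `directionality_set` from [generate_directionality_set()].
#' @param n_balanced Events per condition entering each SVM (default 30).
#' @param folds CV folds (default 5).
#' @param repeats Repetitions with fresh random selections (default 3).
#' @param seed Seed.
#' @return A list with `per_offset` (data frame `offset`, `accuracy`) and
#'   `overall` (mean accuracy across offsets).
#' @export
directionality_protocol <- function(dirset, n_balanced = 30L, folds = 5L,
                                    repeats = 3L, seed = 1L) {
  stopifnot(inherits(dirset, "directionality_set"))
  raw <- t(vapply(dirset$events, function(e) c(e$force, e$displacement),
                  numeric(2 * length(dirset$events[[1]]$force))))
  with_seed(seed, {
    offsets <- sort(unique(dirset$offset))
    acc <- vapply(offsets, function(off) {
      perp <- which(dirset$offset == off & dirset$condition == "perpendicular")
      para <- which(dirset$offset == off & dirset$condition == "parallel")
      if (length(perp) < n_balanced || length(para) < n_balanced) {
        stop("offset ", off, " mm has fewer than ", n_balanced,
             " events in a condition")
      }
      mean(vapply(seq_len(repeats), function(r) {
        sel <- c(if (length(perp) > n_balanced) sample(perp, n_balanced) else perp,
                 sample(para, n_balanced))
        y <- factor(rep(c("perpendicular", "parallel"), each = n_balanced))
        X <- raw[sel, , drop = FALSE]
        fold_of <- sample(rep_len(seq_len(folds), length(sel)))
        mean(vapply(seq_len(folds), function(f) {
          tr <- fold_of != f
          m <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr],
                          kernel = "linear", scale = FALSE)
          mean(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
        }, numeric(1)))
      }, numeric(1)))
    }, numeric(1))
    list(per_offset = data.frame(offset = offsets, accuracy = acc),
         overall = mean(acc))
  })
}
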