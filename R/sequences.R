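#' Sample single-replicate sequences from an insertion
#'
#' The test bed records three replicate probe events at every depth;
#' sequence sampling draws one replicate uniformly at random per depth to
#' form a sequence with exactly one feature vector per depth. Sampling more
#' sequences than once augments the training pool (the bench protocol drew
#' ten sequences per training insertion, giving 120 from 12 insertions).
#' Replicate order within a depth carries no information downstream.
#'
#' @param feats Output of [featurize_insertion()].
#' @param n_sequences Number of independent sequences to draw.
#' @param seed Optional seed (caller RNG preserved when supplied).
#' @return A list of `sampled_sequence` objects, each with `insertion_id`,
#'   `bone_strike_depth`, `depths`, `distances`, feature matrix `X` (one row
#'   per depth), and the `replicate_choices` made.
#' @export
sample_sequences <- function(feats, n_sequences = 1L, seed = NULL) {
  meta <- feats$meta
  depth_rows <- split(seq_len(nrow(meta)), meta$needle_depth)
  n_at_depth <- lengths(depth_rows)
  if (any(n_at_depth == 0)) stop("a depth has zero replicate events")
  depths <- as.numeric(names(depth_rows))
  ord <- order(depths)
  depth_rows <- depth_rows[ord]
  depths <- depths[ord]
  with_seed(seed, {
    lapply(seq_len(n_sequences), function(s) {
      rows <- vapply(depth_rows, function(idx) {
        if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)]
      }, integer(1))
      structure(
        list(insertion_id = feats$insertion_id,
             bone_strike_depth = feats$bone_strike_depth,
             depths = depths,
             distances = meta$distance_from_bone[rows],
             X = feats$X[rows, , drop = FALSE],
             replicate_choices = meta$replicate_index[rows]),
        class = "sampled_sequence"
      )
    })
  })
}

#' Compile multiprobe windows along a sequence
#'
#' At each depth, concatenates the feature vector at the current depth with
#' those of the `N - 1` previous depths, so the classifier sees a window of
#' `N` consecutive probe events (oldest first, current depth last). Every
#' depth yields one window. Two treatments of the first `N - 1` depths are
#' available: `repeat_first` pads by repeating the shallowest feature vector
#' (keeping every depth classifiable, which the first-positive detection
#' rule needs), and `skip` drops those depths instead.
#'
#' @param sequence A `sampled_sequence` from [sample_sequences()].
#' @param N Window length in probe events (>= 1).
#' @param padding `"repeat_first"` or `"skip"`.
#' @return A list with `depths`, `distances`, and window matrix `X` of
#'   `N * ncol(sequence$X)` columns.
#' @export
compile_multiprobe <- function(sequence, N = 1L,
                               padding = c("repeat_first", "skip")) {
  padding <- match.arg(padding)
  if (N < 1) stop("multiprobe window length N must be >= 1")
  n <- length(sequence$depths)
  if (!n) stop("sequence is empty")
  keep <- if (padding == "skip") seq_len(n)[seq_len(n) >= N] else seq_len(n)
  if (!length(keep)) stop("sequence shorter than multiprobe window with skip padding")
  windows <- t(vapply(keep, function(i) {
    idx <- pmax(seq(i - N + 1L, i), 1L)
    as.numeric(t(sequence$X[idx, , drop = FALSE]))
  }, numeric(N * ncol(sequence$X))))
  colnames(windows) <- paste0("w", rep(seq_len(N) - N, each = ncol(sequence$X)),
                              ".", colnames(sequence$X))
  list(depths = sequence$depths[keep],
       distances = sequence$distances[keep],
       X = windows)
}
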