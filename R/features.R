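#' Canonical subsequence windows of a probe event
#'
#' Regions of interest within the 0.25 s recording, fixed for all probe
#' events: `initial_conditions` (0-12.5 ms, before actuation), `step_input`
#' (12.5-30 ms, the probe in motion), `unsteady_force` (12.5-60 ms, the
#' transient), and `steady_state` (200-250 ms, the settled response).
#'
#' @return A data frame with columns `name`, `t_start`, `t_end` (ms).
#' @export
subsequence_specs <- function() {
  data.frame(
    name = c("initial_conditions", "step_input", "unsteady_force",
             "steady_state"),
    t_start = c(0, 12.5, 12.5, 200),
    t_end = c(12.5, 30, 60, 250),
    stringsAsFactors = FALSE
  )
}

#' Extract a timing window from a sampled series
#'
#' Sample `i` (zero-based) at sampling rate `fs` carries timestamp
#' `1000 * i / fs` ms; the window is half-open, keeping samples with
#' `t_start <= t < t_end`, so adjacent windows do not overlap.
#'
#' @param series Numeric vector of length `acquisition$n_samples`.
#' @param t_start,t_end Window bounds in ms.
#' @param acquisition An [acquisition_spec()].
#' @return The windowed samples.
#' @examples
#' acq <- acquisition_spec()
#' length(extract_subsequence(rnorm(100), 200, 250, acq))  # 20
#' @export
extract_subsequence <- function(series, t_start, t_end, acquisition) {
  if (length(series) != acquisition$n_samples) {
    stop("series length ", length(series), " does not match acquisition (",
         acquisition$n_samples, " samples)")
  }
  t_ms <- 1000 * (seq_along(series) - 1) / acquisition$sampling_rate
  keep <- t_ms >= t_start & t_ms < t_end
  if (!any(keep)) {
    stop("window [", t_start, ", ", t_end, ") ms contains no samples at ",
         acquisition$sampling_rate, " Hz")
  }
  series[keep]
}

#' Statistical moment features of a series
#'
#' Population moments: mean, standard deviation `sqrt(m2)`, skewness
#' `m3 / m2^1.5`, and excess kurtosis `m4 / m2^2 - 3`. A zero-variance
#' series returns sd = skewness = kurtosis = 0 rather than NaN.
#'
#' @param series Nonempty numeric vector.
#' @return Named numeric vector `(mean, sd, skewness, kurtosis)`.
#' @examples
#' moment_features(c(1, 2, 3, 4, 10))
#' @export
moment_features <- function(series) {
  if (!length(series)) stop("series must be nonempty")
  m <- mean(series)
  dev <- series - m
  m2 <- mean(dev^2)
  if (m2 == 0) {
    return(c(mean = m, sd = 0, skewness = 0, kurtosis = 0))
  }
  c(mean = m,
    sd = sqrt(m2),
    skewness = mean(dev^3) / m2^1.5,
    kurtosis = mean(dev^4) / m2^2 - 3)
}

#' FFT magnitude features of a series
#'
#' Magnitude of the nonredundant half-spectrum of the real signal — bins 0
#' (DC) through `floor(n/2)`, so `floor(n/2) + 1` values. No window
#' function or detrending is applied and phase is discarded.
#'
#' @param series Nonempty numeric vector.
#' @return Numeric vector of `floor(length(series)/2) + 1` magnitudes.
#' @examples
#' fft_features(rep(2, 100))[1]  # DC bin: 200
#' @export
fft_features <- function(series) {
  if (!length(series)) stop("series must be nonempty")
  Mod(fft(series))[seq_len(floor(length(series) / 2) + 1)]
}

# Component table for a named feature set: one row per (channel, window,
# transform) block, concatenated in order to form the feature vector.
feature_set_components <- function(name) {
  subs <- subsequence_specs()$name
  switch(
    name,
    force_fft_union_dist_fft = data.frame(
      channel = c("force", "displacement"),
      window = "full", transform = "fft_magnitude",
      stringsAsFactors = FALSE
    ),
    force_union_dist = data.frame(
      channel = c("force", "displacement"),
      window = "full", transform = "raw",
      stringsAsFactors = FALSE
    ),
    raw_union_stats = rbind(
      data.frame(channel = c("force", "displacement"), window = "full",
                 transform = "raw", stringsAsFactors = FALSE),
      expand.grid(transform = c("mean", "sd"),
                  channel = c("force", "displacement"),
                  window = subs,
                  stringsAsFactors = FALSE)[, c("channel", "window",
                                                "transform")]
    ),
    subsequence_force_ffts = data.frame(
      channel = "force", window = subs, transform = "fft_magnitude",
      stringsAsFactors = FALSE
    ),
    stop("unknown feature set '", name, "'")
  )
}

#' Declarative specification of a feature set
#'
#' The four named sets mirror the study's feature-set families:
#' \describe{
#'   \item{`force_fft_union_dist_fft`}{FFT magnitudes of the full force and
#'     displacement series (51 + 51 = 102 features).}
#'   \item{`force_union_dist`}{the raw time-domain force and displacement
#'     samples (100 + 100 = 200).}
#'   \item{`raw_union_stats`}{raw samples of both channels plus mean and sd
#'     of each of the four subsequence windows on both channels
#'     (200 + 16 = 216).}
#'   \item{`subsequence_force_ffts`}{FFT magnitudes of the force channel
#'     restricted to each subsequence window (3 + 4 + 10 + 11 = 28).}
#' }
#' A custom composition can be supplied as a data frame of
#' `(channel, window, transform)` rows, where `channel` is `force` or
#' `displacement`, `window` is `full` or a subsequence name, and
#' `transform` is one of `raw`, `mean`, `sd`, `skewness`, `kurtosis`,
#' `fft_magnitude`.
#'
#' @param name One of the four canonical names (ignored when `components`
#'   is given, except as a label).
#' @param components Optional custom component data frame.
#' @return An object of class `feature_set_spec`.
#' @export
feature_set_spec <- function(name = c("subsequence_force_ffts",
                                      "force_fft_union_dist_fft",
                                      "force_union_dist",
                                      "raw_union_stats"),
                             components = NULL) {
  if (is.null(components)) {
    name <- match.arg(name)
    components <- feature_set_components(name)
  } else {
    name <- if (length(name) == 1) name else "custom"
    stopifnot(is.data.frame(components), nrow(components) > 0,
              all(c("channel", "window", "transform") %in% names(components)))
  }
  structure(list(name = name, components = components),
            class = "feature_set_spec")
}

# Evaluate one component block on an event; returns a named numeric vector.
eval_component <- function(event, channel, window, transform, acquisition) {
  series <- switch(channel,
                   force = event$force,
                   displacement = event$displacement,
                   stop("unknown channel '", channel, "'"))
  if (window != "full") {
    subs <- subsequence_specs()
    row <- subs[subs$name == window, ]
    if (!nrow(row)) stop("unknown subsequence window '", window, "'")
    series <- extract_subsequence(series, row$t_start, row$t_end, acquisition)
  }
  prefix <- paste(channel, window, transform, sep = ".")
  vals <- switch(
    transform,
    raw = setNames(series, paste0(prefix, ".", seq_along(series) - 1)),
    fft_magnitude = {
      v <- fft_features(series)
      setNames(v, paste0(prefix, ".bin", seq_along(v) - 1))
    },
    mean = ,
    sd = ,
    skewness = ,
    kurtosis = setNames(moment_features(series)[[transform]], prefix),
    stop("unknown transform '", transform, "'")
  )
  vals
}

#' Build the feature vector for one probe event
#'
#' Concatenates the feature-set components in their declared order; the
#' layout (component label per element) is attached as the names of the
#' returned vector and is identical for every event, so vectors from
#' different events are directly comparable.
#'
#' @param event A [probe_event()].
#' @param spec A [feature_set_spec()].
#' @param acquisition An [acquisition_spec()].
#' @return Named numeric feature vector.
#' @examples
#' acq <- acquisition_spec()
#' ev <- probe_event(rnorm(100), rnorm(100), needle_depth = 1)
#' length(build_feature_vector(ev, feature_set_spec("subsequence_force_ffts"),
#'                             acq))  # 28
#' @export
build_feature_vector <- function(event, spec, acquisition) {
  comp <- spec$components
  parts <- lapply(seq_len(nrow(comp)), function(i) {
    eval_component(event, comp$channel[i], comp$window[i], comp$transform[i],
                   acquisition)
  })
  out <- unlist(parts)
  if (any(!is.finite(out))) stop("non-finite feature values produced")
  out
}

#' Feature matrix for every probe event of an insertion
#'
#' @param insertion A labelled [needle_insertion()].
#' @param spec A [feature_set_spec()].
#' @param acquisition An [acquisition_spec()].
#' @return A list with `X` (events x features matrix) and `meta` (data frame
#'   of `needle_depth`, `replicate_index`, `distance_from_bone` per row).
#' @export
featurize_insertion <- function(insertion, spec, acquisition) {
  vecs <- lapply(insertion$events, build_feature_vector, spec = spec,
                 acquisition = acquisition)
  X <- do.call(rbind, vecs)
  meta <- data.frame(
    needle_depth = vapply(insertion$events, function(e) e$needle_depth,
                          numeric(1)),
    replicate_index = vapply(insertion$events, function(e) e$replicate_index,
                             integer(1)),
    distance_from_bone = vapply(insertion$events,
                                function(e) e$distance_from_bone, numeric(1))
  )
  list(X = X, meta = meta, insertion_id = insertion$insertion_id,
       bone_strike_depth = insertion$bone_strike_depth)
}
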