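#' Acquisition specification for probe events
#'
#' Describes how a single probe event is sampled: the recording lasts
#' `duration` seconds and captures `n_samples` points on both the force and
#' displacement channels, so the sampling rate is `n_samples / duration`.
#' The defaults (0.25 s, 100 samples) give the 400 Hz rate used throughout;
#' `depth_increment` is the needle advance between successive probe depths.
#'
#' @param duration Recording duration in seconds.
#' @param n_samples Number of samples per channel.
#' @param depth_increment Needle advance between probing depths, mm.
#' @return An object of class `acquisition_spec` with a derived
#'   `sampling_rate` field (Hz).
#' @examples
#' acquisition_spec()$sampling_rate  # 400
#' @export
acquisition_spec <- function(duration = 0.25, n_samples = 100L,
                             depth_increment = 0.5) {
  stopifnot(duration > 0, n_samples >= 1, depth_increment > 0)
  structure(
    list(
      duration = duration,
      n_samples = as.integer(n_samples),
      sampling_rate = n_samples / duration,
      depth_increment = depth_increment
    ),
    class = "acquisition_spec"
  )
}

#' Construct a probe event
#'
#' One mechanical stimulation of the tissue ahead of the needle tip: paired
#' force and probe-displacement series of equal length, recorded at a known
#' needle depth. `distance_from_bone` is `NA` until the parent insertion is
#' labelled with [label_distance()].
#'
#' @param force Numeric vector, force in N.
#' @param displacement Numeric vector, probe displacement in mm; same length
#'   as `force`.
#' @param needle_depth Needle depth at which the event was recorded, mm.
#' @param replicate_index Zero-based replicate index at this depth.
#' @param distance_from_bone Distance from bone in mm, or `NA` if unlabelled.
#' @return An object of class `probe_event`.
#' @export
probe_event <- function(force, displacement, needle_depth,
                        replicate_index = 0L, distance_from_bone = NA_real_) {
  if (length(force) != length(displacement)) {
    stop("force and displacement series must have identical length (got ",
         length(force), " and ", length(displacement), ")")
  }
  if (needle_depth < 0) stop("needle_depth must be >= 0")
  if (replicate_index < 0) stop("replicate_index must be >= 0")
  structure(
    list(
      force = as.numeric(force),
      displacement = as.numeric(displacement),
      needle_depth = as.numeric(needle_depth),
      replicate_index = as.integer(replicate_index),
      distance_from_bone = as.numeric(distance_from_bone)
    ),
    class = "probe_event"
  )
}

#' Construct a needle insertion
#'
#' The ordered series of probe events collected as the needle advances toward
#' bone, together with the ground-truth bone-strike depth. Events must be in
#' nondecreasing depth order and no event may lie deeper than the strike
#' depth. This is the unit of train/test grouping: probe events from one
#' insertion never straddle a train/test boundary.
#'
#' @param events List of [probe_event()] objects in nondecreasing depth order.
#' @param bone_strike_depth Needle depth at which bone was struck, mm.
#' @param insertion_id Unique identifier string.
#' @param replicates_per_depth Nominal number of replicate events per depth.
#' @return An object of class `needle_insertion`.
#' @export
needle_insertion <- function(events, bone_strike_depth, insertion_id,
                             replicates_per_depth = 3L) {
  stopifnot(is.list(events), bone_strike_depth > 0)
  depths <- vapply(events, function(e) e$needle_depth, numeric(1))
  if (length(depths) > 1 && any(diff(depths) < 0)) {
    stop("events must be ordered by nondecreasing needle_depth in insertion '",
         insertion_id, "'")
  }
  if (length(depths) && max(depths) > bone_strike_depth) {
    stop("insertion '", insertion_id, "' has an event at depth ",
         max(depths), " mm beyond its bone_strike_depth of ",
         bone_strike_depth, " mm")
  }
  structure(
    list(
      events = events,
      bone_strike_depth = as.numeric(bone_strike_depth),
      insertion_id = as.character(insertion_id),
      replicates_per_depth = as.integer(replicates_per_depth)
    ),
    class = "needle_insertion"
  )
}

#' @export
print.needle_insertion <- function(x, ...) {
  depths <- insertion_depths(x)
  cat("<needle_insertion> ", x$insertion_id, ": ", length(x$events),
      " probe events over ", length(depths), " depths, bone strike at ",
      x$bone_strike_depth, " mm\n", sep = "")
  invisible(x)
}

#' Distinct probing depths of an insertion
#'
#' @param insertion A [needle_insertion()].
#' @return Sorted numeric vector of distinct needle depths, mm.
#' @export
insertion_depths <- function(insertion) {
  sort(unique(vapply(insertion$events, function(e) e$needle_depth, numeric(1))))
}

#' Construct an insertion dataset
#'
#' A collection of needle insertions with a split assignment mapping each
#' insertion to `train`, `test`, or `validation`, plus the acquisition
#' specification shared by all events.
#'
#' @param insertions List of [needle_insertion()] objects.
#' @param split_assignment Named character vector (`insertion_id` ->
#'   `"train"`/`"test"`/`"validation"`). Defaults to all-train.
#' @param acquisition An [acquisition_spec()].
#' @return An object of class `insertion_dataset`.
#' @export
insertion_dataset <- function(insertions,
                              split_assignment = NULL,
                              acquisition = acquisition_spec()) {
  ids <- vapply(insertions, function(x) x$insertion_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate insertion ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(split_assignment)) {
    split_assignment <- setNames(rep("train", length(ids)), ids)
  }
  if (!all(ids %in% names(split_assignment))) {
    stop("split_assignment missing ids: ",
         paste(setdiff(ids, names(split_assignment)), collapse = ", "))
  }
  bad <- setdiff(unique(split_assignment), c("train", "test", "validation"))
  if (length(bad)) stop("unknown split labels: ", paste(bad, collapse = ", "))
  names(insertions) <- ids
  structure(
    list(
      insertions = insertions,
      split_assignment = split_assignment[ids],
      acquisition = acquisition
    ),
    class = "insertion_dataset"
  )
}

#' @export
print.insertion_dataset <- function(x, ...) {
  tab <- table(factor(x$split_assignment,
                      levels = c("train", "test", "validation")))
  cat("<insertion_dataset> ", length(x$insertions), " insertions (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ") at ",
      x$acquisition$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Label probe events with their distance from bone
#'
#' Sets every event's `distance_from_bone` to
#' `bone_strike_depth - needle_depth`. Idempotent: relabelling an already
#' labelled insertion gives the same result.
#'
#' @param insertion A [needle_insertion()] with `bone_strike_depth` set.
#' @return The insertion with all events labelled.
#' @export
label_distance <- function(insertion) {
  stopifnot(inherits(insertion, "needle_insertion"))
  depths <- vapply(insertion$events, function(e) e$needle_depth, numeric(1))
  if (length(depths) && max(depths) > insertion$bone_strike_depth) {
    stop("cannot label insertion '", insertion$insertion_id,
         "': event at depth ", max(depths),
         " mm lies beyond bone_strike_depth ", insertion$bone_strike_depth,
         " mm")
  }
  insertion$events <- lapply(insertion$events, function(e) {
    e$distance_from_bone <- insertion$bone_strike_depth - e$needle_depth
    e
  })
  insertion
}

#' Binary close-to-bone label
#'
#' Probe events within the forewarning margin of bone receive label 1, all
#' others 0. The boundary is inclusive: a distance exactly equal to the
#' threshold is labelled 1, the safer convention for a proximity alarm.
#'
#' @param distance Distance(s) from bone, mm; must be nonnegative.
#' @param threshold Forewarning margin, mm (default 5).
#' @return Integer vector of 0/1 labels.
#' @examples
#' binary_label(c(3.5, 5, 12))  # 1 1 0
#' @export
binary_label <- function(distance, threshold = 5.0) {
  if (any(is.na(distance))) stop("distance contains NA; label the insertion first")
  if (any(distance < 0)) stop("distance must be >= 0")
  as.integer(distance <= threshold)
}

# ---- serialization -----------------------------------------------------

# On-disk layout: <dir>/manifest.json with dataset-level metadata and one
# <dir>/<insertion_id>.csv per insertion with columns needle_depth,
# replicate_index, sample_index, force_N, displacement_mm. Distances are
# recomputed from bone_strike_depth at read time.

#' Write an insertion dataset to a directory
#'
#' @param dataset An [insertion_dataset()].
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "insertion_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format = "boneprox-dataset",
    version = 1L,
    acquisition = list(
      duration = dataset$acquisition$duration,
      n_samples = dataset$acquisition$n_samples,
      depth_increment = dataset$acquisition$depth_increment
    ),
    insertions = lapply(dataset$insertions, function(ins) {
      list(
        insertion_id = ins$insertion_id,
        bone_strike_depth = ins$bone_strike_depth,
        replicates_per_depth = ins$replicates_per_depth,
        split = unname(dataset$split_assignment[[ins$insertion_id]]),
        file = paste0(ins$insertion_id, ".csv")
      )
    })
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (ins in dataset$insertions) {
    rows <- do.call(rbind, lapply(ins$events, function(e) {
      n <- length(e$force)
      data.frame(
        needle_depth = rep(e$needle_depth, n),
        replicate_index = rep(e$replicate_index, n),
        sample_index = seq_len(n) - 1L,
        force_N = e$force,
        displacement_mm = e$displacement
      )
    }))
    if (is.null(rows)) {
      rows <- data.frame(needle_depth = numeric(), replicate_index = integer(),
                         sample_index = integer(), force_N = numeric(),
                         displacement_mm = numeric())
    }
    write.csv(rows, file.path(path, paste0(ins$insertion_id, ".csv")),
              row.names = FALSE)
  }
  invisible(path)
}

#' Read an insertion dataset from a directory
#'
#' Validates series lengths against the manifest's acquisition spec and warns
#' (rather than fails) when an insertion is missing replicates at some depth,
#' since bench data can drop events. Distance labels are recomputed from each
#' insertion's bone-strike depth.
#'
#' @param path Directory written by [write_dataset()].
#' @return An [insertion_dataset()].
#' @export
read_dataset <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json found under '", path, "'")
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  acq <- acquisition_spec(
    duration = manifest$acquisition$duration,
    n_samples = manifest$acquisition$n_samples,
    depth_increment = manifest$acquisition$depth_increment
  )
  ids <- vapply(manifest$insertions, function(m) m$insertion_id, character(1))
  if (anyDuplicated(ids)) {
    stop("manifest contains duplicate insertion ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  insertions <- lapply(manifest$insertions, function(m) {
    f <- file.path(path, m$file)
    if (!file.exists(f)) stop("missing data file '", m$file, "' for insertion '",
                              m$insertion_id, "'")
    tab <- read.csv(f)
    events <- list()
    if (nrow(tab)) {
      key <- interaction(tab$needle_depth, tab$replicate_index, drop = TRUE)
      for (grp in split(tab, key)) {
        grp <- grp[order(grp$sample_index), ]
        if (nrow(grp) != acq$n_samples) {
          stop("insertion '", m$insertion_id, "', depth ",
               grp$needle_depth[1], " mm, replicate ", grp$replicate_index[1],
               ": series has ", nrow(grp), " samples, expected ",
               acq$n_samples)
        }
        events[[length(events) + 1L]] <- probe_event(
          force = grp$force_N, displacement = grp$displacement_mm,
          needle_depth = grp$needle_depth[1],
          replicate_index = grp$replicate_index[1]
        )
      }
      ord <- order(vapply(events, function(e) e$needle_depth, numeric(1)),
                   vapply(events, function(e) e$replicate_index, integer(1)))
      events <- events[ord]
      counts <- table(vapply(events, function(e) e$needle_depth, numeric(1)))
      if (any(counts < m$replicates_per_depth)) {
        warning("insertion '", m$insertion_id, "' has fewer than ",
                m$replicates_per_depth, " replicates at ",
                sum(counts < m$replicates_per_depth), " depth(s)")
      }
    }
    label_distance(needle_insertion(
      events, bone_strike_depth = m$bone_strike_depth,
      insertion_id = m$insertion_id,
      replicates_per_depth = m$replicates_per_depth
    ))
  })
  split_assignment <- setNames(
    vapply(manifest$insertions, function(m) m$split, character(1)), ids)
  insertion_dataset(insertions, split_assignment, acq)
}
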