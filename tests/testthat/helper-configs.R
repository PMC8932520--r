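# Small, fast simulator configurations used across the unit tests.
# Short insertions (shallow strike depths) keep per-test runtime low while
# exercising the same code paths as full-length insertions.

noise_free_sensors <- function() {
  sensor_model(force_noise_sd = 0, displacement_noise_sd = 0)
}

quiet_sensors <- function() {
  # noise at the instrument resolution: visible but easily averaged out
  sensor_model(force_noise_sd = 2.9e-2, displacement_noise_sd = 3.1e-4)
}

fast_config <- function(mechanics = mechanical_params(),
                        sensors = quiet_sensors(),
                        strike_depth_range = c(8, 12),
                        replicates_per_depth = 3L,
                        seed = 1L, ...) {
  simulation_config(
    mechanics = mechanics, sensors = sensors,
    strike_depth_range = strike_depth_range,
    replicates_per_depth = replicates_per_depth, seed = seed, ...
  )
}

# A deterministic toy insertion whose feature structure is trivial: events
# carry constant series so every feature vector is known in closed form.
constant_insertion <- function(strike = 6, increment = 0.5, value = 1,
                               replicates = 2L, id = "toy") {
  depths <- increment * seq_len(floor(strike / increment))
  events <- list()
  for (d in depths) {
    for (r in seq_len(replicates) - 1L) {
      events[[length(events) + 1L]] <-
        probe_event(rep(value, 100), rep(value, 100), needle_depth = d,
                    replicate_index = r)
    }
  }
  label_distance(needle_insertion(events, strike, id,
                                  replicates_per_depth = replicates))
}
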