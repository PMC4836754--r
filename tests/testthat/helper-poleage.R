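# shared fixtures for the test suite

# the short-lived mutant's per-pole-age stop schedule used throughout
csra_schedule <- function() hazard_schedule(c(0, 0, 0.25, 0.40, 0.55, 0.65))

# deterministic complete binary tree observed to the given depth
complete_tree_sim <- function(depth, seed = 1, T = 40, frame_interval = 5) {
  simulate_lineage(sim_config(
    hazard_schedule(0), seed = seed, geometry = "agar_colony", n_founders = 1,
    interdivision_mean = T, interdivision_cv = 0, division_noise_cv = 0,
    duration = depth * T + T / 2, frame_interval = frame_interval))
}

# hand-written tracking table: one root dividing once into two children
minimal_division_table <- function() {
  data.frame(
    frame = c(0, 1, 2, 2, 3, 3),
    time_min = c(0, 10, 20, 20, 30, 30),
    cell_id = c("a", "a", "b", "c", "b", "c"),
    parent_id = c(NA, NA, "a", "a", "a", "a"),
    length_um = c(2, 3, 2, 2, 2.5, 2.5),
    mean_fluor = NA_real_, pixel_count = NA_integer_,
    channel_id = "ch1",
    old_pole_child = c(NA, NA, 1, 0, 1, 0),
    stringsAsFactors = FALSE
  )
}

# a mother-machine run of the csrA-like conditions, reused by several tests
mm_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_lineage(sim_config(
        csra_schedule(), seed = 42, geometry = "mother_machine",
        n_channels = 150, duration = 2000))
    }
    cache
  }
})
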