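#!/usr/bin/env Rscript
# Generate the synthetic study data: mother-machine time-lapse lineages of a
# short-lived (csrA-like) strain with an old-pole aggregate reporter and a
# chromosome reporter, plus OD600 microplate curves for the mutant-like and
# wild-type-like strains. All downstream drivers read these artifacts.

suppressPackageStartupMessages(library(poleage))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20160419

# per-pole-age stop probabilities of the short-lived strain; zero for the
# first two ages ("cells almost never stop when the pole is one or two
# divisions old"), then steeply rising
sched <- hazard_schedule(c(0, 0, 0.25, 0.40, 0.55, 0.65))

cfg <- sim_config(sched, seed = seed, geometry = "mother_machine",
                  n_channels = 500, interdivision_mean = 40,
                  interdivision_cv = 0.1, duration = 2000, frame_interval = 5,
                  last_division_size_penalty = 0.8, division_noise_cv = 0.1,
                  fluor = fluor_config(emit_profile = TRUE))
sim <- simulate_lineage(cfg)
write_sim_config(cfg, file.path(out, "sim_config.yaml"))
write_tracking_table(sim$table, file.path(out, "tracking.csv"))
utils::write.csv(sim$individuals, file.path(out, "ground_truth.csv"),
                 row.names = FALSE)

# 48 wells per strain; exponential-phase rates giving 42.9 / 42.6 min, with
# well-to-well biological rate variability on top of the 1% read noise
od <- rbind(
  simulate_od(log(2) / 42.9, od0 = 0.005, lag = 120, od_max = 1.2,
              noise_cv = 0.01, rate_cv = 0.1, read_interval = 2,
              duration = 700, n_wells = 48, strain = "csrA_like",
              seed = seed + 1L),
  simulate_od(log(2) / 42.6, od0 = 0.005, lag = 120, od_max = 1.2,
              noise_cv = 0.01, rate_cv = 0.1, read_interval = 2,
              duration = 700, n_wells = 48, strain = "wt_like",
              seed = seed + 2L))
write_od_series(od, file.path(out, "od_plate.csv"))

pipeline_manifest(list(schedule = sched$h, tail = sched$tail,
                       n_channels = 500, duration = 2000, n_wells = 48),
                  seed, file.path(out, "manifest.json"))
cat("Simulated", nrow(sim$table), "tracking rows,",
    nrow(sim$individuals), "ground-truth individuals,",
    length(unique(paste(od$strain, od$well))), "OD wells ->", out, "\n")
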