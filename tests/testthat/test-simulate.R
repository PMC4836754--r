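test_that("simulation is deterministic under a fixed seed, byte-identical on disk", {
  cfg <- sim_config(csra_schedule(), seed = 5, geometry = "mother_machine",
                    n_channels = 10, duration = 1200)
  s1 <- simulate_lineage(cfg)
  s2 <- simulate_lineage(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$individuals, s2$individuals)
  p1 <- tempfile(); p2 <- tempfile()
  write_tracking_table(s1$table, p1)
  write_tracking_table(s2$table, p2)
  expect_identical(readLines(p1), readLines(p2))

  od1 <- simulate_od(log(2) / 42, n_wells = 48, seed = 3)
  od2 <- simulate_od(log(2) / 42, n_wells = 48, seed = 3)
  expect_identical(od1, od2)
})

test_that("signals and length are conserved exactly at every division", {
  cfg <- sim_config(csra_schedule(), seed = 8, geometry = "mother_machine",
                    n_channels = 25, duration = 1500, fluor = fluor_config())
  sim <- simulate_lineage(cfg)
  dv <- sim$divisions
  expect_gt(nrow(dv), 100)
  # conserved to the last floating-point digit
  expect_equal(dv$A_old + dv$A_new, dv$A_before, tolerance = 1e-14)
  expect_equal(dv$C_old + dv$C_new, dv$C_before, tolerance = 1e-14)
  expect_equal(dv$L_old + dv$L_new, dv$L_before, tolerance = 1e-14)
})

test_that("full retention gives constant daughter and strictly rising mother signal", {
  cfg <- sim_config(csra_schedule(), seed = 9, geometry = "mother_machine",
                    n_channels = 5, duration = 1500,
                    fluor = fluor_config(retention = 1))
  sim <- simulate_lineage(cfg)
  dv <- sim$divisions
  expect_true(all(dv$A_new == 0))
  # along each bottom-cell chain the mother's post-division signal rises
  asg <- assign_pole_ages(build_lineage(sim$table), "keep_root_as_unknown")
  cells <- asg$cells
  for (ii in unique(cells$individual_id[cells$pole_age >= 3])) {
    chain <- cells[cells$individual_id == ii, ]
    chain <- chain[order(chain$pole_age), ]
    a0 <- vapply(chain$cell_id, function(cid) {
      d <- sim$table[sim$table$cell_id == cid, ]
      d$agg_au[which.min(d$time_min)]
    }, 1)
    expect_true(all(diff(a0) > 0))
  }
})

test_that("empirical stop ages match the analytic distribution at n = 10,000", {
  sched <- csra_schedule()
  ind <- simulate_individuals(10000, sched, seed = 12)
  ages <- seq_len(max(ind$stop_pole_age))
  F_true <- 1 - survivorship(hazard_schedule(sched$h, sched$tail), ages)
  F_emp <- vapply(ages, function(a) mean(ind$stop_pole_age <= a), 1)
  band <- 3 * sqrt(F_true * (1 - F_true) / nrow(ind))
  expect_true(all(abs(F_emp - F_true) <= pmax(band, 1e-12)))
})

test_that("zero hazard reproduces the complete binary tree and its census", {
  sim <- complete_tree_sim(6)
  expect_equal(nrow(sim$individuals), 2^6)          # one individual per division + founder
  asg <- assign_pole_ages(build_lineage(sim$table))
  cen <- pole_age_census(asg)
  expect_equal(cen$count, c(2^(5:0), 1))
})

test_that("mother-machine output keeps only the channel lineage", {
  sim <- mm_sim()
  # per channel: at most mm_generations fully observed chains, rest pushed out
  gt <- sim$individuals
  expect_true(all(table(gt$channel_id[gt$fate != "discarded"]) <=
                    sim$config$mm_generations))
  # pushed-out cells never have tracked children
  tree <- build_lineage(sim$table)
  disc <- gt$individual_id[gt$fate == "discarded"]
  expect_gt(length(disc), 0)
})

test_that("OD curves are exact exponentials in the window and reproducible", {
  od <- simulate_od(log(2) / 40, noise_cv = 0, duration = 600)
  w <- od$od600 >= 0.0625 & od$od600 <= 0.125
  lods <- log(od$od600[w])
  slopes <- diff(lods) / diff(od$time_min[w])
  expect_equal(slopes, rep(log(2) / 40, sum(w) - 1), tolerance = 1e-10)

  lagged <- simulate_od(log(2) / 40, lag = 100, noise_cv = 0.01, seed = 2,
                        duration = 400)
  early <- lagged$od600[lagged$time_min < 100]
  expect_true(all(early <= 0.005 * (1 + 3 * 0.01)))

  expect_error(simulate_od(0.02, od0 = 0.5, od_max = 0.4),
               class = "poleage_config_error")
  expect_error(simulate_od(-1), class = "poleage_config_error")
})

test_that("configuration is validated and round trips through YAML", {
  expect_error(sim_config(csra_schedule()), class = "poleage_config_error")
  expect_error(hazard_schedule(c(0, 1.5)), class = "poleage_config_error")
  expect_error(fluor_config(retention = 0.3), class = "poleage_config_error")

  cfg <- sim_config(csra_schedule(), seed = 77, geometry = "mother_machine",
                    n_channels = 3, duration = 900,
                    fluor = fluor_config(retention = 0.9))
  p <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, p)
  cfg2 <- read_sim_config(p)
  expect_equal(cfg2$schedule$h, cfg$schedule$h)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$fluor$retention, 0.9)
  expect_identical(simulate_lineage(cfg)$table, simulate_lineage(cfg2)$table)
})

test_that("pipeline manifest is stable for identical configurations", {
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  m1 <- pipeline_manifest(list(a = 1, b = "x"), seed = 4, p1)
  m2 <- pipeline_manifest(list(a = 1, b = "x"), seed = 4, p2)
  expect_identical(m1$config_hash, m2$config_hash)
  expect_identical(readLines(p1), readLines(p2))
})
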