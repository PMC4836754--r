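test_that("stop criterion follows the gap and observation-span rules", {
  cr <- stop_criterion(mean_interdivision = 40)
  # gap 400 > 2 x 40, span 900 >= 850
  expect_equal(detect_stop(0, c(460, 500), 900, 900, cr), "stopped")
  # gap 20 too short
  expect_equal(detect_stop(0, c(840, 880), 900, 900, cr), "censored")
  # observed only 600 min
  expect_equal(detect_stop(0, 100, 600, 900, cr), "excluded")
  # edge cases: gap exactly 2 x interval is NOT a stop (strict inequality);
  # observation of exactly 850 min is kept
  expect_equal(detect_stop(0, 820, 900, 900, cr), "censored")   # gap 80 == 2*40
  expect_equal(detect_stop(0, 500, 850, 850, cr), "stopped")    # span == 850
  expect_error(detect_stop(-5, 100, 900, 900, cr),
               class = "poleage_validation_error")
  expect_error(stop_criterion(interval_factor = 1),
               class = "poleage_config_error")
})

test_that("shorter observation never converts a censored fate into stopped", {
  sim <- mm_sim()
  asg <- assign_pole_ages(build_lineage(sim$table), "discard_root_use_last_daughter")
  full <- assign_fates(asg$individuals, 2000, stop_criterion())
  # re-classify with everything truncated at 850 min
  trunc <- asg$individuals
  divs <- lapply(strsplit(trunc$division_times_min, ";"), function(v) {
    v <- suppressWarnings(as.numeric(v)); v[!is.na(v) & v <= 850]
  })
  trunc$division_times_min <- vapply(divs, paste, "", collapse = ";")
  trunc$n_divisions <- lengths(divs)
  trunc$last_obs_time_min <- pmin(trunc$last_obs_time_min, 850)
  short <- assign_fates(trunc[trunc$birth_time_min <= 850, ], 850,
                        stop_criterion(mean_interdivision = full$mean_interdivision_used[1]))
  m <- match(short$individual_id, full$individual_id)
  was_censored <- full$fate[m] == "censored"
  expect_false(any(short$fate[was_censored] == "stopped"))
})

test_that("stop curve hazards, risk sets and the cumulative identity are exact", {
  ind <- data.frame(individual_id = as.character(1:4), n_divisions = 2L,
                    fate = "stopped", included = TRUE)
  cv <- stop_curve(ind)
  expect_equal(cv$cumulative, c(0, 0, 1))
  expect_equal(cv$hazard, c(0, 0, 1))
  expect_equal(cv$n_at_risk, c(4L, 4L, 4L))

  # 2 of 4 at risk stop at age 2, survivors divide on (censored later)
  ind2 <- data.frame(individual_id = as.character(1:4),
                     n_divisions = c(1L, 1L, 3L, 3L),
                     fate = c("stopped", "stopped", "censored", "censored"),
                     included = TRUE)
  cv2 <- stop_curve(ind2)
  expect_equal(cv2$hazard[2], 0.5)
  expect_equal(cv2$n_at_risk, c(4L, 4L, 2L))
  # consistency identity
  expect_equal(cv2$cumulative, 1 - cumprod(1 - cv2$hazard))

  expect_error(stop_curve(ind[0, ]), class = "poleage_empty_curve")
})

test_that("estimated hazards recover the generating schedule within binomial error", {
  sched <- csra_schedule()
  ind <- simulate_individuals(10000, sched, seed = 7)
  cv <- stop_curve(ind)
  h_true <- hazard_at(sched, cv$pole_age)
  keep <- cv$n_at_risk >= 30
  band <- 3 * sqrt(h_true * (1 - h_true) / cv$n_at_risk)
  expect_true(all(abs(cv$hazard - h_true)[keep] <= band[keep]))
  # analytic discrete median of this schedule is 4
  expect_equal(median_stop_age(cv), 4)
})

test_that("median stop age is interpolated on the cumulative curve", {
  cv <- data.frame(pole_age = 1:4, cumulative = c(0, 0.25, 0.55, 0.8))
  class(cv) <- c("stop_curve", "data.frame")
  expect_equal(median_stop_age(cv, "discrete"), 3)
  expect_equal(median_stop_age(cv, "interpolated"), 2 + (0.5 - 0.25) / 0.30,
               tolerance = 1e-12)
  flat <- data.frame(pole_age = 1:5, cumulative = rep(0, 5))
  class(flat) <- c("stop_curve", "data.frame")
  expect_true(is.na(median_stop_age(flat)))
})

test_that("logistic trend test finds rising hazards and flags separation", {
  rising <- hazard_schedule(c(0.01, 0.05, 0.2, 0.5, 0.8))
  ind <- simulate_individuals(1000, rising, seed = 11)
  ht <- hazard_trend_test(ind)
  expect_gt(ht$slope, 0)
  expect_lt(ht$p_value, 0.001)
  expect_false(ht$separation)

  # all survive age 1, all stop at age 2: complete separation
  sep <- data.frame(individual_id = as.character(1:200),
                    n_divisions = 1L, fate = "stopped", included = TRUE)
  expect_warning(hts <- hazard_trend_test(sep), class = "poleage_separation")
  expect_true(hts$separation)
})

test_that("trend test keeps nominal type-I error under a constant hazard", {
  const <- hazard_schedule(0.3)
  cover <- vapply(1:100, function(s) {
    ind <- simulate_individuals(1000, const, seed = 1000 + s)
    ht <- hazard_trend_test(ind)
    abs(ht$slope) <= stats::qnorm(0.975) * ht$se
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("smaller size and higher concentration mark last divisions", {
  set.seed(5)
  n <- 200
  is_last <- rep(c(TRUE, FALSE), c(60, 140))
  len <- stats::rnorm(n, mean = ifelse(is_last, 0.7 * 2.1, 2.1), sd = 0.2)
  rec <- data.frame(is_last = is_last, length_after_um = len)
  rep_out <- last_division_predictors(rec)
  expect_lt(rep_out$coefficient[1], 0)
  expect_lt(rep_out$p_value[1], 0.01)

  const <- data.frame(is_last = is_last, length_after_um = 2)
  expect_error(last_division_predictors(const), class = "poleage_degenerate_model")
  expect_error(last_division_predictors(rec[1, ]), class = "poleage_degenerate_model")
})

test_that("rank correlation of birth state with replicative potential behaves", {
  # potential strictly decreasing in concentration: rho = -1
  rec <- data.frame(birth_conc_au_per_um3 = 1:10,
                    replicative_potential = 10:1)
  out <- birth_state_vs_potential(rec)
  expect_equal(out$rho, -1)

  # independent values at n = 78: |rho| < 0.3 in >= 95% of seeds
  small <- vapply(1:100, function(s) {
    set.seed(s)
    d <- data.frame(birth_conc_au_per_um3 = stats::rnorm(78),
                    replicative_potential = sample(1:8, 78, replace = TRUE))
    abs(birth_state_vs_potential(d)$rho) < 0.3
  }, logical(1))
  expect_gte(mean(small), 0.95)

  ties <- data.frame(birth_conc_au_per_um3 = rep(1, 10),
                     replicative_potential = rep(2, 10))
  expect_error(birth_state_vs_potential(ties), class = "poleage_degenerate_model")
  expect_error(birth_state_vs_potential(rec[1:2, ]),
               class = "poleage_insufficient_data")
})

test_that("mother and last-daughter first intervals are compared pairwise", {
  make_pairs <- function(x, y) {
    n <- length(x)
    moms <- data.frame(
      individual_id = sprintf("m%03d", 1:n), mother_individual_id = NA_character_,
      birth_index = NA_integer_, birth_time_min = 0, n_divisions = 2L,
      division_times_min = paste(x, x + 40, sep = ";"),
      last_obs_time_min = 2000, included = TRUE, stringsAsFactors = FALSE)
    kids <- data.frame(
      individual_id = sprintf("d%03d", 1:n),
      mother_individual_id = sprintf("m%03d", 1:n),
      birth_index = 2L, birth_time_min = x + 40, n_divisions = 1L,
      division_times_min = as.character(x + 40 + y),
      last_obs_time_min = 2000, included = FALSE, stringsAsFactors = FALSE)
    rbind(moms, kids)
  }
  set.seed(9)
  iv <- stats::rnorm(38, 40, 5)
  same <- interdivision_comparison(make_pairs(iv, iv),
                                   focal_ids = sprintf("m%03d", 1:38))
  expect_equal(same$mean_difference, 0)
  expect_gt(same$p_value, 0.99)

  shifted <- interdivision_comparison(make_pairs(iv, iv + 20),
                                      focal_ids = sprintf("m%03d", 1:38))
  expect_equal(shifted$mean_difference, 20, tolerance = 1e-9)
  expect_lt(shifted$p_value, 0.001)

  # n = 2 pairs: wide-CI result but no crash
  tiny <- interdivision_comparison(make_pairs(iv[1:2], iv[1:2] + 1),
                                   focal_ids = sprintf("m%03d", 1:2))
  expect_equal(tiny$n_pairs, 2L)
})

test_that("division and birth records feed the last-division and potential analyses", {
  cfg <- sim_config(csra_schedule(), seed = 23, geometry = "mother_machine",
                    n_channels = 80, duration = 2000, division_noise_cv = 0.1,
                    last_division_size_penalty = 0.8, fluor = fluor_config())
  sim <- simulate_lineage(cfg)
  asg <- assign_pole_ages(build_lineage(sim$table), "discard_root_use_last_daughter")
  fates <- assign_fates(asg$individuals, 2000, stop_criterion())
  rec <- division_records(asg, fates)
  expect_true(all(rec$pole_age == rec$division_index))
  expect_true(any(rec$is_last))
  expect_true(all(is.finite(rec$conc_au_per_um3)))
  # a 0.7x size penalty on terminal divisions shows as a negative coefficient
  rep_len <- last_division_predictors(rec, "length_after_um")
  expect_lt(rep_len$coefficient, 0)
  expect_lt(rep_len$p_value, 0.01)
  # aggregate concentration is higher right after a last division
  rep_conc <- last_division_predictors(rec, "conc_au_per_um3")
  expect_gt(rep_conc$coefficient, 0)

  br <- birth_records(asg, fates)
  expect_gt(nrow(br), 30)
  expect_true(all(br$replicative_potential == fates$n_divisions[
    match(br$individual_id, fates$individual_id)]))
  out <- birth_state_vs_potential(br)
  expect_true(all(is.finite(out$rho)))
})

test_that("post-last-division elongation is a percent change with interpolation", {
  expect_equal(post_last_division_elongation(c(0, 10, 25), c(2, 2, 2)), 0)
  expect_equal(post_last_division_elongation(c(0, 25), c(2.0, 2.15)), 7.5)
  # missing frames inside the horizon: linear interpolation between neighbors
  expect_equal(post_last_division_elongation(c(0, 20, 40), c(2.0, 2.2, 2.4)),
               100 * (2.25 - 2) / 2)
  expect_error(post_last_division_elongation(c(0, 10), c(2, 2.1)),
               class = "poleage_trajectory_too_short")
})

test_that("stopped cells in the simulator elongate by the residual fraction", {
  sim <- mm_sim()
  asg <- assign_pole_ages(build_lineage(sim$table), "discard_root_use_last_daughter")
  fates <- assign_fates(asg$individuals, 2000, stop_criterion())
  el <- elongation_after_stop(asg, fates)
  expect_gt(nrow(el), 50)
  # measured at the 5-min frame grid, the 7.5% ramp reads out slightly lower
  expect_gt(mean(el$percent_elongation, na.rm = TRUE), 5)
  expect_lt(mean(el$percent_elongation, na.rm = TRUE), 8)
})
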