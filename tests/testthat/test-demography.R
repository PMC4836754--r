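test_that("survivorship is the cumulative product of continuation probabilities", {
  zero <- hazard_schedule(0)
  expect_equal(survivorship(zero, 1:10), rep(1, 10))
  sched <- hazard_schedule(c(0, 0, 0.25, 0.40))
  expect_equal(survivorship(sched, 3), 0.75)
  expect_equal(survivorship(sched, 4), 0.45)
  expect_equal(survivorship(sched, 0), 1)  # empty product
  wall <- hazard_schedule(c(0, 0, 0, 0, 1))
  expect_equal(survivorship(wall, 5:8), rep(0, 4))
  expect_error(survivorship(sched, -1), class = "poleage_domain_error")
})

test_that("Euler-Lotka rate matches closed forms and a root-finding oracle", {
  # immortal population: exact closed form
  expect_equal(euler_lotka_rate(demographic_model(40, hazard_schedule())),
               log(2) / 40, tolerance = 1e-12)

  # deterministic stop after 3 divisions: 1 = x + x^2 + x^3, i.e. 2x - x^4 = 1
  m3 <- demographic_model(40, hazard_schedule(c(0, 0, 0), tail = 1))
  x3 <- exp(-euler_lotka_rate(m3) * 40)
  x3_oracle <- stats::uniroot(function(x) x + x^2 + x^3 - 1, c(0.1, 0.9),
                              tol = 1e-13)$root
  expect_equal(x3, x3_oracle, tolerance = 1e-10)
  expect_equal(2 * x3 - x3^4, 1, tolerance = 1e-10)

  # deterministic stop after 17 divisions: x = 1/2 + eps with eps ~ 2^-19
  m17 <- demographic_model(40, hazard_schedule(rep(0, 17), tail = 1))
  x17 <- exp(-euler_lotka_rate(m17) * 40)
  x17_oracle <- stats::uniroot(function(x) sum(x^(1:17)) - 1, c(0.4, 0.9),
                               tol = 1e-14)$root
  expect_equal(x17, x17_oracle, tolerance = 1e-9)
  expect_gt(x17, 0.5)
  expect_equal(x17 - 0.5, 2^-19, tolerance = 0.05)

  expect_error(euler_lotka_rate(demographic_model(40, hazard_schedule(1))),
               class = "poleage_no_growth")
})

test_that("solver agrees with the Leslie-matrix dominant eigenvalue on random schedules", {
  set.seed(101)
  for (k in 1:100) {
    len <- sample(3:25, 1)
    h <- c(stats::runif(len - 1, 0, 0.6), 1)  # finite lifespan: exact Leslie
    sched <- hazard_schedule(h, tail = 1)
    T <- stats::runif(1, 10, 120)
    r_el <- tryCatch(euler_lotka_rate(demographic_model(T, sched)),
                     poleage_no_growth = function(e) NA_real_)
    if (is.na(r_el)) next
    r_leslie <- leslie_growth_rate(sched, T, n_classes = len + 1L)
    expect_equal(r_el, r_leslie, tolerance = 1e-9)
  }
})

test_that("growth-rate reduction is relative, scale invariant, and matches oracles", {
  expect_equal(growth_reduction(demographic_model(40, hazard_schedule())), 0)
  s3 <- hazard_schedule(c(0, 0, 0), tail = 1)
  red3 <- growth_reduction(demographic_model(40, s3))
  # from the x-oracle: reduction = 1 - (-log x)/log 2
  x3 <- stats::uniroot(function(x) x + x^2 + x^3 - 1, c(0.1, 0.9), tol = 1e-13)$root
  expect_equal(red3, 1 - (-log(x3)) / log(2), tolerance = 1e-9)
  expect_equal(red3, 0.121, tolerance = 0.005)
  # T cancels out
  expect_equal(red3, growth_reduction(demographic_model(40 * 7.3, s3)),
               tolerance = 1e-10)
  # asymptotics: stop after A divisions ~ 2 * 2^-(A+2) / log(2) for large A
  for (A in c(15, 20)) {
    red <- growth_reduction(demographic_model(40, hazard_schedule(rep(0, A), tail = 1)))
    expect_equal(red, 2 * 2^-(A + 2) / log(2), tolerance = 0.01)
  }
})

test_that("stable pole-age distribution halves with each age and matches the Leslie eigenvector", {
  m0 <- demographic_model(40, hazard_schedule())
  d <- stable_pole_age_distribution(m0)
  expect_equal(sum(d$fraction), 1, tolerance = 1e-12)
  expect_equal(d$fraction[1:6], 2^-(1:6), tolerance = 1e-9)

  # with mortality: must equal the dominant right eigenvector of the Leslie matrix
  sched <- csra_schedule()
  m <- demographic_model(40, sched)
  d2 <- stable_pole_age_distribution(m)
  A <- leslie_matrix(sched, 60)
  eg <- eigen(A)
  v <- abs(Re(eg$vectors[, which.max(Re(eg$values))]))
  v <- v / sum(v)
  expect_equal(d2$fraction[1:20], v[1:20], tolerance = 1e-7)

  expect_error(stable_pole_age_distribution(demographic_model(40, hazard_schedule(1))),
               class = "poleage_no_growth")
})

test_that("reduction decreases strictly with mortality onset age and vanishes beyond 17", {
  sw <- onset_sweep(csra_schedule(), onsets = 3:20)
  expect_true(all(diff(sw$reduction) < 0))
  # a cell whose hazard first bites at age 18 has completed 17 divisions; the
  # growth cost of such late mortality falls below the 1e-5 selection threshold
  late <- onset_sweep(hazard_schedule(numeric(0), tail = 1), onsets = 18:19)
  expect_true(all(late$reduction < 1e-5))
  total <- onset_sweep(hazard_schedule(1), onsets = 1)
  expect_true(total$no_growth)
})

test_that("selection threshold separates purged from effectively neutral effects", {
  st <- selection_threshold(1e5, reduction = c(0.06, 5.5e-6))
  expect_equal(st$threshold, 1e-5)
  expect_equal(st$verdict, c("purged", "effectively_neutral"))
})
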