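p4 <- kinetic_params()

test_that("pure-decay closed form is reproduced", {
  # every rate zero except protein decay: Y(t) = Y0 exp(-k_deg t)
  p <- kinetic_params(k_op = 0, k_r = 0, k3 = 0, k5 = 0, k_f = 0, k_imp = 0)
  y0 <- state_template(0)
  y0[["Y"]] <- 5
  tr <- integrate_timecourse(model_spec("reg_binding", params = p),
                             times = seq(0, 500, by = 10), y0 = y0)
  expect_equal(tr$states[, "Y"], 5 * exp(-p$k_deg * tr$times),
               tolerance = 1e-6)
})

test_that("operon-knockout external AI-2 follows its closed form", {
  tr <- integrate_timecourse(model_spec("reg_binding", "lsr_operon"), 10)
  ref <- 10 * exp(-p4$k_f * tr$times)
  expect_lt(max(abs(tr$states[, "Aout"] - ref) / ref), 1e-6)
})

test_that("adaptive integrator agrees with the fixed-step RK4 oracle", {
  grid <- seq(0, 500, by = 10)
  for (case in list(list(v = "reg_binding", ko = character(0), dose = 40),
                    list(v = "first", ko = character(0), dose = 20),
                    list(v = "reg_binding", ko = "lsr_operon", dose = 40))) {
    tr <- integrate_timecourse(model_spec(case$v, case$ko), case$dose, grid)
    oracle <- rk4_oracle(p4, case$v, case$ko, case$dose, grid, dt = 0.02)
    scale <- max(abs(oracle))
    expect_lt(max(abs(tr$states - oracle)) / scale, 1e-4)
  }
})

test_that("integration inputs are validated and failures are reported", {
  spec <- model_spec("reg_binding")
  expect_error(integrate_timecourse(spec, -1), "non-negative")
  expect_error(integrate_timecourse(spec, 10, times = c(0, 0, 1)),
               "strictly increasing")
  expect_error(integrate_timecourse(spec, 10, y0 = c(bad = 1)), "named")
})

test_that("non-negativity and AI-2 pool monotonicity hold along trajectories", {
  set.seed(11)
  grid <- seq(0, 500, by = 5)
  for (i in 1:10) {
    p <- kinetic_params(k_op = runif(1, 0.5, 10), k_r = runif(1, 0.5, 5),
                        k1 = runif(1, 0.05, 1), k2 = runif(1, 0.05, 1),
                        k3 = runif(1, 0.001, 0.1), k5 = runif(1, 0, 0.01),
                        k_f = runif(1, 0.001, 0.05),
                        k_imp = runif(1, 0.001, 0.05),
                        nOP = sample(1:6, 1), nR = sample(1:6, 1))
    kos <- sample(c("lsr_operon", "lsrR", "lsrK"), sample(0:1, 1))
    tr <- integrate_timecourse(model_spec("reg_binding", kos, p),
                               dose = runif(1, 0, 40), times = grid)
    expect_gt(min(tr$states), -1e-9)
    expect_true(all(diff(tr$states[, "Aout"]) <= 1e-9))
    pool <- rowSums(tr$states[, c("Aout", "Ap", "U", "C_R", "C_G")])
    expect_true(all(diff(pool) <= 1e-9))
  }
})

test_that("summaries are stable under grid refinement and tighter tolerances", {
  spec <- model_spec("reg_binding")
  pk1 <- peak_activity(integrate_timecourse(spec, 40, seq(0, 500, by = 1)))
  pk2 <- peak_activity(integrate_timecourse(spec, 40, seq(0, 500, by = 0.5)))
  expect_lt(abs(pk2[["peak"]] / pk1[["peak"]] - 1), 1e-3)

  tr_tight <- integrate_timecourse(spec, 40, rtol = 1e-9, atol = 1e-11)
  tr_def <- integrate_timecourse(spec, 40)
  expect_lt(abs(peak_activity(tr_tight)[["peak"]] /
                  peak_activity(tr_def)[["peak"]] - 1), 1e-4)
  expect_lt(abs(activity_at_fixed_time(tr_tight, 300) /
                  activity_at_fixed_time(tr_def, 300) - 1), 1e-4)
})

test_that("peak_activity and activity_at_fixed_time follow their contracts", {
  mk <- function(times, reporter) {
    structure(list(times = times,
                   states = matrix(0, length(times), 9,
                                   dimnames = list(NULL, colnames(
                                     integrate_timecourse(model_spec(), 0,
                                                          c(0, 1))$states))),
                   reporter = reporter, dose = 0,
                   scenario = "intact", variant = "reg_binding"),
              class = "lsr_trajectory")
  }
  # earliest-time tie-break on a constant series
  tr <- mk(c(0, 60, 120), c(2, 2, 2))
  expect_equal(peak_activity(tr), c(t_peak = 0, peak = 2))
  tr <- mk(c(0, 60, 120), c(0, 5, 3))
  expect_equal(peak_activity(tr), c(t_peak = 60, peak = 5))
  # interpolation exact on nodes and for linear series
  tr <- mk(c(0, 100, 200), c(0, 10, 20))
  expect_equal(activity_at_fixed_time(tr, 100), 10)
  expect_equal(activity_at_fixed_time(tr, 150), 15)
  expect_error(activity_at_fixed_time(tr, 300), "outside")
})

test_that("dose series: ordering, baselines and structural identities", {
  grid <- seq(0, 500, by = 2)
  dr <- run_dose_series(model_spec("reg_binding"), times = grid)
  # higher AI-2 concentrations give higher peak expression
  expect_true(all(diff(dr$peak_table$peak_miller) > 0))
  expect_identical(dr$doses, sort(default_dose_panel()))

  # lsrK knockout decouples the reporter from dose entirely
  drk <- run_dose_series(model_spec("reg_binding", "lsrK"), doses = c(1, 40),
                         times = grid)
  expect_equal(drk$trajectories[[1]]$reporter, drk$trajectories[[2]]$reporter,
               tolerance = 1e-8)

  # dose-0 baseline: knockouts outside the reporter path leave it unchanged
  base <- integrate_timecourse(model_spec("reg_binding"), 0, grid)$reporter
  ko_k <- integrate_timecourse(model_spec("reg_binding", "lsrK"), 0, grid)$reporter
  expect_equal(ko_k, base, tolerance = 1e-8)
  # in the FIRST topology the operon knockout is also silent at dose 0
  base1 <- integrate_timecourse(model_spec("first"), 0, grid)$reporter
  ko_op <- integrate_timecourse(model_spec("first", "lsr_operon"), 0, grid)$reporter
  expect_equal(ko_op, base1, tolerance = 1e-8)

  expect_error(run_dose_series(model_spec(), doses = c(1, 1)), "distinct")
})

test_that("dose-response export writes tidy CSV and JSON summary", {
  dr <- run_dose_series(model_spec("reg_binding"), doses = c(0, 40),
                        times = seq(0, 480, by = 60))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_dose_response(dr, csv, js)
  tidy <- utils::read.csv(csv)
  expect_setequal(names(tidy), c("scenario", "variant", "dose_uM", "time_min",
                                 "species", "value"))
  expect_setequal(unique(tidy$dose_uM), c(0, 40))
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$peak_table$peak_miller, dr$peak_table$peak_miller)
})
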