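p4 <- kinetic_params()  # published best-fit set

test_that("promoter_activity limits and examples", {
  # zero-repressor limit equals the maximal rate
  expect_equal(promoter_activity(0, 0, p4, "reg_binding"), p4$k_op)
  expect_equal(promoter_activity(0, 0, p4, "first"), p4$k_op)
  # half-maximal at R = repression coefficient (any cooperativity)
  for (n in c(1, 2, 4)) {
    p <- kinetic_params(nOP = n)
    expect_equal(promoter_activity(p$k1, 0, p, "first"), p$k_op / 2)
  }
  # full-repression limit
  expect_lt(promoter_activity(1e9, 0, p4, "first"), 1e-20)
  # FIRST ignores G; REG variants do not
  expect_equal(promoter_activity(0, 65, p4, "first"), p4$k_op)
  expect_equal(promoter_activity(0, 65, p4, "reg_binding"), p4$k_op / 2)
  # domain errors
  expect_error(promoter_activity(-1, 0, p4), ">= 0")
  expect_error(promoter_activity(1, 0, kinetic_params(k1 = 0)), "> 0")
})

test_that("promoter_activity is monotone decreasing in R and G", {
  set.seed(42)
  for (i in 1:25) {
    p <- kinetic_params(k_op = runif(1, 0.1, 20), k1 = runif(1, 0.01, 10),
                        k4 = runif(1, 0.1, 100), nOP = runif(1, 1, 6),
                        nG = runif(1, 1, 4))
    R <- sort(runif(5, 0, 10)); G <- sort(runif(5, 0, 100))
    aR <- vapply(R, promoter_activity, 0, G = 1, p = p, variant = "reg_binding")
    aG <- vapply(G, promoter_activity, 0, R = 1, p = p, variant = "reg_binding")
    expect_true(all(diff(aR) < 0))
    expect_true(all(diff(aG) < 0))
  }
})

test_that("rhs structure at the origin and with transport off", {
  spec <- model_spec("reg_binding")
  d <- lsr_rhs(state_template(0), spec = spec)
  expect_equal(unname(d[c("OP", "G", "Y")]), rep(p4$k_op, 3))
  expect_equal(unname(d["R"]), p4$k_r)
  expect_equal(unname(d[c("Ap", "U", "Aout", "C_R", "C_G")]), rep(0, 5))

  # OP = 0, external AI-2 present: only the alternative-pathway flux moves it
  s <- state_template(10)
  d <- lsr_rhs(s, spec = spec)
  expect_equal(unname(d["Aout"]), -p4$k_f * 10)
  expect_equal(unname(d["Ap"]), p4$k_f * 10)
})

test_that("rhs matches an independent hand evaluation", {
  spec <- model_spec("reg_binding")
  s <- state_template(10)
  s[c("OP", "R", "Ap")] <- c(1, 1, 1)
  d <- lsr_rhs(s, spec = spec)
  P <- 7 / 626  # k_op / (1 + (R/k1)^nOP), G = 0
  expect_equal(unname(d["OP"]), P - 0.02)
  expect_equal(unname(d["G"]), P)
  expect_equal(unname(d["R"]), 2 / 10001 - 0.02 - 0.05)
  expect_equal(unname(d["Ap"]), 0.2 - 0.05)    # import (0.01*1+0.01)*10 - k3*R*Ap
  expect_equal(unname(d["Aout"]), -0.2)
  expect_equal(unname(d["C_R"]), 0.05)
  expect_equal(unname(d["C_G"]), 0)
  expect_equal(unname(d["Y"]), P)
  expect_error(lsr_rhs(s * NaN, spec = spec), "non-finite")
})

test_that("R and C++ right-hand sides agree on random admissible states", {
  set.seed(7)
  for (i in 1:20) {
    variant <- sample(c("first", "reg_no_binding", "reg_binding"), 1)
    kos <- sample(c("lsr_operon", "lsrR", "lsrK"), sample(0:2, 1))
    p <- kinetic_params(k1 = runif(1, 0.05, 1), k2 = runif(1, 0.05, 1),
                        nOP = sample(1:4, 1), nR = sample(1:4, 1))
    spec <- model_spec(variant, kos, p)
    s <- state_template(runif(1, 0, 40))
    s[c("OP", "G", "R", "Ap", "Y")] <- runif(5, 0, 5)
    if (spec$knockouts[["lsrR"]]) s[["R"]] <- 0
    if (spec$knockouts[["lsrK"]]) s[["Ap"]] <- 0
    if (variant == "first") s[["G"]] <- 0
    # one tiny adaptive "integration" step approximates the derivative
    tr <- integrate_timecourse(spec, times = c(0, 1e-6), y0 = s)
    fd <- (tr$states[2, ] - tr$states[1, ]) / 1e-6
    expect_lt(max(abs(fd - lsr_rhs(s, spec = spec))), 1e-4)
  }
})

test_that("knockout transforms have the stated structure", {
  # lsrR knockout: R pinned at zero, promoter sees no LsrR
  spec <- model_spec("reg_binding", "lsrR")
  tr <- integrate_timecourse(spec, 40, times = seq(0, 200, by = 10))
  expect_true(all(tr$states[, "R"] == 0))

  # lsrK knockout: no phosphorylation; import accumulates in U; Ap stays 0
  spec <- model_spec("reg_binding", "lsrK")
  tr <- integrate_timecourse(spec, 40, times = seq(0, 500, by = 10))
  expect_true(all(tr$states[, "Ap"] == 0))
  expect_gt(tr$states[nrow(tr$states), "U"], 0)
  # dose decoupling: reporter independent of dose
  tr1 <- integrate_timecourse(spec, 1, times = seq(0, 500, by = 10))
  expect_equal(tr1$reporter, tr$reporter, tolerance = 1e-8)

  # operon knockout: external AI-2 decays through the alternative pathway only
  spec <- model_spec("reg_binding", "lsr_operon")
  tr <- integrate_timecourse(spec, 10, times = seq(0, 500, by = 5))
  expect_equal(tr$states[, "Aout"], 10 * exp(-p4$k_f * tr$times),
               tolerance = 1e-6)
  expect_true(all(tr$states[, "OP"] == 0))
  # the reporter fusion still responds
  expect_gt(max(tr$reporter), 0)

  # double knockout is accepted and both transforms apply
  spec <- model_spec("reg_binding", c("lsrR", "lsrK"))
  tr <- integrate_timecourse(spec, 40, times = seq(0, 100, by = 10))
  expect_true(all(tr$states[, c("R", "Ap")] == 0))
})

test_that("scenario labels round-trip", {
  for (kos in list(character(0), "lsrR", c("lsr_operon", "lsrK"),
                   c("lsr_operon", "lsrR", "lsrK"))) {
    lab <- scenario_label(kos)
    expect_identical(parse_scenario(lab), knockout_set(kos))
  }
  expect_identical(scenario_label(character(0)), "intact")
  expect_error(knockout_set("luxS"), "unknown knockout")
})

test_that("variant nesting: k5 = 0 collapses binding; k4 -> Inf approaches FIRST", {
  p0 <- kinetic_params(k5 = 0)
  grid <- seq(0, 500, by = 10)
  a <- integrate_timecourse(model_spec("reg_binding", params = p0), 40, grid)
  b <- integrate_timecourse(model_spec("reg_no_binding", params = p0), 40, grid)
  expect_equal(a$states, b$states, tolerance = 1e-9)

  ref <- integrate_timecourse(model_spec("first"), 40, grid)
  dist <- vapply(c(1e4, 1e6, 1e8), function(k4) {
    tr <- integrate_timecourse(
      model_spec("reg_no_binding", params = kinetic_params(k4 = k4)), 40, grid)
    max(abs(tr$reporter - ref$reporter))
  }, 0.0)
  expect_true(all(diff(dist) < 0))             # sup-distance shrinks with k4
  expect_lt(dist[3] / max(ref$reporter), 1e-5) # and converges to FIRST
})
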