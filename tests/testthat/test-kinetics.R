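# Forward compartment model: generator structure, exact solutions,
# staining, and the paired-probe simulator.

test_that("generator encodes washout, exchange and variant/probe structure", {
  r <- rate_constants(F = 0.2, k3 = 0, k4 = 0.3, k5 = 0, k6 = 0.7)
  A <- build_generator(r, "DPM-NS", "targeted", washout_active = TRUE)
  # with k3 = k5 = 0 nothing couples into bound/ns from free; the only
  # drain on a (0-initialized) free compartment is washout
  expect_equal(A["free", "free"], -0.2)
  expect_equal(A["bound", "free"], 0)
  expect_equal(A["ns", "free"], 0)

  # binding exchange conserves probe: column sums excluding washout are 0
  r2 <- rate_constants(F = 0.4, k3 = 0.3, k4 = 0.1, k5 = 0.16, k6 = 0.06)
  A2 <- build_generator(r2, "DPM-NS", "targeted", washout_active = TRUE)
  A2["free", "free"] <- A2["free", "free"] + r2$F
  expect_equal(colSums(A2), c(free = 0, bound = 0, ns = 0))

  # DPM variant zeroes the ns row/column; untargeted zeroes bound
  Adpm <- build_generator(r2, "DPM", "targeted")
  expect_true(all(Adpm["ns", ] == 0) && all(Adpm[, "ns"] == 0))
  Au <- build_generator(r2, "DPM-NS", "untargeted")
  expect_true(all(Au["bound", ] == 0) && all(Au[, "bound"] == 0))

  expect_error(build_generator(r2, "XXX"), "arg")
})

test_that("stationary specific binding satisfies k3 C_free = k4 C_bound", {
  r <- rate_constants(F = 0, k3 = 0.3, k4 = 0.1)
  st <- solve_compartments(c(1, 0, 0), r, c(0, 500), "DPM", "targeted",
                           washout_active = TRUE)
  expect_equal(unname(st[2L, "bound"] / st[2L, "free"]), 3,
               tolerance = 1e-6)
})

test_that("pure washout decays monoexponentially", {
  r <- rate_constants(F = 0.1)
  st <- solve_compartments(c(1, 0, 0), r, c(0, 10), "DPM-NS", "targeted")
  expect_equal(attr(st, "total")[2L], exp(-1), tolerance = 1e-10)

  # with binding but no washout, total is conserved
  r2 <- rate_constants(F = 0, k3 = 0.3, k4 = 0.1, k5 = 0.16, k6 = 0.06)
  st2 <- solve_compartments(c(2, 1, 0.5), r2, seq(0, 20, 2), "DPM-NS",
                            "targeted", washout_active = FALSE)
  expect_rel_equal(attr(st2, "total"), rep(3.5, 11), 1e-10)

  expect_error(solve_compartments(c(1, 0, 0), r, c(-1, 2)), "non-negative")
})

test_that("closed-form solution matches the ODE-integrator oracle", {
  set.seed(11)
  for (i in 1:40) {
    r <- rate_constants(F = runif(1), k3 = runif(1), k4 = runif(1),
                        k5 = runif(1), k6 = runif(1))
    c0 <- runif(3, 0, 100)
    tt <- sort(runif(4, 0, 10))
    st <- solve_compartments(c0, r, tt, "DPM-NS", "targeted")
    orc <- ode_oracle(c0, r, tt, "DPM-NS", "targeted")
    expect_rel_equal(unclass(st)[, 1:3], orc, 1e-6)
  }
})

test_that("long-time equilibrium ratios equal the rate-constant ratios", {
  r <- rate_constants(F = 0, k3 = 0.3, k4 = 0.12, k5 = 0.16, k6 = 0.06)
  st <- solve_compartments(c(1, 0, 0), r, c(0, 2000), "DPM-NS", "targeted")
  expect_equal(unname(st[2L, "bound"] / st[2L, "free"]), 0.3 / 0.12,
               tolerance = 1e-6)
  expect_equal(unname(st[2L, "ns"] / st[2L, "free"]), 0.16 / 0.06,
               tolerance = 1e-6)
})

test_that("free compartment decreases strictly during rinsing", {
  r <- study_rates(bp = 2)
  s0 <- simulate_stain_phase(150, r, 10, "DPM-NS", "targeted")
  st <- solve_compartments(s0, r, seq(0, 5, 0.5), "DPM-NS", "targeted")
  expect_true(all(diff(st[, "free"]) < 0))
})

test_that("staining conserves the applied concentration", {
  # no binding: everything stays free
  st <- simulate_stain_phase(150, rate_constants(), 10)
  expect_equal(unname(st), c(150, 0, 0))

  # nonspecific binding fills but does not reach equilibrium in 10 min
  r <- rate_constants(k5 = 0.16, k6 = 0.06)
  st2 <- simulate_stain_phase(150, r, 10, "DPM-NS", "untargeted")
  expect_equal(sum(st2), 150, tolerance = 1e-8)
  expect_lt(st2[["ns"]] / st2[["free"]], 0.16 / 0.06)
  # and matches the independent ODE integration
  orc <- ode_oracle(c(150, 0, 0), r, 10, "DPM-NS", "untargeted",
                    washout_active = FALSE)
  expect_rel_equal(unname(st2), as.vector(orc), 1e-8)

  st3 <- simulate_stain_phase(150, study_rates(bp = 3), 10)
  expect_equal(sum(st3), 150, tolerance = 1e-8)
})

test_that("schedule times are 0-based multiples of the rinse interval", {
  sch <- acquisition_schedule()
  expect_equal(schedule_times(sch), seq(0, 5, 0.5))
  sch2 <- acquisition_schedule(include_pre_rinse = FALSE, n_rinses = 4)
  expect_equal(schedule_times(sch2), c(0.5, 1, 1.5, 2))
  expect_error(acquisition_schedule(n_rinses = 1), "n_rinses")
})

test_that("dual-probe simulation is deterministic and control-symmetric", {
  r <- study_rates(bp = 0)        # k3 = 0: ideal-control symmetry
  m <- simulate_dual_probe(r, noise_percent = 0, seed = 5)
  expect_equal(m$targeted$values, m$untargeted$values, tolerance = 1e-12)

  r2 <- study_rates(bp = 2.17)
  m1 <- simulate_dual_probe(r2, noise_percent = 0.48, seed = 99)
  m2 <- simulate_dual_probe(r2, noise_percent = 0.48, seed = 99)
  expect_identical(m1$targeted$values, m2$targeted$values)
  expect_identical(m1$untargeted$values, m2$untargeted$values)
  m3 <- simulate_dual_probe(r2, noise_percent = 0.48, seed = 100)
  expect_false(identical(m1$targeted$values, m3$targeted$values))

  # specific binding adds retention at every post-stain point
  m0 <- simulate_dual_probe(r2, noise_percent = 0)
  expect_true(all(m0$targeted$values >= m0$untargeted$values))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_dual_probe(study_rates(1), seed = 7))
  expect_identical(runif(1), a)
})
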