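# Reference integrator, steady-state initialization, fixtures and the
# random model generator.

test_that("a model at rest stays at rest", {
  m <- compile_model(
    "(Membrane-potential M
      (Membrane-capacitance 1.0 uF/cm*cm)
      (Ohmic-current Leak (E = -65 mV) (g_max = 0.3 mS/cm*cm)))")
  tr <- simulate_model(m$sys, duration = 20, v0 = -65,
                       times = seq(0, 20, 0.1))
  expect_true(all(abs(tr$v - (-65)) < 1e-6))
  # and with zero conductance the potential is constant anywhere
  m0 <- compile_model(
    "(Membrane-potential M
      (Membrane-capacitance 1.0 uF/cm*cm)
      (Ohmic-current Leak (E = -65 mV) (g_max = 0 mS/cm*cm)))")
  tr0 <- simulate_model(m0$sys, duration = 20, v0 = 13,
                        times = seq(0, 20, 0.1))
  expect_true(all(abs(tr0$v - 13) < 1e-9))
})

test_that("suprathreshold stimulation of the HH model produces spikes", {
  m <- compile_model(hh_fixture())
  tr <- simulate_model(m$sys, duration = 50, stim = 20,
                       times = seq(0, 50, 0.025))
  upcross <- sum(diff(tr$v > 50) == 1)
  expect_gte(upcross, 1)
  expect_gt(max(tr$v), 80)   # full-height action potential
})

test_that("gate steady states follow alpha/(alpha+beta)", {
  # alpha = beta: steady state one half
  m <- compile_model(
    "(Membrane-potential M
      (Membrane-capacitance 1.0 uF/cm*cm)
      (Ohmic-current X (E = 0 mV) (g_max = 1 mS/cm*cm)
       (gating a (power 1) (forward-rate (0.7)) (reverse-rate (0.7)))))")
  y <- steady_state_init(m$sys, 0)
  expect_equal(y[["X_a"]], 0.5, tolerance = 1e-12)

  # the printed sodium activation rates at V = 0
  hh <- compile_model(hh_fixture())
  a <- 2.5 / (exp(2.5) - 1)
  b <- 0.125
  y0 <- steady_state_init(hh$sys, 0)
  expect_equal(y0[["Na_m"]], a / (a + b), tolerance = 1e-12)
  expect_identical(y0[["v"]], 0)
})

test_that("kinetic steady states satisfy detailed balance", {
  m <- compile_model(
    "(Membrane-potential M
      (Membrane-capacitance 1.0 uF/cm*cm)
      (Ohmic-current X (E = 0 mV) (g_max = 1 mS/cm*cm)
       (reaction z (transitions (<- A B (0.6) (0.2))) (open B))))")
  y <- steady_state_init(m$sys, 0)
  # forward 3k, reverse k: occupancies (1/4, 3/4)
  expect_equal(y[["X_A"]], 0.25, tolerance = 1e-12)
  expect_equal(y[["X_B"]], 0.75, tolerance = 1e-12)
})

test_that("occupancies remain conserved along simulated trajectories", {
  k <- compile_model(kr_fixture())
  tr <- simulate_model(k$sys, duration = 200, times = seq(0, 200, 1))
  occ <- rowSums(tr[, k$sys$reactions[[1]]$states])
  expect_true(all(abs(occ - 1) < 1e-8))
})

test_that("tightening tolerances barely changes the trajectory", {
  m <- compile_model(hh_fixture())
  t_out <- seq(0, 50, 0.05)
  a <- simulate_model(m$sys, duration = 50, stim = 20, times = t_out)
  b <- simulate_model(m$sys, duration = 50, stim = 20, times = t_out,
                      rtol = 1e-8, atol = 1e-10)
  rms <- sqrt(mean((a$v - b$v)^2))
  expect_lt(rms, 1e-3)
})

test_that("internal and emitted solver trajectories agree", {
  m <- compile_model(hh_fixture())
  t_out <- seq(0, 50, 0.025)
  internal <- simulate_model(m$sys, duration = 50, stim = 20, times = t_out)
  bundle <- eval(parse(text = emit_solver_function(m$sys)))
  f <- function(t, y, parms) list(bundle$rhs(t, y, 20))
  y0 <- steady_state_init(m$sys, 0)
  emitted <- deSolve::ode(as.numeric(y0), t_out, f, NULL, method = "lsoda",
                          rtol = 1e-7, atol = 1e-9)
  rel <- max(abs(internal$v - emitted[, 2])) / max(abs(internal$v))
  expect_lt(rel, 1e-6)
})

test_that("the HH fixture carries the printed constants", {
  txt <- hh_fixture()
  expect_match(txt, "(Membrane-capacitance 1.0 uF/cm*cm)", fixed = TRUE)
  expect_match(txt, "(E = 115 mV)", fixed = TRUE)
  expect_match(txt, "(g_max = 120 mS/cm*cm)", fixed = TRUE)
  expect_match(txt, "(const duration = 2000)", fixed = TRUE)
  m <- compile_model(txt)
  expect_length(m$sys$state_index, 4)
})

test_that("the Purkinje fixture has the expected component set", {
  comp <- parse_component(parse_sexpr(kr_fixture()))
  types <- vapply(comp$children, function(c) c$ctype, "")
  names_ <- vapply(comp$children, function(c) c$cname, "")
  expect_identical(sum(types == "Membrane-capacitance"), 1L)
  expect_identical(sum(types == "decaying-pool"), 1L)
  expect_true(all(c("Narsg", "Kv3", "CaBK", "Leak", "CaP") %in% names_))
  expect_true("voltage-clamp" %in% types)
  m <- compile_model(kr_fixture())
  expect_length(m$sys$state_index, 18)   # v + 3 gates + pool + 13 scheme states
})

test_that("the random model generator is seed-deterministic and honest about size", {
  expect_identical(random_model(7, 3), random_model(7, 3))
  expect_false(identical(random_model(7, 3), random_model(8, 3)))
  for (s in c(1, 12, 33)) {
    n <- 1 + s %% 4
    comp <- parse_component(parse_sexpr(random_model(s, n)))
    expect_identical(
      sum(vapply(comp$children, function(c) c$ctype, "") == "Ohmic-current"),
      as.integer(n))
  }
  # generator leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(random_model(3, 2)); after <- runif(1)
  expect_identical(before, after)
})

test_that("trajectories expose current densities as columns", {
  m <- compile_model(hh_fixture())
  tr <- simulate_model(m$sys, duration = 5, stim = 10,
                       times = seq(0, 5, 0.05))
  expect_true(all(c("i_Na", "i_K", "i_Leak") %in% names(tr)))
  expect_true(all(is.finite(tr$i_Na)))
})
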