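# Lowering of gates, kinetic schemes, current laws, pools and the
# membrane-potential equation.

test_that("HH gate expansion produces the printed gating dynamics", {
  g <- gate_spec("m", power = 3,
                 forward = parse_rate_expr("(2.5 - 0.1*v)/((exp (2.5 - 0.1*v)) - 1)"),
                 reverse = parse_rate_expr("0.125 * exp(-v/80)"))
  ents <- expand_hh_gating(g)
  expect_length(ents, 3)
  rate <- ents[[3]]
  expect_identical(rate$kind, "RATE")
  expect_identical(ionmodl:::expr_text(rate$rhs),
                   "alpha_m(v) * (1 - m) - beta_m(v) * m")
  expect_error(gate_spec("m", power = 0, forward = ionmodl:::ex_num(1),
                         reverse = ionmodl:::ex_num(1)),
               "power", class = "im_validation_error")
  expect_error(gate_spec("m", power = 1, forward = ionmodl:::ex_num(1)),
               "rate form", class = "im_validation_error")
})

test_that("the HH conductance product matches the printed equation", {
  m <- compile_model(hh_fixture())
  g <- ionmodl:::env_get(m$env, "Na_g")
  expect_identical(ionmodl:::expr_text(g$rhs), "Na_g_max * Na_m ^ 3 * Na_h")
  i <- ionmodl:::env_get(m$env, "Na_i")
  expect_identical(ionmodl:::expr_text(i$rhs), "Na_g * (v - Na_E)")
})

test_that("kinetic scheme expansion conserves total occupancy symbolically", {
  rx <- build_entity(parse_sexpr(
    "(reaction rx
      (transitions (<- A B (k1) (k2)) (<- B C (k3)) (<- C A (k4) (k5)))
      (conserve 1) (open C (power 2)))"))
  ents <- expand_reaction(rx)
  expect_length(ents, 3)
  set.seed(3)
  for (i in 1:20) {
    b <- c(A = runif(1), B = runif(1), C = runif(1),
           k1 = runif(1, 0, 5), k2 = runif(1, 0, 5), k3 = runif(1, 0, 5),
           k4 = runif(1, 0, 5), k5 = runif(1, 0, 5))
    total <- sum(vapply(ents, function(e) eval_expr(e$rhs, b), 0))
    expect_equal(total, 0, tolerance = 1e-12)
  }
})

test_that("the 13-state resurgent sodium scheme yields 13 state equations", {
  k <- compile_model(kr_fixture())
  rx <- k$sys$reactions[[1]]
  expect_length(rx$states, 13)
  expect_length(expand_reaction(rx), 13)
})

test_that("Ohmic assembly: zero current at the reversal potential", {
  m <- compile_model(hh_fixture())
  ek <- ionmodl:::build_evaluator(m$sys)
  ev <- ek$env
  ev$v <- 115
  ev$Na_m <- 0.3; ev$Na_h <- 0.6; ev$K_n <- 0.4
  ionmodl:::eval_dynamic(ek)
  expect_equal(get("Na_i", ev), 0)
  # gates fully open: g = gbar
  ev$Na_m <- 1; ev$Na_h <- 1
  ionmodl:::eval_dynamic(ek)
  expect_equal(get("Na_g", ev), 120)
})

test_that("GHK flux limits and signs", {
  z <- 2; ci <- 1e-4; co <- 2.4
  F <- 96485.33212
  # analytic limit at v -> 0 (also the exact guarded value at v = 0)
  lim <- z * F * (ci - co)
  expect_equal(ghk_flux(0, ci, co, z), lim, tolerance = 1e-12)
  expect_equal(ghk_flux(1e-9, ci, co, z), lim, tolerance = 1e-6)
  # symmetric concentrations: exactly linear in v (Ohmic-like, E = 0)
  vs <- c(-80, -20, -1e-4, 1e-4, 5, 40)
  r <- ghk_flux(vs, 1.5, 1.5, 1) / vs
  expect_true(all(abs(r / r[1] - 1) < 1e-9))
  # ci = 0, co > 0, v > 0, z = 2: inward (negative)
  expect_lt(ghk_flux(10, 0, 2.4, 2), 0)
  expect_error(ghk_flux(10, 1, 1, 0), "valence",
               class = "im_validation_error")
})

test_that("GHK current assembly references permeability, gates and pool", {
  k <- compile_model(kr_fixture())
  i <- ionmodl:::env_get(k$env, "CaP_i")
  fv <- free_vars(i$rhs)
  expect_true(all(c("CaP_permeability_pmax", "CaP_m", "v", "cai",
                    "CaP_ca_cao", "celsius") %in% fv))
  # gates fully closed -> zero current
  ek <- ionmodl:::build_evaluator(k$sys)
  ev <- ek$env
  ev$v <- -30; ev$CaP_m <- 0; ev$ca_cac <- 1e-4
  ev$Kv3_n <- 0; ev$CaBK_m <- 0
  for (s in grep("^Narsg_", ek$states, value = TRUE)) assign(s, 0, ev)
  ionmodl:::eval_dynamic(ek)
  expect_identical(get("CaP_i", ev), 0)
})

test_that("decaying pool dynamics have the Traub form and fixed point", {
  p <- pool_spec("ca", sources = "CaP", exported = "cac")
  rate <- expand_decaying_pool(p)
  expect_identical(rate$kind, "RATE")
  # no current: exponential relaxation towards steady
  b <- c(i_CaP = 0, cac = 0.5, steady = 1e-4, tau = 2, b = 0.01)
  expect_equal(eval_expr(rate$rhs, b), -(0.5 - 1e-4) / 2, tolerance = 1e-12)
  # constant inward current: fixed point cac = steady + b*|i|*tau
  i_in <- -8
  b2 <- b; b2[["i_CaP"]] <- i_in
  b2[["cac"]] <- 1e-4 + 0.01 * abs(i_in) * 2
  expect_equal(eval_expr(rate$rhs, b2), 0, tolerance = 1e-12)
})

test_that("membrane potential sums all currents over the capacitance", {
  m <- compile_model(hh_fixture())
  vode <- m$sys$odes[[1]]
  expect_identical(vode$state, "v")
  expect_identical(
    ionmodl:::expr_text(vode$rhs),
    "(i_stim - (i_Na + i_K + i_Leak)) / Membrane_capacitance_C")
  # mixed Ohmic + GHK model: both current kinds in the sum
  k <- compile_model(kr_fixture())
  fv <- free_vars(k$sys$odes[[1]]$rhs)
  expect_true(all(c("i_Narsg", "i_CaP") %in% fv))
})

test_that("a single leak current at its reversal potential is at rest", {
  m <- compile_model(
    "(Membrane-potential M
      (Membrane-capacitance 1.0 uF/cm*cm)
      (Ohmic-current Leak (E = -65 mV) (g_max = 0.3 mS/cm*cm)))")
  ek <- ionmodl:::build_evaluator(m$sys)
  ev <- ek$env
  ev$v <- -65
  ionmodl:::eval_dynamic(ek)
  expect_equal(eval(ek$ode_lang[[1]], ev), 0)
})

test_that("gating variables stay within [0, 1] along HH trajectories", {
  m <- compile_model(hh_fixture())
  tr <- simulate_model(m$sys, duration = 50, stim = 15,
                       times = seq(0, 50, 0.05))
  for (g in c("Na_m", "Na_h", "K_n")) {
    expect_true(all(tr[[g]] >= -1e-9 & tr[[g]] <= 1 + 1e-9))
  }
})

test_that("GHK with symmetric concentrations matches an Ohmic law with E = 0", {
  vs <- setdiff(seq(-60, 60, by = 7.5), 0)
  flux <- ghk_flux(vs, 2, 2, 1)
  ohmic <- vs - 0
  ratio <- flux / ohmic
  expect_true(all(abs(ratio / ratio[1] - 1) < 1e-9))
})
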