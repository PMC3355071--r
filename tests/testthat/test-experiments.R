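# Simulation and voltage-clamp experiments.

test_that("the simulation component yields duration and stepsize", {
  cfg <- build_sim_config(parse_sexpr(
    "(simulation (out duration stepsize)
      (const duration = 2000)
      (const stepsize = 1e-4))"))
  expect_identical(cfg$duration, 2000)
  expect_identical(cfg$stepsize, 1e-4)
  expect_error(build_sim_config(parse_sexpr(
    "(simulation (out duration stepsize)
      (const duration = 1) (const stepsize = 2))")),
    "stepsize < duration", class = "im_validation_error")
  expect_error(build_sim_config(parse_sexpr(
    "(simulation (out duration stepsize) (const duration = 10))")),
    "missing const 'stepsize'", class = "im_grammar_error")
})

test_that("the CaBK clamp protocol reads the declared constants", {
  k <- compile_model(kr_fixture())
  p <- k$clamps[[1]]
  expect_identical(p$current, "CaBK")
  expect_identical(p$hold, -90)
  expect_identical(p$base, -40)
  expect_identical(p$stepsize, 10)
  expect_identical(p$nsteps, 5L)
  expect_identical(p$holding_duration, 5)
  expect_identical(p$base_duration, 20)
})

test_that("a clamp must name an existing current", {
  k <- compile_model(kr_fixture())
  expect_error(build_clamp_protocol(parse_sexpr(
    "(voltage-clamp (name Nope)
      (const hold = -90) (const base = -40) (const stepsize = 10)
      (const nsteps = 2) (const holding-duration = 5)
      (const base-duration = 20))"), k),
    "no ionic current component", class = "im_consistency_error")
})

test_that("two clamps over two currents give two protocols", {
  k <- compile_model(kr_fixture())
  p2 <- build_clamp_protocol(parse_sexpr(
    "(voltage-clamp (name Kv3)
      (const hold = -90) (const base = -50) (const stepsize = 20)
      (const nsteps = 3) (const holding-duration = 5)
      (const base-duration = 10))"), k)
  expect_identical(p2$current, "Kv3")
  expect_identical(expand_clamp_steps(p2), c(-50, -30, -10))
})

test_that("command voltages ascend from base in stepsize increments", {
  k <- compile_model(kr_fixture())
  p <- k$clamps[[1]]
  expect_identical(expand_clamp_steps(p), c(-40, -30, -20, -10, 0))
  p1 <- p; p1$nsteps <- 1L
  expect_identical(expand_clamp_steps(p1), -40)
  p0 <- p; p0$stepsize <- 0
  expect_identical(expand_clamp_steps(p0), rep(-40, 5))
})

test_that("clamping replaces only the membrane-potential equation", {
  m <- compile_model(hh_fixture())
  csys <- ionmodl:::clamp_system(m$sys)
  for (i in seq_along(m$sys$odes)) {
    if (m$sys$odes[[i]]$state == "v") {
      expect_identical(csys$odes[[i]]$rhs, ionmodl:::ex_num(0))
    } else {
      expect_identical(csys$odes[[i]], m$sys$odes[[i]])
    }
  }
  expect_identical(csys$ordered_defs, m$sys$ordered_defs)
  expect_identical(csys$relations, m$sys$relations)
})

test_that("a clamped HH sodium current activates then inactivates", {
  # hold below rest so the activation gate starts nearly closed
  hh_clamp <- fixture_clamp(hh_fixture(),
    "(voltage-clamp (name Na)
      (const hold = -30) (const base = 40) (const stepsize = 10)
      (const nsteps = 2) (const holding-duration = 5)
      (const base-duration = 20))")
  cl <- run_clamp(hh_clamp$model, hh_clamp$protocol,
                  points_per_phase = 150)
  expect_length(cl$sweeps, 2)
  s <- cl$sweeps[[2]]                 # command = 50 mV, strongly activating
  step <- s[s$time > 5, ]             # after the step
  peak_idx <- which.max(abs(step$i))
  peak <- abs(step$i[peak_idx])
  expect_gt(peak, abs(step$i[1]) * 5)           # transient activation
  expect_lt(abs(step$i[nrow(step)]), peak / 2)  # then inactivation
  expect_gt(peak_idx, 1)
  expect_lt(peak_idx, nrow(step))
  # the potential is held constant within each phase
  expect_true(all(abs(s$v[s$time < 5] - (-30)) < 1e-9))
  expect_true(all(abs(s$v[s$time > 5.001] - 50) < 1e-9))
})

test_that("generated clamp scripts have one sweep per command", {
  k <- compile_model(kr_fixture())
  p <- k$clamps[[1]]
  for (target in c("solver", "octave")) {
    txt <- generate_clamp_script(p, k, target)
    marker <- if (target == "solver") "# sweep " else "% sweep "
    expect_identical(
      lengths(regmatches(txt, gregexpr(marker, txt, fixed = TRUE))),
      p$nsteps)
  }
})

test_that("the generated R clamp script runs and reproduces run_clamp", {
  hh_clamp <- fixture_clamp(hh_fixture(),
    "(voltage-clamp (name Na)
      (const hold = -30) (const base = 40) (const stepsize = 20)
      (const nsteps = 2) (const holding-duration = 2)
      (const base-duration = 8))")
  txt <- generate_clamp_script(hh_clamp$protocol, hh_clamp$model, "solver")
  env <- new.env(parent = globalenv())
  eval(parse(text = txt), envir = env)
  expect_length(env$sweeps, 2)
  ref <- run_clamp(hh_clamp$model, hh_clamp$protocol,
                   points_per_phase = 150)
  for (kk in 1:2) {
    i_script <- env$sweeps[[kk]]$i
    expect_true(all(is.finite(i_script)))
    # same order of magnitude / sign of the peak as the internal runner
    expect_equal(max(abs(i_script)), max(abs(ref$sweeps[[kk]]$i)),
                 tolerance = 0.05)
  }
})
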