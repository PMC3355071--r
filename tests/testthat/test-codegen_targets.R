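# Emitted artifacts: R solver function, Octave script, NMODL mechanisms.

test_that("the emitted solver function matches the hand-coded HH oracle", {
  m <- compile_model(hh_fixture())
  bundle <- eval(parse(text = emit_solver_function(m$sys)))
  set.seed(101)
  for (i in 1:100) {
    y <- c(runif(1, -20, 120), runif(3))
    stim <- runif(1, -5, 25)
    got <- bundle$rhs(0, y, stim)
    want <- hh_oracle_rhs(0, y, stim)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("a one-equation system emits a working rhs", {
  env <- env_new()
  env <- extend_env(env, build_entity(parse_sexpr("(d (x) = -x)")))
  sys <- build_ode_system(order_entities(env))
  b <- eval(parse(text = emit_solver_function(sys)))
  expect_equal(b$rhs(0, 2), -2)
  expect_equal(b$rhs(0, -3.5), 3.5)
})

test_that("emitted code loads and evaluates for generated models", {
  for (s in 1:100) {
    m <- compile_model(random_model(s + 2000, 1 + s %% 3))
    b <- eval(parse(text = emit_solver_function(m$sys)))
    y0 <- b$init(-60)
    dy <- b$rhs(0, y0)
    expect_length(dy, length(m$sys$state_index))
    expect_true(all(is.finite(dy)))
  }
})

test_that("emission is deterministic and byte-stable", {
  m <- compile_model(hh_fixture())
  expect_identical(emit_solver_function(m$sys), emit_solver_function(m$sys))
  cfg <- build_sim_config(parse_sexpr(
    "(simulation (out duration stepsize)
      (const duration = 100) (const stepsize = 0.025))"))
  expect_identical(emit_octave_script(m$sys, cfg),
                   emit_octave_script(m$sys, cfg))
  expect_identical(emit_nmodl(m$sys, m$info, TRUE),
                   emit_nmodl(m$sys, m$info, TRUE))
})

test_that("the Octave script declares one function per relation", {
  m <- compile_model(hh_fixture())
  cfg <- build_sim_config(parse_sexpr(
    "(simulation (out duration stepsize)
      (const duration = 100) (const stepsize = 0.025))"))
  txt <- emit_octave_script(m$sys, cfg)
  for (rel in names(m$sys$relations)) {
    expect_true(grepl(paste0("function r = ", rel, "\\(v\\)"), txt))
  }
  expect_true(grepl("function dy = model_rhs", txt))
  expect_true(grepl("function y0 = model_init", txt))
  expect_true(grepl("duration = 100", txt))
})

test_that("NMODL mechanisms follow the NEURON ion conventions", {
  m <- compile_model(hh_fixture())
  mods <- emit_nmodl(m$sys, m$info, merge = FALSE)
  expect_setequal(names(mods), c("Na.mod", "K.mod", "Leak.mod"))
  expect_match(mods[["Na.mod"]], "USEION na READ ena WRITE ina")
  expect_match(mods[["K.mod"]], "USEION k READ ek WRITE ik")
  expect_match(mods[["Leak.mod"]], "NONSPECIFIC_CURRENT Leak_i")
  expect_match(mods[["Na.mod"]], "SOLVE states METHOD cnexp")
})

test_that("merged NMODL has one SUFFIX, all currents, no duplicate names", {
  m <- compile_model(hh_fixture())
  merged <- emit_nmodl(m$sys, m$info, merge = TRUE)
  expect_length(merged, 1)
  txt <- merged[[1]]
  expect_identical(
    lengths(regmatches(txt, gregexpr("SUFFIX ", txt))), 1L)
  for (iv in c("Na_i", "K_i", "Leak_i")) {
    expect_match(txt, paste0(iv, " ="))
  }
  decl <- ionmodl:::nmodl_declared_names(txt)
  expect_identical(anyDuplicated(decl), 0L)
})

test_that("merged and per-mechanism NMODL contain the same equations", {
  m <- compile_model(hh_fixture())
  separate <- emit_nmodl(m$sys, m$info, merge = FALSE)
  merged <- emit_nmodl(m$sys, m$info, merge = TRUE)
  eq_sep <- sort(unlist(lapply(separate, read_nmodl_equations),
                        use.names = FALSE))
  eq_mer <- read_nmodl_equations(merged[[1]])
  expect_setequal(eq_sep, eq_mer)
})

test_that("kinetic schemes emit sparse KINETIC blocks with CONSERVE", {
  k <- compile_model(kr_fixture())
  mods <- emit_nmodl(k$sys, k$info, merge = FALSE)
  na <- mods[["Narsg.mod"]]
  expect_match(na, "SOLVE Narsg_z METHOD sparse")
  expect_match(na, "~ Narsg_C1 <-> Narsg_C2")
  expect_match(na, "CONSERVE Narsg_C1 \\+ ")
  expect_match(na, "SOLVE Narsg_z STEADYSTATE sparse")
  # GHK current: calcium USEION with valence and the constant-field FUNCTION
  cap <- mods[["CaP.mod"]]
  expect_match(cap, "USEION ca READ cai WRITE ica VALENCE 2")
  expect_match(cap, "FUNCTION ghk")
  # pool mechanism writes the internal concentration
  pool <- mods[["ca.mod"]]
  expect_match(pool, "USEION ca READ ica WRITE cai")
  expect_match(pool, "ca_cac' =")
})

test_that("all identifiers within each emitted file are unique", {
  for (src in list(hh_fixture(), kr_fixture())) {
    m <- compile_model(src)
    for (txt in emit_nmodl(m$sys, m$info, merge = FALSE)) {
      expect_identical(anyDuplicated(ionmodl:::nmodl_declared_names(txt)), 0L)
    }
    merged <- emit_nmodl(m$sys, m$info, merge = TRUE)[[1]]
    expect_identical(anyDuplicated(ionmodl:::nmodl_declared_names(merged)), 0L)
  }
})
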