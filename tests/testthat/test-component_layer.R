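# Components, nesting, flattening, input wiring.

test_that("component environments carry type, name and checked outputs", {
  env <- build_component_env(parse_component(parse_sexpr(
    "(pore (out gbar) (const gbar = 120 mS/cm*cm))")))
  expect_identical(env$ctype, "pore")
  expect_identical(env$outputs, "gbar")
  expect_identical(eval_expr(ionmodl:::env_get(env, "gbar")$rhs), 120)

  expect_error(
    build_component_env(parse_component(parse_sexpr("(pore (out gbar))"))),
    "output 'gbar'", class = "im_output_error")
})

test_that("sibling gates in different currents flatten to distinct names", {
  m <- lower_model(
    "(Membrane-potential M
      (Membrane-capacitance 1.0 uF/cm*cm)
      (Ohmic-current Na (E = 50 mV) (g_max = 10 mS/cm*cm)
       (gating m (power 3) (forward-rate (1 + v/100)) (reverse-rate (2))))
      (Ohmic-current K (E = -70 mV) (g_max = 5 mS/cm*cm)
       (gating m (power 4) (forward-rate (2)) (reverse-rate (1)))))")
  nms <- names(m$entries)
  expect_true(all(c("Na_m", "K_m", "Na_alpha_m", "K_alpha_m") %in% nms))
  expect_false(anyDuplicated(nms) > 0)
})

test_that("inner expressions resolve identifiers through enclosing scopes", {
  m <- lower_model(
    "(Membrane-potential M
      (const scale = 3)
      (Membrane-capacitance 1.0 uF/cm*cm)
      (Ohmic-current X (E = 0 mV) (g_max = 1 mS/cm*cm)
       (q = scale * 2)
       (gating a (power 1) (forward-rate (scale)) (reverse-rate (1)))))")
  q <- ionmodl:::env_get(m, "X_q")
  expect_identical(free_vars(q$rhs), "scale")   # root name, unmangled
  expect_identical(eval_expr(q$rhs, c(scale = 3)), 6)
  # the gate rate relation references the outer parameter too
  fwd <- ionmodl:::env_get(m, "X_alpha_a")
  expect_identical(free_vars(fwd$rhs), "scale")
})

test_that("flattening preserves evaluation semantics", {
  comp <- parse_component(parse_sexpr(
    "(Membrane-potential M
      (const a = 2)
      (Membrane-capacitance 1.0 uF/cm*cm)
      (Ohmic-current X (E = 0 mV) (g_max = 1 mS/cm*cm)
       (w = a + v * 3)
       (gating g1 (power 2) (forward-rate (1 + a)) (reverse-rate (2)))))"))
  nested <- build_component_env(comp)
  flat <- flatten(nested)
  # the expression for w before flattening...
  w_nested <- ionmodl:::env_get(
    ionmodl:::env_get(nested, "X"), "w")
  w_flat <- ionmodl:::env_get(flat, "X_w")
  set.seed(5)
  for (i in 1:50) {
    b <- c(a = runif(1, -5, 5), v = runif(1, -100, 100))
    expect_equal(eval_expr(w_nested$rhs, b), eval_expr(w_flat$rhs, b),
                 tolerance = 1e-12)
  }
})

test_that("flattening is collision-free on 200 random nested models", {
  for (s in 1:200) {
    flat <- flatten(build_component_env(
      ionmodl:::strip_experiments(
        parse_component(parse_sexpr(random_model(s, 1 + s %% 3))))$comp))
    nms <- names(flat$entries)
    expect_identical(anyDuplicated(nms), 0L)
  }
})

test_that("unresolved references are reported with the offending name", {
  expect_error(lower_model(
    "(Membrane-potential M
      (Membrane-capacitance 1.0 uF/cm*cm)
      (Ohmic-current X (E = 0 mV) (g_max = 1 mS/cm*cm)
       (w = nonexistent + 1)))"),
    "unresolved reference 'nonexistent'", class = "im_unresolved_error")
})

test_that("input wiring binds exported values across components", {
  m <- lower_model(kr_fixture())
  cai <- ionmodl:::env_get(m, "cai")
  expect_identical(cai$kind, "ASSIGNMENT")
  expect_identical(ionmodl:::expr_text(cai$rhs), "ca_cac")
  # and the GHK current consumes the wired name
  expect_true("cai" %in% free_vars(ionmodl:::env_get(m, "CaP_i")$rhs))
})

test_that("wiring errors: missing components and ambiguous outputs", {
  m <- lower_model(kr_fixture())
  expect_error(
    resolve_inputs(m, list(list(local = "x", src_ctype = "decaying-pool",
                                src_cname = "nope", output = NA))),
    "no component", class = "im_wiring_error")

  flat <- flatten(build_component_env(parse_component(parse_sexpr(
    "(Membrane-potential M
      (Membrane-capacitance 1.0 uF/cm*cm)
      (Ohmic-current X (E = 0 mV) (g_max = 1 mS/cm*cm)
       (pore p2 (out gbar2 q) (const gbar2 = 1) (const q = 2))))"))))
  expect_error(
    resolve_inputs(flat, list(list(local = "foo", src_ctype = "pore",
                                   src_cname = "p2", output = NA))),
    "name one explicitly", class = "im_wiring_error")
  ok <- resolve_inputs(flat, list(list(local = "foo", src_ctype = "pore",
                                       src_cname = "p2", output = "q")))
  expect_identical(ionmodl:::expr_text(ionmodl:::env_get(ok, "foo")$rhs),
                   "X_p2_q")
})

test_that("templates enforce their required entity names", {
  expect_error(lower_model(
    "(Membrane-potential M
      (Membrane-capacitance 1.0 uF/cm*cm)
      (Ohmic-current X (E = 0 mV) (g_max = 1 mS/cm*cm)
       (hh-gating-dynamics n (power 4)
        (fun n_inf (v) = (1 / (1 + exp(-v / 10)))))))"),
    "exactly 'tau_n'", class = "im_template_error")
})

test_that("structural rules are enforced", {
  expect_error(lower_model(
    "(Membrane-potential M (Membrane-capacitance 1.0)
      (Membrane-capacitance 2.0)
      (Ohmic-current X (E = 0) (g_max = 1)))"),
    "exactly one membrane-capacitance", class = "im_structural_error")
  expect_error(lower_model(
    "(Membrane-potential M (Membrane-capacitance 1.0))"),
    "at least one current", class = "im_structural_error")
  expect_error(lower_model(
    "(Membrane-potential M (Membrane-capacitance 1.0)
      (Ohmic-current X (E = 0)))"),
    "conductance source", class = "im_structural_error")
  # GHK needs a permeating ion with valence
  expect_error(lower_model(
    "(Membrane-potential M (Membrane-capacitance 1.0)
      (Ohmic-current X
       (permeability (out pmax) (const pmax = 1e-5))))"),
    "permeating-ion", class = "im_structural_error")
})
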