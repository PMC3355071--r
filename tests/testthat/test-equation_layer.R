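# Entities, environments, expressions.

test_that("declarations map to the five entity kinds", {
  p <- build_entity(parse_sexpr("(const duration = 2000)"))
  expect_identical(p$kind, "PARAMETER")
  expect_identical(eval_expr(p$rhs), 2000)

  a <- build_entity(parse_sexpr("(x = y + 1)"))
  expect_identical(a$kind, "ASSIGNMENT")

  f <- build_entity(parse_sexpr("(fun f (a b) = a * b)"))
  expect_identical(f$kind, "RELATION")
  expect_identical(f$formals, c("a", "b"))

  r <- build_entity(parse_sexpr("(d (m) = alpha(v) * (1 - m) - beta(v) * m)"))
  expect_identical(r$kind, "RATE")
  expect_identical(r$state, "m")

  k <- build_entity(parse_sexpr(
    "(reaction rx (transitions (<- C O (2) (1))) (open O (power 1)))"))
  expect_identical(k$kind, "REACTION")
  expect_setequal(k$states, c("C", "O"))
  expect_length(k$transitions, 1)
  expect_identical(k$conserve, 1)
})

test_that("bad declarations are grammar errors", {
  expect_error(build_entity(parse_sexpr("(frobnicate x = 1)")),
               "unknown declaration head", class = "im_grammar_error")
  expect_error(build_entity(parse_sexpr("(const x = y)")),
               "literal", class = "im_grammar_error")
  expect_error(build_entity(parse_sexpr(
    "(reaction rx (transitions (<- C O (1) (1))) (open Q))")),
    "open state", class = "im_grammar_error")
  # disconnected scheme
  expect_error(build_entity(parse_sexpr(
    "(reaction rx (transitions (<- A B (1) (1)) (<- C D (1) (1))) (open B))")),
    "disconnected", class = "im_grammar_error")
})

test_that("environments are persistent and match an association-list oracle", {
  e0 <- env_new()
  e1 <- extend_env(e0, build_entity(parse_sexpr("(const a = 1)")))
  e2 <- extend_env(e1, build_entity(parse_sexpr("(const b = 2)")))
  expect_identical(eval_expr(ionmodl:::env_get(e2, "a")$rhs), 1)
  expect_identical(eval_expr(ionmodl:::env_get(e2, "b")$rhs), 2)
  # persistence: e1 unchanged by the later extension
  expect_null(ionmodl:::env_get(e1, "b"))
  expect_error(extend_env(e2, build_entity(parse_sexpr("(const a = 9)"))),
               "redefinition", class = "im_redef_error")

  set.seed(42)
  alist <- list()
  env <- env_new()
  for (i in 1:100) {
    nm <- paste0("k", i)
    val <- runif(1)
    alist[[nm]] <- val
    env <- extend_env(env, ionmodl:::ent_parameter(nm, ionmodl:::ex_num(val)))
  }
  for (nm in names(alist)) {
    expect_identical(eval_expr(ionmodl:::env_get(env, nm)$rhs), alist[[nm]])
  }
})

test_that("free variables follow the printed examples", {
  expect_identical(free_vars(ionmodl:::ex_num(2000)), character(0))
  e1 <- parse_rate_expr("(2.5 - 0.1*V)/((exp (2.5 - 0.1*V)) - 1)")
  expect_identical(free_vars(e1), "V")
  e2 <- parse_rate_expr("g_max * m*m*m * h")
  expect_identical(free_vars(e2), c("g_max", "m", "h"))
})

test_that("expression evaluation matches the printed rate functions", {
  alpha_m <- parse_rate_expr("(2.5 - 0.1*V)/((exp (2.5 - 0.1*V)) - 1)")
  expect_equal(eval_expr(alpha_m, c(V = 0)), 2.5 / (exp(2.5) - 1),
               tolerance = 1e-12)
  beta_m <- parse_rate_expr("0.125 * exp(-V/80)")
  expect_identical(eval_expr(beta_m, c(V = 0)), 0.125)
  expect_error(eval_expr(ionmodl:::ex_sym("x")), "unbound symbol 'x'",
               class = "im_eval_error")
  rel <- build_entity(parse_sexpr("(fun f (a) = a + 1)"))
  expect_error(
    eval_expr(parse_rate_expr("f(1, 2)"), relations = list(f = rel)),
    "expects 1 argument", class = "im_eval_error")
})

test_that("evaluation agrees with base R on 1000 random expressions", {
  set.seed(7)
  env <- list(x = 1.7, y = -0.4, z = 2.25)
  for (i in 1:1000) {
    txt <- random_expr_text(3)
    want <- eval(parse(text = txt), env)
    got <- eval_expr(parse_rate_expr(txt), env)
    if (is.finite(want) && abs(want) > 1e-12) {
      expect_equal(got, want, tolerance = 1e-12)
    } else {
      expect_identical(got, want)
    }
  }
})

test_that("substitution respects frames, chains and formals", {
  e <- parse_rate_expr("x + y")
  expect_identical(ionmodl:::expr_text(subst(e, list(x = "a"))), "a + y")
  expect_identical(subst(e, list()), e)
  s <- subst_env(list(x = ionmodl:::ex_num(1)),
                 subst_env(list(y = ionmodl:::ex_num(2))))
  expect_identical(ionmodl:::expr_text(subst(parse_rate_expr("x * y"), s)),
                   "1 * 2")
  # inner frame shadows outer
  s2 <- subst_env(list(x = ionmodl:::ex_num(10)),
                  subst_env(list(x = ionmodl:::ex_num(20))))
  expect_identical(eval_expr(subst(parse_rate_expr("x"), s2)), 10)
  # skip protects relation formals
  expect_identical(
    ionmodl:::expr_text(subst(e, list(x = "a"), skip = "x")), "x + y")
})

test_that("substituted identifiers never survive as free variables", {
  set.seed(11)
  for (i in 1:50) {
    e <- parse_rate_expr(random_expr_text(3))
    s <- list(x = "u1", y = "u2")
    fv <- free_vars(subst(e, s))
    expect_false(any(c("x", "y") %in% fv))
  }
})
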