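# Independent oracles used across the suite.

# Hand-coded Hodgkin-Huxley right-hand side, written directly from the
# model's printed equations (shifted convention, E_Na = 115 mV,
# g_max_Na = 120 mS/cm^2, C = 1 uF/cm^2). Deliberately independent of the
# compiler: plain arithmetic, no package structures.
hh_oracle_rhs <- function(t, y, i_stim = 0) {
  v <- y[[1]]; m <- y[[2]]; h <- y[[3]]; n <- y[[4]]
  alpha_m <- (2.5 - 0.1 * v) / (exp(2.5 - 0.1 * v) - 1)
  beta_m <- 0.125 * exp(-v / 80)
  alpha_h <- 0.07 * exp(-v / 20)
  beta_h <- 1 / (exp(3 - 0.1 * v) + 1)
  alpha_n <- (0.1 - 0.01 * v) / (exp(1 - 0.1 * v) - 1)
  beta_n <- 0.125 * exp(-v / 80)
  i_na <- 120 * m^3 * h * (v - 115)
  i_k <- 36 * n^4 * (v - (-12))
  i_l <- 0.3 * (v - 10.613)
  c((i_stim - (i_na + i_k + i_l)) / 1.0,
    alpha_m * (1 - m) - beta_m * m,
    alpha_h * (1 - h) - beta_h * h,
    alpha_n * (1 - n) - beta_n * n)
}

# Random arithmetic expression over x, y, z that is legal in both the
# model dialect and R, so base R's parser/evaluator can serve as oracle.
random_expr_text <- function(depth = 3) {
  leaf <- function() {
    if (runif(1) < 0.5) sprintf("%.4f", runif(1, 0.1, 5)) else
      sample(c("x", "y", "z"), 1)
  }
  build <- function(d) {
    if (d <= 0 || runif(1) < 0.25) return(leaf())
    r <- runif(1)
    if (r < 0.6) {
      op <- sample(c(" + ", " - ", " * ", " / "), 1)
      paste0("(", build(d - 1L), op, build(d - 1L), ")")
    } else if (r < 0.8) {
      paste0("exp(", build(d - 1L), " / 10)")
    } else {
      paste0("(0 - ", build(d - 1L), ")")
    }
  }
  build(depth)
}

parse_rate_expr <- function(text) {
  node <- parse_sexpr(paste0("(", text, ")"))
  ionmodl:::parse_expr_items(node$children)
}

# Every name referenced by an ordered definition must be introduced
# earlier (or be a state / reserved global).
check_topological <- function(sys) {
  states <- names(sys$state_index)
  seen <- character(0)
  for (d in sys$ordered_defs) {
    fv <- free_vars(d$rhs)
    ok <- fv %in% c(seen, states, "t", "celsius", "i_stim")
    if (!all(ok)) return(fv[!ok])
    seen <- c(seen, d$name)
  }
  character(0)
}

fixture_clamp <- function(model_text, clamp_text) {
  m <- compile_model(model_text)
  p <- build_clamp_protocol(parse_sexpr(clamp_text), m)
  list(model = m, protocol = p)
}
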