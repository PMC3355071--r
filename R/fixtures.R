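# Bundled model fixtures and the random model generator.

#' The Hodgkin-Huxley squid-axon model
#'
#' Returns the source text of the classic Hodgkin-Huxley model in the
#' shifted convention (resting potential at 0 mV, E_Na = 115 mV,
#' g_max_Na = 120 mS/cm^2, C = 1 uF/cm^2), including the standard
#' simulation block (duration 2000 ms, stepsize 1e-4 ms). The sodium
#' activation rates are
#' `alpha_m = (2.5 - 0.1 V) / (exp(2.5 - 0.1 V) - 1)` and
#' `beta_m = 0.125 exp(-V/80)`; the remaining gates use the classical
#' squid-axon rate functions.
#'
#' @return Model source text (single character string).
#' @examples
#' m <- compile_model(hh_fixture())
#' names(m$sys$state_index)   # v, m, h, n
#' @export
hh_fixture <- function() {
"(Membrane-potential HH
 (Membrane-capacitance 1.0 uF/cm*cm)
 (Ohmic-current Na (E = 115 mV) (g_max = 120 mS/cm*cm)
  (gating m (power 3)
   (forward-rate (2.5 - 0.1*V)/((exp (2.5 - 0.1*V)) - 1))
   (reverse-rate (0.125 * exp(-V/80))))
  (gating h (power 1)
   (forward-rate (0.07 * exp(-V/20)))
   (reverse-rate 1/((exp (3 - 0.1*V)) + 1))))
 (Ohmic-current K (E = -12 mV) (g_max = 36 mS/cm*cm)
  (gating n (power 4)
   (forward-rate (0.1 - 0.01*V)/((exp (1 - 0.1*V)) - 1))
   (reverse-rate (0.125 * exp(-V/80)))))
 (Ohmic-current Leak (E = 10.613 mV) (g_max = 0.3 mS/cm*cm))
 (simulation (out duration stepsize)
  (const duration = 2000)
  (const stepsize = 1e-4))
) ;; end of Membrane-potential
"
}

#' A Purkinje-neuron style model (Khaliq-Raman reconstruction)
#'
#' A layer-oriented reconstruction of the structure of the 2003
#' Khaliq-Raman Purkinje neuron model (ModelDB 48332): membrane
#' capacitance, a resurgent sodium current with the 13-state Raman-Bean
#' kinetic scheme (5 closed, 5 inactivated, open, blocked, open-inactivated
#' states), a Kv3-type potassium current written with the
#' HH-gating-dynamics template, a calcium-activated-type BK current
#' (simplified to voltage gating), a leak, a P-type calcium current using
#' the GHK constant-field law with the internal calcium concentration
#' wired from a Traub-style decaying pool, and the CaBK voltage-clamp
#' protocol (hold -90 mV, base -40 mV, 5 steps of 10 mV, holding duration
#' 5 ms, base duration 20 ms).
#'
#' This fixture is a transcription/reconstruction: the kinetic-scheme
#' topology and its rate constants follow the published Raman-Bean
#' resurgent sodium scheme, while the remaining rate functions are
#' simplified stand-ins with Purkinje-like voltage dependence (the
#' original supplementary listing is not distributed with this package).
#'
#' @return Model source text (single character string).
#' @export
kr_fixture <- function() {
"(Membrane-potential KhaliqRaman
 (Membrane-capacitance 1.0 uF/cm*cm)
 (Ohmic-current Narsg
  (fun alfa (v) = (150 * exp(v/20)))
  (fun bta (v) = (3 * exp(-v/20)))
  (const gamma = 150)
  (const delta = 40)
  (const epsilon = 1.75)
  (fun zeta (v) = (0.03 * exp(-v/25)))
  (const Con = 0.005)
  (const Coff = 0.5)
  (const Oon = 0.75)
  (const Ooff = 0.005)
  (const aS = 3.4965)  ;; (Oon/Con)^(1/4)
  (const bS = 0.31623) ;; (Ooff/Coff)^(1/4)
  (reaction z
   (transitions
    (<- C1 C2 (4 * alfa(v)) (bta(v)))
    (<- C2 C3 (3 * alfa(v)) (2 * bta(v)))
    (<- C3 C4 (2 * alfa(v)) (3 * bta(v)))
    (<- C4 C5 (alfa(v)) (4 * bta(v)))
    (<- C5 O (gamma) (delta))
    (<- O B (epsilon) (zeta(v)))
    (<- O I6 (Oon) (Ooff))
    (<- C1 I1 (Con) (Coff))
    (<- C2 I2 (Con * aS) (Coff * bS))
    (<- C3 I3 (Con * aS^2) (Coff * bS^2))
    (<- C4 I4 (Con * aS^3) (Coff * bS^3))
    (<- C5 I5 (Con * aS^4) (Coff * bS^4))
    (<- I1 I2 (4 * alfa(v) * aS) (bta(v) * bS))
    (<- I2 I3 (3 * alfa(v) * aS) (2 * bta(v) * bS))
    (<- I3 I4 (2 * alfa(v) * aS) (3 * bta(v) * bS))
    (<- I4 I5 (alfa(v) * aS) (4 * bta(v) * bS))
    (<- I5 I6 (gamma) (delta)))
   (conserve 1)
   (open O (power 1)))
  (pore (out gbar) (const gbar = 16 mS/cm*cm))
  (permeating-ion (name na) (out e) (const e = 60 mV)))
 (Ohmic-current Kv3 (E = -88 mV) (g_max = 32 mS/cm*cm)
  (hh-gating-dynamics n (power 4)
   (fun n_inf (v) = (1 / (1 + exp(-(v + 24) / 15.4))))
   (fun tau_n (v) = (0.2 + 1.5 / (1 + exp((v + 20) / 10))))))
 (Ohmic-current CaBK (E = -88 mV) (g_max = 14 mS/cm*cm)
  (gating m (power 3)
   (forward-rate (2.5 / (1 + exp(-(v + 28) / 9))))
   (reverse-rate (1.5 / (1 + exp((v + 25) / 9))))))
 (Ohmic-current Leak (E = -60 mV) (g_max = 0.09 mS/cm*cm))
 (Ohmic-current CaP
  (hh-gating-dynamics m (power 1)
   (fun m_inf (v) = (1 / (1 + exp(-(v + 19) / 5.5))))
   (fun tau_m (v) = (0.2 + 0.8 / (1 + exp((v + 30) / 8)))))
  (permeability (out pmax) (const pmax = 5e-5))
  (permeating-ion (name ca) (valence 2)
   (const cao = 2.4 mM)
   (input (cai from decaying-pool ca))))
 (decaying-pool ca (out cac)
  (current CaP)
  (const steady = 1e-4 mM)
  (const tau = 1 ms)
  (const b = 0.005))
 (simulation (out duration stepsize)
  (const duration = 2000)
  (const stepsize = 1e-4))
 (voltage-clamp (name CaBK)
  (out hold base stepsize nsteps holding-duration base-duration)
  (const hold = -90)
  (const base = -40)
  (const stepsize = 10)
  (const nsteps = 5)
  (const holding-duration = 5)
  (const base-duration = 20))
)
"
}

## ------------------------------------------------ random model generator ----

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

rnum <- function(lo, hi) sprintf("%.6g", stats::runif(1, lo, hi))

random_rate <- function(sign = 1) {
  # bounded exponential/sigmoid families: values stay positive and finite
  # over the physiological voltage range, avoiding rate blow-up
  a <- rnum(0.05, 3)
  b <- rnum(-40, 40)
  c <- rnum(15, 60)
  if (stats::runif(1) < 0.5) {
    sprintf("(%s * exp(%s(v - %s) / %s))", a, if (sign > 0) "" else "-", b, c)
  } else {
    sprintf("(%s / (1 + exp(%s(v - %s) / %s)))", a,
            if (sign > 0) "-" else "", b, c)
  }
}

random_gate <- function(k) {
  sprintf("  (gating g%d (power %d)\n   (forward-rate %s)\n   (reverse-rate %s))",
          k, sample(1:4, 1), random_rate(+1), random_rate(-1))
}

random_reaction <- function() {
  k1 <- rnum(0.2, 4); k2 <- rnum(0.2, 4)
  k3 <- rnum(0.2, 4); k4 <- rnum(0.2, 4)
  paste0("  (reaction z\n   (transitions\n",
         sprintf("    (<- C1 C2 (%s) (%s))\n", k1, k2),
         sprintf("    (<- C2 O (%s) (%s)))\n", k3, k4),
         "   (conserve 1)\n   (open O (power 1)))")
}

random_current <- function(k) {
  name <- paste0("Cur", k)
  kind <- sample(c("hh", "hh", "hh", "kin", "ghk"), 1)
  if (kind == "ghk") {
    paste0(
      "(Ohmic-current ", name, "\n",
      random_gate(1L), "\n",
      "  (permeability (out pmax) (const pmax = ", rnum(1e-6, 1e-4), "))\n",
      "  (permeating-ion (name ca) (valence 2)\n",
      "   (const cai = ", rnum(5e-5, 2e-4), ")\n",
      "   (const cao = ", rnum(1, 3), ")))")
  } else {
    gates <- if (kind == "kin") {
      random_reaction()
    } else {
      paste(vapply(seq_len(sample(1:2, 1)), random_gate, ""),
            collapse = "\n")
    }
    if (stats::runif(1) < 0.5) {
      # compact conductance/reversal parameters
      paste0("(Ohmic-current ", name,
             " (E = ", rnum(-100, 120), " mV)",
             " (g_max = ", rnum(0.05, 50), " mS/cm*cm)\n",
             gates, ")")
    } else {
      paste0("(Ohmic-current ", name, "\n", gates, "\n",
             "  (pore (out gbar) (const gbar = ", rnum(0.05, 50), "))\n",
             "  (permeating-ion (name ion", k, ") (out e) (const e = ",
             rnum(-100, 120), ")))")
    }
  }
}

#' Generate a random, structurally valid model
#'
#' Produces the source text of a well-formed model with a membrane
#' capacitance and `n_currents` current components whose gates, powers and
#' rate functions are drawn from bounded exponential/sigmoid families
#' (kinetic-scheme and GHK currents are included with fixed probability).
#' The same seed always yields byte-identical output; the caller's RNG
#' state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_currents Number of current components (>= 1).
#' @return Model source text.
#' @export
random_model <- function(seed, n_currents = 2) {
  if (n_currents < 1) validation_error("n_currents must be >= 1")
  with_preserved_rng({
    set.seed(as.integer(seed %% 2147483647L))
    body <- vapply(seq_len(n_currents), random_current, "")
    paste0("(Membrane-potential Rand", as.integer(seed %% 2147483647L), "\n",
           " (Membrane-capacitance 1.0 uF/cm*cm)\n ",
           paste(body, collapse = "\n "), "\n)\n")
  })
}
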