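# Shared fixtures: control parameters, short protocols, random-case
# generators, and small synthetic-trace builders used across the suite.

ctrl <- qk_params()

short_step <- function(v = 40, dur = 100, tail_v = -40, tail_dur = 50)
  qk_protocol(data.frame(v_mV = c(v, tail_v),
                         duration_ms = c(dur, tail_dur)))

# random short protocol (2-3 epochs) for property-based tests
random_protocol <- function() {
  k <- sample(2:3, 1)
  qk_protocol(data.frame(v_mV = stats::runif(k, -120, 80),
                         duration_ms = sample(5:40, k, replace = TRUE)))
}

# control parameters with all prefactors/couplings perturbed +-20%
perturbed_params <- function() {
  f <- function(x) x * stats::runif(1, 0.8, 1.2)
  qk_params(a1 = f(ctrl$a1), c1 = f(ctrl$c1), a2 = f(ctrl$a2),
            c2 = f(ctrl$c2), a3 = f(ctrl$a3), c3 = f(ctrl$c3),
            m = f(ctrl$m), n = f(ctrl$n), b = f(ctrl$b), d = f(ctrl$d),
            k1 = f(ctrl$k1), k2 = f(ctrl$k2), k3 = f(ctrl$k3),
            k4 = f(ctrl$k4), label = "perturbed")
}

# noise-free rising double-exponential "activation current"
make_rising_trace <- function(tau_f = 48, tau_s = 600, A_f = 1,
                              A_s = 0.5, C = 0, T = 4000, dt = 1,
                              sigma = 0) {
  t <- seq(0, T, by = dt)
  y <- C + A_f * (1 - exp(-t / tau_f)) + A_s * (1 - exp(-t / tau_s))
  if (sigma > 0) y <- y + stats::rnorm(length(y), 0, sigma * max(abs(y)))
  qk_trace(t, y)
}

# tail built from the hook double-exponential form
make_hook_trace <- function(A1 = -1, tau1 = 300, A2 = 0.4, tau2 = 40,
                            C = 0, T = 2000, dt = 1, sigma = 0) {
  t <- seq(0, T, by = dt)
  y <- A1 * exp(-t / tau1) + A2 * exp(-t / tau2) + C
  if (sigma > 0) y <- y + stats::rnorm(length(y), 0, sigma * max(abs(y)))
  qk_trace(t, y)
}

boltz <- function(v, V12, z, Tk = 295.15) {
  s0 <- 1000 * 8.31446261815324 * Tk / 96485.33212
  1 / (1 + exp(-z * (v - V12) / s0))
}

# left-nullspace stationary distribution via eigen-decomposition
# (independent of the qr.solve path used by steady_state)
eigen_steady <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  p <- Re(e$vectors[, i])
  p / sum(p)
}
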