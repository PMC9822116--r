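# shared fixtures for the model tests

fig2_weights <- function() single_pop_weights(3.5 / 0.05)

ring_weights_fig45 <- function() build_single_env_weights(100, 13 / 0.01, 30 / 0.01)

# single population with J = 0 and external drive tuned so f(h*) = f0
constant_rate_params <- function(f0 = 5, N = 50, tau_D = 0.8, U0 = 0.8) {
  trp <- transfer_params(r = 3.15, a = 0.25, h0 = 2)
  mu0 <- 2 + 0.25 * log(expm1(f0 / (3.15 * 0.25)))
  meso_params(tau = 0.05, mu = mu0, transfer = trp,
              synapse = synapse_params(tau_D, U0), J_tau = 0, N = N)
}

# subthreshold, strongly stable single fixed point (no excitability):
# fig2 physiology with reduced drive, for linearization-based oracles
stable_node_params <- function(N = 200) {
  p <- preset_params("fig2", N = N)
  p$mu <- 0.5
  p
}

# analytic stationary variance of (h, x, Q) for the diffusion model
# linearized about a fixed point: solves the Lyapunov equation
# A S + S A' + g g' = 0 of the Ornstein-Uhlenbeck approximation
ou_variance_h <- function(params) {
  J <- params$J_tau / params$tau
  U0 <- params$synapse$U0; tauD <- params$synapse$tau_D; tau <- params$tau
  fp <- find_fixed_points(params)
  stopifnot(nrow(fp) == 1)
  h0 <- fp$h[1]; x0 <- fp$x[1]
  f <- transfer_function(h0, params$transfer)
  f1 <- transfer_deriv(h0, params$transfer)
  Q0 <- x0 / (1 + tauD * U0 * (2 - U0) * f / 2)
  A <- matrix(c(-1 / tau + J * U0 * x0 * f1, J * U0 * f, 0,
                -U0 * x0 * f1, -1 / tauD - U0 * f, 0,
                -U0 * (2 - U0) * Q0 * f1, 2 / tauD,
                -2 / tauD - U0 * (2 - U0) * f),
              3, 3, byrow = TRUE)
  s <- sqrt(Q0 * f / params$N)
  g <- c(J * U0 * s, -U0 * s, 0)
  S <- matrix(solve(kronecker(diag(3), A) + kronecker(A, diag(3)),
                    -as.vector(outer(g, g))), 3, 3)
  S[1, 1]
}

# normalized L1 distance between two spectral densities on (0, fmax]
spectral_distance <- function(s1, s2, fmax = 50) {
  keep <- s1$freq > 0 & s1$freq <= fmax
  sum(abs(s1$power[keep] - s2$power[keep])) /
    sum((s1$power[keep] + s2$power[keep]) / 2)
}
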