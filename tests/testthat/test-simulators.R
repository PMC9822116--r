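test_that("seeded runs are bit-reproducible", {
  p <- preset_params("fig2", N = 30)
  W <- fig2_weights()
  a <- simulate_jump_diffusion(p, W, T = 5, seed = 42)
  b <- simulate_jump_diffusion(p, W, T = 5, seed = 42)
  expect_identical(a$A, b$A)
  expect_identical(a$h, b$h)
  m1 <- simulate_microscopic(p, W, T = 3, seed = 9, raster = TRUE)
  m2 <- simulate_microscopic(p, W, T = 3, seed = 9, raster = TRUE)
  expect_identical(m1$raster, m2$raster)
  m3 <- simulate_microscopic(p, W, T = 3, seed = 10, raster = TRUE)
  expect_false(identical(m1$raster, m3$raster))
})

test_that("silent network relaxes to mu and full resources", {
  # threshold far above reach: f = 0 exactly (threshold-linear branch)
  p <- meso_params(tau = 0.05, mu = 1,
                   transfer = transfer_params(r = 1, a = 0, h0 = 100),
                   synapse = synapse_params(0.8, 0.4), J_tau = 0, N = 20)
  W <- single_pop_weights(0)
  tr <- simulate_microscopic(p, W, T = 2, seed = 1,
                             init = list(h = 0, x = 0.5), record = c("h", "x"))
  expect_equal(sum(tr$A), 0)
  expect_equal(tr$h[nrow(tr$h), 1], 1, tolerance = 1e-4)
  expect_equal(tr$x[nrow(tr$x), 1], 1, tolerance = 0.05)
  # intermediate-time relaxation follows exp(-t/tau)
  i <- which.min(abs(tr$times - 0.05))
  expect_equal(tr$h[i, 1], 1 - exp(-1), tolerance = 1e-2)
  # diffusion model: without spiking x -> 1 and Q -> 1, hence y -> 0
  pd <- meso_params(tau = 0.05, mu = -5,
                    transfer = transfer_params(r = 1, a = 0, h0 = 100),
                    synapse = synapse_params(0.3, 0.4), J_tau = 1, N = 50)
  d <- simulate_diffusion(pd, single_pop_weights(1 / 0.05), T = 3, seed = 2,
                          init = list(x = 0.4, Q = 0.2))
  n <- length(d$times)
  expect_equal(d$x[n, 1], 1, tolerance = 1e-3)
  expect_equal(d$Q[n, 1], 1, tolerance = 1e-3)
  expect_equal(d$Q[n, 1] - d$x[n, 1]^2, 0, tolerance = 2e-3)
})

test_that("microscopic depression settles at its analytic stationary mean", {
  p <- constant_rate_params(f0 = 5, N = 50)
  tr <- simulate_microscopic(p, single_pop_weights(0), T = 250, seed = 7,
                             record = "x")
  xbar <- mean(tr$x[tr$times > 20, 1])
  expect_equal(xbar, 1 / (1 + 0.8 * 0.8 * 5), tolerance = 0.02)
})

test_that("jump-diffusion resource variance settles at the fixed point of its drift", {
  f0 <- 5; U0 <- 0.8; tauD <- 0.8
  p <- constant_rate_params(f0 = f0, N = 50)
  tr <- simulate_jump_diffusion(p, single_pop_weights(0), T = 250, seed = 8,
                                record = c("x", "m2"))
  xb <- 1 / (1 + tauD * U0 * f0)
  ystar <- U0^2 * xb^2 * f0 / (2 / tauD + U0 * (2 - U0) * f0)
  expect_equal(mean(tr$y[tr$times > 20, 1]), ystar, tolerance = 0.06)
})

test_that("both stochastic models reduce to the macroscopic integrator as N -> Inf", {
  p <- preset_params("fig3", N = Inf)
  W <- fig2_weights()
  init <- list(h = 3, x = 0.8)
  mac <- simulate_macroscopic(p, W, T = 4, init = init, record = "h")
  jd <- simulate_jump_diffusion(p, W, T = 4, seed = 1,
                                init = c(init, list(y = 0)), record = "h")
  df <- simulate_diffusion(p, W, T = 4, seed = 1,
                           init = c(init, list(Q = 0.64)), record = "h")
  expect_lt(max(abs(jd$h - mac$h)), 1e-10)
  expect_lt(max(abs(df$h - mac$h)), 1e-10)
})

test_that("Q- and y-formulations of the second moment are consistent", {
  # noise-free skew systems from matched initial conditions: y = Q - x^2
  p <- preset_params("fig3", N = Inf)
  W <- fig2_weights()
  x0 <- 0.7; Q0 <- 0.55          # genuine spread: y0 = Q0 - x0^2 = 0.06
  jd <- simulate_jump_diffusion(p, W, T = 3, seed = 1,
                                init = list(h = 2.2, x = x0, y = Q0 - x0^2),
                                record = c("x", "m2"))
  df <- simulate_diffusion(p, W, T = 3, seed = 1,
                           init = list(h = 2.2, x = x0, Q = Q0),
                           record = c("x", "m2"))
  y_from_Q <- df$Q - df$x^2
  expect_lt(max(abs(jd$y - y_from_Q)), 5e-4)  # O(dt) transform error
  expect_lt(max(abs(jd$x - df$x)), 1e-10)
})

test_that("diffusion-model potential variance follows the linearized OU prediction", {
  p <- stable_node_params(N = 200)
  tr <- simulate_diffusion(p, fig2_weights(), T = 300, seed = 9, record = "h")
  v <- var(tr$h[tr$times > 20, 1])
  expect_equal(v, ou_variance_h(p), tolerance = 0.15)
})

test_that("stationary potential variance scales as 1/N", {
  Ns <- c(50, 100, 200, 400)
  vs <- vapply(Ns, function(N) {
    p <- stable_node_params(N = N)
    tr <- simulate_diffusion(p, fig2_weights(), T = 80, seed = N, record = "h")
    var(tr$h[tr$times > 10, 1])
  }, numeric(1))
  slope <- unname(coef(lm(log(vs) ~ log(Ns)))[2])
  expect_equal(slope, -1, tolerance = 0.1)
})

test_that("state variables stay in their physical ranges, clamps are reported", {
  p <- preset_params("fig45", N = 50)
  W <- build_single_env_weights(50, 13 / 0.01, 30 / 0.01)
  tr <- simulate_jump_diffusion(p, W, T = 20, seed = 3,
                                record = c("A", "x", "m2"))
  expect_true(all(tr$x >= 0 & tr$x <= 1))
  expect_true(all(tr$y >= 0))
  expect_true(all(tr$A >= 0))
  expect_named(tr$clamp, c("x", "y"))
  # clamping is rare relative to the number of population-steps
  expect_lt(sum(tr$clamp), 0.01 * 20 / 1e-4 * 50)
})

test_that("microscopic simulator warns on coarse steps and rejects invalid setups", {
  p <- meso_params(tau = 0.05, mu = 30,
                   transfer = transfer_params(r = 10, a = 0, h0 = 0),
                   synapse = synapse_params(0.8, 0.4), J_tau = 0, N = 5,
                   dt = 1e-3)  # f(h*) * dt = 0.3: legal but coarse
  expect_warning(simulate_microscopic(p, single_pop_weights(0), T = 0.2,
                                      seed = 1),
                 "f\\(h\\)\\*dt")
  # spike probability above one aborts with a diagnostic
  pbad <- meso_params(tau = 0.05, mu = 30,
                      transfer = transfer_params(r = 100, a = 0, h0 = 0),
                      synapse = synapse_params(0.8, 0.4), J_tau = 0, N = 5,
                      dt = 1e-3)
  expect_error(simulate_microscopic(pbad, single_pop_weights(0), T = 0.2,
                                    seed = 1),
               "f\\(h\\)\\*dt > 1")
  p2 <- preset_params("fig2", N = Inf)
  expect_error(simulate_microscopic(p2, fig2_weights(), T = 1), "finite N")
})

test_that("recorded activity equals spike counts over the recording stride", {
  p <- preset_params("fig2", N = 30)
  tr <- simulate_microscopic(p, fig2_weights(), T = 5, seed = 21,
                             raster = TRUE, record_every = 10L)
  # reconstruct A from the raster: spikes per neuron per second per bin
  bins <- ceiling(tr$raster$time / tr$dt - 1e-9)
  cnt <- tabulate(bins, nbins = length(tr$times))
  expect_equal(tr$A[, 1], cnt / (30 * tr$dt), tolerance = 1e-10)
})
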