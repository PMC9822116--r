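# Shared plumbing for the Euler-Maruyama simulators.
#
# All simulators integrate with a fixed step params$dt (Ito convention: drift
# and noise coefficients from the state at t-), record the population
# activity A averaged over `record_every` steps, and sample the remaining
# state variables at the record instants. The single R RNG stream drives all
# noise channels; runs are bit-reproducible given (params, W, T, seed).

resolve_weights <- function(W, params) {
  if (inherits(W, "weight_matrix")) return(W)
  if (is.matrix(W)) {
    M <- nrow(W)
    return(structure(list(J = W, theta = 2 * pi * seq_len(M) / M,
                          kind = "dense", M = M, J0 = 0, J1 = NA,
                          U = NULL, V = NULL),
                     class = "weight_matrix"))
  }
  if (is.numeric(W) && length(W) == 1) return(single_pop_weights(W))
  stop("'W' must be a weight_matrix, a square matrix, or a scalar coupling")
}

default_init <- function(params, W) {
  # spatially uniform low-activity state: h at the lowest fixed point of the
  # macroscopic system with the row-averaged (DC) coupling, x = 1, y = 0
  Jdc <- mean(rowSums(W$J)) / W$M
  h <- uniform_fixed_point(params, Jdc)
  list(h = rep(h, W$M), x = rep(1, W$M))
}

new_sim_trace <- function(model_kind, params, W, T, dt_rec, seed, raw,
                          extra = list()) {
  nrec <- raw$n_steps / (dt_rec / params$dt)
  times <- seq_len(nrec) * dt_rec
  out <- c(list(model_kind = model_kind, times = times, dt = dt_rec,
                dt_sim = params$dt, duration = max(times), seed = seed,
                M = W$M, N = params$N, params = params,
                theta = W$theta),
           if (nrow(raw$A) > 0) list(A = raw$A),
           extra)
  structure(out, class = "sim_trace")
}

check_meso_raw <- function(raw, params) {
  if (raw$fdt_warn > 0)
    warning(sprintf("f(h)*dt exceeded 0.1 in %d population-steps; consider a smaller dt",
                    as.integer(raw$fdt_warn)))
  invisible(raw)
}

meso_call <- function(kind, params, W, T, record_every, init, record) {
  M <- W$M
  mu <- rep_len(params$mu, M)
  use_dense <- is.null(W$U)
  emptyM <- matrix(0, 0, 0)
  sim_meso_cpp(kind, params$N, T, params$dt, as.integer(record_every),
               params$tau, params$synapse$tau_D, params$synapse$U0,
               params$transfer$r, params$transfer$a, params$transfer$h0,
               mu,
               if (use_dense) emptyM else W$U,
               if (use_dense) emptyM else W$V,
               W$J0, use_dense,
               if (use_dense) W$J else emptyM,
               init$h, init$x, init$m2,
               "A" %in% record, "h" %in% record, "x" %in% record,
               "m2" %in% record)
}

#' Simulate the mesoscopic jump-diffusion model
#'
#' Integrates the hybrid-noise Langevin dynamics of `M` populations: the
#' population activity is Poisson shot noise, \eqn{A = \Delta n/(N \Delta t)}
#' with \eqn{\Delta n \sim \mathrm{Pois}(N f(h) \Delta t)}, and synapse-to-
#' synapse heterogeneity of the depression variables enters as Gaussian white
#' noise with variance \eqn{y f(h)/N}, where `y` is the population variance
#' of the per-neuron depression variables. The identical stochastic drive
#' realization enters the potential and resource equations. `N = Inf`
#' disables all noise and recovers the macroscopic limit (with the `y`
#' equation carried along as a skew system).
#'
#' @param params a [meso_params()] object (N, dt, and all physiology).
#' @param W coupling: a [build_single_env_weights()] /
#'   [build_multi_env_weights()] / [single_pop_weights()] object, a plain
#'   square matrix, or a scalar (single population).
#' @param T duration (s).
#' @param seed integer seed.
#' @param record_every record state every this many integration steps
#'   (default 10, i.e. 1 ms at `dt = 1e-4`); activity is averaged over the
#'   stride, other state variables are sampled.
#' @param init optional named list with elements `h`, `x`, `y` (length `M`
#'   or scalar); defaults: `h` at the uniform low-activity fixed point,
#'   `x = 1`, `y = 0`.
#' @param record which series to keep: subset of `c("A", "h", "x", "m2")`
#'   (`"A"` is the empirical activity; drop it for long ring runs analysed
#'   on the rate representation to halve the memory footprint).
#' @return A `"sim_trace"` object with matrices (time x population) `A` and,
#'   as requested, `h`, `x`, `y`; fields `dt` (recording step), `times`,
#'   `clamp` counts.
#' @export
simulate_jump_diffusion <- function(params, W, T, seed = 1L,
                                    record_every = 10L, init = NULL,
                                    record = c("A", "h", "x", "m2")) {
  stopifnot(inherits(params, "meso_params"))
  W <- resolve_weights(W, params)
  ini <- default_init(params, W)
  init <- utils::modifyList(list(h = ini$h, x = ini$x, y = 0), as.list(init))
  init$m2 <- rep_len(init$y, W$M)  # y = Q - x^2
  init$h <- rep_len(init$h, W$M); init$x <- rep_len(init$x, W$M)
  set.seed(seed)
  raw <- meso_call(0L, params, W, T, record_every, init, record)
  check_meso_raw(raw, params)
  extra <- list(clamp = c(x = raw$clamp_x, y = raw$clamp_m2),
                state_final = list(h = raw$h_final, x = raw$x_final,
                                   y = raw$m2_final))
  if ("h" %in% record) extra$h <- raw$h
  if ("x" %in% record) extra$x <- raw$x
  if ("m2" %in% record) extra$y <- raw$m2
  new_sim_trace("jump_diffusion", params, W, T, params$dt * record_every,
                seed, raw, extra)
}

#' Simulate the mesoscopic diffusion model
#'
#' Pure-Gaussian mesoscopic dynamics: a single white noise per population
#' multiplies \eqn{\sqrt{Q f(h)/N}} and enters the potential equation with
#' `+J U0` and the resource equation with `-U0` (the same realization, i.e.
#' perfectly anticorrelated), where `Q` is the second moment of the
#' per-neuron depression variables, integrated as
#' \eqn{\dot Q = 2(x - Q)/\tau_D - U_0(2-U_0) Q f(h)}.
#'
#' @inheritParams simulate_jump_diffusion
#' @param init optional list with `h`, `x`, `Q` (defaults `Q = 1`).
#' @return A `"sim_trace"`; recorded activity is the rate \eqn{f(h)}.
#' @export
simulate_diffusion <- function(params, W, T, seed = 1L, record_every = 10L,
                               init = NULL, record = c("A", "h", "x", "m2")) {
  stopifnot(inherits(params, "meso_params"))
  W <- resolve_weights(W, params)
  ini <- default_init(params, W)
  init <- utils::modifyList(list(h = ini$h, x = ini$x, Q = 1), as.list(init))
  init$m2 <- rep_len(init$Q, W$M)
  init$h <- rep_len(init$h, W$M); init$x <- rep_len(init$x, W$M)
  set.seed(seed)
  raw <- meso_call(1L, params, W, T, record_every, init, record)
  check_meso_raw(raw, params)
  extra <- list(clamp = c(x = raw$clamp_x, Q = raw$clamp_m2),
                state_final = list(h = raw$h_final, x = raw$x_final,
                                   Q = raw$m2_final))
  if ("h" %in% record) extra$h <- raw$h
  if ("x" %in% record) extra$x <- raw$x
  if ("m2" %in% record) extra$Q <- raw$m2
  new_sim_trace("diffusion", params, W, T, params$dt * record_every,
                seed, raw, extra)
}

#' Simulate the macroscopic (deterministic) model
#'
#' Euler integration of the noise-free mean-field limit
#' \eqn{\dot h_\alpha = (\mu - h_\alpha)/\tau + M^{-1}\sum_\beta J_{\alpha\beta}
#' U_0 x_\beta f(h_\beta)}, \eqn{\dot x_\alpha = (1-x_\alpha)/\tau_D -
#' U_0 x_\alpha f(h_\alpha)}. Requires an explicit initial state for
#' non-default runs; the default starts at the uniform low-activity fixed
#' point with `x = 1`. Note that the spatially uniform state is an exact
#' solution on the ring, so fatigue-driven traveling-wave regimes need a
#' symmetry-breaking perturbation in `init` (see [run_experiment()], which
#' seeds mode 1 with 0.01 mV for ring macro runs).
#'
#' @inheritParams simulate_jump_diffusion
#' @param init named list with `h` and `x` (length `M` or scalar).
#' @return A `"sim_trace"`; activity is \eqn{f(h)}.
#' @export
simulate_macroscopic <- function(params, W, T, init = NULL,
                                 record_every = 10L,
                                 record = c("A", "h", "x")) {
  stopifnot(inherits(params, "meso_params"))
  W <- resolve_weights(W, params)
  ini <- default_init(params, W)
  init <- utils::modifyList(list(h = ini$h, x = ini$x), as.list(init))
  init$m2 <- rep_len(0, W$M)
  init$h <- rep_len(init$h, W$M); init$x <- rep_len(init$x, W$M)
  raw <- meso_call(2L, params, W, T, record_every, init, record)
  extra <- list(state_final = list(h = raw$h_final, x = raw$x_final))
  if ("h" %in% record) extra$h <- raw$h
  if ("x" %in% record) extra$x <- raw$x
  new_sim_trace("macro", params, W, T, params$dt * record_every,
                NA_integer_, raw, extra)
}

#' Simulate the microscopic LNP spiking network
#'
#' Networks of `M` populations of `N` linear-nonlinear-Poisson neurons with
#' per-neuron Tsodyks-Markram depression (and optionally facilitation). In
#' each step each neuron spikes independently with probability
#' \eqn{f(h^\alpha(t^-))\Delta t} (Bernoulli). A spike of neuron `j` in
#' population \eqn{\beta} makes every potential jump by
#' \eqn{M^{-1} J_{\alpha\beta} U_0 x_j(t^-)/N} and depletes its own resource
#' by \eqn{U_0 x_j(t^-)}; between spikes \eqn{h} and \eqn{x_j} relax with
#' \eqn{\tau} and \eqn{\tau_D}. All neurons of a population share one input
#' potential (identical by construction under homogeneous initial
#' conditions).
#'
#' @inheritParams simulate_jump_diffusion
#' @param raster if `TRUE`, return the spike raster (data frame
#'   `time`, `neuron`).
#' @param record subset of `c("h", "x", "Q")`: per-population mean potential,
#'   mean resource, and second resource moment sampled at record instants.
#' @return A `"sim_trace"` with population activity `A` (spikes per neuron
#'   per second, averaged over the recording stride).
#' @export
simulate_microscopic <- function(params, W, T, seed = 1L, record_every = 10L,
                                 init = NULL, record = c("h", "x"),
                                 raster = FALSE) {
  stopifnot(inherits(params, "meso_params"))
  if (is.infinite(params$N)) stop("microscopic simulation needs finite N")
  W <- resolve_weights(W, params)
  ini <- default_init(params, W)
  init <- utils::modifyList(list(h = ini$h, x = 1), as.list(init))
  mu <- rep_len(params$mu, W$M)
  use_dense <- is.null(W$U)
  emptyM <- matrix(0, 0, 0)
  sy <- params$synapse
  set.seed(seed)
  raw <- sim_micro_cpp(as.integer(params$N), T, params$dt,
                       as.integer(record_every),
                       params$tau, sy$tau_D, sy$U0,
                       sy$facilitation,
                       if (sy$facilitation) sy$tau_F else 1,
                       if (sy$facilitation) sy$U else 0,
                       params$transfer$r, params$transfer$a,
                       params$transfer$h0, mu,
                       if (use_dense) emptyM else W$U,
                       if (use_dense) emptyM else W$V,
                       W$J0, use_dense,
                       if (use_dense) W$J else emptyM,
                       rep_len(init$h, W$M), init$x[1],
                       "h" %in% record, "x" %in% record, "Q" %in% record,
                       raster)
  if (raw$fdt_warn > 0)
    warning(sprintf("f(h)*dt exceeded 0.1 in %d population-steps",
                    as.integer(raw$fdt_warn)))
  extra <- list()
  if ("h" %in% record) extra$h <- raw$h
  if ("x" %in% record) {
    extra$x <- raw$x
    if (sy$facilitation) extra$u <- raw$u
  }
  if ("Q" %in% record) extra$Q <- raw$Q
  if (raster)
    extra$raster <- data.frame(time = raw$raster_t, neuron = raw$raster_id)
  new_sim_trace("micro", params, W, T, params$dt * record_every, seed, raw,
                extra)
}

#' Simulate the full short-term-plasticity mesoscopic model
#'
#' Integrates the six-moment Langevin system for depression plus
#' facilitation: means `h`, `u`, `x` and second moments `P`, `Q`, `R` (of
#' utilization, resources, and their cross-moment). The population activity
#' is Poisson, and two correlated Gaussian channels with variances
#' \eqn{(P - u^2) f/N} and \eqn{(Q - x^2) f/N} and correlation
#' \eqn{\rho = (R - u x)/\sqrt{(P-u^2)(Q-x^2)}} (clipped to \eqn{[-1,1]})
#' carry the across-synapse heterogeneity. Variance arguments are clamped at
#' zero before square roots; clamp and clip events are counted.
#'
#' @inheritParams simulate_jump_diffusion
#' @param params must carry facilitation parameters (`tau_F`, `U`).
#' @param init optional list with `h`, `u`, `x`, `P`, `Q`, `R`; defaults
#'   `u = U0`, `x = 1`, `P = U0^2`, `Q = 1`, `R = U0` (zero initial
#'   population variance).
#' @return A `"sim_trace"` with all six state series and `A`.
#' @export
simulate_full_stp <- function(params, W, T, seed = 1L, record_every = 10L,
                              init = NULL) {
  stopifnot(inherits(params, "meso_params"))
  sy <- params$synapse
  if (!sy$facilitation)
    stop("simulate_full_stp() needs facilitation parameters (tau_F, U)")
  W <- resolve_weights(W, params)
  ini <- default_init(params, W)
  U0 <- sy$U0
  init <- utils::modifyList(
    list(h = ini$h, u = U0, x = 1, P = U0^2, Q = 1, R = U0), as.list(init))
  for (nm in c("h", "u", "x", "P", "Q", "R"))
    init[[nm]] <- rep_len(init[[nm]], W$M)
  mu <- rep_len(params$mu, W$M)
  use_dense <- is.null(W$U)
  emptyM <- matrix(0, 0, 0)
  set.seed(seed)
  raw <- sim_fullstp_cpp(params$N, T, params$dt, as.integer(record_every),
                         params$tau, sy$tau_D, sy$tau_F, U0, sy$U,
                         params$transfer$r, params$transfer$a,
                         params$transfer$h0, mu,
                         if (use_dense) emptyM else W$U,
                         if (use_dense) emptyM else W$V,
                         W$J0, use_dense,
                         if (use_dense) W$J else emptyM,
                         init$h, init$u, init$x, init$P, init$Q, init$R)
  extra <- list(h = raw$h, u = raw$u, x = raw$x, P = raw$P, Q = raw$Q,
                R = raw$R,
                clamp = c(var = raw$clamp_var, rho = raw$clip_rho))
  new_sim_trace("full_stp", params, W, T, params$dt * record_every, seed,
                raw, extra)
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace> %s model: M = %d, N = %s, T = %g s (dt_sim = %g s, recorded every %g s)\n",
              x$model_kind, x$M,
              if (is.infinite(x$N)) "Inf" else format(x$N), x$duration,
              x$dt_sim, x$dt))
  act <- if (!is.null(x$A)) x$A else rate_matrix(x)
  if (!is.null(act))
    cat(sprintf("  mean population activity: %.3f Hz\n", mean(act)))
  if (!is.null(x$clamp) && any(x$clamp > 0))
    cat("  clamp events:",
        paste(sprintf("%s = %d", names(x$clamp), as.integer(x$clamp)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Population-averaged activity of a trace
#'
#' @param trace a `sim_trace`.
#' @param burn_in initial period to discard (s), default 5.
#' @return List with `times` and `activity` (population mean, Hz).
#' @export
mean_activity <- function(trace, burn_in = 5) {
  stopifnot(inherits(trace, "sim_trace"))
  act <- if (!is.null(trace$A)) trace$A else rate_matrix(trace)
  if (is.null(act)) stop("trace recorded neither activity nor potential")
  keep <- trace$times > burn_in
  list(times = trace$times[keep], activity = rowMeans(act[keep, , drop = FALSE]))
}

#' Plot a simulation trace
#'
#' Population-averaged activity over time; for multi-population traces also
#' an image of the per-population activity.
#'
#' @param x a `sim_trace`.
#' @param burn_in initial seconds to hide.
#' @param ... passed to [plot()].
#' @export
plot.sim_trace <- function(x, burn_in = 0, ...) {
  act <- if (!is.null(x$A)) x$A else rate_matrix(x)
  if (is.null(act)) stop("trace recorded neither activity nor potential")
  keep <- x$times > burn_in
  avg <- rowMeans(act[keep, , drop = FALSE])
  if (x$M > 1) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    graphics::image(x = x$times[keep], y = seq_len(x$M), z = act[keep, ],
                    xlab = "time [s]", ylab = "population", useRaster = TRUE)
  }
  plot(x$times[keep], avg, type = "l", xlab = "time [s]",
       ylab = "mean activity [Hz]", ...)
  invisible(x)
}

#' Write / read a simulation trace as delimited text
#'
#' Persists the recorded series (optionally down-sampled) as a TSV plus a
#' YAML metadata side file, and reads the pair back into a `sim_trace`.
#'
#' @param trace a `sim_trace`.
#' @param path base path; `<path>.tsv` and `<path>.yml` are written.
#' @param every keep every `every`-th recorded sample (default 1).
#' @return `write_sim_trace()` returns `path` invisibly; `read_sim_trace()`
#'   the restored object (matrix fields only; parameters reattached from
#'   metadata).
#' @export
write_sim_trace <- function(trace, path, every = 1L) {
  stopifnot(inherits(trace, "sim_trace"))
  idx <- seq(1, length(trace$times), by = every)
  fields <- intersect(c("A", "h", "x", "y", "Q", "u", "P", "R"), names(trace))
  fields <- fields[vapply(fields, function(f)
    is.matrix(trace[[f]]) && nrow(trace[[f]]) > 0, logical(1))]
  df <- data.frame(time = trace$times[idx])
  for (f in fields) {
    m <- trace[[f]][idx, , drop = FALSE]
    colnames(m) <- paste0(f, seq_len(ncol(m)))
    df <- cbind(df, m)
  }
  utils::write.table(format(df, digits = 17, trim = TRUE),
                     paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(model_kind = trace$model_kind, M = trace$M,
               N = if (is.infinite(trace$N)) "Inf" else trace$N,
               dt = trace$dt * every, dt_sim = trace$dt_sim,
               duration = trace$duration, seed = trace$seed,
               fields = as.list(fields))
  yaml::write_yaml(meta, paste0(path, ".yml"), precision = 17L)
  invisible(path)
}

#' @rdname write_sim_trace
#' @export
read_sim_trace <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  df <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  out <- list(model_kind = meta$model_kind, times = df$time, dt = meta$dt,
              dt_sim = meta$dt_sim, duration = meta$duration,
              seed = meta$seed, M = meta$M,
              N = if (identical(meta$N, "Inf")) Inf else meta$N)
  for (f in unlist(meta$fields)) {
    cols <- grep(paste0("^", f, "[0-9]+$"), names(df), value = TRUE)
    out[[f]] <- as.matrix(df[cols])
    dimnames(out[[f]]) <- NULL
  }
  structure(out, class = "sim_trace")
}

#' Write a spike raster as two-column delimited text
#' @param trace a microscopic `sim_trace` simulated with `raster = TRUE`.
#' @param path file path.
#' @export
write_raster <- function(trace, path) {
  if (is.null(trace$raster)) stop("trace carries no raster")
  utils::write.table(format(trace$raster, digits = 17, trim = TRUE), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
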