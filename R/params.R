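#' Transfer-function parameters
#'
#' Parameters of the static nonlinearity \eqn{f(h) = r a \log(1 + e^{(h-h_0)/a})}
#' mapping input potential (mV) to firing rate (Hz). In the limit `a = 0` the
#' function becomes threshold-linear, \eqn{f(h) = r [h - h_0]_+}.
#'
#' @param r suprathreshold slope (Hz/mV), must be positive.
#' @param a smoothness at threshold (mV), non-negative; `a = 0` selects the
#'   threshold-linear branch.
#' @param h0 threshold (mV).
#' @return An object of class `"transfer_params"`.
#' @seealso [transfer_function()]
#' @export
transfer_params <- function(r, a, h0) {
  stopifnot(is.numeric(r), is.numeric(a), is.numeric(h0))
  if (!all(is.finite(c(r, a, h0)))) stop("transfer parameters must be finite")
  if (r <= 0) stop("slope 'r' must be positive")
  if (a < 0) stop("smoothness 'a' must be non-negative")
  structure(list(r = as.numeric(r), a = as.numeric(a), h0 = as.numeric(h0)),
            class = "transfer_params")
}

#' Short-term plasticity parameters
#'
#' Tsodyks-Markram synapse parameters. With `tau_F = NULL` (and `U = NULL`)
#' the synapse is depression-only: utilization is pinned at `U0`. Supplying
#' `tau_F` and `U` enables facilitation.
#'
#' @param tau_D depression recovery time constant (s), positive.
#' @param U0 baseline utilization of synaptic resources, in (0, 1].
#' @param tau_F facilitation time constant (s), optional.
#' @param U utilization increment per spike, in \[0, 1\], required with `tau_F`.
#' @return An object of class `"synapse_params"`.
#' @export
synapse_params <- function(tau_D, U0, tau_F = NULL, U = NULL) {
  stopifnot(is.numeric(tau_D), is.numeric(U0))
  if (!is.finite(tau_D) || tau_D <= 0) stop("'tau_D' must be positive and finite")
  if (!is.finite(U0) || U0 <= 0 || U0 > 1) stop("'U0' must lie in (0, 1]")
  facil <- !is.null(tau_F)
  if (facil) {
    if (is.null(U)) stop("facilitation requires both 'tau_F' and 'U'")
    if (!is.finite(tau_F) || tau_F <= 0) stop("'tau_F' must be positive and finite")
    if (!is.finite(U) || U < 0 || U > 1) stop("'U' must lie in [0, 1]")
  } else if (!is.null(U)) {
    stop("'U' given without 'tau_F'; supply both to enable facilitation")
  }
  structure(list(tau_D = as.numeric(tau_D), U0 = as.numeric(U0),
                 tau_F = if (facil) as.numeric(tau_F) else NULL,
                 U = if (facil) as.numeric(U) else NULL,
                 facilitation = facil),
            class = "synapse_params")
}

#' Model parameters for one simulation
#'
#' Bundles membrane, synaptic and transfer parameters together with the
#' network geometry. Couplings are specified as the products `J*tau` (mV), the
#' form in which they are conventionally reported; the effective weight used
#' in the drift is `J = (J*tau)/tau` so that `tau * J * U0 * x * f(h)` carries
#' units of mV. Either `J_tau` (uniform single-population coupling) or the
#' pair `J0_tau`/`J1_tau` (ring: uniform inhibition / map-specific coupling)
#' must be given.
#'
#' @param tau membrane (leaky-filter) time constant (s).
#' @param mu external input (mV); a scalar, recycled over populations.
#' @param transfer a [transfer_params()] object.
#' @param synapse a [synapse_params()] object.
#' @param J_tau coupling constant times tau (mV), single population.
#' @param J0_tau,J1_tau inhibition / map-specific couplings times tau (mV).
#' @param N neurons per population.
#' @param dt integration step (s); default 1e-4.
#' @return An object of class `"meso_params"`.
#' @export
meso_params <- function(tau, mu, transfer, synapse,
                        J_tau = NULL, J0_tau = NULL, J1_tau = NULL,
                        N = 100, dt = 1e-4) {
  stopifnot(inherits(transfer, "transfer_params"),
            inherits(synapse, "synapse_params"))
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be positive and finite")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive and finite")
  if (!(is.infinite(N) || (is.finite(N) && N >= 1))) stop("'N' must be >= 1 (or Inf)")
  if (dt > tau / 10 || dt > synapse$tau_D / 10)
    warning("dt is not small against tau and tau_D; integration may be inaccurate")
  ring <- !is.null(J0_tau)
  if (ring) {
    if (is.null(J1_tau)) stop("ring coupling needs both 'J0_tau' and 'J1_tau'")
    if (!is.null(J_tau)) stop("give either 'J_tau' or ('J0_tau', 'J1_tau'), not both")
  } else if (is.null(J_tau)) {
    stop("one of 'J_tau' or ('J0_tau', 'J1_tau') is required")
  }
  structure(list(tau = as.numeric(tau), mu = as.numeric(mu),
                 transfer = transfer, synapse = synapse,
                 J_tau = if (!ring) as.numeric(J_tau) else NULL,
                 J0_tau = if (ring) as.numeric(J0_tau) else NULL,
                 J1_tau = if (ring) as.numeric(J1_tau) else NULL,
                 ring = ring, N = N, dt = as.numeric(dt)),
            class = "meso_params")
}

#' @export
print.meso_params <- function(x, ...) {
  cat("<meso_params>\n")
  cat(sprintf("  tau = %g s, tau_D = %g s, U0 = %g", x$tau, x$synapse$tau_D,
              x$synapse$U0))
  if (x$synapse$facilitation)
    cat(sprintf(", tau_F = %g s, U = %g", x$synapse$tau_F, x$synapse$U))
  cat("\n")
  cat(sprintf("  f(h): r = %g Hz/mV, a = %g mV, h0 = %g mV\n",
              x$transfer$r, x$transfer$a, x$transfer$h0))
  if (x$ring) {
    cat(sprintf("  ring coupling: J0*tau = %g mV, J1*tau = %g mV\n",
                x$J0_tau, x$J1_tau))
  } else {
    cat(sprintf("  coupling: J*tau = %g mV\n", x$J_tau))
  }
  cat(sprintf("  mu = %g mV, N = %g, dt = %g s\n", x$mu, x$N, x$dt))
  invisible(x)
}

# effective weights (units mV * Hz^-1 ... used as J in drift terms J*U0*x*f)
eff_J <- function(p) p$J_tau / p$tau
eff_J0 <- function(p) p$J0_tau / p$tau
eff_J1 <- function(p) p$J1_tau / p$tau

#' Canonical parameter presets
#'
#' Named parameter sets for the four standard regimes studied with this model
#' family: `"fig2"` population spikes in a single excitatory population,
#' `"fig3"` Up-Down bistability, `"fig45"` fluctuation-driven replay on a
#' single-environment ring (M = 100), and `"fig6"` replay across three
#' embedded environments (M = 300).
#'
#' @param name one of `"fig2"`, `"fig3"`, `"fig45"`, `"fig6"`.
#' @param N neurons per population; defaults to the value used in the
#'   corresponding regime.
#' @param dt integration step (s).
#' @return A [meso_params()] object. Ring presets carry attribute `"M"`
#'   (number of populations) and, for `"fig6"`, `"K"` and `"f_select"`.
#' @export
preset_params <- function(name = c("fig2", "fig3", "fig45", "fig6"),
                          N = NULL, dt = 1e-4) {
  name <- match.arg(name)
  p <- switch(name,
    fig2 = meso_params(tau = 0.05, mu = 1.4,
                       transfer = transfer_params(r = 3.15, a = 0.25, h0 = 2),
                       synapse = synapse_params(tau_D = 0.8, U0 = 0.4),
                       J_tau = 3.5, N = if (is.null(N)) 30 else N, dt = dt),
    fig3 = meso_params(tau = 0.05, mu = 1.4,
                       transfer = transfer_params(r = 3.15, a = 0.2, h0 = 2),
                       synapse = synapse_params(tau_D = 0.6, U0 = 0.4),
                       J_tau = 3.5, N = if (is.null(N)) 100 else N, dt = dt),
    fig45 = meso_params(tau = 0.01, mu = -1.4,
                        transfer = transfer_params(r = 1, a = 1, h0 = 0),
                        synapse = synapse_params(tau_D = 0.8, U0 = 0.8),
                        J0_tau = 13, J1_tau = 30,
                        N = if (is.null(N)) 50 else N, dt = dt),
    fig6 = meso_params(tau = 0.01, mu = -1.5,
                       transfer = transfer_params(r = 1, a = 1, h0 = 0),
                       synapse = synapse_params(tau_D = 0.8, U0 = 0.8),
                       J0_tau = 16, J1_tau = 25,
                       N = if (is.null(N)) 50 else N, dt = dt))
  attr(p, "preset") <- name
  attr(p, "M") <- switch(name, fig2 = 1L, fig3 = 1L, fig45 = 100L, fig6 = 300L)
  if (name == "fig6") {
    attr(p, "K") <- 3L
    attr(p, "f_select") <- 0.3
  }
  # external input used by the deterministic macroscopic variant of the
  # ring regimes (fatigue-driven replay)
  attr(p, "mu_macro") <- switch(name, fig45 = -0.9, fig6 = -0.35, NULL)
  p
}

#' Write / read parameter sets as YAML configs
#'
#' Round-trip serialization of [meso_params()] objects to a structured
#' key-value config file, one file per experiment.
#'
#' @param params a `meso_params` object.
#' @param path file path.
#' @return `write_params_config()` returns `path` invisibly;
#'   `read_params_config()` returns a `meso_params` object.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "meso_params"))
  lst <- list(
    tau = params$tau, mu = params$mu,
    transfer = unclass(params$transfer),
    synapse = list(tau_D = params$synapse$tau_D, U0 = params$synapse$U0,
                   tau_F = params$synapse$tau_F, U = params$synapse$U),
    J_tau = params$J_tau, J0_tau = params$J0_tau, J1_tau = params$J1_tau,
    N = if (is.infinite(params$N)) "Inf" else params$N,
    dt = params$dt)
  yaml::write_yaml(lst, path, precision = 17L)
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  lst <- yaml::read_yaml(path)
  N <- if (identical(lst$N, "Inf")) Inf else lst$N
  meso_params(tau = lst$tau, mu = lst$mu,
              transfer = transfer_params(lst$transfer$r, lst$transfer$a,
                                         lst$transfer$h0),
              synapse = synapse_params(lst$synapse$tau_D, lst$synapse$U0,
                                       lst$synapse$tau_F, lst$synapse$U),
              J_tau = lst$J_tau, J0_tau = lst$J0_tau, J1_tau = lst$J1_tau,
              N = N, dt = lst$dt)
}
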