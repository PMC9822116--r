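#' Fixed points of the macroscopic single-population system
#'
#' Finds all fixed points of
#' \deqn{\dot h = (\mu - h)/\tau + J U_0 x f(h), \qquad
#'       \dot x = (1 - x)/\tau_D - U_0 x f(h)}
#' by eliminating \eqn{x^* = 1/(1 + \tau_D U_0 f(h))} and bracketing the
#' reduced scalar equation in `h` over
#' \eqn{[h_0 - 20 a - |\mu|,\; h_0 + 5 (J\tau) U_0 r + |\mu|]}
#' (2000 subintervals), followed by root polishing. Each root is classified
#' from the eigenvalues of the analytic 2 x 2 Jacobian.
#'
#' @param params a [meso_params()] object with single-population coupling
#'   `J_tau` (alternatively pass `J` explicitly).
#' @param J optional effective coupling overriding `params$J_tau / tau`.
#' @return A data frame of class `"fixed_points"`, one row per fixed point
#'   sorted by `h`: columns `h`, `x`, `eig_re`, `eig_im` (of the
#'   leading/complex pair), `classification`, plus attribute `"eigen"` with
#'   the full eigenvalue pairs.
#' @export
find_fixed_points <- function(params, J = NULL) {
  stopifnot(inherits(params, "meso_params"))
  if (is.null(J)) {
    if (params$ring) stop("find_fixed_points() analyses the M = 1 system; pass J explicitly")
    J <- eff_J(params)
  }
  tr <- params$transfer; sy <- params$synapse
  tau <- params$tau; tauD <- sy$tau_D; U0 <- sy$U0; mu <- params$mu
  xeq <- function(h) 1 / (1 + tauD * U0 * transfer_function(h, tr))
  g <- function(h) (mu - h) / tau +
    J * U0 * xeq(h) * transfer_function(h, tr)
  lo <- tr$h0 - 20 * tr$a - abs(mu)
  hi <- tr$h0 + 5 * abs(J * tau) * U0 * tr$r + abs(mu)
  grid <- seq(lo, hi, length.out = 2001L)
  gv <- vapply(grid, g, numeric(1))
  sgn <- sign(gv)
  roots <- numeric(0)
  for (i in which(sgn[-1] * sgn[-length(sgn)] < 0)) {
    rt <- stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-14)$root
    roots <- c(roots, rt)
  }
  roots <- c(roots, grid[gv == 0])
  roots <- sort(unique(roots))
  if (length(roots) == 0) {
    warning("no fixed point found in search interval")
    return(structure(data.frame(h = numeric(0), x = numeric(0),
                                eig_re = numeric(0), eig_im = numeric(0),
                                classification = character(0)),
                     class = c("fixed_points", "data.frame")))
  }
  res <- lapply(roots, function(h) {
    x <- xeq(h)
    ls <- linear_stability(c(h = h, x = x), params, J = J)
    data.frame(h = h, x = x,
               eig_re = Re(ls$eigenvalues[1]), eig_im = abs(Im(ls$eigenvalues[1])),
               classification = ls$classification,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "eigen") <- lapply(roots, function(h)
    linear_stability(c(h = h, x = xeq(h)), params, J = J)$eigenvalues)
  attr(out, "J") <- J
  class(out) <- c("fixed_points", "data.frame")
  out
}

#' Linear stability of a macroscopic fixed point
#'
#' Evaluates the analytic Jacobian
#' \deqn{\begin{pmatrix} -1/\tau + J U_0 x f'(h) & J U_0 f(h) \\
#'  -U_0 x f'(h) & -1/\tau_D - U_0 f(h) \end{pmatrix}}
#' at a fixed point and classifies it from the eigenvalues (1/s).
#'
#' @param fp named numeric vector `c(h = , x = )`; must satisfy the
#'   fixed-point equations to residual 1e-8 (relative to the drift scale).
#' @param params a [meso_params()] object.
#' @param J effective coupling (defaults to `params$J_tau / tau`).
#' @return List with `eigenvalues` (complex pair), `jacobian`, and
#'   `classification` in stable/unstable node/focus or saddle.
#' @export
linear_stability <- function(fp, params, J = NULL) {
  stopifnot(inherits(params, "meso_params"))
  if (is.null(J)) J <- eff_J(params)
  h <- unname(fp["h"]); x <- unname(fp["x"])
  tr <- params$transfer; sy <- params$synapse
  tau <- params$tau; tauD <- sy$tau_D; U0 <- sy$U0; mu <- params$mu
  f <- transfer_function(h, tr); fp1 <- transfer_deriv(h, tr)
  res_h <- (mu - h) / tau + J * U0 * x * f
  res_x <- (1 - x) / tauD - U0 * x * f
  scale <- max(1 / tau, abs(J * U0 * f), 1 / tauD, 1)
  if (max(abs(res_h), abs(res_x)) > 1e-8 * scale)
    stop("(h, x) is not a fixed point of the macroscopic system")
  Jm <- matrix(c(-1 / tau + J * U0 * x * fp1, J * U0 * f,
                 -U0 * x * fp1, -1 / tauD - U0 * f),
               2, 2, byrow = TRUE)
  ev <- eigen(Jm, only.values = TRUE)$values
  detJ <- Jm[1, 1] * Jm[2, 2] - Jm[1, 2] * Jm[2, 1]
  cls <- if (detJ < 0) "saddle" else {
    stable <- all(Re(ev) < 0)
    focus <- any(Im(ev) != 0)
    paste(if (stable) "stable" else "unstable",
          if (focus) "focus" else "node")
  }
  list(eigenvalues = ev, jacobian = Jm, classification = cls)
}

#' Trace an invariant manifold of a saddle fixed point
#'
#' Integrates the macroscopic vector field from `fp +/- eps * v`, where `v`
#' is the eigenvector of the selected eigenvalue: forward in time for the
#' unstable manifold, in reversed time for the stable manifold (the
#' separatrix). Integration stops when the trajectory leaves the bounding
#' box or the time horizon is exhausted.
#'
#' @param fp a saddle fixed point, named vector `c(h = , x = )`.
#' @param params a [meso_params()] object.
#' @param which `"stable"` or `"unstable"`.
#' @param J effective coupling (defaults from `params`).
#' @param eps seeding offset along the eigenvector (default 1e-6).
#' @param t_max time horizon per branch (s).
#' @param box bounding box `c(h_min, h_max, x_min, x_max)`.
#' @return List with two data frames `branch_pos` and `branch_neg` (columns
#'   `time`, `h`, `x`), ordered away from the saddle.
#' @export
trace_manifold <- function(fp, params, which = c("stable", "unstable"),
                           J = NULL, eps = 1e-6, t_max = 60,
                           box = NULL) {
  which <- match.arg(which)
  stopifnot(inherits(params, "meso_params"))
  if (is.null(J)) J <- eff_J(params)
  ls <- linear_stability(fp, params, J = J)
  if (ls$classification != "saddle") stop("fixed point is not a saddle")
  ev <- eigen(ls$jacobian)
  lam <- Re(ev$values)
  i <- if (which == "unstable") which.max(lam) else which.min(lam)
  v <- Re(ev$vectors[, i]); v <- v / sqrt(sum(v^2))
  tr <- params$transfer; sy <- params$synapse
  if (is.null(box))
    box <- c(tr$h0 - 20 * tr$a - abs(params$mu) - 5,
             tr$h0 + 5 * abs(J * params$tau) * sy$U0 * tr$r + abs(params$mu) + 5,
             -0.05, 1.05)
  sgn_t <- if (which == "unstable") 1 else -1
  deriv <- function(t, s, parms) {
    f <- transfer_function(s[1], tr)
    list(sgn_t * c((params$mu - s[1]) / params$tau + J * sy$U0 * s[2] * f,
                   (1 - s[2]) / sy$tau_D - sy$U0 * s[2] * f))
  }
  rootfun <- function(t, s, parms)
    min(s[1] - box[1], box[2] - s[1], s[2] - box[3], box[4] - s[2])
  run <- function(dir) {
    s0 <- c(unname(fp["h"]), unname(fp["x"])) + dir * eps * v
    times <- seq(0, t_max, by = 1e-3)
    sol <- deSolve::lsodar(y = s0, times = times, func = deriv, parms = NULL,
                           rootfunc = rootfun, rtol = 1e-10, atol = 1e-12)
    data.frame(time = sol[, 1], h = sol[, 2], x = sol[, 3])
  }
  list(branch_pos = run(1), branch_neg = run(-1),
       eigenvector = v, eigenvalue = ev$values[i])
}

# lowest-h fixed point of the spatially uniform macroscopic system with DC
# coupling Jdc; used for default initial conditions
uniform_fixed_point <- function(params, Jdc) {
  tr <- params$transfer; sy <- params$synapse
  xeq <- function(h) 1 / (1 + sy$tau_D * sy$U0 * transfer_function(h, tr))
  g <- function(h) (params$mu - h) / params$tau +
    Jdc * sy$U0 * xeq(h) * transfer_function(h, tr)
  lo <- tr$h0 - 20 * tr$a - abs(params$mu) - 10
  hi <- tr$h0 + 5 * abs(Jdc * params$tau) * sy$U0 * tr$r + abs(params$mu) + 10
  grid <- seq(lo, hi, length.out = 2001L)
  gv <- vapply(grid, g, numeric(1))
  sgn <- sign(gv)
  i <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(i) == 0) return(params$mu)
  stats::uniroot(g, c(grid[i[1]], grid[i[1] + 1]), tol = 1e-13)$root
}

#' @export
print.fixed_points <- function(x, ...) {
  cat(sprintf("<fixed_points> %d fixed point(s)\n", nrow(x)))
  print.data.frame(x, digits = 6)
  invisible(x)
}

#' Write a fixed-point table as delimited text
#' @param fp a `fixed_points` object.
#' @param path file path.
#' @export
write_fixed_points <- function(fp, path) {
  utils::write.table(as.data.frame(fp), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
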