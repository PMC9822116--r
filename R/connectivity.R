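#' Ring connectivity for a single circular environment
#'
#' Builds the M x M symmetric circulant weight matrix
#' \deqn{J_{\alpha\beta} = J_1 \cos(\theta_\alpha - \theta_\beta) - J_0,}
#' with place-field angles \eqn{\theta_\alpha = 2\pi\alpha/M} equally spaced
#' on the ring. `J1` scales map-specific interactions (local excitation), `J0`
#' is uniform feedback inhibition. Weights are effective weights, i.e. the
#' caller passes `J0 = (J0*tau)/tau` etc.
#'
#' @param M number of populations (>= 3 for a meaningful ring).
#' @param J0 uniform inhibition (effective units, mV/s per Hz of drive).
#' @param J1 map-specific coupling, same units.
#' @return A `"weight_matrix"` object: dense matrix `J`, angles `theta`,
#'   and the low-rank factors (`U`, `V`, `J0`) used by the O(M) coupling
#'   evaluation \eqn{J = U V^\top - J_0}.
#' @export
build_single_env_weights <- function(M, J0, J1) {
  if (!is.numeric(M) || M < 1) stop("'M' must be a positive integer")
  M <- as.integer(M)
  if (M >= 3 && !(J1 > J0 && J0 >= 0))
    warning("J1 > J0 >= 0 expected for the excitatory-center ring regime")
  theta <- 2 * pi * seq_len(M) / M
  ct <- cos(theta); st <- sin(theta)
  J <- J1 * cos(outer(theta, theta, "-")) - J0
  U <- cbind(J1 * ct, J1 * st)
  V <- cbind(ct, st)
  structure(list(J = J, theta = theta, kind = "single", M = M,
                 J0 = J0, J1 = J1, U = U, V = V),
            class = "weight_matrix")
}

#' Pseudo-random selectivity for multiple circular environments
#'
#' Assigns to each of `M` populations a binary selectivity vector over `K`
#' environments such that exactly `f*M` populations are selective for each
#' environment, and place-field angles, unique and evenly spaced on
#' \eqn{\{2\pi/(fM), \dots, 2\pi\}}, to the selective populations of each
#' environment.
#'
#' For the balanced three-environment construction (`K = 3`) the overlap
#' structure is symmetric: of the `fM` populations selective for environment
#' k, 7 are selective for all three environments, 10 + 10 are shared with
#' each of the other two environments, and the remaining `fM - 27` are
#' exclusive. Units are shuffled with the seeded generator so the
#' construction is reproducible from `(M, K, f, seed)`. For other `K` a
#' simple random construction without overlap bookkeeping is used (flagged
#' in the result).
#'
#' @param M number of populations.
#' @param K number of environments.
#' @param f selectivity fraction in (0, 1]; `f*M` must be an integer.
#' @param seed integer seed for the shuffles.
#' @return An `"environment_map"`: binary `M x K` matrix `zeta`, `M x K`
#'   angle matrix `theta` (NA where not selective), and bookkeeping fields.
#' @export
build_selectivity <- function(M, K, f, seed = 1L) {
  M <- as.integer(M); K <- as.integer(K)
  if (M < 1 || K < 1) stop("'M' and 'K' must be positive")
  if (f <= 0 || f > 1) stop("'f' must lie in (0, 1]")
  fM <- f * M
  if (abs(fM - round(fM)) > 1e-9) stop("'f*M' must be an integer")
  fM <- as.integer(round(fM))
  zeta <- matrix(0L, M, K)
  balanced <- FALSE
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (K == 1L) {
    zeta[sample.int(M, fM), 1L] <- 1L
  } else if (K == 3L) {
    # balanced overlap: 7 triple-selective, 10 per environment pair,
    # fM - 27 exclusive per environment
    n_excl <- fM - 27L
    if (n_excl < 0L || M < 3L * n_excl + 3L * 10L + 7L)
      stop("overlap bookkeeping infeasible for requested (M, K, f)")
    perm <- sample.int(M)  # which physical units play which role
    idx <- 0L
    take <- function(n) {
      res <- perm[idx + seq_len(n)]
      idx <<- idx + n
      res
    }
    triple <- take(7L)
    pair12 <- take(10L); pair13 <- take(10L); pair23 <- take(10L)
    ex1 <- take(n_excl); ex2 <- take(n_excl); ex3 <- take(n_excl)
    zeta[c(triple, pair12, pair13, ex1), 1L] <- 1L
    zeta[c(triple, pair12, pair23, ex2), 2L] <- 1L
    zeta[c(triple, pair13, pair23, ex3), 3L] <- 1L
    balanced <- TRUE
  } else {
    for (k in seq_len(K)) zeta[sample.int(M, fM), k] <- 1L
  }
  theta <- matrix(NA_real_, M, K)
  base_angles <- 2 * pi * seq_len(fM) / fM
  for (k in seq_len(K)) {
    sel <- which(zeta[, k] == 1L)
    theta[sel, k] <- base_angles[sample.int(fM)]
  }
  structure(list(zeta = zeta, theta = theta, K = K, M = M, f = f,
                 fM = fM, balanced = balanced, seed = seed),
            class = "environment_map")
}

#' Ring connectivity storing multiple environments
#'
#' Superimposes `K` cosine maps in a Hopfield-like manner:
#' \deqn{J_{\alpha\beta} = \frac{1}{f}\sum_k J_1\,\zeta^k_\alpha \zeta^k_\beta
#'   \cos(\theta^k_\alpha - \theta^k_\beta) - J_0.}
#' Map-specific interactions only occur between populations selective for the
#' same environment; `J0` is uniform feedback inhibition.
#'
#' @param env an [build_selectivity()] environment map.
#' @param J0,J1 effective couplings as in [build_single_env_weights()].
#' @return A `"weight_matrix"` with `kind = "multi"`, carrying the map and
#'   the rank-`2K` factors plus DC term.
#' @export
build_multi_env_weights <- function(env, J0, J1) {
  stopifnot(inherits(env, "environment_map"))
  M <- env$M; K <- env$K
  if (any(env$zeta == 1L & is.na(env$theta)))
    stop("angle undefined for a selective population")
  U <- matrix(0, M, 2L * K)
  V <- matrix(0, M, 2L * K)
  J <- matrix(-J0, M, M)
  for (k in seq_len(K)) {
    zk <- env$zeta[, k]
    ck <- ifelse(zk == 1L, cos(env$theta[, k]), 0)
    sk <- ifelse(zk == 1L, sin(env$theta[, k]), 0)
    U[, 2L * k - 1L] <- (J1 / env$f) * ck
    U[, 2L * k] <- (J1 / env$f) * sk
    V[, 2L * k - 1L] <- ck
    V[, 2L * k] <- sk
    J <- J + (J1 / env$f) * (outer(ck, ck) + outer(sk, sk))
  }
  structure(list(J = J, theta = env$theta, kind = "multi", M = M,
                 J0 = J0, J1 = J1, env = env, U = U, V = V),
            class = "weight_matrix")
}

#' Single-population "weight matrix"
#'
#' Convenience wrapper representing the 1 x 1 coupling `J` of a single
#' homogeneous population in the same container the multi-population
#' simulators consume.
#'
#' @param J effective coupling (J*tau / tau).
#' @return A `"weight_matrix"` with `M = 1`.
#' @export
single_pop_weights <- function(J) {
  structure(list(J = matrix(J, 1, 1), theta = 2 * pi, kind = "single_pop",
                 M = 1L, J0 = 0, J1 = J,
                 U = matrix(J, 1, 1), V = matrix(1, 1, 1)),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> kind = %s, M = %d", x$kind, x$M))
  if (x$kind != "single_pop") cat(sprintf(", J0 = %g, J1 = %g", x$J0, x$J1))
  cat("\n")
  invisible(x)
}

#' @export
print.environment_map <- function(x, ...) {
  cat(sprintf("<environment_map> M = %d, K = %d, f = %g (fM = %d)%s\n",
              x$M, x$K, x$f, x$fM,
              if (x$balanced) ", balanced overlap" else ""))
  invisible(x)
}

# coupling drive c = (1/M) * J %*% D evaluated through the low-rank factors;
# used by R-side checks (the C++ kernels do the same computation)
coupling_drive <- function(W, D) {
  (drop(W$U %*% crossprod(W$V, D)) - W$J0 * sum(D)) / W$M
}

#' Serialize connectivity to delimited text
#'
#' Writes the dense weight matrix (and for environment maps the selectivity
#' and angle matrices) as tab-separated text for inspection, and reads them
#' back.
#'
#' @param x a `weight_matrix` or `environment_map`.
#' @param path file path (for environment maps, a path prefix; two files
#'   `<path>_zeta.tsv` and `<path>_theta.tsv` are written).
#' @return `write_connectivity()` returns `path` invisibly.
#' @export
write_connectivity <- function(x, path) {
  if (inherits(x, "weight_matrix")) {
    utils::write.table(format(x$J, digits = 17), path, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else if (inherits(x, "environment_map")) {
    utils::write.table(x$zeta, paste0(path, "_zeta.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(format(x$theta, digits = 17), paste0(path, "_theta.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
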