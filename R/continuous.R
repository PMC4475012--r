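# Fuzzy-logic continuous approximation of the Boolean dynamics.
#
# Each rule's truth table is rewritten in disjunctive normal form and read
# under Zadeh's fuzzy semantics: conjunction = min, disjunction = max,
# negation = 1 - x. The resulting input function w_i(q) agrees with the
# Boolean rule exactly at every vertex of the unit hypercube. The
# continuous dynamics is
#
#   dq_i/dt = 1 / (1 + exp(-2 b (w_i(q) - w_i^thr))) - alpha_i q_i
#
# a steep sigmoidal activation minus linear relaxation; as b grows the
# activation approaches a Heaviside step at the threshold w_i^thr and the
# stable steady states approach the Boolean fixed points (for alpha = 1).

#' Fuzzify the rules of a logical network
#'
#' @param net A `logic_network`.
#' @return Named list (per node) of fuzzy input functions; each takes a
#'   named numeric vector `q` in `[0,1]^n` and returns the fuzzy activation
#'   `w` in `[0,1]`. At 0/1 vertices the Boolean rule is reproduced exactly.
#' @export
fuzzify <- function(net) {
  out <- lapply(net$nodes, function(nd) {
    r <- net$rules[[nd]]
    k <- length(r$regulators)
    if (k == 0L) {
      const <- as.numeric(r$table[1])
      return(function(q) const)
    }
    ones <- which(r$table == 1L) - 1L
    if (!length(ones)) return(function(q) 0)
    if (length(ones) == 2L^k) return(function(q) 1)
    signs <- t(vapply(ones, function(code) bit_of(code, seq_len(k)),
                      integer(k)))
    regs <- r$regulators
    function(q) {
      v <- q[regs]
      lit <- matrix(rep(v, each = nrow(signs)), nrow = nrow(signs))
      lit[signs == 0L] <- 1 - lit[signs == 0L]
      max(apply(lit, 1L, min))
    }
  })
  names(out) <- net$nodes
  out
}

#' Default parameters of the continuous model
#'
#' @param net A `logic_network`.
#' @param b Input saturation rate (sigmoid gain); dimensionless, > 0.
#' @param alpha Relaxation rate per node (1/time); scalar or named vector.
#' @param w_thr Activation threshold per node in (0,1); scalar or named.
#' @return List of class `continuous_params`.
#' @export
continuous_params <- function(net, b = 10, alpha = 1, w_thr = 0.5) {
  expand <- function(x) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, n_nodes(net)), net$nodes)
    x[net$nodes]
  }
  if (b <= 0) abort2("b must be > 0")
  alpha <- expand(alpha); w_thr <- expand(w_thr)
  if (any(alpha <= 0)) abort2("alpha must be > 0")
  if (any(w_thr <= 0 | w_thr >= 1)) abort2("w_thr must lie in (0,1)")
  structure(list(b = b, alpha = alpha, w_thr = w_thr),
            class = "continuous_params")
}

#' Build the continuous vector field of a logical network
#'
#' @param net A `logic_network`.
#' @param params A `continuous_params` object.
#' @return Function `(q) -> dq` over named vectors in `[0,1]^n`, suitable
#'   for [deSolve::ode()] wrappers and [find_steady_states()].
#' @export
build_ode <- function(net, params = continuous_params(net)) {
  w <- fuzzify(net)
  nodes <- net$nodes
  b <- params$b; alpha <- params$alpha; thr <- params$w_thr
  function(q) {
    q <- stats::setNames(pmin(pmax(as.numeric(q[nodes]), 0), 1), nodes)
    wv <- vapply(nodes, function(nd) w[[nd]](q), numeric(1))
    act <- 1 / (1 + exp(-2 * b * (wv - thr)))
    stats::setNames(act - alpha * q, nodes)
  }
}

#' Locate continuous steady states from given starts
#'
#' Integrates the fuzzy-logic ODE (stiff-capable `lsoda`) from each start
#' until the field residual falls below `tol`; stability is probed by
#' perturbing each steady state and checking re-convergence to it.
#'
#' @param net A `logic_network`.
#' @param starts Matrix of start states (rows; columns named by node), e.g.
#'   Boolean attractor states. Defaults to all Boolean fixed points.
#' @param params `continuous_params`.
#' @param tol Residual (max |dq/dt|) defining a steady state.
#' @param t_max,n_rounds Integration horizon per round and maximum rounds.
#' @param perturb_size Perturbation magnitude for the stability probe.
#' @param re_tol Maximum distance from the original steady state for the
#'   perturbed trajectory to count as re-converged.
#' @return Data frame: one row per start with steady-state coordinates,
#'   `residual`, `converged`, `stable`, plus the rounded 0/1 pattern as a
#'   `pattern` string.
#' @export
find_steady_states <- function(net, starts = NULL,
                               params = continuous_params(net),
                               tol = 1e-6, t_max = 50, n_rounds = 8,
                               perturb_size = 0.05, re_tol = 0.02) {
  field <- build_ode(net, params)
  deriv <- function(t, q, p) list(as.numeric(field(q)))
  if (is.null(starts)) {
    at <- enumerate_attractors(net)
    fps <- Filter(function(a) a$period == 1L, at$attractors)
    starts <- do.call(rbind, lapply(fps, function(a) a$states))
  }
  starts <- as.matrix(starts)[, net$nodes, drop = FALSE]
  run_to_ss <- function(q0) {
    q <- stats::setNames(as.numeric(q0), net$nodes)
    for (i in seq_len(n_rounds)) {
      res <- deSolve::ode(y = q, times = c(0, t_max), func = deriv,
                          parms = NULL, method = "lsoda",
                          atol = 1e-8, rtol = 1e-8)
      q <- stats::setNames(as.numeric(res[nrow(res), -1]), net$nodes)
      if (max(abs(field(q))) < tol) break
    }
    q
  }
  rows <- lapply(seq_len(nrow(starts)), function(i) {
    ss <- run_to_ss(starts[i, ])
    resid <- max(abs(field(ss)))
    converged <- resid < tol
    stable <- NA
    if (converged) {
      up <- run_to_ss(pmin(ss + perturb_size, 1))
      dn <- run_to_ss(pmax(ss - perturb_size, 0))
      stable <- max(abs(up - ss)) < re_tol && max(abs(dn - ss)) < re_tol
    }
    c(as.list(ss), list(residual = resid, converged = converged,
                        stable = stable,
                        pattern = paste(round(ss), collapse = "")))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, optional = TRUE)))
}
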