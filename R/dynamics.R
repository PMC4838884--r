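#' Hill parameter set
#'
#' Parameters of the normalized Hill rate law: the coefficient `n` sets the
#' steepness of each regulatory interaction and the threshold `a` the input
#' level at which the interaction is half-active. Parameters may be global
#' (one pair for every edge) or per-edge vectors aligned with the network's
#' edge order; per-edge values stored on the network's edges themselves
#' override the global default when the parameter set is expanded.
#'
#' @param n Hill coefficient(s), all >= 1. Default 3.
#' @param a threshold(s) in (0,1) on the normalized activity scale.
#'   Default 0.5, the natural midpoint of the `[0,1]` scale.
#' @param mode `"global"` (scalars recycled over edges) or `"per_edge"`
#'   (vectors, one entry per edge)
#' @param rate_law multi-input composition rule: `"hill_summed"` (default;
#'   activator inputs summed inside one saturating term, inhibitor inputs
#'   summed inside one repressive term) or `"hill_product"` (independent
#'   per-edge terms, activators combined as 1 - prod(1 - term)); the
#'   alternative form is provided for sensitivity checks.
#' @return an object of class `endo_params`
#' @export
hill_params <- function(n = 3, a = 0.5, mode = c("global", "per_edge"),
                        rate_law = c("hill_summed", "hill_product")) {
  mode <- match.arg(mode)
  rate_law <- match.arg(rate_law)
  if (any(n < 1)) stop("all Hill coefficients must be >= 1")
  if (any(a <= 0 | a >= 1)) stop("all thresholds must lie in (0,1)")
  if (mode == "global" && (length(n) != 1 || length(a) != 1))
    stop("global mode takes scalar n and a")
  structure(list(n = n, a = a, mode = mode, rate_law = rate_law),
            class = "endo_params")
}

#' @export
print.endo_params <- function(x, ...) {
  cat("Hill parameters (", x$mode, ", ", x$rate_law, "): ", sep = "")
  if (x$mode == "global") cat("n =", x$n, " a =", x$a, "\n")
  else cat("per-edge, n in [", min(x$n), ",", max(x$n), "], a in [",
           min(x$a), ",", max(x$a), "]\n")
  invisible(x)
}

# Expand a parameter set over a network's edges, honouring per-edge values
# stored on the edges themselves. Returns vectors n, a of length n_edges.
expand_params <- function(net, params) {
  ne <- nrow(net$edges)
  if (params$mode == "per_edge") {
    if (length(params$n) != ne || length(params$a) != ne)
      stop("per-edge parameter vectors must align with the ", ne, " network edges")
    n <- params$n; a <- params$a
  } else {
    n <- rep(params$n, ne); a <- rep(params$a, ne)
  }
  if (ne > 0) {
    n <- ifelse(is.na(net$edges$n), n, net$edges$n)
    a <- ifelse(is.na(net$edges$a), a, net$edges$a)
  }
  list(n = n, a = a)
}

# Compile a network + parameters into fast per-node index structures.
compile_net <- function(net, params) {
  N <- n_nodes(net)
  p <- expand_params(net, params)
  tgt <- match(net$edges$target, net$nodes$name)
  src <- match(net$edges$source, net$nodes$name)
  act <- net$edges$sign == "activation"
  comp <- vector("list", N)
  for (i in seq_len(N)) {
    ia <- which(tgt == i & act)
    ii <- which(tgt == i & !act)
    comp[[i]] <- list(
      act_src = src[ia], act_n = p$n[ia], act_a = p$a[ia],
      inh_src = src[ii], inh_n = p$n[ii], inh_a = p$a[ii]
    )
  }
  list(N = N, comp = comp, rate_law = params$rate_law,
       names = net$nodes$name)
}

#' Hill activation term
#'
#' Saturating activation contribution `x^n / (a^n + x^n)`: zero at zero
#' input, one half at the threshold `x = a`, approaching 1 for strong input.
#'
#' @param x input activity in `[0,1]`
#' @param n Hill coefficient >= 1
#' @param a threshold in (0,1)
#' @return contribution in `[0,1]`, non-decreasing in `x`
#' @export
hill_activation <- function(x, n = 3, a = 0.5) {
  if (any(n < 1) || any(a <= 0 | a >= 1)) stop("parameters out of range")
  if (any(x < 0 | x > 1)) stop("input activity outside [0,1]")
  u <- (x / a)^n
  u / (1 + u)
}

#' Hill inhibition term
#'
#' Repressive contribution `a^n / (a^n + x^n)`: one at zero input (an
#' absent inhibitor imposes no repression), one half at `x = a`, approaching
#' 0 for strong input. Complementary to [hill_activation()]:
#' the two sum to 1 at matched `(x, n, a)`.
#'
#' @inheritParams hill_activation
#' @return contribution in `[0,1]`, non-increasing in `x`
#' @export
hill_inhibition <- function(x, n = 3, a = 0.5) {
  if (any(n < 1) || any(a <= 0 | a >= 1)) stop("parameters out of range")
  if (any(x < 0 | x > 1)) stop("input activity outside [0,1]")
  u <- (x / a)^n
  1 / (1 + u)
}

# generation rate for one compiled node; x is the clipped state vector
node_rate_compiled <- function(cn, rate_law, x) {
  has_act <- length(cn$act_src) > 0
  has_inh <- length(cn$inh_src) > 0
  if (!has_act && !has_inh) return(0)
  if (rate_law == "hill_summed") {
    A <- if (has_act) {
      U <- sum((x[cn$act_src] / cn$act_a)^cn$act_n)
      U / (1 + U)
    } else 1
    B <- if (has_inh) {
      V <- sum((x[cn$inh_src] / cn$inh_a)^cn$inh_n)
      1 / (1 + V)
    } else 1
  } else {
    A <- if (has_act) {
      u <- (x[cn$act_src] / cn$act_a)^cn$act_n
      1 - prod(1 / (1 + u))
    } else 1
    B <- if (has_inh) {
      v <- (x[cn$inh_src] / cn$inh_a)^cn$inh_n
      prod(1 / (1 + v))
    } else 1
  }
  A * B
}

#' Generation rate of a single node
#'
#' Evaluates the Hill-type generation rate `f_i` for one node given the full
#' network state: activator inputs are pooled into a saturating term,
#' inhibitor inputs into a repressive term, and the two multiply. A node
#' with no incoming edges has generation rate 0 (pure decay); a node with
#' only inhibitors has activation part 1 (full production when unrepressed).
#'
#' @param net an `endo_network`
#' @param params an `endo_params`
#' @param node node name
#' @param state numeric state vector in `[0,1]^N`, node order
#' @return generation rate in `[0,1]`
#' @export
node_rate <- function(net, params, node, state) {
  i <- node_index(net, node)
  cm <- compile_net(net, params)
  check_state(state, cm$N)
  node_rate_compiled(cm$comp[[i]], cm$rate_law, clip01(state))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

check_state <- function(state, N) {
  if (length(state) != N)
    stop("state dimension ", length(state), " does not match node count ", N)
  invisible()
}

rhs_compiled <- function(cm, x) {
  xe <- clip01(x)
  f <- vapply(cm$comp, node_rate_compiled, numeric(1),
              rate_law = cm$rate_law, x = xe)
  f - x
}

#' Right-hand side of the network ODE
#'
#' The dynamics of each node are `dx_i/dt = f_i(x) - x_i`: Hill-type
#' generation minus first-order self-degradation, in units of the
#' degradation timescale. Because `f_i` takes values in `[0,1]`, the unit
#' box `[0,1]^N` is forward invariant.
#'
#' @inheritParams node_rate
#' @param state numeric state vector
#' @return derivative vector, each component in `[-1, 1]`
#' @export
network_rhs <- function(net, params, state) {
  cm <- compile_net(net, params)
  check_state(state, cm$N)
  rhs_compiled(cm, state)
}

jacobian_compiled <- function(cm, x) {
  N <- cm$N
  xe <- clip01(x)
  J <- matrix(0, N, N)
  for (i in seq_len(N)) {
    cn <- cm$comp[[i]]
    has_act <- length(cn$act_src) > 0
    has_inh <- length(cn$inh_src) > 0
    if (!has_act && !has_inh) next
    if (cm$rate_law == "hill_summed") {
      u <- if (has_act) (xe[cn$act_src] / cn$act_a)^cn$act_n else numeric()
      v <- if (has_inh) (xe[cn$inh_src] / cn$inh_a)^cn$inh_n else numeric()
      U <- sum(u); V <- sum(v)
      A <- if (has_act) U / (1 + U) else 1
      B <- if (has_inh) 1 / (1 + V) else 1
      if (has_act) {
        du <- cn$act_n * xe[cn$act_src]^(cn$act_n - 1) / cn$act_a^cn$act_n
        dA <- du / (1 + U)^2
        for (k in seq_along(cn$act_src))
          J[i, cn$act_src[k]] <- J[i, cn$act_src[k]] + dA[k] * B
      }
      if (has_inh) {
        dv <- cn$inh_n * xe[cn$inh_src]^(cn$inh_n - 1) / cn$inh_a^cn$inh_n
        dB <- -dv / (1 + V)^2
        for (k in seq_along(cn$inh_src))
          J[i, cn$inh_src[k]] <- J[i, cn$inh_src[k]] + A * dB[k]
      }
    } else {
      u <- if (has_act) (xe[cn$act_src] / cn$act_a)^cn$act_n else numeric()
      v <- if (has_inh) (xe[cn$inh_src] / cn$inh_a)^cn$inh_n else numeric()
      pa <- 1 / (1 + u); pb <- 1 / (1 + v)
      A <- if (has_act) 1 - prod(pa) else 1
      B <- if (has_inh) prod(pb) else 1
      if (has_act) {
        du <- cn$act_n * xe[cn$act_src]^(cn$act_n - 1) / cn$act_a^cn$act_n
        for (k in seq_along(cn$act_src)) {
          dA <- prod(pa[-k]) * du[k] / (1 + u[k])^2
          J[i, cn$act_src[k]] <- J[i, cn$act_src[k]] + dA * B
        }
      }
      if (has_inh) {
        dv <- cn$inh_n * xe[cn$inh_src]^(cn$inh_n - 1) / cn$inh_a^cn$inh_n
        for (k in seq_along(cn$inh_src)) {
          dB <- -prod(pb[-k]) * dv[k] / (1 + v[k])^2
          J[i, cn$inh_src[k]] <- J[i, cn$inh_src[k]] + A * dB
        }
      }
    }
  }
  diag(J) <- diag(J) - 1
  J
}

#' Jacobian of the network ODE
#'
#' Analytic matrix of partial derivatives of [network_rhs()] with respect to
#' the state; the diagonal carries the `-1` degradation term and the
#' off-diagonal sparsity pattern follows the edge adjacency.
#'
#' @inheritParams network_rhs
#' @return an `N x N` numeric matrix
#' @export
network_jacobian <- function(net, params, state) {
  cm <- compile_net(net, params)
  check_state(state, cm$N)
  jacobian_compiled(cm, state)
}

#' Integrate the network ODE
#'
#' Solves the Hill-type dynamics from a given initial state with `lsoda`
#' (adaptive, stiff-capable; relative tolerance 1e-8, absolute 1e-10 —
#' steep Hill nonlinearities at large `n` make the system locally stiff).
#' Selected nodes may be clamped: their coordinates are set to the clamp
#' value and their derivative held at zero for the whole integration,
#' modelling a sustained intervention on that node.
#'
#' @inheritParams network_rhs
#' @param x0 initial state in `[0,1]^N`
#' @param horizon integration time (in degradation-time units)
#' @param clamps optional named numeric vector/list, `node = value` with
#'   values in `[0,1]`
#' @param n_out number of output time points (default 101)
#' @return an `endo_trajectory`: list with `times` and a `states` matrix
#'   (rows = time points, columns = nodes)
#' @export
simulate_network <- function(net, params = hill_params(), x0, horizon,
                             clamps = NULL, n_out = 101) {
  cm <- compile_net(net, params)
  check_state(x0, cm$N)
  if (horizon <= 0) stop("horizon must be positive")
  cl_idx <- integer(); cl_val <- numeric()
  if (!is.null(clamps) && length(clamps) > 0) {
    cl_val <- unlist(clamps)
    if (any(cl_val < 0 | cl_val > 1)) stop("clamp values must lie in [0,1]")
    cl_idx <- node_index(net, names(cl_val))
    x0[cl_idx] <- cl_val
  }
  dfun <- function(t, y, parms) {
    dy <- rhs_compiled(cm, y)
    if (length(cl_idx)) dy[cl_idx] <- 0
    list(dy)
  }
  times <- seq(0, horizon, length.out = max(2, n_out))
  sol <- deSolve::lsoda(y = x0, times = times, func = dfun, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failure; last valid state: ",
         paste(signif(sol[nrow(sol), -1], 6), collapse = ", "))
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- cm$names
  structure(list(times = sol[, 1], states = states, clamps = clamps),
            class = "endo_trajectory")
}

#' @export
print.endo_trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$times), "time points over [0,",
      max(x$times), "],", ncol(x$states), "nodes\n")
  cat("final state:", paste(signif(x$states[nrow(x$states), ], 4),
                            collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.endo_trajectory <- function(x, nodes = NULL, ...) {
  S <- x$states
  if (!is.null(nodes)) S <- S[, nodes, drop = FALSE]
  graphics::matplot(x$times, S, type = "l", lty = 1, lwd = 1.5,
                    xlab = "time (degradation units)", ylab = "activity",
                    ylim = c(0, 1), ...)
  graphics::legend("topright", legend = colnames(S), lty = 1,
                   col = seq_len(ncol(S)), cex = 0.7, bty = "n")
  invisible(x)
}

# Integrate until max-norm residual < tol or total time exceeds horizon.
# Works on a compiled model; used by the fixed-point and perturbation code.
relax_compiled <- function(cm, x0, tol = 1e-6, horizon = 100, chunk = 10,
                           cl_idx = integer(), cl_val = numeric()) {
  x <- x0
  if (length(cl_idx)) x[cl_idx] <- cl_val
  dfun <- function(t, y, parms) {
    dy <- rhs_compiled(cm, y)
    if (length(cl_idx)) dy[cl_idx] <- 0
    list(dy)
  }
  t_done <- 0
  repeat {
    r <- rhs_compiled(cm, x)
    if (length(cl_idx)) r[cl_idx] <- 0
    if (max(abs(r)) < tol) return(list(state = x, converged = TRUE, time = t_done))
    if (t_done >= horizon) return(list(state = x, converged = FALSE, time = t_done))
    sol <- deSolve::lsoda(y = x, times = c(0, chunk), func = dfun, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    x <- unname(sol[nrow(sol), -1])
    t_done <- t_done + chunk
  }
}
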