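#' Fit the attractor landscape of a signed interaction network
#'
#' The central entry point of the package: compiles a network into its
#' Hill-type dynamics, enumerates and classifies its fixed points
#' (attractors, saddles, other unstable points), and links them into the
#' saddle-mediated transition graph. The returned object is the "fitted
#' model" of the network's cell-fate landscape and supports the usual
#' methods: `print`, `summary`, `coef` (attractor state matrix), `predict`
#' (basin assignment of new states), `simulate` (trajectories), `plot`
#' (transition graph) and `residuals` (rhs norms at the fixed points).
#'
#' @param net an `endo_network`
#' @param params an `endo_params` (default global n = 3, a = 0.5)
#' @param n_starts random initial conditions for attractor sampling
#' @param n_seeds random Newton seeds for saddle/unstable search
#' @param seed RNG seed; the fit is reproducible bit-for-bit given the seed
#' @param eps escape displacement used for the transition graph
#' @param ... passed on to [enumerate_fixed_points()]
#' @return an object of class `attractor_landscape`
#' @examples
#' net <- make_toggle_switch()
#' fit <- attractor_landscape(net, n_starts = 200, seed = 1)
#' fit
#' coef(fit)
#' @export
attractor_landscape <- function(net, params = hill_params(), n_starts = 1000,
                                n_seeds = 300, seed = 1, eps = 1e-3, ...) {
  fps <- enumerate_fixed_points(net, params, n_starts = n_starts,
                                n_seeds = n_seeds, seed = seed, ...)
  graph <- build_transition_graph(net, params, fps, eps = eps)
  structure(list(network = net, params = params, fixed_points = fps,
                 attractors = fps$attractors, graph = graph, seed = seed,
                 call = match.call()),
            class = "attractor_landscape")
}

#' @export
print.attractor_landscape <- function(x, ...) {
  cat("Attractor landscape of a network with", n_nodes(x$network), "nodes\n")
  cs <- x$fixed_points$census
  cat(sprintf("  %d attractor(s), %d saddle(s), %d other unstable, %d degenerate\n",
              cs[["attractor"]], cs[["saddle"]], cs[["unstable"]],
              cs[["degenerate"]]))
  cat(" ", nrow(x$graph$adjacency), "saddle-mediated attractor adjacencies\n")
  invisible(x)
}

#' @export
summary.attractor_landscape <- function(object, ...) {
  print(object)
  cat("\nAttractors (basin tallies over", object$attractors$n_starts,
      "random starts):\n")
  print(object$attractors)
  cat("\nDiscretized profiles:\n")
  pt <- profile_table(object$attractors)
  print(ifelse(pt == "active", 1, 0))
  invisible(object)
}

#' @export
coef.attractor_landscape <- function(object, ...) {
  attractor_states(object$attractors)
}

#' Assign states to basins of attraction
#'
#' Relaxes each supplied state under the fitted dynamics and reports the
#' id of the attractor reached (or `NA` for non-convergence / an unknown
#' endpoint).
#'
#' @param object an `attractor_landscape`
#' @param newdata numeric state vector or matrix (rows = states)
#' @param ... unused
#' @return character vector of attractor ids
#' @export
predict.attractor_landscape <- function(object, newdata, ...) {
  cm <- compile_net(object$network, object$params)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    r <- relax_compiled(cm, newdata[i, ], tol = 1e-6, horizon = 200)
    out[i] <- if (r$converged)
      match_attractor(object$attractors, r$state) else NA_character_
  }
  out
}

#' Simulate trajectories from a fitted landscape
#'
#' @param object an `attractor_landscape`
#' @param nsim number of trajectories
#' @param seed RNG seed for the random initial conditions
#' @param x0 optional fixed initial state (overrides random starts)
#' @param horizon integration time (default 50)
#' @param ... passed to [simulate_network()]
#' @return list of `endo_trajectory` objects (a single trajectory when
#'   `nsim = 1`)
#' @export
simulate.attractor_landscape <- function(object, nsim = 1, seed = NULL,
                                         x0 = NULL, horizon = 50, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- n_nodes(object$network)
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    start <- if (is.null(x0)) stats::runif(N) else x0
    out[[k]] <- simulate_network(object$network, object$params, start,
                                 horizon = horizon, ...)
  }
  if (nsim == 1) out[[1]] else out
}

#' @export
residuals.attractor_landscape <- function(object, ...) {
  vapply(object$fixed_points$points, function(f) f$residual, numeric(1))
}

#' @export
plot.attractor_landscape <- function(x, ...) {
  plot(x$graph, ...)
}
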