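#' Classify a fixed point by its Jacobian spectrum
#'
#' The index of a fixed point is the number of eigenvalues with positive
#' real part: index 0 is an attractor (a stable phenotype), index 1 a
#' saddle (the "pass" between two basins), index >= 2 an unstable point.
#' Eigenvalues whose real part is within `degeneracy_tol` of zero cannot be
#' classified reliably and flag the point as degenerate.
#'
#' @param eigenvalues complex spectrum of the Jacobian at the fixed point
#' @param degeneracy_tol tolerance on `|Re(lambda)|` below which the point
#'   is flagged degenerate (default 1e-6)
#' @return list with `class` (one of `"attractor"`, `"saddle"`,
#'   `"unstable"`, `"degenerate"`) and `index`
#' @export
classify_fixed_point <- function(eigenvalues, degeneracy_tol = 1e-6) {
  re <- Re(eigenvalues)
  if (any(abs(re) < degeneracy_tol))
    return(list(class = "degenerate", index = sum(re > 0)))
  idx <- sum(re > 0)
  cls <- if (idx == 0) "attractor" else if (idx == 1) "saddle" else "unstable"
  list(class = cls, index = idx)
}

#' Refine a fixed-point guess by damped Newton iteration
#'
#' Solves `rhs(x) = 0` from `guess` by Newton steps with backtracking line
#' search on the residual norm, every iterate projected back into the unit
#' box. On success the Jacobian spectrum and stability class are attached.
#'
#' @inheritParams network_rhs
#' @param guess starting state in `[0,1]^N`
#' @param tol residual (max-norm) tolerance (default 1e-9)
#' @param max_iter iteration cap
#' @param degeneracy_tol passed to [classify_fixed_point()]
#' @return an `endo_fp`: list with `state`, `residual`, `eigenvalues`,
#'   `stability_class`, `index`
#' @export
refine_fixed_point <- function(net, params = hill_params(), guess,
                               tol = 1e-9, max_iter = 100,
                               degeneracy_tol = 1e-6) {
  cm <- compile_net(net, params)
  check_state(guess, cm$N)
  fp <- refine_compiled(cm, guess, tol, max_iter)
  if (!fp$converged)
    stop("Newton refinement did not converge (best residual ",
         signif(fp$residual, 3), "); best iterate: ",
         paste(signif(fp$state, 6), collapse = ", "))
  finish_fp(cm, fp$state, degeneracy_tol)
}

refine_compiled <- function(cm, guess, tol = 1e-9, max_iter = 100) {
  x <- clip01(guess)
  F <- rhs_compiled(cm, x)
  best <- list(state = x, residual = max(abs(F)))
  for (it in seq_len(max_iter)) {
    if (max(abs(F)) < tol)
      return(list(state = x, residual = max(abs(F)), converged = TRUE))
    J <- jacobian_compiled(cm, x)
    step <- tryCatch(solve(J, -F), error = function(e) NULL)
    if (is.null(step))
      return(list(state = best$state, residual = best$residual, converged = FALSE))
    lam <- 1
    improved <- FALSE
    for (bt in 1:30) {
      xn <- clip01(x + lam * step)
      Fn <- rhs_compiled(cm, xn)
      if (max(abs(Fn)) < max(abs(F))) { improved <- TRUE; break }
      lam <- lam / 2
    }
    if (!improved)
      return(list(state = best$state, residual = best$residual, converged = FALSE))
    x <- xn; F <- Fn
    if (max(abs(F)) < best$residual) best <- list(state = x, residual = max(abs(F)))
  }
  if (max(abs(F)) < tol)
    return(list(state = x, residual = max(abs(F)), converged = TRUE))
  list(state = best$state, residual = best$residual, converged = FALSE)
}

finish_fp <- function(cm, state, degeneracy_tol = 1e-6) {
  ev <- eigen(jacobian_compiled(cm, state), only.values = TRUE)$values
  cl <- classify_fixed_point(ev, degeneracy_tol)
  structure(list(state = state, residual = max(abs(rhs_compiled(cm, state))),
                 eigenvalues = ev, stability_class = cl$class,
                 index = cl$index),
            class = "endo_fp")
}

#' @export
print.endo_fp <- function(x, ...) {
  cat(sprintf("Fixed point (%s, index %d, residual %.2e)\n",
              x$stability_class, x$index, x$residual))
  cat("  state:", paste(signif(x$state, 4), collapse = " "), "\n")
  invisible(x)
}

#' Greedy deduplication of states
#'
#' Clusters states in input order by the max-norm: a state joins the first
#' representative within `tol`, otherwise it opens a new cluster. The
#' output order is deterministic (order of first appearance).
#'
#' @param states list of numeric state vectors, or a matrix (rows = states)
#' @param tol max-norm radius (default 1e-3)
#' @return list with `representatives` (matrix, one row each) and
#'   `membership` (integer vector mapping each input state to its
#'   representative)
#' @export
dedupe_states <- function(states, tol = 1e-3) {
  if (tol <= 0) stop("tol must be positive")
  if (is.matrix(states)) states <- lapply(seq_len(nrow(states)), function(i) states[i, ])
  reps <- list()
  membership <- integer(length(states))
  for (i in seq_along(states)) {
    hit <- 0L
    for (j in seq_along(reps)) {
      if (max(abs(states[[i]] - reps[[j]])) <= tol) { hit <- j; break }
    }
    if (hit == 0L) { reps[[length(reps) + 1]] <- states[[i]]; hit <- length(reps) }
    membership[i] <- hit
  }
  list(representatives = do.call(rbind, reps), membership = membership)
}

#' Sample attractors from random initial conditions
#'
#' Integrates the dynamics from `n_starts` uniform random states in the
#' unit box until the residual drops below `tol` (or `horizon` is reached),
#' refines each converged endpoint by Newton iteration, deduplicates, and
#' keeps the stable points. Basin counts tally how many random starts
#' reached each attractor — a sampled, not certified, view of basin sizes.
#'
#' @inheritParams network_rhs
#' @param n_starts number of random initial conditions
#' @param seed RNG seed; results are reproducible bit-for-bit given the seed
#' @param horizon relaxation time cap (degradation-time units, default 100)
#' @param tol convergence tolerance on the max-norm of the rhs (default 1e-6)
#' @param dedup_tol max-norm radius for identifying attractors (default 1e-3)
#' @return an `endo_attractors`: list with `points` (list of `endo_fp`),
#'   `basin_counts`, `n_starts`, `n_nonconverged`, `seed`
#' @export
sample_attractors <- function(net, params = hill_params(), n_starts = 1000,
                              seed = 1, horizon = 100, tol = 1e-6,
                              dedup_tol = 1e-3) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  cm <- compile_net(net, params)
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * cm$N), nrow = n_starts)
  pts <- list(); nonconv <- 0L
  for (k in seq_len(n_starts)) {
    r <- relax_compiled(cm, starts[k, ], tol = tol, horizon = horizon)
    if (!r$converged) { nonconv <- nonconv + 1L; next }
    ref <- refine_compiled(cm, r$state)
    pts[[length(pts) + 1]] <- if (ref$converged) ref$state else r$state
  }
  if (length(pts) == 0)
    return(structure(list(points = list(), basin_counts = integer(),
                          n_starts = n_starts, n_nonconverged = nonconv,
                          seed = seed, dedup_tol = dedup_tol,
                          net = net, params = params),
                     class = "endo_attractors"))
  dd <- dedupe_states(pts, tol = dedup_tol)
  counts <- tabulate(dd$membership, nbins = nrow(dd$representatives))
  fps <- lapply(seq_len(nrow(dd$representatives)), function(j)
    finish_fp(cm, dd$representatives[j, ]))
  stable <- vapply(fps, function(f) f$stability_class == "attractor", logical(1))
  fps <- fps[stable]; counts <- counts[stable]
  # stable presentation order: decreasing basin size, then state lexicographic
  keys <- vapply(fps, function(f) paste(round(f$state, 6), collapse = ","),
                 character(1))
  ord <- order(-counts, keys)
  fps <- fps[ord]; counts <- counts[ord]
  names(fps) <- paste0("A", seq_along(fps))
  structure(list(points = fps, basin_counts = stats::setNames(counts, names(fps)),
                 n_starts = n_starts, n_nonconverged = nonconv, seed = seed,
                 dedup_tol = dedup_tol, net = net, params = params),
            class = "endo_attractors")
}

#' @export
print.endo_attractors <- function(x, ...) {
  cat("Attractor set:", length(x$points), "attractor(s) from", x$n_starts,
      "random starts (seed", x$seed, ")\n")
  for (id in names(x$points)) {
    fp <- x$points[[id]]
    cat(sprintf("  %s  basin %d/%d  state [%s]\n", id, x$basin_counts[[id]],
                x$n_starts, paste(signif(fp$state, 3), collapse = " ")))
  }
  if (x$n_nonconverged > 0)
    cat("  (", x$n_nonconverged, "start(s) did not converge )\n")
  invisible(x)
}

#' Attractor state matrix
#' @param x an `endo_attractors`
#' @return numeric matrix, one row per attractor, columns = nodes
#' @export
attractor_states <- function(x) {
  if (length(x$points) == 0) return(matrix(numeric(), 0, 0))
  m <- t(vapply(x$points, function(f) f$state, numeric(length(x$points[[1]]$state))))
  colnames(m) <- x$net$nodes$name
  m
}

#' Enumerate fixed points of all stability classes
#'
#' Combines three search strategies: (i) attractors found by relaxation
#' from random starts ([sample_attractors()]), (ii) Newton refinement from
#' `n_seeds` fresh random interior seeds, and (iii) Newton refinement from
#' midpoints of segments joining each attractor pair — saddles mediating
#' transitions tend to lie between the basins they separate. The union is
#' deduplicated and classified.
#'
#' @inheritParams sample_attractors
#' @param n_seeds random Newton seeds (default 500)
#' @return an `endo_fps`: list with `points` (list of `endo_fp`, ids `F1..`),
#'   `attractors` (the underlying `endo_attractors`), and `census`
#'   (counts per stability class)
#' @export
enumerate_fixed_points <- function(net, params = hill_params(),
                                   n_starts = 1000, n_seeds = 500, seed = 1,
                                   horizon = 100, tol = 1e-6,
                                   dedup_tol = 1e-3) {
  cm <- compile_net(net, params)
  att <- sample_attractors(net, params, n_starts = n_starts, seed = seed,
                           horizon = horizon, tol = tol, dedup_tol = dedup_tol)
  cand <- lapply(att$points, function(f) f$state)
  set.seed(seed + 1L)
  seeds <- matrix(stats::runif(n_seeds * cm$N), nrow = n_seeds)
  for (k in seq_len(n_seeds)) {
    ref <- refine_compiled(cm, seeds[k, ])
    if (ref$converged) cand[[length(cand) + 1]] <- ref$state
  }
  A <- length(att$points)
  if (A >= 2) {
    for (i in seq_len(A - 1)) for (j in (i + 1):A) {
      mid <- (att$points[[i]]$state + att$points[[j]]$state) / 2
      ref <- refine_compiled(cm, mid)
      if (ref$converged) cand[[length(cand) + 1]] <- ref$state
    }
  }
  dd <- dedupe_states(cand, tol = dedup_tol)
  fps <- lapply(seq_len(nrow(dd$representatives)), function(j)
    finish_fp(cm, dd$representatives[j, ]))
  cls <- vapply(fps, function(f) f$stability_class, character(1))
  ord <- order(match(cls, c("attractor", "saddle", "unstable", "degenerate")),
               vapply(fps, function(f) paste(round(f$state, 6), collapse = ","),
                      character(1)))
  fps <- fps[ord]
  names(fps) <- paste0("F", seq_along(fps))
  census <- table(factor(vapply(fps, function(f) f$stability_class, character(1)),
                         levels = c("attractor", "saddle", "unstable", "degenerate")))
  structure(list(points = fps, attractors = att, census = census,
                 net = net, params = params, dedup_tol = dedup_tol),
            class = "endo_fps")
}

#' @export
print.endo_fps <- function(x, ...) {
  cat("Fixed-point census:",
      sprintf("%d attractor(s), %d saddle(s), %d unstable, %d degenerate\n",
              x$census[["attractor"]], x$census[["saddle"]],
              x$census[["unstable"]], x$census[["degenerate"]]))
  for (id in names(x$points)) {
    fp <- x$points[[id]]
    cat(sprintf("  %s  %-9s index %d  [%s]\n", id, fp$stability_class, fp$index,
                paste(signif(fp$state, 3), collapse = " ")))
  }
  invisible(x)
}
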