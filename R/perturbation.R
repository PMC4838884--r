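#' Define a clamp-and-release perturbation protocol
#'
#' A protocol is an ordered list of stages. During each stage the listed
#' nodes are clamped (held at fixed values, modelling sustained
#' up-/down-regulation, e.g. by a drug); at stage end the clamps release
#' and the network relaxes freely to an attractor before the next stage
#' begins.
#'
#' @param ... stages, each a list with elements `clamps` (named vector,
#'   `node = value` in `[0,1]`) and `duration` (time units, > 0; default 50)
#' @return an `endo_protocol`
#' @examples
#' perturbation_protocol(
#'   list(clamps = c(B = 1), duration = 50)
#' )
#' @export
perturbation_protocol <- function(...) {
  stages <- list(...)
  if (length(stages) == 1 && is.list(stages[[1]]) &&
      !("clamps" %in% names(stages[[1]]))) stages <- stages[[1]]
  stages <- lapply(stages, function(st) {
    if (is.null(st$duration)) st$duration <- 50
    if (st$duration <= 0) stop("stage durations must be positive")
    if (length(st$clamps) > 0 && any(unlist(st$clamps) < 0 | unlist(st$clamps) > 1))
      stop("clamp values must lie in [0,1]")
    st
  })
  structure(list(stages = stages), class = "endo_protocol")
}

#' @export
print.endo_protocol <- function(x, ...) {
  cat("Perturbation protocol with", length(x$stages), "stage(s):\n")
  for (i in seq_along(x$stages)) {
    st <- x$stages[[i]]
    cl <- if (length(st$clamps)) paste(names(st$clamps), "=",
                                       unlist(st$clamps), collapse = ", ") else "(none)"
    cat(sprintf("  stage %d: clamp %s for %g time units\n", i, cl, st$duration))
  }
  invisible(x)
}

match_attractor <- function(attractors, state, tol = NULL) {
  if (is.null(tol)) tol <- attractors$dedup_tol
  A <- attractor_states(attractors)
  if (nrow(A) == 0) return(NA_character_)
  dist <- apply(abs(sweep(A, 2, state)), 1, max)
  j <- which.min(dist)
  if (dist[j] <= tol) rownames(A)[j] else NA_character_
}

#' Run a perturbation protocol from an attractor
#'
#' Executes the stages of a protocol: for each stage the clamped
#' coordinates are set to their clamp values and held for the stage
#' duration, then released, and the network relaxes to convergence; the
#' attractor reached is identified before the next stage. The result
#' records the full trajectory and the attractors visited between stages.
#'
#' @inheritParams network_rhs
#' @param start starting state, usually (near) a known attractor
#' @param protocol an `endo_protocol` (or list of stages)
#' @param attractors an `endo_attractors` used to identify visited states
#' @param relax_horizon post-release relaxation cap (default 200 time units)
#' @return an `endo_switch`: list with `start_attractor`, `end_attractor`
#'   (id or `"none"`), `intermediate_attractors`, `trajectory`,
#'   `final_state`
#' @export
apply_protocol <- function(net, params = hill_params(), start, protocol,
                           attractors, relax_horizon = 200) {
  if (!inherits(protocol, "endo_protocol"))
    protocol <- perturbation_protocol(protocol)
  cm <- compile_net(net, params)
  check_state(start, cm$N)
  start_id <- match_attractor(attractors, start)
  x <- start
  t0 <- 0
  times <- numeric(); states <- list()
  intermediates <- character()
  ok <- TRUE
  for (st in protocol$stages) {
    cl_val <- unlist(st$clamps)
    cl_idx <- if (length(cl_val)) node_index(net, names(cl_val)) else integer()
    # clamped phase
    traj <- simulate_network(net, params, x, horizon = st$duration,
                             clamps = st$clamps, n_out = 51)
    times <- c(times, t0 + traj$times)
    states[[length(states) + 1]] <- traj$states
    t0 <- t0 + st$duration
    x <- traj$states[nrow(traj$states), ]
    # release and relax
    r <- relax_compiled(cm, x, tol = 1e-6, horizon = relax_horizon)
    x <- r$state
    times <- c(times, t0 + r$time)
    states[[length(states) + 1]] <- matrix(x, nrow = 1,
                                           dimnames = list(NULL, cm$names))
    t0 <- t0 + r$time
    if (!r$converged) { ok <- FALSE; break }
    intermediates <- c(intermediates, match_attractor(attractors, x))
  }
  end_id <- if (!ok) "none"
    else if (length(intermediates) == 0) {
      if (is.na(start_id)) "none" else start_id
    } else {
      id <- intermediates[length(intermediates)]
      if (is.na(id)) "none" else id
    }
  if (length(states) == 0) {
    times <- 0
    states <- list(matrix(x, nrow = 1, dimnames = list(NULL, cm$names)))
  }
  traj_all <- structure(list(times = times,
                             states = do.call(rbind, states)),
                        class = "endo_trajectory")
  structure(list(start_attractor = start_id, end_attractor = end_id,
                 intermediate_attractors = intermediates,
                 trajectory = traj_all, final_state = x),
            class = "endo_switch")
}

#' @export
print.endo_switch <- function(x, ...) {
  cat("Induced switch:", x$start_attractor, "->", x$end_attractor, "\n")
  if (length(x$intermediate_attractors) > 1)
    cat("  via:", paste(utils::head(x$intermediate_attractors, -1),
                        collapse = " -> "), "\n")
  invisible(x)
}

#' Single-stage switching experiment
#'
#' Convenience wrapper over [apply_protocol()]: clamp the given nodes for
#' one dwell period starting from a known attractor, release, and report
#' the attractor reached.
#'
#' @inheritParams apply_protocol
#' @param from_attractor attractor id in `attractors`
#' @param clamps named vector/list, `node = value`
#' @param duration dwell time of the clamp (default 50)
#' @return an `endo_switch`
#' @export
switch_experiment <- function(net, params = hill_params(), from_attractor,
                              clamps, duration = 50, attractors) {
  if (!from_attractor %in% names(attractors$points))
    stop("unknown attractor id: ", from_attractor)
  start <- attractors$points[[from_attractor]]$state
  apply_protocol(net, params, start,
                 perturbation_protocol(list(clamps = clamps, duration = duration)),
                 attractors)
}

#' Screen for minimal clamp sets that switch between two attractors
#'
#' Exhaustively tests clamp sets of size 1, 2, ... up to `max_set_size`,
#' with each selected node clamped to 0 or 1 (full suppression or full
#' activation), in lexicographic node order, and returns every successful
#' set of the smallest successful size. This is the "dry experiment" search
#' for minimal interventions — candidate therapeutic target combinations.
#'
#' @inheritParams switch_experiment
#' @param to_attractor target attractor id
#' @param max_set_size largest clamp-set size tried (default 2)
#' @param candidate_nodes optional node subset to restrict the search
#' @param keep_all return all successful sets up to `max_set_size` instead
#'   of stopping at the smallest successful size
#' @return list of named numeric vectors (successful clamp sets); empty
#'   when none succeeds within the size bound
#' @export
perturbation_screen <- function(net, params = hill_params(), from_attractor,
                                to_attractor, max_set_size = 2,
                                candidate_nodes = NULL, duration = 50,
                                attractors, keep_all = FALSE) {
  for (id in c(from_attractor, to_attractor))
    if (!id %in% names(attractors$points)) stop("unknown attractor id: ", id)
  nodes <- sort(if (is.null(candidate_nodes)) net$nodes$name else candidate_nodes)
  hits <- list()
  for (k in seq_len(max_set_size)) {
    if (k > length(nodes)) break
    sets <- utils::combn(nodes, k, simplify = FALSE)
    levels_grid <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
    for (set in sets) for (r in seq_len(nrow(levels_grid))) {
      cl <- stats::setNames(as.numeric(levels_grid[r, ]), set)
      res <- switch_experiment(net, params, from_attractor, cl,
                               duration = duration, attractors = attractors)
      if (identical(res$end_attractor, to_attractor))
        hits[[length(hits) + 1]] <- cl
    }
    if (length(hits) > 0 && !keep_all) break
  }
  hits
}
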