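#' Attractors reached by escaping along a fixed point's unstable directions
#'
#' For each eigenvalue with positive real part, the state is displaced by
#' `+eps` and `-eps` along the corresponding (realified) unit eigenvector
#' and relaxed to convergence; each endpoint is matched to the nearest
#' known attractor within the dedup tolerance. Complex unstable pairs are
#' handled by displacing along the real and imaginary parts separately.
#'
#' @inheritParams network_rhs
#' @param fp an `endo_fp` with `stability_class` saddle or unstable
#' @param attractors an `endo_attractors` (the reference attractor set)
#' @param eps displacement magnitude (default 1e-3)
#' @param match_tol max-norm radius for endpoint-to-attractor matching
#'   (default: the attractor set's dedup tolerance)
#' @return data frame with one row per escape trial: `direction`, `sgn`,
#'   `attractor` (id or `NA` for a novel endpoint), plus the endpoint
#'   coordinates in an attribute `endpoints`
#' @export
escape_flows <- function(net, params = hill_params(), fp, attractors,
                         eps = 1e-3, match_tol = NULL) {
  if (!inherits(fp, "endo_fp")) stop("fp must be an endo_fp")
  if (fp$stability_class == "attractor")
    stop("escape_flows expects a saddle or unstable fixed point, not an attractor")
  if (eps <= 0) stop("eps must be positive")
  if (is.null(match_tol)) match_tol <- attractors$dedup_tol
  cm <- compile_net(net, params)
  J <- jacobian_compiled(cm, fp$state)
  ed <- eigen(J)
  pos <- which(Re(ed$values) > 0)
  dirs <- list()
  seen_im <- rep(FALSE, length(pos))
  for (k in seq_along(pos)) {
    v <- ed$vectors[, pos[k]]
    re <- Re(v); im <- Im(v)
    if (sqrt(sum(re^2)) > 1e-12) dirs[[length(dirs) + 1]] <- re / sqrt(sum(re^2))
    if (sqrt(sum(im^2)) > 1e-12) dirs[[length(dirs) + 1]] <- im / sqrt(sum(im^2))
  }
  # drop duplicate directions (conjugate pairs give the same plane)
  if (length(dirs) > 1) {
    keep <- rep(TRUE, length(dirs))
    for (i in seq_along(dirs)) for (j in seq_len(i - 1)) {
      if (keep[j] && max(abs(abs(dirs[[i]]) - abs(dirs[[j]]))) < 1e-9) keep[i] <- FALSE
    }
    dirs <- dirs[keep]
  }
  A <- attractor_states(attractors)
  rows <- list(); endpoints <- list()
  for (d in seq_along(dirs)) for (sgn in c(1, -1)) {
    x0 <- clip01(fp$state + sgn * eps * dirs[[d]])
    r <- relax_compiled(cm, x0, tol = 1e-8, horizon = 500)
    id <- NA_character_
    if (nrow(A) > 0) {
      dist <- apply(abs(sweep(A, 2, r$state)), 1, max)
      j <- which.min(dist)
      if (dist[j] <= match_tol) id <- rownames(A)[j]
    }
    rows[[length(rows) + 1]] <- data.frame(direction = d, sgn = sgn,
                                           attractor = id,
                                           stringsAsFactors = FALSE)
    endpoints[[length(endpoints) + 1]] <- r$state
  }
  out <- do.call(rbind, rows)
  attr(out, "endpoints") <- do.call(rbind, endpoints)
  out
}

#' Build the saddle-mediated transition graph
#'
#' Applies [escape_flows()] to every non-attractor fixed point, collecting
#' directed flow edges (saddle/unstable point -> attractor). Attractor
#' adjacency — which phenotype switches are dynamically accessible through
#' a single pass — is derived from saddles (index 1) only: two attractors
#' are adjacent iff some saddle flows to both.
#'
#' @inheritParams escape_flows
#' @param fps an `endo_fps` from [enumerate_fixed_points()]
#' @return an `endo_tgraph`: list with `vertices` (data frame: id, class,
#'   index), `flows` (data frame: from, to, direction, sgn), `adjacency`
#'   (attractor-id edge list data frame), and `novel` (escape endpoints
#'   matching no known attractor)
#' @export
build_transition_graph <- function(net, params = hill_params(), fps,
                                   eps = 1e-3) {
  att <- fps$attractors
  if (length(att$points) < 1) stop("fps must contain at least one attractor")
  cls <- vapply(fps$points, function(f) f$stability_class, character(1))
  vertices <- data.frame(
    id = names(fps$points), class = cls,
    index = vapply(fps$points, function(f) f$index, numeric(1)),
    stringsAsFactors = FALSE)
  # map attractor-class vertices to attractor-set ids by state
  A <- attractor_states(att)
  vid_of_attractor <- function(state) {
    if (nrow(A) == 0) return(NA_character_)
    dist <- apply(abs(sweep(A, 2, state)), 1, max)
    j <- which.min(dist)
    if (dist[j] <= att$dedup_tol) rownames(A)[j] else NA_character_
  }
  flows <- list(); novel <- list()
  for (id in vertices$id[vertices$class %in% c("saddle", "unstable")]) {
    fl <- escape_flows(net, params, fps$points[[id]], att, eps = eps)
    ep <- attr(fl, "endpoints")
    for (r in seq_len(nrow(fl))) {
      if (is.na(fl$attractor[r])) {
        novel[[length(novel) + 1]] <- ep[r, ]
      } else {
        flows[[length(flows) + 1]] <- data.frame(
          from = id, to = fl$attractor[r], direction = fl$direction[r],
          sgn = fl$sgn[r], stringsAsFactors = FALSE)
      }
    }
  }
  flows <- if (length(flows)) unique(do.call(rbind, flows)) else
    data.frame(from = character(), to = character(),
               direction = numeric(), sgn = numeric(), stringsAsFactors = FALSE)
  rownames(flows) <- NULL
  # attractor adjacency through shared saddles
  adj <- list()
  saddle_ids <- vertices$id[vertices$class == "saddle"]
  for (sid in saddle_ids) {
    reached <- sort(unique(flows$to[flows$from == sid]))
    if (length(reached) >= 2) {
      prs <- utils::combn(reached, 2)
      for (c in seq_len(ncol(prs)))
        adj[[length(adj) + 1]] <- data.frame(a = prs[1, c], b = prs[2, c],
                                             via = sid, stringsAsFactors = FALSE)
    }
  }
  adj <- if (length(adj)) unique(do.call(rbind, adj)) else
    data.frame(a = character(), b = character(), via = character(),
               stringsAsFactors = FALSE)
  rownames(adj) <- NULL
  structure(list(vertices = vertices, flows = flows, adjacency = adj,
                 attractor_ids = rownames(A),
                 novel = if (length(novel)) do.call(rbind, novel) else NULL,
                 eps = eps),
            class = "endo_tgraph")
}

#' @export
print.endo_tgraph <- function(x, ...) {
  cat("Transition graph:", nrow(x$vertices), "fixed points,",
      nrow(x$flows), "flow edges,", nrow(x$adjacency),
      "saddle-mediated attractor adjacencies\n")
  if (nrow(x$adjacency) > 0) {
    for (i in seq_len(nrow(x$adjacency)))
      cat(sprintf("  %s -- %s  (via %s)\n", x$adjacency$a[i],
                  x$adjacency$b[i], x$adjacency$via[i]))
  }
  if (!is.null(x$novel))
    cat("  +", nrow(x$novel), "novel escape endpoint(s) matching no known attractor\n")
  invisible(x)
}

#' @export
plot.endo_tgraph <- function(x, ...) {
  vs <- unique(c(x$attractor_ids, x$flows$from, x$flows$to))
  if (length(vs) == 0) { graphics::plot.new(); return(invisible(x)) }
  g <- igraph::graph_from_data_frame(
    x$flows[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = vs))
  cls <- ifelse(vs %in% x$attractor_ids, "attractor",
                x$vertices$class[match(vs, x$vertices$id)])
  igraph::V(g)$color <- ifelse(cls == "attractor", "lightblue",
                               ifelse(cls == "saddle", "gold", "grey80"))
  igraph::plot.igraph(g, ...)
  invisible(x)
}

#' Routes between attractors in the transition graph
#'
#' All simple paths between two attractors in the saddle-mediated
#' adjacency graph, up to `max_hops` edges, ordered shortest first with a
#' lexicographic tie-break on the id sequence.
#'
#' @param graph an `endo_tgraph`
#' @param from,to attractor ids present in the graph
#' @param max_hops maximum number of adjacency edges in a route (default 4)
#' @return list of character vectors (attractor id sequences); a
#'   zero-length route (`from` only) when `from == to`; empty list when
#'   no route exists
#' @export
find_route <- function(graph, from, to, max_hops = 4) {
  ids <- graph$attractor_ids
  if (!from %in% ids) stop("unknown attractor id: ", from)
  if (!to %in% ids) stop("unknown attractor id: ", to)
  if (from == to) return(list(from))
  if (nrow(graph$adjacency) == 0) return(list())
  g <- igraph::graph_from_data_frame(graph$adjacency[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  paths <- igraph::all_simple_paths(g, from = from, to = to, cutoff = max_hops)
  routes <- lapply(paths, function(p) igraph::as_ids(p))
  if (length(routes) == 0) return(list())
  key <- vapply(routes, function(r) paste(r, collapse = ">"), character(1))
  len <- vapply(routes, length, integer(1))
  routes[order(len, key)]
}
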