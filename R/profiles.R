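#' Discretize a state into an activity profile
#'
#' A node is called `active` iff its value is strictly greater than the
#' threshold (the `> 0.5` convention on the normalized activity scale);
#' a value exactly at the threshold is `inactive`.
#'
#' @param state numeric state vector
#' @param threshold activity cut in (0,1), default 0.5
#' @param names optional node names for the result
#' @return character vector of calls, `"active"`/`"inactive"`
#' @export
discretize_state <- function(state, threshold = 0.5, names = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)")
  out <- ifelse(state > threshold, "active", "inactive")
  if (!is.null(names)) names(out) <- names
  out
}

#' Attractor-by-node activity profile table
#'
#' The binary molecular profile of every attractor: rows ordered by
#' attractor id, columns by network node order. This is the tabular view
#' of "which molecules are on in which phenotype".
#'
#' @param attractors a non-empty `endo_attractors`
#' @param threshold activity cut (default 0.5)
#' @return character matrix of `"active"`/`"inactive"` calls
#' @export
profile_table <- function(attractors, threshold = 0.5) {
  if (length(attractors$points) == 0) stop("empty attractor set")
  S <- attractor_states(attractors)
  out <- matrix(discretize_state(S, threshold), nrow = nrow(S),
                dimnames = dimnames(S))
  out
}

#' Differential call between two states
#'
#' Per-node `up`/`down`/`flat` calls for an ordered state pair: `up` when
#' the value rises by more than `delta`, `down` when it falls by more than
#' `delta`, `flat` otherwise. This is how a pair of attractor profiles is
#' turned into the analogue of a differential-expression call table.
#'
#' @param before,after numeric state vectors of equal length
#' @param delta minimal change magnitude for a non-flat call (default 0.2)
#' @param names optional node names
#' @return character vector of calls
#' @export
diff_call <- function(before, after, delta = 0.2, names = NULL) {
  if (length(before) != length(after)) stop("state dimensions differ")
  if (delta <= 0) stop("delta must be positive")
  d <- after - before
  out <- ifelse(d > delta, "up", ifelse(-d > delta, "down", "flat"))
  if (!is.null(names)) names(out) <- names
  out
}

#' Concordance between model and observed differential calls
#'
#' Scores agreement between a model-derived differential profile and an
#' observed up/down/flat call table over the nodes that are non-flat in
#' both. Observed genes are mapped onto network nodes through `node_map`
#' (one node may map to several genes; such nodes aggregate their genes by
#' majority call, ties giving `flat`). Unmapped observed genes are ignored
#' but counted.
#'
#' @param model named character vector of `up`/`down`/`flat` calls per node
#' @param observed data frame with columns `gene` and `call`, or a named
#'   character vector of calls per gene
#' @param node_map optional data frame with columns `node`, `gene`; by
#'   default genes are matched to nodes by name
#' @return a `ConcordanceScore` list: `score`, `agree`, `compared`,
#'   `per_node` (data frame), `n_unmapped`
#' @export
concordance <- function(model, observed, node_map = NULL) {
  if (is.data.frame(observed)) {
    obs <- stats::setNames(as.character(observed$call), observed$gene)
  } else obs <- observed
  nodes <- names(model)
  if (is.null(node_map)) {
    node_map <- data.frame(node = nodes, gene = nodes, stringsAsFactors = FALSE)
  }
  n_unmapped <- sum(!names(obs) %in% node_map$gene)
  obs_node <- character(0)
  for (nd in unique(node_map$node)) {
    genes <- node_map$gene[node_map$node == nd]
    calls <- obs[names(obs) %in% genes]
    if (length(calls) == 0) next
    tab <- sort(table(calls), decreasing = TRUE)
    obs_node[nd] <- if (length(tab) > 1 && tab[1] == tab[2]) "flat" else names(tab)[1]
  }
  common <- intersect(nodes, names(obs_node))
  mc <- model[common]; oc <- obs_node[common]
  use <- mc != "flat" & oc != "flat"
  compared <- sum(use)
  if (compared == 0) stop("no node is non-flat in both profiles; nothing to compare")
  agree <- sum(mc[use] == oc[use])
  per_node <- data.frame(node = common, model = unname(mc),
                         observed = unname(oc),
                         compared = unname(use),
                         agree = unname(mc == oc & use),
                         stringsAsFactors = FALSE)
  list(score = agree / compared, agree = agree, compared = compared,
       per_node = per_node, n_unmapped = n_unmapped)
}
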