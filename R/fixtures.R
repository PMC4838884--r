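#' Single self-activating node
#'
#' The minimal bistable motif: one node with a self-activation edge. Under
#' the default parameters (n = 3, a = 0.5) the 1-D dynamics
#' `dx/dt = x^n/(a^n + x^n) - x` has three fixed points: stable at 0,
#' unstable near the threshold, and stable near 1.
#'
#' @param n,a optional per-edge Hill parameters stored on the self-edge
#'   (`NA` = use the global defaults at simulation time)
#' @return an `endo_network` with one node `A`
#' @export
make_self_activator <- function(n = NA, a = NA) {
  endo_network(
    nodes = data.frame(name = "A", module = "core"),
    edges = data.frame(source = "A", target = "A", sign = "activation",
                       n = n, a = a),
    modules = "core")
}

#' Mutual-inhibition toggle switch
#'
#' Two nodes repressing each other — the canonical bistable motif, echoing
#' the mutual suppression between normal-state and disease-state programs.
#' Without self-activation the continuous system (defaults n = 3, a = 0.5)
#' has two asymmetric attractors and one saddle at exactly (0.5, 0.5);
#' with self-activation the all-off state becomes a third attractor.
#'
#' @param with_self_activation add a self-activation edge on each node
#' @param n,a optional per-edge parameters applied to every edge
#' @return an `endo_network` with nodes `A`, `B`
#' @export
make_toggle_switch <- function(with_self_activation = FALSE, n = NA, a = NA) {
  edges <- data.frame(source = c("A", "B"), target = c("B", "A"),
                      sign = "inhibition", n = n, a = a,
                      stringsAsFactors = FALSE)
  if (with_self_activation) {
    edges <- rbind(edges,
                   data.frame(source = c("A", "B"), target = c("A", "B"),
                              sign = "activation", n = n, a = a,
                              stringsAsFactors = FALSE))
  }
  endo_network(
    nodes = data.frame(name = c("A", "B"), module = "core"),
    edges = edges, modules = "core")
}

#' Three-node inhibition ring
#'
#' A repressilator-style ring A -| B -| C -| A. Under the default Hill
#' parameters the continuous system spirals into the symmetric fixed point;
#' the synchronous Boolean dynamics has two cycles (periods 2 and 6) and no
#' fixed point.
#'
#' @return an `endo_network` with nodes `A`, `B`, `C`
#' @export
make_inhibition_ring <- function() {
  endo_network(
    nodes = data.frame(name = c("A", "B", "C"), module = "core"),
    edges = data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
                       sign = "inhibition"),
    modules = "core")
}

#' Miniature cell-fate network
#'
#' A frozen, hand-designed 10-node caricature of a fate-decision circuit:
#' two mutually suppressing self-activating fate hubs (`FA`, `FB`), each
#' driving a two-node downstream differentiation module, a self-activating
#' apoptosis hub (`AP`) in mutual inhibition with a survival node (`SRV`)
#' that both fates support, an apoptosis effector and a cell-cycle node.
#' Under the default parameters it supports at least four attractors with
#' disjoint discretized profiles: fate-A, fate-B, apoptotic, and all-off.
#' The wiring is fixed so oracle-computed censuses can be frozen in tests.
#'
#' @return an `endo_network` with 10 nodes in 3 modules
#' @export
make_miniature_fate_network <- function() {
  nodes <- data.frame(
    name   = c("FA", "FB", "DA1", "DA2", "DB1", "DB2", "AP", "AE1", "SRV", "CYC"),
    module = c("fate", "fate", "fate", "fate", "fate", "fate",
               "apoptosis", "apoptosis", "apoptosis", "cycle"),
    stringsAsFactors = FALSE)
  e <- function(s, t, sg) data.frame(source = s, target = t, sign = sg,
                                     stringsAsFactors = FALSE)
  edges <- rbind(
    e("FA", "FA", "activation"), e("FB", "FB", "activation"),
    e("FA", "FB", "inhibition"), e("FB", "FA", "inhibition"),
    e("AP", "FA", "inhibition"), e("AP", "FB", "inhibition"),
    e("FA", "DA1", "activation"), e("FA", "DA2", "activation"),
    e("FB", "DB1", "activation"), e("FB", "DB2", "activation"),
    e("AP", "AP", "activation"),
    e("FA", "AP", "inhibition"), e("FB", "AP", "inhibition"),
    e("SRV", "AP", "inhibition"), e("AP", "SRV", "inhibition"),
    e("FA", "SRV", "activation"), e("FB", "SRV", "activation"),
    e("AP", "AE1", "activation"),
    e("FA", "CYC", "activation"), e("FB", "CYC", "activation"),
    e("AP", "CYC", "inhibition"))
  endo_network(nodes, edges, modules = c("fate", "apoptosis", "cycle"))
}

#' Random signed network
#'
#' Draws, for each node, an in-degree from a Poisson distribution (shifted
#' so every node keeps at least one in-edge unless `allow_sources`), then
#' picks distinct regulators uniformly and assigns inhibition with the
#' given probability. Fully reproducible from the seed.
#'
#' @param n_nodes number of nodes (>= 2)
#' @param mean_in_degree target mean in-degree (default 2)
#' @param inhibition_fraction probability an edge is inhibitory (default 0.4)
#' @param seed RNG seed
#' @param allow_sources permit nodes with no in-edges (default FALSE, so
#'   the dynamics are non-degenerate)
#' @return an `endo_network` with nodes `N1..Nk`
#' @export
make_random_signed_network <- function(n_nodes, mean_in_degree = 2,
                                       inhibition_fraction = 0.4, seed = 1,
                                       allow_sources = FALSE) {
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  if (inhibition_fraction < 0 || inhibition_fraction > 1)
    stop("inhibition_fraction must lie in [0,1]")
  set.seed(seed)
  names <- paste0("N", seq_len(n_nodes))
  edges <- list()
  for (i in seq_len(n_nodes)) {
    if (allow_sources) {
      k <- stats::rpois(1, mean_in_degree)
    } else {
      k <- 1 + stats::rpois(1, max(mean_in_degree - 1, 0))
    }
    k <- min(k, n_nodes)
    if (k == 0) next
    src <- sample(names, k)
    sign <- ifelse(stats::runif(k) < inhibition_fraction,
                   "inhibition", "activation")
    edges[[length(edges) + 1]] <- data.frame(source = src, target = names[i],
                                             sign = sign,
                                             stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  edges <- unique(edges)
  endo_network(data.frame(name = names, module = "random"), edges,
               modules = "random")
}

#' Synthetic up/down expression call table
#'
#' Emulates a discretized differential-expression table consistent with a
#' pair of attractor profiles: each mapped gene carries the true
#' differential call of its node with probability `1 - flip_rate`, and one
#' of the two other calls (chosen uniformly) otherwise. Deterministic
#' given the seed.
#'
#' @param profile_before,profile_after named `"active"`/`"inactive"` call
#'   vectors (from [discretize_state()]) for the two states compared
#' @param node_map optional data frame `node`, `gene`; default maps each
#'   node to one like-named gene
#' @param flip_rate corruption probability in `[0, 0.5)`
#' @param seed RNG seed
#' @return data frame with columns `gene`, `call`
#' @export
generate_expression_table <- function(profile_before, profile_after,
                                      node_map = NULL, flip_rate = 0.1,
                                      seed = 1) {
  if (flip_rate < 0 || flip_rate >= 0.5) stop("flip_rate must lie in [0, 0.5)")
  nodes <- names(profile_before)
  if (is.null(node_map))
    node_map <- data.frame(node = nodes, gene = nodes, stringsAsFactors = FALSE)
  truth <- ifelse(profile_before == profile_after, "flat",
                  ifelse(profile_after == "active", "up", "down"))
  set.seed(seed)
  calls <- character(nrow(node_map))
  for (i in seq_len(nrow(node_map))) {
    tc <- truth[[node_map$node[i]]]
    if (stats::runif(1) < flip_rate) {
      calls[i] <- sample(setdiff(c("up", "down", "flat"), tc), 1)
    } else calls[i] <- tc
  }
  data.frame(gene = node_map$gene, call = calls, stringsAsFactors = FALSE)
}
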