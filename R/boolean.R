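#' One step of the Boolean network dynamics
#'
#' The discrete analogue of the continuous Hill rate law: a node switches on
#' iff its activation condition holds and no inhibitor is on. Activators are
#' OR-combined; a node with inhibitors but no activators has the activation
#' condition satisfied by default (matching the continuous law, whose
#' production is maximal when an unopposed repressive input is absent); a
#' node with no regulators at all decays to 0.
#'
#' @param net an `endo_network`
#' @param s integer/logical vector of bits, one per node
#' @param scheme `"synchronous"` (all nodes update together, default) or
#'   `"asynchronous"` (only `node` updates)
#' @param node node name for the asynchronous scheme
#' @return the next Boolean state (integer 0/1 vector)
#' @export
boolean_update <- function(net, s, scheme = c("synchronous", "asynchronous"),
                           node = NULL) {
  scheme <- match.arg(scheme)
  N <- n_nodes(net)
  check_state(s, N)
  s <- as.integer(s != 0)
  tgt <- match(net$edges$target, net$nodes$name)
  src <- match(net$edges$source, net$nodes$name)
  act <- net$edges$sign == "activation"
  step1 <- function(i) {
    ia <- src[tgt == i & act]; ii <- src[tgt == i & !act]
    if (length(ia) == 0 && length(ii) == 0) return(0L)
    act_ok <- if (length(ia) == 0) TRUE else any(s[ia] == 1L)
    inh_ok <- all(s[ii] == 0L)
    as.integer(act_ok && inh_ok)
  }
  if (scheme == "synchronous") {
    out <- vapply(seq_len(N), step1, integer(1))
  } else {
    if (is.null(node)) stop("asynchronous update needs a `node`")
    i <- node_index(net, node)
    out <- s
    out[i] <- step1(i)
  }
  out
}

# Encode the synchronous update as a functional map over integer-coded
# states (bit i of the code = node i). Vectorized over all 2^N states.
boolean_successor_table <- function(net) {
  N <- n_nodes(net)
  if (N > 24) stop("exhaustive enumeration limited to 24 nodes")
  tgt <- match(net$edges$target, net$nodes$name)
  src <- match(net$edges$source, net$nodes$name)
  act <- net$edges$sign == "activation"
  states <- 0:(2^N - 1)
  nxt <- integer(length(states))
  for (i in seq_len(N)) {
    ia <- src[tgt == i & act]; ii <- src[tgt == i & !act]
    if (length(ia) == 0 && length(ii) == 0) next
    actmask <- sum(bitwShiftL(1L, ia - 1L))
    inhmask <- sum(bitwShiftL(1L, ii - 1L))
    act_ok <- if (length(ia) == 0) rep(TRUE, length(states))
              else bitwAnd(states, actmask) != 0L
    inh_ok <- if (length(ii) == 0) rep(TRUE, length(states))
              else bitwAnd(states, inhmask) == 0L
    bit <- act_ok & inh_ok
    nxt <- nxt + as.integer(bit) * bitwShiftL(1L, i - 1L)
  }
  nxt
}

decode_bits <- function(code, N) {
  vapply(seq_len(N), function(i) bitwAnd(bitwShiftR(code, i - 1L), 1L),
         integer(1))
}

encode_bits <- function(bits) {
  sum(as.integer(bits != 0) * bitwShiftL(1L, seq_along(bits) - 1L))
}

#' Boolean attractors (fixed points and cycles)
#'
#' For networks up to `max_exhaustive` nodes the full synchronous state
#' space (2^N states) is enumerated exactly; larger networks are explored by
#' iterating sampled random states to cycle detection. Each attractor is
#' reported with its member states and period (period 1 = fixed point).
#'
#' @param net an `endo_network`
#' @param max_exhaustive node-count bound for exact enumeration (default 20)
#' @param n_samples random starts used above the bound
#' @param seed RNG seed for the sampled regime
#' @return list of attractors; each has `states` (matrix, one row per
#'   member state, columns = nodes) and `period`
#' @export
boolean_attractors <- function(net, max_exhaustive = 20, n_samples = 1000,
                               seed = 1) {
  N <- n_nodes(net)
  if (N <= max_exhaustive) {
    nxt <- boolean_successor_table(net)
    # pointer doubling: land every state on its terminal cycle
    reach <- nxt
    for (k in seq_len(ceiling(log2(2^N + 1)) + 1)) reach <- reach[reach + 1L]
    cyc_codes <- sort(unique(reach))
    seen <- integer()
    attrs <- list()
    for (c0 in cyc_codes) {
      if (c0 %in% seen) next
      cyc <- c0
      s <- nxt[c0 + 1L]
      while (s != c0) { cyc <- c(cyc, s); s <- nxt[s + 1L] }
      seen <- c(seen, cyc)
      attrs[[length(attrs) + 1]] <- cyc
    }
  } else {
    set.seed(seed)
    attrs <- list()
    known <- character()
    for (k in seq_len(n_samples)) {
      s <- as.integer(stats::runif(N) < 0.5)
      seen_states <- new.env(hash = TRUE)
      path <- list()
      repeat {
        key <- paste(s, collapse = "")
        if (!is.null(seen_states[[key]])) {
          start <- seen_states[[key]]
          cyc_states <- path[start:length(path)]
          cyc <- vapply(cyc_states, encode_bits, integer(1))
          break
        }
        seen_states[[key]] <- length(path) + 1L
        path[[length(path) + 1]] <- s
        s <- boolean_update(net, s)
      }
      kk <- paste(sort(cyc), collapse = ",")
      if (!kk %in% known) {
        known <- c(known, kk)
        attrs[[length(attrs) + 1]] <- cyc
      }
    }
  }
  out <- lapply(attrs, function(cyc) {
    states <- t(vapply(cyc, decode_bits, integer(n_nodes(net)), N = n_nodes(net)))
    colnames(states) <- net$nodes$name
    list(states = states, period = length(cyc))
  })
  # deterministic order: by period then by smallest member code
  ord <- order(vapply(out, function(a) a$period, numeric(1)),
               vapply(attrs, min, numeric(1)))
  out[ord]
}

#' Does a Boolean state lie on a synchronous attractor?
#'
#' Iterates the synchronous update from `s`; the state lies on an attractor
#' iff the trajectory returns to `s`. Used to cross-validate continuous
#' attractors: the >0.5-discretized profile of every continuous attractor
#' should recur under the Boolean dynamics.
#'
#' @inheritParams boolean_update
#' @param max_steps iteration cap
#' @return logical
#' @export
on_boolean_attractor <- function(net, s, max_steps = 2^16) {
  s0 <- as.integer(s != 0)
  key0 <- paste(s0, collapse = "")
  visited <- new.env(hash = TRUE)
  visited[[key0]] <- TRUE
  s <- boolean_update(net, s0)
  for (k in seq_len(max_steps)) {
    if (all(s == s0)) return(TRUE)
    key <- paste(s, collapse = "")
    if (!is.null(visited[[key]])) return(FALSE)  # closed a cycle avoiding s0
    visited[[key]] <- TRUE
    s <- boolean_update(net, s)
  }
  FALSE
}
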