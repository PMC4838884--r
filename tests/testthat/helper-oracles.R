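# Independent brute-force oracles. The Hill formulas here are written out
# by hand and never call the package's rate-law code, so grid scans stay
# independent of the implementation they check.

hill_act_ref <- function(x, n, a) x^n / (a^n + x^n)
hill_inh_ref <- function(x, n, a) a^n / (a^n + x^n)

# 1-D fixed points of the self-activator dx = act(x) - x, by sign-change
# scan at the given step, each root bisected to high precision.
oracle_self_activator_roots <- function(n = 3, a = 0.5, step = 1e-3) {
  f <- function(x) hill_act_ref(x, n, a) - x
  xs <- seq(0, 1, by = step)
  fv <- f(xs)
  roots <- xs[fv == 0]
  ch <- which(fv[-1] * fv[-length(fv)] < 0)
  for (i in ch) {
    lo <- xs[i]; hi <- xs[i + 1]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  sort(unique(roots))
}

# 2-D fixed points of the pure toggle (A -| B, B -| A). On the nullclines
# x = h1(y), y = h2(x), so fixed points are the roots of g(x) = h1(h2(x)) - x;
# h1 carries the parameters of the B->A edge, h2 those of A->B.
oracle_toggle_fps <- function(n1 = 3, a1 = 0.5, n2 = 3, a2 = 0.5, step = 1e-3) {
  h1 <- function(y) hill_inh_ref(y, n1, a1)
  h2 <- function(x) hill_inh_ref(x, n2, a2)
  g <- function(x) h1(h2(x)) - x
  xs <- seq(0, 1, by = step)
  gv <- g(xs)
  roots <- xs[gv == 0]
  ch <- which(gv[-1] * gv[-length(gv)] < 0)
  for (i in ch) {
    lo <- xs[i]; hi <- xs[i + 1]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- sort(unique(roots))
  cbind(A = roots, B = h2(roots))
}

# Exhaustive synchronous Boolean enumeration by direct iteration over all
# 2^N bit vectors, using the stated rule directly (no successor-table code).
oracle_boolean_fixed_points <- function(net) {
  N <- nrow(net$nodes)
  tgt <- net$edges$target; src <- net$edges$source
  act <- net$edges$sign == "activation"
  step <- function(s) {
    vapply(seq_len(N), function(i) {
      nm <- net$nodes$name[i]
      ia <- src[tgt == nm & act]; ii <- src[tgt == nm & !act]
      if (length(ia) == 0 && length(ii) == 0) return(0L)
      a_ok <- if (length(ia) == 0) TRUE else any(s[match(ia, net$nodes$name)] == 1L)
      i_ok <- all(s[match(ii, net$nodes$name)] == 0L)
      as.integer(a_ok && i_ok)
    }, integer(1))
  }
  fixed <- list()
  for (code in 0:(2^N - 1)) {
    s <- as.integer(bitwAnd(bitwShiftR(code, seq_len(N) - 1L), 1L))
    if (all(step(s) == s)) fixed[[length(fixed) + 1]] <- s
  }
  do.call(rbind, fixed)
}

# Designed fixture family with brute-force-known attractor structure.
designed_fixtures <- function() {
  list(self_activator = make_self_activator(),
       toggle = make_toggle_switch(),
       toggle_self = make_toggle_switch(with_self_activation = TRUE),
       inhibition_ring = make_inhibition_ring(),
       mini_fate = make_miniature_fate_network())
}

toggle_attractor_ids <- function(att) {
  st <- attractor_states(att)
  list(a_high = rownames(st)[st[, "A"] > 0.5],
       b_high = rownames(st)[st[, "B"] > 0.5])
}
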