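test_that("Hill activation and inhibition terms have the stated shape", {
  expect_equal(hill_activation(0, 3, 0.5), 0)
  expect_equal(hill_inhibition(0, 3, 0.5), 1)
  # half-saturation at x = a for both forms
  for (a in c(0.3, 0.5, 0.7)) for (n in c(1, 2, 3, 8)) {
    expect_equal(hill_activation(a, n, a), 0.5)
    expect_equal(hill_inhibition(a, n, a), 0.5)
    # complementarity at matched (x, n, a)
    x <- seq(0, 1, by = 0.1)
    expect_equal(hill_activation(x, n, a) + hill_inhibition(x, n, a),
                 rep(1, length(x)))
  }
  # monotone, bounded in [0,1]
  x <- seq(0, 1, by = 0.01)
  av <- hill_activation(x, 3, 0.5); iv <- hill_inhibition(x, 3, 0.5)
  expect_true(all(diff(av) >= 0) && all(diff(iv) <= 0))
  expect_true(all(av >= 0 & av <= 1 & iv >= 0 & iv <= 1))
  # steepening: above threshold the term approaches 1 as n grows
  expect_gt(hill_activation(0.7, 20, 0.5), hill_activation(0.7, 2, 0.5))
  expect_gt(hill_activation(0.8, 20, 0.5), 0.999)
  expect_error(hill_activation(0.5, 0.5, 0.5), "out of range")
  expect_error(hill_activation(1.5, 3, 0.5), "outside")
})

test_that("node_rate composes multiple inputs as the rate law dictates", {
  p <- hill_params()
  # no incoming edges -> pure decay
  net0 <- endo_network(data.frame(name = c("A", "B"), module = "m"),
                       data.frame(source = "A", target = "B", sign = "activation"))
  expect_equal(node_rate(net0, p, "A", c(0.7, 0.2)), 0)
  # one activator at 0 and one inhibitor at 0 -> no production
  net1 <- endo_network(data.frame(name = c("T", "X", "Y"), module = "m"),
                       data.frame(source = c("X", "Y"), target = "T",
                                  sign = c("activation", "inhibition")))
  expect_equal(node_rate(net1, p, "T", c(0.9, 0, 0)), 0)
  # a single activator reduces to the activation term
  net2 <- endo_network(data.frame(name = c("T", "X"), module = "m"),
                       data.frame(source = "X", target = "T", sign = "activation"))
  for (x in c(0.2, 0.5, 0.9))
    expect_equal(node_rate(net2, p, "T", c(0, x)), hill_activation(x, 3, 0.5))
  # inhibitors veto multiplicatively: saturated inhibitor kills production
  val <- node_rate(net1, p, "T", c(0, 1, 1))
  expect_lt(val, hill_activation(1, 3, 0.5) / 2)
  expect_error(node_rate(net1, p, "Q", c(0, 0, 0)), "unknown node")
})

test_that("rhs is generation minus decay and vanishes at fixed points", {
  p <- hill_params()
  tog <- make_toggle_switch()
  # symmetric wiring forces equal components on the diagonal
  r <- network_rhs(tog, p, c(0.3, 0.3))
  expect_equal(r[1], r[2])
  # (0.5, 0.5) is the exact symmetric fixed point at n=3, a=0.5
  expect_equal(network_rhs(tog, p, c(0.5, 0.5)), c(0, 0))
  # isolated input-free node: pure exponential decay
  iso <- endo_network(data.frame(name = "Z", module = "m"))
  expect_equal(network_rhs(iso, p, 0.7), -0.7)
  expect_true(all(abs(network_rhs(make_miniature_fate_network(), p,
                                  runif(10))) <= 1))
})

test_that("analytic Jacobian matches central differences", {
  p <- hill_params()
  nets <- list(make_toggle_switch(), make_miniature_fate_network(),
               make_random_signed_network(8, seed = 3))
  set.seed(7)
  h <- 1e-6
  for (net in nets) {
    N <- n_nodes(net)
    for (rep in 1:3) {
      x <- runif(N, 0.05, 0.95)
      J <- network_jacobian(net, p, x)
      Jfd <- matrix(0, N, N)
      for (j in seq_len(N)) {
        xp <- x; xm <- x
        xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
        Jfd[, j] <- (network_rhs(net, p, xp) - network_rhs(net, p, xm)) / (2 * h)
      }
      expect_lt(max(abs(J - Jfd)), 1e-5)
    }
  }
  # no edges -> -Identity
  iso <- endo_network(data.frame(name = c("U", "V"), module = "m"))
  expect_equal(network_jacobian(iso, p, c(0.4, 0.9)), -diag(2))
  # toggle symmetric point: exactly one unstable eigenvalue (the classic saddle)
  ev <- eigen(network_jacobian(make_toggle_switch(), p, c(0.5, 0.5)))$values
  expect_equal(sum(Re(ev) > 0), 1)
  expect_equal(sort(Re(ev)), c(-2.5, 0.5))
})

test_that("the alternative rate law preserves the toggle's bistability", {
  p_alt <- hill_params(rate_law = "hill_product")
  att <- sample_attractors(make_toggle_switch(), p_alt, n_starts = 100, seed = 1)
  expect_equal(length(att$points), 2)
  profs <- attractor_states(att) > 0.5
  expect_setequal(apply(profs, 1, function(p) paste(as.integer(p), collapse = "")),
                  c("10", "01"))
})

test_that("integration matches closed-form decay and respects clamps", {
  iso <- endo_network(data.frame(name = "Z", module = "m"))
  traj <- simulate_network(iso, hill_params(), x0 = 1, horizon = 1)
  expect_equal(unname(traj$states[nrow(traj$states), 1]), exp(-1),
               tolerance = 1e-7)
  # full decay curve x0 * e^(-t)
  expect_lt(max(abs(traj$states[, 1] - exp(-traj$times))), 1e-6)
  # toggle basin: start near A-high converges there
  tog <- make_toggle_switch()
  tr <- simulate_network(tog, hill_params(), c(0.9, 0.1), horizon = 60)
  fin <- tr$states[nrow(tr$states), ]
  expect_gt(fin["A"], 0.9); expect_lt(fin["B"], 0.2)
  # clamping B holds it exactly; A relaxes to its B-inhibited steady value
  tr2 <- simulate_network(tog, hill_params(), c(0.9, 0.1),
                          horizon = 60, clamps = c(B = 1))
  expect_true(all(tr2$states[, "B"] == 1))
  expect_equal(unname(tr2$states[nrow(tr2$states), "A"]),
               hill_inhibition(1, 3, 0.5), tolerance = 1e-6)
  expect_error(simulate_network(tog, hill_params(), c(0.9, 0.1),
                                horizon = 10, clamps = c(Q = 1)), "unknown node")
})

test_that("trajectories stay inside the unit box (forward invariance)", {
  set.seed(11)
  worst <- 0
  for (sd in 1:3) {
    net <- make_random_signed_network(12, seed = sd)
    for (rep in 1:10) {
      tr <- simulate_network(net, hill_params(), runif(12), horizon = 20)
      worst <- max(worst, max(tr$states - 1), max(-tr$states))
    }
  }
  expect_lt(worst, 1e-7)
})
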