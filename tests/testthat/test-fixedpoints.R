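test_that("classification follows the eigenvalue index convention", {
  expect_equal(classify_fixed_point(c(-1, -2, -0.5))$class, "attractor")
  expect_equal(classify_fixed_point(c(0.3, -1, -1))$class, "saddle")
  expect_equal(classify_fixed_point(c(0.3, 0.2, -1))$class, "unstable")
  expect_equal(classify_fixed_point(c(1e-9, -1))$class, "degenerate")
  expect_equal(classify_fixed_point(complex(real = c(-0.2, -0.2), imaginary = c(1, -1)))$class,
               "attractor")
})

test_that("greedy dedup clusters by max-norm radius in input order", {
  s <- list(c(0, 0), c(0, 0), c(0, 4e-4), c(0.5, 0.5), c(0, 2e-3))
  dd <- dedupe_states(s, tol = 1e-3)
  expect_equal(nrow(dd$representatives), 3)
  expect_equal(dd$membership, c(1, 1, 1, 2, 3))
  expect_error(dedupe_states(s, tol = 0), "positive")
})

test_that("Newton refinement lands on oracle roots and reports class", {
  tog <- make_toggle_switch()
  fp <- refine_fixed_point(tog, guess = c(0.52, 0.48))
  expect_equal(fp$state, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(fp$stability_class, "saddle")
  expect_equal(fp$index, 1)
  expect_lt(fp$residual, 1e-9)
  # origin of the no-edge network is an exact attractor
  iso <- endo_network(data.frame(name = c("U", "V", "W"), module = "m"))
  fp0 <- refine_fixed_point(iso, guess = c(0, 0, 0))
  expect_equal(fp0$state, c(0, 0, 0))
  expect_equal(fp0$stability_class, "attractor")
})

test_that("attractor sampling finds the brute-force census and is reproducible", {
  # no-edge network: global decay to the origin
  iso <- endo_network(data.frame(name = c("U", "V", "W"), module = "m"))
  att0 <- sample_attractors(iso, n_starts = 50, seed = 1)
  expect_equal(length(att0$points), 1)
  expect_equal(att0$points[[1]]$state, c(0, 0, 0), tolerance = 1e-6)
  # toggle: exactly the two oracle attractors
  tog <- make_toggle_switch()
  att <- sample_attractors(tog, n_starts = 200, seed = 1)
  expect_equal(length(att$points), 2)
  oracle <- oracle_toggle_fps()
  stable <- oracle[c(1, 3), ]  # outer roots are the stable ones
  found <- attractor_states(att)
  for (i in 1:2) {
    d <- apply(abs(sweep(stable, 2, found[i, ])), 1, max)
    expect_lt(min(d), 1e-4)
  }
  expect_equal(sum(att$basin_counts), att$n_starts - att$n_nonconverged)
  # bit-for-bit reproducibility
  att2 <- sample_attractors(tog, n_starts = 200, seed = 1)
  expect_identical(attractor_states(att), attractor_states(att2))
  expect_identical(att$basin_counts, att2$basin_counts)
})

test_that("full enumeration matches the 1-D and 2-D grid-scan oracles", {
  # self-activator: three roots at 0, a, (1+sqrt(5))/4 for n=3, a=0.5
  sa <- make_self_activator()
  fps <- enumerate_fixed_points(sa, n_starts = 100, n_seeds = 60, seed = 1)
  roots <- oracle_self_activator_roots()
  expect_equal(length(fps$points), length(roots))
  got <- unname(sort(vapply(fps$points, function(f) f$state, numeric(1))))
  expect_equal(got, roots, tolerance = 1e-4)
  expect_equal(as.integer(fps$census[c("attractor", "saddle")]), c(2L, 1L))
  # toggle: 2 attractors + 1 saddle at the oracle locations
  tog <- make_toggle_switch()
  tfps <- enumerate_fixed_points(tog, n_starts = 200, n_seeds = 100, seed = 1)
  oracle <- oracle_toggle_fps()
  expect_equal(length(tfps$points), nrow(oracle))
  for (fp in tfps$points) {
    d <- apply(abs(sweep(oracle, 2, fp$state)), 1, max)
    expect_lt(min(d), 1e-4)
  }
  expect_equal(sum(vapply(tfps$points, function(f) f$stability_class == "saddle",
                          logical(1))), 1)
  # every reported point re-verifies its residual
  for (fp in tfps$points)
    expect_lt(max(abs(network_rhs(tog, hill_params(), fp$state))), 1e-6)
})

test_that("attractor discovery is monotone in the number of starts", {
  net <- make_miniature_fate_network()
  a_small <- sample_attractors(net, n_starts = 60, seed = 5)
  a_big <- sample_attractors(net, n_starts = 240, seed = 5)
  small_keys <- apply(attractor_states(a_small) > 0.5, 1, paste, collapse = "")
  big_keys <- apply(attractor_states(a_big) > 0.5, 1, paste, collapse = "")
  expect_true(all(small_keys %in% big_keys))
})
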