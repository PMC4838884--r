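toggle_setup <- function() {
  tog <- make_toggle_switch()
  att <- sample_attractors(tog, n_starts = 200, seed = 1)
  ids <- toggle_attractor_ids(att)
  list(net = tog, att = att, a = ids$a_high, b = ids$b_high)
}

test_that("clamp switching crosses the toggle and is deterministic", {
  ts <- toggle_setup()
  r <- switch_experiment(ts$net, hill_params(), ts$a, c(B = 1),
                         duration = 10, attractors = ts$att)
  expect_equal(r$start_attractor, ts$a)
  expect_equal(r$end_attractor, ts$b)
  r2 <- switch_experiment(ts$net, hill_params(), ts$a, c(B = 1),
                          duration = 10, attractors = ts$att)
  expect_identical(r$final_state, r2$final_state)
  expect_identical(r$end_attractor, r2$end_attractor)
  expect_error(switch_experiment(ts$net, hill_params(), "A9", c(B = 1),
                                 duration = 1, attractors = ts$att), "unknown")
})

test_that("sub-maximal clamps show dwell-time dependence", {
  ts <- toggle_setup()
  short <- switch_experiment(ts$net, hill_params(), ts$a, c(B = 0.6),
                             duration = 0.01, attractors = ts$att)
  long <- switch_experiment(ts$net, hill_params(), ts$a, c(B = 0.6),
                            duration = 50, attractors = ts$att)
  expect_equal(short$end_attractor, ts$a)  # brief partial push relaxes back
  expect_equal(long$end_attractor, ts$b)   # sustained suppression switches
})

test_that("the null protocol is the identity on attractors", {
  ts <- toggle_setup()
  for (id in names(ts$att$points)) {
    r <- apply_protocol(ts$net, hill_params(), ts$att$points[[id]]$state,
                        perturbation_protocol(), ts$att)
    expect_equal(r$end_attractor, id)
  }
})

test_that("staged protocols chain with release between stages", {
  mini <- make_miniature_fate_network()
  att <- sample_attractors(mini, n_starts = 400, seed = 1)
  st <- attractor_states(att)
  fa <- rownames(st)[st[, "FA"] > 0.5]
  fb <- rownames(st)[st[, "FB"] > 0.5]
  ap <- rownames(st)[st[, "AP"] > 0.5]
  proto <- perturbation_protocol(
    list(clamps = c(FA = 0, FB = 1), duration = 30),
    list(clamps = c(AP = 1), duration = 30))
  r <- apply_protocol(mini, hill_params(), att$points[[fa]]$state, proto, att)
  expect_equal(r$start_attractor, fa)
  expect_equal(r$intermediate_attractors[1], fb)
  expect_equal(r$end_attractor, ap)
  expect_error(perturbation_protocol(list(clamps = c(FA = 2), duration = 1)),
               "\\[0,1\\]")
  expect_error(perturbation_protocol(list(clamps = c(FA = 1), duration = -1)),
               "positive")
})

test_that("the screen reproduces brute force over all size-1 clamps", {
  ts <- toggle_setup()
  hits <- perturbation_screen(ts$net, hill_params(), ts$a, ts$b,
                              max_set_size = 1, attractors = ts$att)
  # brute force over all (node, level) pairs, written out directly
  brute <- list()
  for (nd in c("A", "B")) for (lv in c(0, 1)) {
    cl <- stats::setNames(lv, nd)
    r <- switch_experiment(ts$net, hill_params(), ts$a, cl,
                           duration = 50, attractors = ts$att)
    if (r$end_attractor == ts$b) brute[[length(brute) + 1]] <- cl
  }
  key <- function(cls) sort(vapply(cls, function(c)
    paste(names(c), c, sep = "=", collapse = ","), character(1)))
  expect_equal(key(hits), key(brute))
  expect_gt(length(hits), 0)
})

test_that("the screen finds a small clamp set switching cell fate", {
  mini <- make_miniature_fate_network()
  att <- sample_attractors(mini, n_starts = 400, seed = 1)
  st <- attractor_states(att)
  fa <- rownames(st)[st[, "FA"] > 0.5]
  fb <- rownames(st)[st[, "FB"] > 0.5]
  hits <- perturbation_screen(mini, hill_params(), fa, fb, max_set_size = 2,
                              attractors = att)
  expect_gt(length(hits), 0)
  expect_lte(length(hits[[1]]), 2)
  # every reported set verifies when replayed
  for (cl in hits) {
    r <- switch_experiment(mini, hill_params(), fa, cl, attractors = att)
    expect_equal(r$end_attractor, fb)
  }
})

test_that("no clamp set can leave a monostable system", {
  iso <- endo_network(data.frame(name = c("U", "V"), module = "m"))
  att <- sample_attractors(iso, n_starts = 40, seed = 1)
  expect_equal(length(att$points), 1)
  # no second attractor exists to reach
  expect_error(perturbation_screen(iso, hill_params(), "A1", "A2",
                                   max_set_size = 2, attractors = att),
               "unknown")
})
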