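test_that("TSV and JSON parsing build the declared network", {
  txt <- c("#module core",
           "NODE A core", "NODE B core",
           "EDGE A B +", "EDGE B A -")
  net <- parse_network(txt)
  expect_s3_class(net, "endo_network")
  expect_equal(net$nodes$name, c("A", "B"))
  expect_equal(net$modules, "core")
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$sign, c("activation", "inhibition"))

  jtxt <- '{"modules":["m1"],
            "nodes":[{"name":"X","module":"m1"},{"name":"Y","module":"m1"}],
            "edges":[{"source":"X","target":"Y","sign":"inhibition","n":4,"a":0.3}]}'
  jnet <- parse_network(jtxt)
  expect_equal(n_nodes(jnet), 2)
  expect_equal(jnet$edges$n, 4)
  expect_equal(jnet$edges$a, 0.3)
})

test_that("parse errors carry line numbers and name unknown endpoints", {
  expect_error(parse_network(c("NODE A", "EDGE A Q +")), "Q")
  expect_error(parse_network(c("NODE A", "FOO bar")), "line 2")
  expect_error(parse_network(c("NODE A", "EDGE A A *")), "line 2")
  expect_error(parse_network("#module x"), "no nodes")
})

test_that("validate_network reports violations as data", {
  expect_equal(nrow(validate_network(make_toggle_switch())), 0)
  # duplicated triple and undeclared module, built as a bare list to bypass
  # the validating constructor
  bad <- list(
    nodes = data.frame(name = c("A", "B"), module = c("core", "other"),
                       stringsAsFactors = FALSE),
    edges = data.frame(source = c("A", "A"), target = c("B", "B"),
                       sign = "activation", n = NA_real_, a = NA_real_,
                       stringsAsFactors = FALSE),
    modules = "core")
  v <- validate_network(bad)
  expect_setequal(v$rule, c("edge_unique", "module_label"))
  # dual regulation (activation + inhibition from the same source) is legal
  dual <- endo_network(data.frame(name = c("A", "B"), module = "m"),
                       data.frame(source = "A", target = c("B", "B"),
                                  sign = c("activation", "inhibition")))
  expect_equal(nrow(validate_network(dual)), 0)
})

test_that("write/parse round trip preserves networks bit-exactly", {
  nets <- list(make_toggle_switch(), make_miniature_fate_network(),
               make_toggle_switch(n = 2.5, a = 0.37))
  for (net in nets) {
    for (d in c("tsv", "json")) {
      back <- parse_network(write_network(net, d))
      expect_equal(back$nodes$name, net$nodes$name)
      expect_equal(back$modules, net$modules)
      expect_equal(back$edges, net$edges)
    }
  }
  empty <- list(nodes = data.frame(name = character(), module = character()),
                edges = data.frame(), modules = character())
  expect_error(write_network(structure(empty, class = "endo_network")),
               "no nodes")
})

test_that("the bundled mini-fate file matches the in-code generator", {
  path <- system.file("extdata", "mini_fate_network.tsv", package = "endonet")
  net <- read_network(path)
  ref <- make_miniature_fate_network()
  expect_equal(net$nodes, ref$nodes)
  expect_equal(net$edges$source, ref$edges$source)
  expect_equal(net$edges$sign, ref$edges$sign)
})

test_that("effective_subnetwork applies the strict >threshold rule", {
  net <- make_toggle_switch(with_self_activation = TRUE)
  expect_equal(n_nodes(effective_subnetwork(net, c(0, 0), 0.5)), 0)
  # A-high attractor of the self-activating toggle: only A and its self-edge
  att <- sample_attractors(net, n_starts = 100, seed = 1)
  st <- attractor_states(att)
  ahigh <- st[st[, "A"] > 0.5 & st[, "B"] < 0.5, , drop = FALSE][1, ]
  sub <- effective_subnetwork(net, ahigh, 0.5)
  expect_equal(sub$nodes$name, "A")
  expect_equal(nrow(sub$edges), 1)
  expect_equal(sub$edges$source, "A")
  expect_equal(sub$edges$target, "A")
  # boundary: a node exactly at the threshold is excluded
  sub2 <- effective_subnetwork(net, c(0.5, 0.7), 0.5)
  expect_equal(sub2$nodes$name, "B")
  expect_error(effective_subnetwork(net, c(1, 1, 1)), "dimension")
})

test_that("effective_subnetwork is idempotent and monotone in the threshold", {
  net <- make_miniature_fate_network()
  set.seed(42)
  for (rep in 1:5) {
    state <- runif(n_nodes(net))
    s1 <- effective_subnetwork(net, state, 0.5)
    s2 <- effective_subnetwork(s1, state[match(s1$nodes$name, net$nodes$name)], 0.5)
    expect_equal(s1$nodes$name, s2$nodes$name)
    counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(t)
      n_nodes(effective_subnetwork(net, state, t)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})
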