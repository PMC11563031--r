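simple_tree_text <- c(
  "# four-leaf tree",
  "root R",
  "edge e1 R P 0.01",
  "edge e2 R Q 0.02",
  "edge e3 P A 0.003",
  "edge e4 P B 0.004",
  "edge e5 Q C 0.005",
  "edge e6 Q D 0.006")

test_that("graph parsing, validation and serialization round-trip", {
  g <- parse_graph(simple_tree_text)
  expect_identical(g$root, "R")
  expect_identical(sort(g$leaves), c("A", "B", "C", "D"))
  expect_identical(nrow(g$edges), 6L)
  expect_identical(nrow(g$admix), 0L)

  g2 <- parse_graph(serialize_graph(g, "text"))
  expect_identical(g2$edges, g$edges)
  expect_identical(g2$admix, g$admix)
  expect_identical(g2$root, g$root)

  # admixture dialect with percentage proportions round-trips too
  txt <- c(simple_tree_text,
           "admix M B C 30%",
           "edge e7 M X 0.001")
  ga <- parse_graph(txt)
  expect_equal(ga$admix$alpha, 0.3)
  # B and C now feed the admixture node, so the leaves are A, D and X
  expect_identical(sort(ga$leaves), c("A", "D", "X"))
  gb <- parse_graph(serialize_graph(ga, "text"))
  expect_equal(gb$admix, ga$admix)
})

test_that("malformed graph files fail with the offending line number", {
  expect_error(parse_graph(c("root R", "edge e1 R")), "line 2")
  expect_error(parse_graph(c("root R", "edge e1 R A x")), "line 2")
  expect_error(parse_graph(c("wat R A")), "line 1")
  expect_error(parse_graph(c("edge e1 A B 0.1", "edge e2 B A 0.1")),
               "cycle|root")
  expect_error(parse_graph(c("edge e1 R A 0.1", "edge e2 S B 0.1")),
               "exactly one root")
  expect_error(parse_graph(c(simple_tree_text, "admix M B C 1.7")),
               "\\[0, 1\\]")
  expect_error(admixture_graph(data.frame(parent = c("R", "R"),
                                          child = c("A", "B"),
                                          length = c(-0.1, 0.2))),
               "negative")
})

test_that("DOT output follows the x1000 rounding and percent contracts", {
  g <- admixture_graph(
    data.frame(parent = c("R", "R", "P", "P", "M"),
               child = c("P", "Q", "A", "B", "X"),
               length = c(0.0266667, 0.002, 0.0004, 0.01, 0.001)),
    data.frame(child = "M", parent1 = "Q", parent2 = "B", alpha = 0.7))
  dot <- serialize_graph(g, "dot")
  expect_true(any(grepl("\"R\" -> \"P\" \\[label=\"27\"\\]", dot)))
  expect_true(any(grepl("label=\"0\"", dot)))     # 0.0004 rounds to 0
  expect_true(any(grepl("label=\"70%\"", dot)))
  expect_true(any(grepl("label=\"30%\"", dot)))
  expect_true(any(grepl("\"A\" \\[shape=box\\]", dot)))
})

test_that("parameter counting matches the combinatorial rules", {
  g4 <- admixkit:::graph_quartet_mixe()
  c4 <- count_parameters(g4)
  expect_identical(c4$n_constraints, 6)
  expect_identical(c4$n_free_parameters, 7)
  expect_identical(c4$compound_reductions, "pAM")
  expect_identical(c4$n_effective_parameters, 5)

  g5 <- admixkit:::graph_five_ulchi()
  c5 <- count_parameters(g5)
  expect_identical(c5$n_constraints, 10)
  expect_identical(c5$n_free_parameters, 9)

  g2 <- admixture_graph(data.frame(parent = c("R", "R"),
                                   child = c("A", "B"),
                                   length = c(0.01, 0.01)))
  c2 <- count_parameters(g2)
  expect_identical(c2$n_constraints, 1)
  expect_identical(c2$n_free_parameters, 1)
  expect_identical(c2$compound_reductions, character(0))
})

test_that("free_topology clears parameters but keeps structure", {
  g <- admixkit:::graph_quartet_mixe()
  f <- free_topology(g)
  expect_true(all(is.na(f$edges$length)))
  expect_true(all(is.na(f$admix$alpha)))
  expect_identical(f$edges$name, g$edges$name)
  expect_identical(f$leaves, g$leaves)
})

test_that("re-rooting preserves expected f-statistics and refuses to cross
           admixture nodes", {
  g <- admixkit:::graph_quartet_mixe()
  for (edge in c("ooa", "west", "Baka_t")) {
    g2 <- reroot_graph(g, edge)
    for (quad in list(c("Mixe", "Baka", "Han", "French"),
                      c("Baka", "French", "Han", "Mixe"))) {
      expect_equal(expected_f4(g2, quad[1], quad[2], quad[3], quad[4])$value,
                   expected_f4(g, quad[1], quad[2], quad[3], quad[4])$value,
                   tolerance = 1e-12)
    }
  }
  expect_error(reroot_graph(g, "z"), "admixture")
  expect_error(reroot_graph(g, "nope"), "unknown drift edge")
})
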