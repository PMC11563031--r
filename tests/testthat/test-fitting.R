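quartet_pops <- c("Baka", "French", "Han", "Mixe")

test_that("basis systems have the right dimension and span all
           f-statistics", {
  p4 <- random_panel(1, n = 120, pops = quartet_pops, n_blocks = 6)
  b4 <- build_basis(p4, quartet_pops)
  expect_length(b4$f_obs, 6L)
  expect_identical(dim(b4$Q), c(6L, 6L))

  pops5 <- c(quartet_pops, "Ulchi")
  b5 <- build_basis(random_panel(2, n = 120, pops = pops5, n_blocks = 6),
                    pops5)
  expect_length(b5$f_obs, 10L)

  # any f4 is a fixed linear combination of the basis:
  # f4(X,Y;Z,W) = f3(base;?) algebra via f2 reconstruction
  sig <- vapply(b4$stats, paste, character(1), collapse = ",")
  f2p <- function(b, X, Y) {
    idx <- function(tup) match(paste(tup, collapse = ","), sig)
    if (X == b$base_pop) return(b$f_obs[idx(c(b$base_pop, Y))])
    if (Y == b$base_pop) return(b$f_obs[idx(c(b$base_pop, X))])
    k <- idx(c(b$base_pop, X, Y))
    if (is.na(k)) k <- idx(c(b$base_pop, Y, X))
    b$f_obs[idx(c(b$base_pop, X))] + b$f_obs[idx(c(b$base_pop, Y))] -
      2 * b$f_obs[k]
  }
  recon <- (f2p(b4, "French", "Mixe") + f2p(b4, "Han", "Baka") -
            f2p(b4, "French", "Baka") - f2p(b4, "Han", "Mixe")) / 2
  direct <- compute_f4(p4, "French", "Han", "Baka", "Mixe")$value
  expect_equal(recon, direct, tolerance = 1e-12)
})

test_that("fitting exact synthetic data recovers the graph up to the
           compound degeneracy", {
  g <- admixkit:::graph_five_ulchi()
  basis <- exact_basis(g, base_pop = "Baka")
  fit <- fit_graph(basis, free_topology(g), fit_options(n_restarts = 3))
  expect_lt(fit$score, 1e-10)
  expect_equal(fit$graph$admix$alpha, 0.7, tolerance = 1e-3)
  len <- setNames(fit$graph$edges$length, fit$graph$edges$name)
  tru <- setNames(g$edges$length, g$edges$name)
  # identified branches recover exactly
  for (nm in c("west", "east", "east2", "French_t", "Han_t", "Ulchi_t"))
    expect_equal(len[[nm]], tru[[nm]], tolerance = 1e-4)
  # the root pair is identified only through its sum
  expect_equal(len[["Baka_t"]] + len[["ooa"]],
               tru[["Baka_t"]] + tru[["ooa"]], tolerance = 1e-4)
  # x, y, z only through the compound alpha^2 x + (1-alpha)^2 y + z
  a <- fit$graph$admix$alpha
  expect_equal(a^2 * len[["x"]] + (1 - a)^2 * len[["y"]] + len[["z"]],
               0.49 * tru[["x"]] + 0.09 * tru[["y"]] + tru[["z"]],
               tolerance = 1e-4)
  # predicted vector equals the expectation under the fitted graph
  W <- branch_weights(fit$graph)
  pred <- vapply(basis$stats, function(s) {
    q <- admixkit:::as_quadruple(s)
    sum(admixkit:::f4_coefficients(W, q[1], q[2], q[3], q[4]) *
          fit$graph$edges$length)
  }, numeric(1))
  expect_equal(fit$residuals$predicted, pred, tolerance = 1e-12)
})

test_that("least-squares mode equals a generalized fit with identity
           covariance", {
  p <- simulate_panel(scenario_spec("quartet_mixe", n_snps = 20000,
                                    seed = 6))
  basis <- build_basis(p, quartet_pops)
  topo <- scenario_topology("quartet_mixe")
  f_lsq <- lsq_fit(basis, topo, fit_options(n_restarts = 2))
  basis_id <- basis
  basis_id$Q <- diag(6)
  basis_id$Q_reg <- diag(6)
  f_gen <- fit_graph(basis_id, topo, fit_options(n_restarts = 2, lsq = TRUE))
  expect_equal(f_lsq$score, f_gen$score, tolerance = 1e-10)
  expect_equal(f_lsq$graph$edges$length, f_gen$graph$edges$length,
               tolerance = 1e-8)
  expect_true(f_lsq$lsq)
})

test_that("fit matches a brute-force grid search on a toy graph", {
  # three populations, C admixed; free parameters: alpha and C's terminal
  # branch; everything else fixed
  toy <- admixture_graph(
    data.frame(name = c("a1", "a2", "ta", "tb", "tc"),
               parent = c("R", "R", "A1", "B1", "Cm"),
               child = c("A1", "B1", "A", "B", "C"),
               length = c(0.01, 0.01, 0.008, 0.012, NA)),
    data.frame(child = "Cm", parent1 = "A1", parent2 = "B1", alpha = NA))
  truth <- toy
  truth$edges$length[5] <- 0.004
  truth$admix$alpha <- 0.35
  p <- simulate_panel(sim_spec(truth, 40000, 40, seed = 8))
  basis <- build_basis(p, c("A", "B", "C"),
                       options = estimator_options(bias_correction = TRUE))
  fit <- fit_graph(basis, toy, fit_options(n_restarts = 3))

  R <- chol(basis$Q_reg)
  score_at <- function(alpha, tc) {
    g <- toy
    g$admix$alpha <- alpha
    g$edges$length[5] <- tc
    X <- admixkit:::basis_design(g, basis$stats)
    r <- backsolve(R, X %*% g$edges$length - basis$f_obs, transpose = TRUE)
    0.5 * sum(r^2)
  }
  grid <- expand.grid(alpha = seq(0, 1, by = 0.005),
                      tc = seq(0, 0.01, by = 5e-5))
  sc <- mapply(score_at, grid$alpha, grid$tc)
  best <- grid[which.min(sc), ]
  expect_lte(fit$score, min(sc) + 1e-4)
  expect_lt(abs(fit$graph$admix$alpha - best$alpha), 0.006)
  expect_lt(abs(fit$graph$edges$length[5] - best$tc), 1e-4)
})

test_that("the optimal score does not depend on the base population", {
  p <- simulate_panel(scenario_spec("five_ulchi", n_snps = 30000, seed = 9))
  pops <- c("Baka", "French", "Han", "Mixe", "Ulchi")
  # fix alpha so the inner solve is exact, and drop the ridge so the two
  # bases are exact linear bijections of each other
  topo <- scenario_topology("five_ulchi", "swapped")
  topo$admix$alpha <- 0.7
  opts <- estimator_options(bias_correction = TRUE)
  s1 <- fit_graph(build_basis(p, pops, base_pop = "Baka", options = opts,
                              diag_reg = 0), topo)$score
  s2 <- fit_graph(build_basis(p, pops, base_pop = "French", options = opts,
                              diag_reg = 0), topo)$score
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("score is non-increasing when an admixture event is freed", {
  p <- simulate_panel(scenario_spec("five_ulchi", n_snps = 30000, seed = 10))
  basis <- build_basis(p, c("Baka", "French", "Han", "Mixe", "Ulchi"),
                       options = estimator_options(bias_correction = TRUE))
  topo <- scenario_topology("five_ulchi")
  s_free <- fit_graph(basis, topo, fit_options(n_restarts = 3))$score
  s_tree <- fit_graph(basis, topo,
                      fit_options(fixed = list("alpha:pAM" = 1)))$score
  expect_lte(s_free, s_tree + 1e-9)
  expect_gt(s_tree, s_free)   # the admixture genuinely improves the fit
})

test_that("residual tables enumerate every statistic and flag the
           misplaced populations first", {
  p <- simulate_panel(scenario_spec("quartet_mixe", n_snps = 20000,
                                    seed = 11))
  basis <- build_basis(p, quartet_pops,
                       options = estimator_options(bias_correction = TRUE))
  fit <- fit_graph(basis, scenario_topology("quartet_mixe"),
                   fit_options(n_restarts = 2))
  rr <- residual_report(fit, p, estimator_options(bias_correction = TRUE))
  expect_identical(nrow(rr), 6L + 12L + 3L)      # f2 + f3 + f4 rows
  expect_true(!is.unsorted(rev(abs(rr$z))))      # |Z| descending

  # a misspecified split order implicates the swapped populations at the top
  p5 <- simulate_panel(scenario_spec("five_ulchi", seed = 5))
  b5 <- build_basis(p5, c("Baka", "French", "Han", "Mixe", "Ulchi"),
                    options = estimator_options(bias_correction = TRUE))
  fs <- fit_graph(b5, scenario_topology("five_ulchi", "swapped"),
                  fit_options(n_restarts = 2))
  rs <- residual_report(fs, p5, estimator_options(bias_correction = TRUE))
  expect_true(grepl("Han|Ulchi", rs$statistic[1]))
})

test_that("identifiability analysis reproduces the rank structure of the
           worked topologies", {
  r4 <- identifiability_report(scenario_topology("quartet_mixe"), seed = 2)
  expect_identical(r4$rank, 6L)
  expect_identical(r4$n_free_theoretical, 7)
  expect_true(r4$underdetermined)
  expect_identical(r4$compound, "pAM")
  expect_gt(length(r4$null_space), 0L)

  r5 <- identifiability_report(scenario_topology("five_ulchi"), seed = 2)
  expect_identical(r5$rank, 9L)
  expect_identical(r5$n_free_theoretical, 9)
  expect_false(r5$underdetermined)

  # sister leaves (French/Hungarian) contribute redundant constraints
  rh <- identifiability_report(scenario_topology("five_hungarian"),
                               seed = 2)
  expect_lt(rh$rank, r5$rank)
  expect_true(rh$underdetermined)
})

test_that("profile curves bound the unconstrained optimum", {
  p <- simulate_panel(scenario_spec("quartet_mixe", n_snps = 20000,
                                    seed = 12))
  basis <- build_basis(p, quartet_pops,
                       options = estimator_options(bias_correction = TRUE))
  topo <- scenario_topology("quartet_mixe")
  prof <- profile_parameter(basis, topo, "pAM", c(0.3, 0.5, 0.7),
                            fit_options(n_restarts = 2))
  expect_gte(min(prof$score), attr(prof, "score_min") - 1e-9)
  expect_error(profile_parameter(basis, topo, "nope", 0.5), "unknown")
})

test_that("model comparisons demand a shared basis and prefer the lower
           score", {
  p <- simulate_panel(scenario_spec("five_ulchi", n_snps = 40000, seed = 13))
  pops <- c("Baka", "French", "Han", "Mixe", "Ulchi")
  basis <- build_basis(p, pops,
                       options = estimator_options(bias_correction = TRUE))
  f_ok <- fit_graph(basis, scenario_topology("five_ulchi"),
                    fit_options(n_restarts = 2))
  f_sw <- fit_graph(basis, scenario_topology("five_ulchi", "swapped"),
                    fit_options(n_restarts = 2))
  cmp <- compare_models(f_ok, f_sw)
  expect_identical(cmp$preferred, "A")
  expect_lt(cmp$difference, 0)
  expect_identical(compare_models(f_ok, f_ok)$difference, 0)

  p2 <- simulate_panel(scenario_spec("five_ulchi", n_snps = 20000,
                                     seed = 14))
  basis2 <- build_basis(p2, pops,
                        options = estimator_options(bias_correction = TRUE))
  f_other <- fit_graph(basis2, scenario_topology("five_ulchi"),
                       fit_options(n_restarts = 2))
  expect_error(compare_models(f_ok, f_other), "not comparable")
  expect_error(compare_models(f_ok, lsq_fit(basis, scenario_topology("five_ulchi"),
                                            fit_options(n_restarts = 2))),
               "not comparable")
})

test_that("trifurcation scanning lists collapsed internal branches only", {
  g <- admixkit:::graph_five_ulchi()
  expect_identical(nrow(trifurcation_scan(g)), 0L)
  g0 <- g
  g0$edges$length[] <- 0
  tz <- trifurcation_scan(g0)
  # internal, non-root, non-stub edges: west, east, east2
  expect_setequal(tz$name, c("west", "east", "east2"))

  basis <- exact_basis(g, base_pop = "Baka")
  fit <- fit_graph(basis, free_topology(g), fit_options(n_restarts = 3))
  expect_identical(nrow(trifurcation_scan(fit)), 0L)
})

test_that("fit rejects mismatched topologies and leaves", {
  p <- random_panel(15, pops = quartet_pops, n_blocks = 4)
  basis <- build_basis(p, quartet_pops)
  expect_error(fit_graph(basis, scenario_topology("five_ulchi")),
               "must equal the basis populations")
})
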