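test_that("f4, f2, f3 and D reproduce hand-computed values", {
  p <- panel_from_freqs(list(A = c(0.5, 0.2, 0.9), B = c(0.1, 0.2, 0.3),
                             C = c(0.4, 0.8, 0.5), D = c(0.2, 0.6, 0.5)))
  # per-site products 0.08, 0, 0
  expect_equal(compute_f4(p, "A", "B", "C", "D")$value, 0.08 / 3,
               tolerance = 1e-12)

  p1 <- panel_from_freqs(list(A = 0.5, B = 0.1, C = 0.9))
  expect_equal(compute_f2(p1, "A", "B")$value, 0.16, tolerance = 1e-12)
  expect_equal(compute_f3(p1, "A", "B", "C")$value, -0.16, tolerance = 1e-12)

  # heterozygosity correction with 2 diploids (4 alleles) per population
  p2 <- panel_from_freqs(list(A = 0.5, B = 0.1), counts = 4)
  corr <- compute_f2(p2, "A", "B", estimator_options(bias_correction = TRUE))
  expect_equal(corr$value, 0.16 - (0.25 * 4 / 3) / 4 - (0.09 * 4 / 3) / 4,
               tolerance = 1e-12)

  pd <- panel_from_freqs(list(A = 1, B = 0, C = 1, D = 0))
  expect_equal(compute_d(pd, "A", "B", "C", "D")$value, 1, tolerance = 1e-12)
})

test_that("degenerate inputs give exact zeros and informative errors", {
  p <- panel_from_freqs(list(A = c(0.4, 0.6), B = c(0.4, 0.6),
                             C = c(0.1, 0.9), D = c(0.5, 0.5)),
                        block = c(1, 2))
  r <- compute_f4(p, "A", "B", "C", "D")
  expect_identical(r$value, 0)
  expect_identical(r$se, 0)
  expect_true(is.na(r$z))

  expect_error(compute_f4(p, "A", "B", "C", "Z"), "Z")
  fr <- cbind(A = c(0.5, NA), B = c(NA, 0.5))
  ct <- cbind(A = c(2, 0), B = c(0, 2))
  p2 <- freq_panel(fr, ct, block = c(1, 2))
  expect_error(compute_f4(p2, "A", "B", "A", "B"), "no overlapping sites")
})

test_that("the five linear identities hold to 1e-12 on random panels", {
  for (seed in 1:25) {
    p <- random_panel(seed)
    v <- function(...) compute_f4(p, ...)$value
    f3v <- function(...) compute_f3(p, ...)$value
    expect_equal(v("A", "B", "C", "D"), v("C", "D", "A", "B"),
                 tolerance = 1e-12)
    expect_equal(v("A", "B", "C", "D"), -v("B", "A", "C", "D"),
                 tolerance = 1e-12)
    expect_equal(v("A", "B", "C", "D"), -v("A", "B", "D", "C"),
                 tolerance = 1e-12)
    expect_equal(v("A", "B", "C", "D"),
                 v("A", "C", "B", "D") + v("A", "D", "C", "B"),
                 tolerance = 1e-12)
    expect_equal(v("A", "B", "C", "D"),
                 f3v("A", "B", "D") - f3v("A", "B", "C"),
                 tolerance = 1e-12)
    # definitional special cases
    expect_equal(compute_f2(p, "A", "B")$value, v("A", "B", "A", "B"),
                 tolerance = 1e-12)
    expect_equal(f3v("A", "B", "C"), v("A", "B", "A", "C"),
                 tolerance = 1e-12)
  }
})

test_that("uncorrected f2 is non-negative and f3 is negative for an
           intermediate first population", {
  for (seed in 26:35) {
    p <- random_panel(seed)
    expect_gte(compute_f2(p, "A", "B")$value, 0)
  }
  set.seed(99)
  b <- runif(50, 0.05, 0.3)
  c_ <- runif(50, 0.7, 0.95)
  a <- (b + c_) / 2
  p <- panel_from_freqs(list(A = a, B = b, C = c_))
  expect_lt(compute_f3(p, "A", "B", "C")$value, 0)
})

test_that("adding sites fixed across populations shrinks f4 toward zero", {
  p <- random_panel(3, n = 40)
  v1 <- abs(compute_f4(p, "A", "B", "C", "D")$value)
  fixed <- matrix(0.5, 40, 4, dimnames = list(NULL, p$pops))
  p2 <- freq_panel(rbind(p$freq, fixed), rbind(p$count, p$count),
                   block = rep(1L, 80))
  v2 <- abs(compute_f4(p2, "A", "B", "C", "D")$value)
  expect_lt(v2, v1)
  expect_equal(v2, v1 / 2, tolerance = 1e-12)
})

test_that("block jackknife matches the leave-one-out oracle", {
  # two equal blocks with per-block means 0.1 and 0.3 (10 sites each):
  # leave-one-out estimates 0.3 and 0.1, SE = sqrt(((m-1)/m) sum dev^2)
  jk <- block_jackknife(sums = c(1.0, 3.0), weights = c(10, 10))
  expect_equal(jk$estimate, 0.2, tolerance = 1e-12)
  expect_equal(jk$se, 0.1, tolerance = 1e-12)
  expect_equal(jk$loo, c(0.3, 0.1), tolerance = 1e-12)

  # identical blocks: zero SE; doubling scales estimate and SE linearly
  expect_equal(block_jackknife(c(2, 2, 2), c(10, 10, 10))$se, 0)
  jk2 <- block_jackknife(c(2.0, 6.0), c(10, 10))
  expect_equal(jk2$estimate, 2 * jk$estimate, tolerance = 1e-12)
  expect_equal(jk2$se, 2 * jk$se, tolerance = 1e-12)

  expect_error(block_jackknife(1, 10), "at least 2")
  # unequal weights agree with a direct implementation of the weighted
  # jackknife variance formula
  sums <- c(0.4, 1.1, 0.2)
  w <- c(4, 10, 2)
  jk3 <- block_jackknife(sums, w)
  n <- sum(w); est <- sum(sums) / n
  loo <- (sum(sums) - sums) / (n - w)
  h <- n / w
  tau <- h * est - (h - 1) * loo
  tj <- 3 * est - sum((1 - w / n) * loo)
  expect_equal(jk3$se, sqrt(mean((tau - tj)^2 / (h - 1))), tolerance = 1e-12)
})

test_that("jackknife covariance is consistent with per-statistic errors", {
  p <- random_panel(11, n = 200, n_blocks = 8)
  stats <- list(c("A", "B"), c("A", "C"), c("A", "B", "C"),
                c("A", "B", "C", "D"), c("A", "B"))
  Q <- jackknife_covariance(p, stats)
  expect_true(isSymmetric(Q))
  expect_gte(min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values),
             -1e-15)
  expect_equal(Q[1, 1], compute_f2(p, "A", "B")$se^2, tolerance = 1e-12)
  expect_equal(Q[4, 4], compute_f4(p, "A", "B", "C", "D")$se^2,
               tolerance = 1e-12)
  # duplicated statistic: perfectly correlated block
  expect_equal(Q[1, 5], Q[1, 1], tolerance = 1e-12)
  expect_equal(Q[5, 5], Q[1, 1], tolerance = 1e-12)
})

test_that("D matches f4 in sign and handles the degenerate denominator", {
  for (seed in 40:45) {
    p <- random_panel(seed)
    f4 <- compute_f4(p, "A", "B", "C", "D")$value
    d <- compute_d(p, "A", "B", "C", "D")$value
    expect_identical(sign(d), sign(f4))
  }
  pfix <- panel_from_freqs(list(A = c(1, 1), B = c(0, 0), C = c(1, 1),
                                D = c(1, 1)), block = c(1, 2))
  expect_error(compute_d(pfix, "A", "A", "C", "D"), "denominator")
})

test_that("quartet_report uses one SNP set and satisfies the permutation
           identity", {
  p <- random_panel(7)
  qr <- quartet_report(p, "A", "B", "C", "D")
  v <- vapply(qr$stats, function(s) s$value, numeric(1))
  # f4(A,B;C,D) = f4(A,C;B,D) + f4(A,D;C,B) = v2 - v3
  expect_equal(v[1], v[2] - v[3], tolerance = 1e-14)
  qr2 <- quartet_report(p, "A", "B", "D", "C")
  expect_equal(qr2$stats[[1]]$value, -v[1], tolerance = 1e-14)
  expect_identical(vapply(qr$stats, function(s) s$n_snps, integer(1)),
                   rep(nrow(p$freq), 3L))
})

test_that("simulated unadmixed quartets do not trigger the admixture flag", {
  tree <- admixture_graph(data.frame(
    parent = c("R", "R", "P", "P", "Q", "Q"),
    child = c("P", "Q", "A", "B", "C", "D"),
    length = c(0.005, 0.005, 0.004, 0.004, 0.004, 0.004)))
  p <- simulate_panel(sim_spec(tree, 1e5, 50, seed = 9))
  qr <- quartet_report(p, "A", "B", "C", "D")
  expect_lt(abs(qr$stats[[1]]$z), 3)       # E f4(A,B;C,D) = 0 on this tree
  expect_false(qr$admixture_implied)
})
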