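#' Build the basis system of f-statistics for graph fitting
#'
#' The f-statistics on `n` populations span a space of dimension
#' `choose(n, 2)`; one convenient basis is the `n - 1` statistics
#' `f2(base, X)` plus the `choose(n - 1, 2)` statistics `f3(base; X, Y)`
#' anchored at a base population.  All are computed on one shared SNP set
#' (sites with data in every model population), with the jackknife
#' covariance matrix `Q` estimated from common leave-one-block-out
#' replicates.  A small relative ridge is added to stabilize the inverse:
#' `diag_reg` (default 0.0001) times the mean diagonal of `Q`.  The ridge
#' is dimensionless so that scores keep their log-likelihood scale
#' regardless of the magnitude of the statistics.
#'
#' @param panel A [freq_panel()] with blocks assigned.
#' @param populations Populations to model (order fixes the basis order).
#' @param base_pop The anchor population; defaults to the first.
#' @param options An [estimator_options()] list.
#' @param diag_reg Ridge added to `diag(Q)`.
#' @return An object of class `basis_system` with fields `base_pop`,
#'   `pops`, `stats` (list of population tuples), `labels`, `f_obs`, `Q`,
#'   `Q_reg`, `diag_reg`, `n_snps`, `n_blocks`.
#' @export
build_basis <- function(panel, populations, base_pop = populations[1],
                        options = estimator_options(), diag_reg = 1e-4) {
  check_pops(panel, populations)
  if (!base_pop %in% populations)
    stop("base_pop must be one of `populations`")
  if (diag_reg < 0) stop("diag_reg must be >= 0")
  others <- setdiff(populations, base_pop)
  stats <- c(lapply(others, function(x) c(base_pop, x)),
             utils::combn(others, 2L, simplify = FALSE) |>
               lapply(function(xy) c(base_pop, xy[1], xy[2])))
  sys <- fstat_block_system(panel, stats, options)
  Q_reg <- sys$Q + diag(diag_reg * mean(diag(sys$Q)), nrow(sys$Q))
  structure(list(base_pop = base_pop, pops = c(base_pop, others),
                 stats = stats, labels = sys$labels,
                 f_obs = unname(sys$estimates), Q = sys$Q, Q_reg = Q_reg,
                 diag_reg = diag_reg, n_snps = sys$n_snps,
                 n_blocks = sys$n_blocks),
            class = "basis_system")
}

#' @export
print.basis_system <- function(x, ...) {
  cat("basis_system: base", x$base_pop, "with", length(x$stats),
      "statistics on", paste(x$pops, collapse = ", "), "\n")
  cat(sprintf("  %d SNPs, %d blocks, diag_reg %g\n", x$n_snps[1],
              x$n_blocks, x$diag_reg))
  invisible(x)
}

#' A basis system from exact expected values (noise-free)
#'
#' Builds a `basis_system` whose observed vector is the exact expectation
#' under a graph, with identity covariance.  Useful for self-consistency
#' checks: fitting the generating topology must reach score zero.
#'
#' @param graph A fully parameterized [admixture_graph()].
#' @param base_pop Anchor population (defaults to first leaf).
#' @return A `basis_system`.
#' @export
exact_basis <- function(graph, base_pop = graph$leaves[1]) {
  others <- setdiff(graph$leaves, base_pop)
  stats <- c(lapply(others, function(x) c(base_pop, x)),
             utils::combn(others, 2L, simplify = FALSE) |>
               lapply(function(xy) c(base_pop, xy[1], xy[2])))
  W <- branch_weights(graph)
  f <- vapply(stats, function(s) {
    q <- as_quadruple(s)
    sum(f4_coefficients(W, q[1], q[2], q[3], q[4]) * graph$edges$length)
  }, numeric(1))
  labels <- vapply(stats, function(p) {
    fstat_label(c("f2", "f3", "f4")[length(p) - 1L], p)
  }, character(1))
  k <- length(stats)
  structure(list(base_pop = base_pop, pops = c(base_pop, others),
                 stats = stats, labels = labels, f_obs = f,
                 Q = diag(k), Q_reg = diag(k), diag_reg = 0,
                 n_snps = NA_integer_, n_blocks = NA_integer_),
            class = "basis_system")
}

# Non-negative least squares (Lawson-Hanson active set).  The inner
# solves use an SVD pseudoinverse because admixture-graph designs are
# routinely rank-deficient: the branches around an admixture event with
# unsampled sources have exactly proportional columns (the compound
# parameter), and the minimum-norm solution distributes such compound
# mass smoothly instead of failing.
nnls_solve <- function(A, b, max_iter = 10L * ncol(A) + 50L) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  pinv_ls <- function(M, y) {
    s <- svd(M)
    r <- sum(s$d > max(s$d[1], 1e-300) * 1e-12)
    if (r == 0) return(numeric(ncol(M)))
    s$v[, 1:r, drop = FALSE] %*%
      ((t(s$u[, 1:r, drop = FALSE]) %*% y) / s$d[1:r])
  }
  tol <- 1e-10 * max(abs(crossprod(A, b)), 1e-300)
  it <- 0L
  repeat {
    w <- as.vector(crossprod(A, b - A %*% x))
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(x = x, converged = FALSE))
      z <- numeric(n)
      z[passive] <- pinv_ls(A[, passive, drop = FALSE], b)
      if (all(z[passive] > 0)) break
      neg <- passive & z <= 0
      ratio <- x[neg] / (x[neg] - z[neg])
      ratio[!is.finite(ratio)] <- 0
      step <- min(ratio)
      x <- x + step * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    x <- z
  }
  list(x = x, converged = TRUE)
}

# Design matrix: rows = basis statistics, cols = drift edges, entries =
# expected-f coefficients at the graph's current admixture proportions.
basis_design <- function(graph, stats) {
  W <- branch_weights(graph)
  t(vapply(stats, function(s) {
    q <- as_quadruple(s)
    f4_coefficients(W, q[1], q[2], q[3], q[4])
  }, numeric(nrow(graph$edges))))
}

#' Options controlling graph fitting
#'
#' @param n_restarts Number of seeded restarts for the admixture
#'   proportion search.
#' @param seed Seed for the restart draws.
#' @param lsq Replace `Q` by the identity (simple least squares).  The
#'   resulting score is in different units and is not a log-likelihood;
#'   correlated statistics are treated as independent, so the full
#'   generalized objective is preferable.
#' @param fixed Named list of parameters to hold fixed: drift edge names
#'   mapped to lengths, or `alpha:<node>` (or the admixture node name)
#'   mapped to proportions.  Used by [profile_parameter()].
#' @param alpha_grid Number of grid points for the initial proportion
#'   scan.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_restarts = 10L, seed = 1L, lsq = FALSE,
                        fixed = list(), alpha_grid = 21L) {
  stopifnot(n_restarts >= 1L)
  structure(list(n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), lsq = isTRUE(lsq), fixed = fixed,
                 alpha_grid = as.integer(alpha_grid)),
            class = "fit_options")
}

#' Fit an admixture graph to observed f-statistics
#'
#' Minimizes the score `S(G) = 1/2 (g - f)' Q^-1 (g - f)` over branch
#' lengths (>= 0) and admixture proportions (in \[0, 1\]), where `f` is
#' the observed basis vector, `g` the model prediction and `Q` the
#' (ridge-regularized) jackknife covariance.  Under multivariate normal
#' errors the score is the model's negative log-likelihood up to a
#' constant.  Because `g` is linear in the branch lengths at fixed
#' proportions, the inner problem is solved exactly by non-negative
#' generalized least squares; the proportions are then optimized by a
#' bounded derivative-free search with seeded restarts.
#'
#' @param basis A [build_basis()] (or [exact_basis()]) system.
#' @param topology An [admixture_graph()] whose leaves are the basis
#'   populations; `NA` lengths/proportions are fitted, fixed values kept.
#' @param options A [fit_options()] list.
#' @return An object of class `admix_fit` with the fitted `graph`,
#'   `score`, basis-level `residuals` table, `identifiability` report,
#'   `converged`, `n_restarts_used` and the basis metadata.
#' @seealso [residual_report()], [profile_parameter()],
#'   [trifurcation_scan()], [compare_models()]
#' @export
fit_graph <- function(basis, topology, options = fit_options()) {
  stopifnot(inherits(basis, "basis_system"),
            inherits(topology, "admixture_graph"))
  if (!setequal(topology$leaves, basis$pops))
    stop("topology leaves (", paste(sort(topology$leaves), collapse = ", "),
         ") must equal the basis populations (",
         paste(sort(basis$pops), collapse = ", "), ")")

  f_obs <- basis$f_obs
  k <- length(f_obs)
  if (options$lsq) {
    wh <- function(M) M
  } else {
    R <- tryCatch(chol(basis$Q_reg),
                  error = function(e)
                    stop("regularized covariance is not positive definite; ",
                         "increase diag_reg", call. = FALSE))
    wh <- function(M) backsolve(R, M, transpose = TRUE)
  }
  b_full <- wh(matrix(f_obs, ncol = 1))

  g0 <- topology
  e <- g0$edges
  a <- g0$admix
  fixed <- options$fixed
  # apply fixed values from options
  for (nm in names(fixed)) {
    if (nm %in% e$name) {
      e$length[e$name == nm] <- fixed[[nm]]
    } else {
      anode <- sub("^alpha:", "", nm)
      if (anode %in% a$child) a$alpha[a$child == anode] <- fixed[[nm]]
      else stop("fixed parameter '", nm, "' matches no edge or admixture node")
    }
  }
  free_len <- is.na(e$length)
  free_alpha <- if (nrow(a)) is.na(a$alpha) else logical(0)
  n_free_a <- sum(free_alpha)

  eval_at <- function(avec) {
    if (n_free_a) a$alpha[free_alpha] <- avec
    g <- g0
    g$admix <- a
    X <- basis_design(g, basis$stats)
    A <- wh(X)
    b <- b_full
    if (any(!free_len))
      b <- b - A[, !free_len, drop = FALSE] %*%
        matrix(e$length[!free_len], ncol = 1)
    if (any(free_len)) {
      Af <- A[, free_len, drop = FALSE]
      sol <- nnls_solve(Af, as.vector(b))
      lens <- e$length
      lens[free_len] <- sol$x
    } else {
      lens <- e$length
    }
    resid <- as.vector(b) -
      if (any(free_len)) Af %*% sol$x else 0
    list(score = 0.5 * sum(resid^2), lengths = lens, alpha = a$alpha,
         X = X)
  }

  set.seed(options$seed)
  if (n_free_a == 0L) {
    best <- eval_at(numeric(0))
    restarts_used <- 1L
    converged <- TRUE
  } else {
    obj <- function(av) eval_at(pmin(pmax(av, 0), 1))$score
    cands <- list()
    if (n_free_a == 1L) {
      grid <- seq(0, 1, length.out = max(options$alpha_grid, 5L))
      sg <- vapply(grid, obj, numeric(1))
      i0 <- which.min(sg)
      lo <- grid[max(1L, i0 - 1L)]
      hi <- grid[min(length(grid), i0 + 1L)]
      o <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
      cands[[1]] <- o$minimum
      for (r in seq_len(options$n_restarts - 1L)) {
        u <- stats::runif(1)
        o2 <- stats::optimize(obj, c(max(0, u - 0.25), min(1, u + 0.25)),
                              tol = 1e-10)
        cands[[r + 1L]] <- o2$minimum
      }
      converged <- TRUE
    } else {
      starts <- c(list(rep(0.5, n_free_a)),
                  lapply(seq_len(options$n_restarts - 1L),
                         function(i) stats::runif(n_free_a)))
      conv <- logical(0)
      for (s in starts) {
        o <- stats::optim(s, obj, method = "Nelder-Mead",
                          control = list(maxit = 500L, reltol = 1e-12))
        cands[[length(cands) + 1L]] <- pmin(pmax(o$par, 0), 1)
        conv <- c(conv, o$convergence == 0L)
      }
      converged <- any(conv)
    }
    restarts_used <- length(cands)
    evals <- lapply(cands, function(av) eval_at(pmin(pmax(av, 0), 1)))
    scores <- vapply(evals, `[[`, numeric(1), "score")
    best_score <- min(scores)
    near <- which(scores <= best_score + 1e-12)
    # reproducible tie-break: lexicographically smallest parameter vector
    if (length(near) > 1L) {
      key <- vapply(evals[near], function(ev)
        paste(sprintf("%.12f", c(ev$alpha, ev$lengths)), collapse = ","),
        character(1))
      near <- near[order(key)][1L]
    }
    best <- evals[[near[1L]]]
  }

  fitted <- g0
  fitted$edges$length <- best$lengths
  if (nrow(a)) fitted$admix$alpha <- best$alpha
  g_pred <- as.vector(best$X %*% best$lengths)
  se <- sqrt(diag(basis$Q))
  resid_tab <- data.frame(statistic = basis$labels, observed = f_obs,
                          predicted = g_pred, se = se,
                          z = ifelse(se > 0, (f_obs - g_pred) / se, NA),
                          stringsAsFactors = FALSE)
  structure(list(graph = fitted, score = best$score, residuals = resid_tab,
                 identifiability = identifiability_report(topology,
                                                          seed = options$seed,
                                                          base_pop =
                                                            basis$base_pop),
                 converged = converged, n_restarts_used =
                   if (n_free_a) restarts_used else 1L,
                 lsq = options$lsq, basis_info = basis_fingerprint(basis),
                 options = options),
            class = "admix_fit")
}

basis_fingerprint <- function(basis) {
  list(base_pop = basis$base_pop, pops = basis$pops, labels = basis$labels,
       f_obs = basis$f_obs, n_snps = basis$n_snps,
       n_blocks = basis$n_blocks)
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("admix_fit: score %.6g (%s)%s\n", x$score,
              if (x$lsq) "least-squares units" else
                "negative log-likelihood up to constant",
              if (x$converged) "" else "  [NOT converged]"))
  worst <- x$residuals[which.max(abs(x$residuals$z)), ]
  if (nrow(worst) && !is.na(worst$z))
    cat(sprintf("  worst basis residual: %s Z = %.2f\n", worst$statistic,
                worst$z))
  if (nrow(x$graph$admix))
    for (i in seq_len(nrow(x$graph$admix)))
      cat(sprintf("  alpha(%s) = %.3f\n", x$graph$admix$child[i],
                  x$graph$admix$alpha[i]))
  invisible(x)
}

#' Simple least-squares fit (no covariance weighting)
#'
#' Identical optimization to [fit_graph()] with `Q` replaced by the
#' identity.  Scores are in squared f-statistic units, are not
#' log-likelihoods and are not comparable with generalized scores;
#' correlated statistics are treated as independent.  Provided for
#' completeness; the generalized objective is preferable.
#'
#' @inheritParams fit_graph
#' @return An `admix_fit` with `lsq = TRUE`.
#' @export
lsq_fit <- function(basis, topology, options = fit_options()) {
  options$lsq <- TRUE
  fit_graph(basis, topology, options)
}

#' Full residual table for a fitted graph
#'
#' Recomputes every f-statistic on the model populations — all
#' `choose(n,2)` f2, `3 choose(n,3)` f3 (three orderings of the first
#' position per triple) and `3 choose(n,4)` f4 (three pairings per
#' quartet) — on the shared SNP set, compares each with its prediction
#' under the fitted graph, and reports Z-scores using the observed
#' statistic's jackknife standard error (a documented approximation to
#' the residual's standard error).  Sorted by |Z| descending, ties broken
#' lexicographically by statistic label.
#'
#' @param fit An `admix_fit`.
#' @param panel The panel the basis was built from.
#' @param options The [estimator_options()] used for the basis.
#' @return A data frame of class `residual_table` with columns
#'   `statistic`, `observed`, `predicted`, `se`, `z`.
#' @export
residual_report <- function(fit, panel, options = estimator_options()) {
  stopifnot(inherits(fit, "admix_fit"))
  g <- fit$graph
  pops <- sort(g$leaves)
  stats <- all_fstat_tuples(pops)
  sys <- fstat_block_system(panel, stats, options)
  W <- branch_weights(g)
  pred <- vapply(stats, function(s) {
    q <- as_quadruple(s)
    sum(f4_coefficients(W, q[1], q[2], q[3], q[4]) * g$edges$length)
  }, numeric(1))
  se <- sqrt(diag(sys$Q))
  z <- ifelse(se > 0, (sys$estimates - pred) / se, NA_real_)
  tab <- data.frame(statistic = sys$labels, observed = unname(sys$estimates),
                    predicted = pred, se = se, z = z,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$z), tab$statistic), ]
  rownames(tab) <- NULL
  class(tab) <- c("residual_table", "data.frame")
  tab
}

all_fstat_tuples <- function(pops) {
  n <- length(pops)
  out <- list()
  for (pr in utils::combn(pops, 2L, simplify = FALSE))
    out[[length(out) + 1L]] <- pr
  if (n >= 3L) for (tr in utils::combn(pops, 3L, simplify = FALSE))
    for (i in 1:3)
      out[[length(out) + 1L]] <- c(tr[i], tr[-i])
  if (n >= 4L) for (qd in utils::combn(pops, 4L, simplify = FALSE)) {
    out[[length(out) + 1L]] <- qd
    out[[length(out) + 1L]] <- qd[c(1, 3, 2, 4)]
    out[[length(out) + 1L]] <- qd[c(1, 4, 2, 3)]
  }
  out
}

#' Numerical identifiability analysis of a topology
#'
#' Evaluates the Jacobian of the predicted basis vector with respect to
#' all graph parameters (every drift-edge length and admixture
#' proportion) at a random interior parameter point, and reports its
#' numerical rank (singular values below `tol_factor` times the largest
#' count as zero).  A rank below the theoretical free-parameter count
#' `2n + 2a - 3` means some parameter combinations are not determined by
#' f-statistics; the null-space basis is reported as readable parameter
#' combinations, and admixture events whose surrounding branches collapse
#' into the compound `alpha^2 x + (1-alpha)^2 y + z` are flagged.
#'
#' @param topology An [admixture_graph()].
#' @param at Optional list with `lengths` and `alpha` giving the
#'   evaluation point; otherwise drawn uniformly (lengths in
#'   \[0.01, 0.05\], proportions in \[0.2, 0.8\]) under `seed`.
#' @param seed Seed for the random evaluation point.
#' @param base_pop Basis anchor (defaults to the first leaf).
#' @param tol_factor Relative singular-value tolerance for the rank.
#' @return A list of class `identifiability_report`.
#' @export
identifiability_report <- function(topology, at = NULL, seed = 1L,
                                   base_pop = topology$leaves[1],
                                   tol_factor = 1e-9) {
  g <- topology
  n_e <- nrow(g$edges)
  n_a <- nrow(g$admix)
  set.seed(seed)
  lens <- if (!is.null(at$lengths)) at$lengths else
    stats::runif(n_e, 0.01, 0.05)
  alph <- if (!is.null(at$alpha)) at$alpha else
    if (n_a) stats::runif(n_a, 0.2, 0.8) else numeric(0)
  g$edges$length <- lens
  if (n_a) g$admix$alpha <- alph
  others <- setdiff(g$leaves, base_pop)
  stats <- c(lapply(others, function(x) c(base_pop, x)),
             utils::combn(others, 2L, simplify = FALSE) |>
               lapply(function(xy) c(base_pop, xy[1], xy[2])))
  X <- basis_design(g, stats)          # d g / d lengths (exact: g linear)
  J <- X
  if (n_a) {
    h <- 1e-6
    for (j in seq_len(n_a)) {
      gp <- g; gm <- g
      gp$admix$alpha[j] <- min(1, alph[j] + h)
      gm$admix$alpha[j] <- max(0, alph[j] - h)
      dg <- (basis_design(gp, stats) %*% lens -
             basis_design(gm, stats) %*% lens) /
        (gp$admix$alpha[j] - gm$admix$alpha[j])
      J <- cbind(J, dg)
    }
  }
  colnames(J) <- c(g$edges$name,
                   if (n_a) paste0("alpha:", g$admix$child))
  sv <- svd(J, nu = 0, nv = ncol(J))
  tol <- tol_factor * max(sv$d)
  rank <- sum(sv$d > tol)
  null_dim <- ncol(J) - rank
  null_space <- list()
  if (null_dim > 0) {
    V <- sv$v[, seq.int(ncol(J) - null_dim + 1L, ncol(J)), drop = FALSE]
    for (j in seq_len(null_dim)) {
      v <- V[, j]
      v[abs(v) < 1e-8] <- 0
      null_space[[j]] <- setNames(round(v, 6), colnames(J))[v != 0]
    }
  }
  cp <- count_parameters(topology)
  structure(list(rank = rank, n_params = ncol(J),
                 n_free_theoretical = cp$n_free_parameters,
                 n_constraints = cp$n_constraints,
                 underdetermined = rank < cp$n_free_parameters,
                 compound = cp$compound_reductions,
                 null_space = null_space, singular_values = sv$d,
                 base_pop = base_pop),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat(sprintf(paste0("identifiability: Jacobian rank %d of %d raw ",
                     "parameters (theoretical free count %d, constraints ",
                     "%d)\n"),
              x$rank, x$n_params, x$n_free_theoretical, x$n_constraints))
  if (x$underdetermined)
    cat("  UNDERDETERMINED: rank below the theoretical free-parameter count\n")
  if (length(x$compound))
    cat("  compound parameter around admixture node(s):",
        paste(x$compound, collapse = ", "), "\n")
  if (length(x$null_space)) {
    cat("  undetermined parameter combinations:\n")
    for (v in x$null_space)
      cat("   ", paste(sprintf("%+.3g*%s", v, names(v)), collapse = " "),
          "\n")
  }
  invisible(x)
}

#' Profile the score along one parameter
#'
#' Re-fits all other parameters with the named parameter fixed at each
#' grid value and returns the score curve.  A flat stretch of the curve
#' marks a non-identifiable interval (the likelihood is constant there);
#' a single clear minimum marks an identified parameter, and the curve
#' can be read as a profile likelihood for confidence intervals.
#'
#' @param basis A [build_basis()] system.
#' @param topology The [admixture_graph()] to fit.
#' @param parameter A drift edge name, an admixture node name, or
#'   `"alpha:<node>"`.
#' @param grid Numeric vector of values at which to fix the parameter.
#' @param options A [fit_options()] list.
#' @return A data frame of class `score_profile` with columns `value` and
#'   `score`; the unconstrained fit's score is attached as attribute
#'   `score_min`.
#' @export
profile_parameter <- function(basis, topology, parameter, grid,
                              options = fit_options()) {
  key <- parameter
  if (key %in% topology$admix$child) key <- paste0("alpha:", key)
  plain <- sub("^alpha:", "", key)
  if (!(sub("^alpha:", "", key) %in% topology$admix$child ||
        key %in% topology$edges$name))
    stop("unknown parameter '", parameter, "' (no such edge or admixture ",
         "node)")
  scores <- vapply(grid, function(v) {
    op <- options
    op$fixed[[key]] <- v
    fit_graph(basis, topology, op)$score
  }, numeric(1))
  free_fit <- fit_graph(basis, topology, options)
  out <- data.frame(value = grid, score = scores)
  attr(out, "score_min") <- free_fit$score
  class(out) <- c("score_profile", "data.frame")
  out
}

#' Compare the fit of two models on the same basis
#'
#' Reports the score difference between two fits of the same populations
#' on the same basis (same base population and SNP set).  The lower score
#' is preferred; with equal numbers of admixture events the difference
#' can be read as a log-likelihood-ratio-style heuristic.  Naive
#' chi-squared p-values for such comparisons are "not well calibrated"
#' (the basis statistics are heavily correlated), so none are produced.
#'
#' @param fitA,fitB `admix_fit` objects from [fit_graph()].
#' @return A list of class `model_comparison` with `score_A`, `score_B`,
#'   `difference` (A minus B), `preferred`, and the admixture-event
#'   counts.
#' @export
compare_models <- function(fitA, fitB) {
  stopifnot(inherits(fitA, "admix_fit"), inherits(fitB, "admix_fit"))
  a <- fitA$basis_info
  b <- fitB$basis_info
  if (fitA$lsq != fitB$lsq)
    stop("scores are not comparable: one fit is least-squares, the other ",
         "generalized")
  if (!identical(a$base_pop, b$base_pop) || !setequal(a$pops, b$pops) ||
      !identical(a$n_snps, b$n_snps) || !isTRUE(all.equal(a$f_obs, b$f_obs)))
    stop("fits are not comparable: they use different basis systems ",
         "(base population, populations or SNP set differ)")
  na <- nrow(fitA$graph$admix)
  nb <- nrow(fitB$graph$admix)
  structure(list(score_A = fitA$score, score_B = fitB$score,
                 difference = fitA$score - fitB$score,
                 preferred = if (fitA$score <= fitB$score) "A" else "B",
                 n_admix_A = na, n_admix_B = nb,
                 same_complexity = na == nb),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("model comparison: score A = %.6g, score B = %.6g (diff %+.6g)\n",
              x$score_A, x$score_B, x$difference))
  cat("  preferred (lower score):", x$preferred, "\n")
  if (!x$same_complexity)
    cat("  note: different numbers of admixture events; the change in\n",
        "  degrees of freedom is not straightforward and no significance\n",
        "  is implied\n")
  cat("  (score-difference p-values are not well calibrated; none given)\n")
  invisible(x)
}

#' Detect collapsed internal branches (trifurcations)
#'
#' An incorrectly specified split order usually shows up as an internal
#' branch fitted to length zero: the optimizer pushes the populations as
#' close as possible to their correct positions but is constrained by the
#' topology.  This scans the fitted graph for internal drift edges below
#' `tolerance` (default 1e-6 f-units).  Terminal edges, edges out of the
#' root (whose individual lengths are not root-invariant) and stub edges
#' into unsampled admixture sources (members of compound parameters) are
#' not scanned.
#'
#' @param fit An `admix_fit`, or an [admixture_graph()] with lengths.
#' @param tolerance Length below which a branch counts as collapsed.
#' @return A data frame of class `trifurcation_scan` (possibly empty)
#'   with the collapsed edges; the advice string is attached as attribute
#'   `advice`.
#' @export
trifurcation_scan <- function(fit, tolerance = 1e-6) {
  g <- if (inherits(fit, "admix_fit")) fit$graph else fit
  stopifnot(inherits(g, "admixture_graph"))
  kids <- graph_children(g)
  e <- g$edges
  is_stub <- vapply(e$child, function(v) {
    ch <- kids[[v]]
    length(ch) == 1L && ch %in% g$admix$child &&
      !(ch %in% e$child[e$parent == v])
  }, logical(1))
  internal <- !(e$child %in% g$leaves) & e$parent != g$root & !is_stub
  hit <- internal & !is.na(e$length) & e$length < tolerance
  out <- e[hit, c("name", "parent", "child", "length")]
  rownames(out) <- NULL
  attr(out, "advice") <-
    "collapsed internal branch(es): adjust the split order and re-try"
  class(out) <- c("trifurcation_scan", "data.frame")
  out
}

#' @export
print.trifurcation_scan <- function(x, ...) {
  if (!nrow(x)) {
    cat("no collapsed internal branches\n")
  } else {
    cat(attr(x, "advice"), "\n")
    print.data.frame(x)
  }
  invisible(x)
}
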