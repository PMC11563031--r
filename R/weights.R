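#' Admixture-weighted branch weights
#'
#' For each leaf and each drift edge, the probability that a lineage
#' sampled from the leaf traverses that edge on its way to the root.  An
#' unadmixed leaf has weight 1 on every edge of its root path; below an
#' admixture node the weight splits `alpha` / `1 - alpha` between the two
#' parental routes, and multiple routes through an edge add up.  All
#' expected f-statistics are linear in branch lengths with coefficients
#' built from these weights.
#'
#' @param graph An [admixture_graph()].  Free (`NA`) proportions are not
#'   allowed here; fix them or fit first.
#' @return A numeric matrix, leaves x drift edges (named).
#' @export
branch_weights <- function(graph) {
  if (nrow(graph$admix) && anyNA(graph$admix$alpha))
    stop("branch weights need fixed admixture proportions (alpha is NA for: ",
         paste(graph$admix$child[is.na(graph$admix$alpha)], collapse = ", "),
         ")")
  leaves <- graph$leaves
  edges <- graph$edges
  rev_order <- rev(graph$order)
  drift_parent <- setNames(edges$parent, edges$child)
  adm <- graph$admix
  W <- matrix(0, length(leaves), nrow(edges),
              dimnames = list(leaves, edges$name))
  for (lf in leaves) {
    w <- setNames(numeric(length(graph$nodes)), graph$nodes)
    w[lf] <- 1
    for (v in rev_order) {
      if (w[v] == 0) next
      ai <- match(v, adm$child)
      if (!is.na(ai)) {
        w[adm$parent1[ai]] <- w[adm$parent1[ai]] + adm$alpha[ai] * w[v]
        w[adm$parent2[ai]] <- w[adm$parent2[ai]] + (1 - adm$alpha[ai]) * w[v]
      } else if (v != graph$root) {
        w[drift_parent[v]] <- w[drift_parent[v]] + w[v]
      }
    }
    W[lf, ] <- w[edges$child]
  }
  W
}

f4_coefficients <- function(W, A, B, C, D) {
  (W[A, ] - W[B, ]) * (W[C, ] - W[D, ])
}

check_leaves <- function(graph, pops) {
  miss <- setdiff(pops, graph$leaves)
  if (length(miss))
    stop("not leaf population(s) of the graph: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Expected f-statistics under an admixture graph
#'
#' The expected f4-statistic is a linear function of the drift-edge
#' lengths: the coefficient of edge `e` is
#' `(w_A(e) - w_B(e)) * (w_C(e) - w_D(e))` with `w` the admixture-weighted
#' [branch_weights()].  For an unadmixed quartet tree ((A,B),(C,D)) all
#' coefficients vanish; with admixture the expectation becomes a branch
#' length times mixture proportions.  `expected_f2` and `expected_f3` are
#' the definitional special cases `f4(A,B;A,B)` and `f4(A,B;A,C)`.
#'
#' @param graph An [admixture_graph()] with fixed proportions.
#' @param A,B,C,D Leaf labels.
#' @return A list of class `f_expectation` with `value` (`NA` if any
#'   contributing edge length is free) and `coefficients` (named by drift
#'   edge).
#' @export
expected_f4 <- function(graph, A, B, C, D) {
  check_leaves(graph, c(A, B, C, D))
  W <- branch_weights(graph)
  co <- f4_coefficients(W, A, B, C, D)
  len <- graph$edges$length
  used <- co != 0
  value <- if (any(used & is.na(len))) NA_real_ else
    sum(co[used] * len[used])
  structure(list(value = value, coefficients = co), class = "f_expectation")
}

#' @rdname expected_f4
#' @export
expected_f2 <- function(graph, A, B) expected_f4(graph, A, B, A, B)

#' @rdname expected_f4
#' @export
expected_f3 <- function(graph, A, B, C) expected_f4(graph, A, B, A, C)

#' @export
print.f_expectation <- function(x, ...) {
  cat("expected f-statistic:", format(x$value, digits = 8), "\n")
  nz <- x$coefficients[x$coefficients != 0]
  if (length(nz)) {
    cat("  edge coefficients:\n")
    for (nm in names(nz)) cat(sprintf("    %-20s %+g\n", nm, nz[nm]))
  }
  invisible(x)
}

#' Check the admixture linearity identity on expected values
#'
#' If leaf `C` is admixed with proportions `alpha` / `1 - alpha` from two
#' sources, then
#' `f4(A,B;C,D) = alpha f4(A,B;C',D) + (1 - alpha) f4(A,B;C'',D)` where
#' `C'` and `C''` are ghost leaves grafted with zero-length edges at the
#' two source positions.  This function grafts the ghosts at the parents
#' of the admixture node nearest above `C` and verifies the identity
#' exactly on expected values.
#'
#' @param graph An [admixture_graph()] with fixed lengths and proportions.
#' @param A,B,C,D Leaf labels; `C` must descend from an admixture node by
#'   drift edges only.
#' @return A list with `lhs`, `rhs`, `alpha`, the two one-source terms,
#'   and `equal`.
#' @export
admixture_linearity_check <- function(graph, A, B, C, D) {
  check_leaves(graph, c(A, B, C, D))
  # nearest admixture node on C's pure-drift ancestry
  v <- C
  repeat {
    if (v %in% graph$admix$child) break
    i <- match(v, graph$edges$child)
    if (is.na(v) || is.na(i))
      stop("population '", C, "' is not admixed (no admixture node on its ",
           "drift ancestry)")
    v <- graph$edges$parent[i]
  }
  ai <- match(v, graph$admix$child)
  alpha <- graph$admix$alpha[ai]
  if (is.na(alpha)) stop("admixture proportion for '", v, "' is free (NA)")
  ghost <- function(src, nm) {
    e <- rbind(graph$edges,
               data.frame(name = paste0("ghost_", nm), parent = src,
                          child = nm, length = 0, stringsAsFactors = FALSE))
    admixture_graph(e, graph$admix, root = graph$root)
  }
  g1 <- ghost(graph$admix$parent1[ai], ".C1")
  g2 <- ghost(graph$admix$parent2[ai], ".C2")
  t1 <- expected_f4(g1, A, B, ".C1", D)$value
  t2 <- expected_f4(g2, A, B, ".C2", D)$value
  lhs <- expected_f4(graph, A, B, C, D)$value
  rhs <- alpha * t1 + (1 - alpha) * t2
  list(lhs = lhs, rhs = rhs, alpha = alpha, term1 = t1, term2 = t2,
       equal = isTRUE(all.equal(lhs, rhs, tolerance = 1e-12)))
}

#' Constraint and parameter counts for an admixture graph
#'
#' With `n` leaf populations there are `choose(n, 2)` linearly independent
#' f-statistic constraints; a graph with `a` admixture events has
#' `2n + 2a - 3` free parameters (the branches of an unrooted binary tree
#' plus two per admixture event).  When an admixed population's two
#' sources are unsampled (each source node leads nowhere except into the
#' admixture), the three surrounding branch lengths `x`, `y`, `z` are not
#' individually determined and form the single compound parameter
#' `alpha^2 x + (1 - alpha)^2 y + z`, reducing the effective count by two.
#'
#' @param graph An [admixture_graph()].
#' @return A list of class `parameter_count` with `n_constraints`,
#'   `n_free_parameters`, `compound_reductions` (character vector of
#'   admixture-node labels with the compound pattern) and
#'   `n_effective_parameters`.
#' @export
count_parameters <- function(graph) {
  n <- n_leaves(graph)
  a <- n_admix(graph)
  kids <- graph_children(graph)
  compound <- character(0)
  for (i in seq_len(nrow(graph$admix))) {
    m <- graph$admix$child[i]
    unsampled <- function(u) {
      ch <- kids[[u]]
      length(ch) == 1L && ch == m && !(u %in% graph$leaves)
    }
    if (unsampled(graph$admix$parent1[i]) &&
        unsampled(graph$admix$parent2[i]))
      compound <- c(compound, m)
  }
  structure(list(n_constraints = choose(n, 2),
                 n_free_parameters = 2 * n + 2 * a - 3,
                 compound_reductions = compound,
                 n_effective_parameters =
                   2 * n + 2 * a - 3 - 2 * length(compound)),
            class = "parameter_count")
}

#' @export
print.parameter_count <- function(x, ...) {
  cat("constraints:", x$n_constraints,
      " free parameters:", x$n_free_parameters, "\n")
  if (length(x$compound_reductions))
    cat("compound parameters (alpha^2 x + (1-alpha)^2 y + z) around:",
        paste(x$compound_reductions, collapse = ", "),
        "-> effective", x$n_effective_parameters, "\n")
  invisible(x)
}
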