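# Shared fixtures and independent oracles used across the test files.

# Panel from explicit per-population frequency vectors (no missing data).
panel_from_freqs <- function(freqs, counts = 20, block = NULL) {
  fr <- do.call(cbind, freqs)
  colnames(fr) <- names(freqs)
  ct <- matrix(counts, nrow(fr), ncol(fr), dimnames = dimnames(fr))
  freq_panel(fr, ct, block = block %||% rep(1L, nrow(fr)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_panel <- function(seed, n = 60, pops = c("A", "B", "C", "D"),
                         n_blocks = 5, counts = 20) {
  set.seed(seed)
  fr <- matrix(runif(n * length(pops), 0.05, 0.95), n, length(pops),
               dimnames = list(NULL, pops))
  ct <- matrix(counts, n, length(pops), dimnames = dimnames(fr))
  assign_blocks(freq_panel(fr, ct), n_blocks = n_blocks)
}

# Uncorrected f-statistic straight from the definition, bypassing the
# package's block machinery.
direct_f4 <- function(panel, A, B, C, D) {
  fr <- panel$freq
  mean((fr[, A] - fr[, B]) * (fr[, C] - fr[, D]))
}

# Reference quartet histories: an unadmixed tree ((A,B),(C,D)) whose
# internal branch of total length `y` carries the root, and the same tree
# with C admixed (proportion `alpha` of B-related ancestry from a source
# on B's terminal branch, `1 - alpha` from C's original position at the
# far end of the internal branch).
tree_ABCD <- function(y = 0.01) {
  admixture_graph(data.frame(
    name = c("p", "q", "ta", "tb", "tc", "td"),
    parent = c("R", "R", "P", "P", "Q", "Q"),
    child = c("P", "Q", "A", "B", "C", "D"),
    length = c(0.6 * y, 0.4 * y, 0.003, 0.005, 0.002, 0.006)))
}

admixed_C <- function(alpha = 0.3, y = 0.02) {
  admixture_graph(
    data.frame(name = c("p", "q", "ta", "tb1", "tb2", "td", "tc"),
               parent = c("R", "R", "P", "P", "Bs", "Q", "Cm"),
               child = c("P", "Q", "A", "Bs", "B", "D", "C"),
               length = c(0.6 * y, 0.4 * y, 0.003, 0.002, 0.004, 0.005,
                          0.002)),
    data.frame(child = "Cm", parent1 = "Bs", parent2 = "Q", alpha = alpha))
}

# --- brute-force expectation oracle ---------------------------------------
# Enumerates every root-to-leaf ancestry route with its probability and
# accumulates edge traversal weights, independently of the package's
# rootward dynamic program.
oracle_routes <- function(graph, leaf) {
  routes <- list()
  walk <- function(node, edges, prob) {
    if (node == graph$root) {
      routes[[length(routes) + 1L]] <<- list(edges = edges, prob = prob)
      return(invisible())
    }
    ai <- match(node, graph$admix$child)
    if (!is.na(ai)) {
      walk(graph$admix$parent1[ai], edges, prob * graph$admix$alpha[ai])
      walk(graph$admix$parent2[ai], edges, prob * (1 - graph$admix$alpha[ai]))
    } else {
      i <- match(node, graph$edges$child)
      walk(graph$edges$parent[i], c(edges, graph$edges$name[i]), prob)
    }
  }
  walk(leaf, character(0), 1)
  routes
}

oracle_weights <- function(graph) {
  W <- matrix(0, length(graph$leaves), nrow(graph$edges),
              dimnames = list(graph$leaves, graph$edges$name))
  for (lf in graph$leaves) {
    for (r in oracle_routes(graph, lf))
      W[lf, r$edges] <- W[lf, r$edges] + r$prob
  }
  W
}

oracle_expected_f4 <- function(graph, A, B, C, D) {
  W <- oracle_weights(graph)
  sum((W[A, ] - W[B, ]) * (W[C, ] - W[D, ]) * graph$edges$length)
}

# Random valid admixture graph: a random binary tree on `n_leaves` plus
# `n_admix` events grafted by subdividing two random edges.
random_graph <- function(seed, n_leaves = 4, n_admix = 1) {
  set.seed(seed)
  leaves <- paste0("L", seq_len(n_leaves))
  counter <- 0L
  edges <- data.frame(parent = character(), child = character(),
                      length = numeric(), stringsAsFactors = FALSE)
  build <- function(set, parent) {
    if (length(set) == 1L) {
      edges <<- rbind(edges, data.frame(parent = parent, child = set,
                                        length = runif(1, 0.002, 0.04),
                                        stringsAsFactors = FALSE))
      return(invisible())
    }
    counter <<- counter + 1L
    node <- paste0("N", counter)
    edges <<- rbind(edges, data.frame(parent = parent, child = node,
                                      length = runif(1, 0.002, 0.04),
                                      stringsAsFactors = FALSE))
    k <- sample(seq_len(length(set) - 1L), 1L)
    pick <- sample(set, k)
    build(pick, node)
    build(setdiff(set, pick), node)
  }
  k <- sample(seq_len(n_leaves - 1L), 1L)
  pick <- sample(leaves, k)
  build(pick, "R")
  build(setdiff(leaves, pick), "R")
  subdivide <- function(edges, i, s) {
    old_child <- edges$child[i]
    l <- edges$length[i]
    mid <- runif(1, 0.2, 0.8)
    edges$child[i] <- s
    edges$length[i] <- l * mid
    rbind(edges, data.frame(parent = s, child = old_child,
                            length = l * (1 - mid),
                            stringsAsFactors = FALSE))
  }
  admix <- NULL
  if (n_admix > 0) {
    for (ai in seq_len(n_admix)) {
      picks <- sample(nrow(edges), 2L)
      s1 <- paste0("S", ai, "a")
      s2 <- paste0("S", ai, "b")
      edges <- subdivide(edges, picks[1], s1)
      edges <- subdivide(edges, picks[2], s2)
      m <- paste0("M", ai)
      edges <- rbind(edges,
                     data.frame(parent = m, child = paste0("AL", ai),
                                length = runif(1, 0.002, 0.02),
                                stringsAsFactors = FALSE))
      admix <- rbind(admix,
                     data.frame(child = m, parent1 = s1, parent2 = s2,
                                alpha = runif(1, 0.1, 0.9),
                                stringsAsFactors = FALSE))
    }
  }
  admixture_graph(edges, admix)
}
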