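#' Specify a drift simulation under an admixture graph
#'
#' The generative model behind expected f-statistics: each SNP draws an
#' ancestral (root) frequency `p0`, then the frequency evolves
#' independently along every drift edge by a Normal increment with
#' variance `length * p0 (1 - p0) / H`, where `H = E[p0 (1 - p0)]` is the
#' mean heterozygosity of the root distribution.  The `p0 (1 - p0)`
#' factor makes per-SNP drift proportional to heterozygosity, as under
#' genetic drift, while the `1 / H` normalization puts branch lengths in
#' the same units as the sample f-statistics: the expected value of every
#' f-statistic equals its path-overlap expression in the graph's branch
#' lengths exactly.  Admixture nodes mix their two parents' frequencies
#' `alpha : 1 - alpha`, and each leaf is observed by binomial sampling of
#' `2 * samples` allele copies.  Frequencies are
#' clipped to \[0, 1\]; the approximation is intended for small branch
#' lengths, and a warning is issued when any root-to-leaf drift exceeds
#' 0.2.
#'
#' @param graph An [admixture_graph()] with all lengths and proportions
#'   fixed.
#' @param n_snps Number of SNPs to simulate.
#' @param n_blocks Number of contiguous equal jackknife blocks (>= 2).
#' @param samples_per_pop Diploid sample size per leaf: a single number or
#'   a named vector; `Inf` records exact population frequencies.
#' @param root_freq Root frequency distribution: `c(lo, hi)` for Uniform,
#'   or `list(beta = c(a, b))`.
#' @param seed Default seed used by [simulate_panel()].
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(graph, n_snps, n_blocks = 100L, samples_per_pop = 10,
                     root_freq = c(0.25, 0.75), seed = 1L) {
  stopifnot(inherits(graph, "admixture_graph"))
  if (anyNA(graph$edges$length) ||
      (nrow(graph$admix) && anyNA(graph$admix$alpha)))
    stop("simulation graph must have all lengths and proportions fixed")
  n_snps <- as.integer(n_snps)
  if (n_snps < 1L) stop("n_snps must be at least 1")
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) stop("n_blocks must be at least 2 (jackknife)")
  if (is.numeric(root_freq) && length(root_freq) == 2L) {
    if (root_freq[1] <= 0 || root_freq[2] >= 1 || root_freq[1] >= root_freq[2])
      stop("uniform root_freq bounds must satisfy 0 < lo < hi < 1")
  } else if (!(is.list(root_freq) && !is.null(root_freq$beta) &&
               length(root_freq$beta) == 2L && all(root_freq$beta > 0))) {
    stop("root_freq must be c(lo, hi) or list(beta = c(a, b))")
  }
  s <- samples_per_pop
  if (is.null(names(s))) {
    s <- setNames(rep(s[1], length(graph$leaves)), graph$leaves)
  } else if (!all(graph$leaves %in% names(s))) {
    stop("samples_per_pop must cover every leaf")
  }
  if (any(s[graph$leaves] < 1)) stop("samples_per_pop must be >= 1")
  depth <- max_drift_depth(graph)
  if (depth > 0.2)
    warning(sprintf(paste0("total root-to-leaf drift reaches %.3g; the ",
                           "Gaussian small-drift approximation degrades and ",
                           "clipping may be common"), depth))
  structure(list(graph = graph, n_snps = n_snps, n_blocks = n_blocks,
                 samples_per_pop = s[graph$leaves], root_freq = root_freq,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# Mean heterozygosity E[p (1 - p)] of the root frequency distribution.
root_het <- function(rf) {
  if (is.list(rf)) {
    a <- rf$beta[1]; b <- rf$beta[2]
    a * b / ((a + b) * (a + b + 1))
  } else {
    lo <- rf[1]; hi <- rf[2]
    (lo + hi) / 2 - (lo^2 + lo * hi + hi^2) / 3
  }
}

max_drift_depth <- function(graph) {
  d <- setNames(numeric(length(graph$nodes)), graph$nodes)
  e <- graph$edges
  a <- graph$admix
  for (v in graph$order) {
    if (v == graph$root) next
    i <- match(v, e$child)
    if (!is.na(i)) {
      d[v] <- d[e$parent[i]] + e$length[i]
    } else {
      j <- match(v, a$child)
      d[v] <- max(d[a$parent1[j]], d[a$parent2[j]])
    }
  }
  max(d[graph$leaves])
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("sim_spec:", x$n_snps, "SNPs,", x$n_blocks, "blocks, leaves:",
      paste(names(x$samples_per_pop), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate an allele-frequency panel under an admixture graph
#'
#' Runs the drift model described in [sim_spec()].  Fully reproducible:
#' the same spec and seed give a bit-identical panel.  The realized
#' clipping rate (fraction of SNP-by-branch drift draws that hit the
#' \[0, 1\] boundary) is attached as attribute `clip_rate`.
#'
#' @param spec A [sim_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return A [freq_panel()] with block labels assigned.
#' @export
simulate_panel <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  g <- spec$graph
  n <- spec$n_snps
  rf <- spec$root_freq
  p0 <- if (is.list(rf)) stats::rbeta(n, rf$beta[1], rf$beta[2])
        else stats::runif(n, rf[1], rf[2])
  v0 <- p0 * (1 - p0) / root_het(rf)
  freqs <- list()
  freqs[[g$root]] <- p0
  n_clip <- 0
  n_draw <- 0
  e <- g$edges
  a <- g$admix
  for (v in g$order) {
    if (v == g$root) next
    i <- match(v, e$child)
    if (!is.na(i)) {
      p <- freqs[[e$parent[i]]] +
        stats::rnorm(n, 0, sqrt(e$length[i] * v0))
      n_draw <- n_draw + n
      n_clip <- n_clip + sum(p < 0 | p > 1)
      freqs[[v]] <- pmin(pmax(p, 0), 1)
    } else {
      j <- match(v, a$child)
      freqs[[v]] <- a$alpha[j] * freqs[[a$parent1[j]]] +
        (1 - a$alpha[j]) * freqs[[a$parent2[j]]]
    }
  }
  leaves <- g$leaves
  fr <- matrix(NA_real_, n, length(leaves), dimnames = list(NULL, leaves))
  ct <- matrix(0, n, length(leaves), dimnames = list(NULL, leaves))
  for (lf in leaves) {
    s <- spec$samples_per_pop[[lf]]
    if (is.infinite(s)) {
      fr[, lf] <- freqs[[lf]]
      ct[, lf] <- Inf
    } else {
      nal <- 2 * s
      fr[, lf] <- stats::rbinom(n, nal, freqs[[lf]]) / nal
      ct[, lf] <- nal
    }
  }
  snp <- data.frame(id = sprintf("snp%06d", seq_len(n)), chrom = 1L,
                    pos = seq_len(n) * 1500L, stringsAsFactors = FALSE)
  panel <- freq_panel(fr, ct, snp = snp)
  panel <- assign_blocks(panel, n_blocks = spec$n_blocks)
  attr(panel, "clip_rate") <- if (n_draw) n_clip / n_draw else 0
  attr(panel, "true_graph") <- g
  panel
}

# ---- canned scenarios ------------------------------------------------------

scenario_names <- c("quartet_mixe", "quartet_kyrgyz", "five_ulchi",
                    "five_hungarian", "five_swapped")

graph_quartet_backbone <- function() {
  data.frame(
    name   = c("Baka_t", "ooa", "west", "east", "French_t", "y", "Han_t",
               "x"),
    parent = c("R", "R", "OOA", "OOA", "W1", "W1", "E1", "E1"),
    child  = c("Baka", "OOA", "W1", "E1", "French", "W2", "Han", "E2"),
    length = c(0.015, 0.010, 0.004, 0.006, 0.005, 0.002, 0.006, 0.0025),
    stringsAsFactors = FALSE)
}

graph_quartet_mixe <- function() {
  e <- rbind(graph_quartet_backbone(),
             data.frame(name = "z", parent = "pAM", child = "Mixe",
                        length = 0.0075, stringsAsFactors = FALSE))
  admixture_graph(e, data.frame(child = "pAM", parent1 = "E2",
                                parent2 = "W2", alpha = 0.7))
}

graph_quartet_kyrgyz <- function() {
  e <- graph_quartet_backbone()
  e$length[e$name == "y"] <- 0.0005
  e$length[e$name == "x"] <- 0.0005
  e <- rbind(e, data.frame(name = "z", parent = "pAM", child = "Kyrgyz",
                           length = 0.001, stringsAsFactors = FALSE))
  admixture_graph(e, data.frame(child = "pAM", parent1 = "E2",
                                parent2 = "W2", alpha = 0.5))
}

graph_five_ulchi <- function(swap = FALSE) {
  han <- if (swap) "Ulchi" else "Han"
  ulchi <- if (swap) "Han" else "Ulchi"
  e <- data.frame(
    name   = c("Baka_t", "ooa", "west", "east", "French_t", "y",
               paste0(han, "_t"), "east2", paste0(ulchi, "_t"), "x", "z"),
    parent = c("R", "R", "OOA", "OOA", "W1", "W1", "E1", "E1", "E1b", "E1b",
               "pAM"),
    child  = c("Baka", "OOA", "W1", "E1", "French", "W2", han, "E1b", ulchi,
               "E2", "Mixe"),
    length = c(0.015, 0.010, 0.004, 0.006, 0.005, 0.002, 0.006, 0.003,
               0.006, 0.0025, 0.0075),
    stringsAsFactors = FALSE)
  admixture_graph(e, data.frame(child = "pAM", parent1 = "E2",
                                parent2 = "W2", alpha = 0.7))
}

graph_five_hungarian <- function() {
  e <- data.frame(
    name   = c("Baka_t", "ooa", "west", "east", "wsplit", "French_t",
               "Hungarian_t", "y", "Han_t", "x", "z"),
    parent = c("R", "R", "OOA", "OOA", "W1", "W1a", "W1a", "W1", "E1", "E1",
               "pAM"),
    child  = c("Baka", "OOA", "W1", "E1", "W1a", "French", "Hungarian",
               "W2", "Han", "E2", "Mixe"),
    length = c(0.015, 0.010, 0.004, 0.006, 0.002, 0.005, 0.0045, 0.002,
               0.006, 0.0025, 0.0075),
    stringsAsFactors = FALSE)
  admixture_graph(e, data.frame(child = "pAM", parent1 = "E2",
                                parent2 = "W2", alpha = 0.7))
}

#' Canned simulation scenarios
#'
#' Fully parameterized [sim_spec()]s for the package's worked example
#' histories, all variations on one human-like quartet (an African
#' outgroup "Baka", western Eurasian "French", eastern Eurasian "Han",
#' and an admixed Native-American-like "Mixe" with 70% eastern / 30%
#' western ancestry):
#' \describe{
#'   \item{quartet_mixe}{the four-population admixed history; all three
#'     quartet f4 permutations are significantly non-zero.}
#'   \item{quartet_kyrgyz}{"Kyrgyz" replaces Mixe: a recent 50/50
#'     admixture with very short terminal drift, so
#'     f3(Kyrgyz; Han, French) is significantly negative.}
#'   \item{five_ulchi}{adds "Ulchi" splitting between Han and the eastern
#'     source of Mixe, which makes the mixture proportion identifiable.}
#'   \item{five_hungarian}{adds "Hungarian" as a sister of French, which
#'     adds no independent constraint.}
#'   \item{five_swapped}{the five_ulchi history with the Han/Ulchi split
#'     order exchanged; its topology serves as the misspecified model for
#'     five_ulchi data.}
#' }
#' Branch lengths and proportions are frozen package constants chosen to
#' reproduce the qualitative Z-score patterns of these histories at
#' simulation scale; they are not estimates from real data.
#'
#' @param name One of the scenario names above.
#' @param n_snps,n_blocks,samples_per_pop,seed Passed to [sim_spec()].
#' @return A [sim_spec()] with the scenario graph attached.
#' @export
scenario_spec <- function(name, n_snps = 200000L, n_blocks = 100L,
                          samples_per_pop = 10, seed = 1L) {
  if (!name %in% scenario_names)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(scenario_names, collapse = ", "))
  g <- switch(name,
              quartet_mixe = graph_quartet_mixe(),
              quartet_kyrgyz = graph_quartet_kyrgyz(),
              five_ulchi = graph_five_ulchi(),
              five_hungarian = graph_five_hungarian(),
              five_swapped = graph_five_ulchi(swap = TRUE))
  spec <- sim_spec(g, n_snps = n_snps, n_blocks = n_blocks,
                   samples_per_pop = samples_per_pop, seed = seed)
  spec$name <- name
  spec
}

#' A two-admixture history that masks one f4-statistic
#'
#' Two admixture events can cancel in a single f4-statistic: this
#' constructor builds a quartet graph in which both C and D are admixed
#' from the B lineage, and solves (using the linearity of expected f4 in
#' the second proportion) for the proportion that makes
#' `E f4(A,B;C,D) = 0` exactly, while other permutations of the quartet
#' still reveal the admixture.  Removing either event un-masks the
#' statistic.
#'
#' @param n_snps,n_blocks,samples_per_pop,seed Passed to [sim_spec()].
#' @return A [sim_spec()]; the masked quadruple is attached as
#'   `$masked_quartet`.
#' @export
masking_scenario <- function(n_snps = 200000L, n_blocks = 100L,
                             samples_per_pop = 10, seed = 1L) {
  base_edges <- function() data.frame(
    name   = c("p", "q", "A_t", "a1", "a2", "B_t", "c0", "d0", "C_t", "D_t"),
    parent = c("R", "R", "P", "P", "B1", "B2", "Q", "Q", "Cm", "Dm"),
    child  = c("P", "Q", "A", "B1", "B2", "B", "C0", "D0", "C", "D"),
    length = c(0.01, 0.01, 0.01, 0.005, 0.005, 0.0025, 0.005, 0.005,
               0.0025, 0.0025),
    stringsAsFactors = FALSE)
  mk <- function(gamma) {
    admixture_graph(base_edges(),
                    data.frame(child = c("Cm", "Dm"),
                               parent1 = c("C0", "B1"),
                               parent2 = c("B2", "D0"),
                               alpha = c(0.7, gamma)))
  }
  # E f4(A,B;C,D) is affine in gamma; solve for the root exactly
  e0 <- expected_f4(mk(0), "A", "B", "C", "D")$value
  e1 <- expected_f4(mk(1), "A", "B", "C", "D")$value
  gamma <- -e0 / (e1 - e0)
  if (gamma < 0 || gamma > 1)
    stop("internal error: masking proportion outside [0, 1]")
  spec <- sim_spec(mk(gamma), n_snps = n_snps, n_blocks = n_blocks,
                   samples_per_pop = samples_per_pop, seed = seed)
  spec$name <- "masking"
  spec$masked_quartet <- c("A", "B", "C", "D")
  spec
}

# ---- fitting topologies for the scenarios ---------------------------------

#' Candidate quartet topologies with a chosen admixed population
#'
#' For four populations with one admixture event, the admixed population
#' `X` mixes two sources grafted onto the branches of two of the
#' remaining populations, with the third as outgroup.  The three possible
#' assignments of (outgroup, source side 1, source side 2) give three
#' candidate topologies; all parameters are left free.
#'
#' @param pops Character vector of the four population labels.
#' @param admixed The label modeled as admixed.
#' @return A named list of three free [admixture_graph()]s.
#' @export
quartet_topologies <- function(pops, admixed) {
  stopifnot(length(pops) == 4L, admixed %in% pops)
  rest <- setdiff(pops, admixed)
  out <- list()
  for (og in rest) {
    s <- setdiff(rest, og)
    e <- data.frame(
      name   = c("og_t", "int", "s1a", "s2a", "s1_t", "x1", "s2_t", "x2",
                 "z"),
      parent = c("R", "R", "I", "I", "S1a", "S1a", "S2a", "S2a", "Xm"),
      child  = c(og, "I", "S1a", "S2a", s[1], "X1", s[2], "X2", admixed),
      length = NA_real_, stringsAsFactors = FALSE)
    a <- data.frame(child = "Xm", parent1 = "X1", parent2 = "X2",
                    alpha = NA_real_)
    out[[paste0("out_", og)]] <- admixture_graph(e, a)
  }
  out
}

#' Fitting topologies for the canned scenarios
#'
#' Returns free-parameter topologies used when fitting scenario panels:
#' the scenario's own topology (`variant = "truth"`), the misspecified
#' version with the African outgroup modeled as admixed instead
#' (`variant = "baka_admixed"`, five-population scenarios), or the
#' swapped Han/Ulchi split order (`variant = "swapped"`, five_ulchi).
#'
#' @param name A scenario name (see [scenario_spec()]).
#' @param variant One of `"truth"`, `"baka_admixed"`, `"swapped"`.
#' @return A free [admixture_graph()].
#' @export
scenario_topology <- function(name,
                              variant = c("truth", "baka_admixed",
                                          "swapped")) {
  variant <- match.arg(variant)
  if (variant == "truth")
    return(free_topology(scenario_spec(name, n_snps = 1L)$graph))
  if (variant == "swapped") {
    if (name != "five_ulchi")
      stop("variant 'swapped' only applies to five_ulchi")
    return(free_topology(graph_five_ulchi(swap = TRUE)))
  }
  # Baka modeled as admixed: one deep source and one western source;
  # the remaining populations form an unadmixed backbone.
  if (name == "five_ulchi") {
    e <- data.frame(
      name   = c("deep", "w0", "bsrc", "w1", "French_t", "e0", "Mixe_t",
                 "e1", "Ulchi_t", "Han_t", "Baka_t"),
      parent = c("R", "R", "W0", "W0", "W1", "R", "E0", "E0", "E1", "E1",
                 "Bm"),
      child  = c("Bdeep", "W0", "Bsrc", "W1", "French", "E0", "Mixe", "E1",
                 "Ulchi", "Han", "Baka"),
      length = NA_real_, stringsAsFactors = FALSE)
  } else if (name == "five_hungarian") {
    e <- data.frame(
      name   = c("deep", "w0", "bsrc", "w1", "fh", "French_t",
                 "Hungarian_t", "e0", "Mixe_t", "Han_t", "Baka_t"),
      parent = c("R", "R", "W0", "W0", "W1", "FH", "FH", "R", "E0", "E0",
                 "Bm"),
      child  = c("Bdeep", "W0", "Bsrc", "W1", "FH", "French", "Hungarian",
                 "E0", "Mixe", "Han", "Baka"),
      length = NA_real_, stringsAsFactors = FALSE)
  } else if (name == "quartet_kyrgyz") {
    return(quartet_topologies(c("Baka", "French", "Han", "Kyrgyz"),
                              admixed = "Baka")$out_Kyrgyz)
  } else {
    stop("variant 'baka_admixed' is defined for five_ulchi, ",
         "five_hungarian and quartet_kyrgyz")
  }
  a <- data.frame(child = "Bm", parent1 = "Bdeep", parent2 = "Bsrc",
                  alpha = NA_real_)
  admixture_graph(e, a)
}
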