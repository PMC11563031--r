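#' Admixture graph
#'
#' A rooted directed acyclic graph of populations.  Ordinary ("drift")
#' edges carry a length in f-statistic units (the variance of
#' allele-frequency change along the branch); an admixture node instead
#' has exactly two parents and receives a proportion `alpha` of its
#' ancestry from the first and `1 - alpha` from the second.  Leaves (nodes
#' without children) are the sampled populations.  Lengths and proportions
#' may be `NA`, marking them as free parameters to be fitted.
#'
#' @param edges Data frame of drift edges with columns `parent`, `child`,
#'   and optionally `length` (`NA` = free) and `name` (defaults to
#'   `parent_child`).
#' @param admix Optional data frame of admixture events with columns
#'   `child`, `parent1`, `parent2` and optionally `alpha` (proportion from
#'   `parent1`; `NA` = free).
#' @param root Root node label; inferred if the graph has a unique
#'   parentless node.
#' @return An object of class `admixture_graph` with fields `edges`,
#'   `admix`, `root`, `nodes`, `leaves`, `order` (topological, root
#'   first).
#' @seealso [parse_graph()], [serialize_graph()], [branch_weights()]
#' @export
admixture_graph <- function(edges, admix = NULL, root = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% names(edges)))
    stop("`edges` needs columns parent, child")
  if (is.null(edges$length)) edges$length <- NA_real_
  if (is.null(edges$name)) edges$name <- paste(edges$parent, edges$child, sep = "_")
  edges <- edges[, c("name", "parent", "child", "length")]
  edges$length <- as.numeric(edges$length)
  if (is.null(admix) || nrow(as.data.frame(admix)) == 0L) {
    admix <- data.frame(child = character(), parent1 = character(),
                        parent2 = character(), alpha = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    admix <- as.data.frame(admix, stringsAsFactors = FALSE)
    if (!all(c("child", "parent1", "parent2") %in% names(admix)))
      stop("`admix` needs columns child, parent1, parent2")
    if (is.null(admix$alpha)) admix$alpha <- NA_real_
    admix <- admix[, c("child", "parent1", "parent2", "alpha")]
    admix$alpha <- as.numeric(admix$alpha)
  }
  g <- structure(list(edges = edges, admix = admix, root = root),
                 class = "admixture_graph")
  validate_graph(g)
}

graph_children <- function(g) {
  # named list: node -> character vector of child nodes (drift + admix)
  nodes <- g$nodes
  kids <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(g$edges)))
    kids[[g$edges$parent[i]]] <- c(kids[[g$edges$parent[i]]], g$edges$child[i])
  for (i in seq_len(nrow(g$admix))) {
    kids[[g$admix$parent1[i]]] <- c(kids[[g$admix$parent1[i]]], g$admix$child[i])
    kids[[g$admix$parent2[i]]] <- c(kids[[g$admix$parent2[i]]], g$admix$child[i])
  }
  kids
}

validate_graph <- function(g) {
  edges <- g$edges
  admix <- g$admix
  nodes <- unique(c(edges$parent, edges$child, admix$child, admix$parent1,
                    admix$parent2))
  if (anyDuplicated(edges$name))
    stop("duplicate drift edge name(s): ",
         paste(unique(edges$name[duplicated(edges$name)]), collapse = ", "))
  drift_children <- edges$child
  admix_children <- admix$child
  dup <- intersect(drift_children, admix_children)
  if (length(dup))
    stop("node(s) with both a drift parent and admixture parents: ",
         paste(dup, collapse = ", "))
  if (anyDuplicated(drift_children))
    stop("node(s) with more than one drift parent: ",
         paste(unique(drift_children[duplicated(drift_children)]),
               collapse = ", "))
  if (anyDuplicated(admix_children))
    stop("node(s) with more than one admixture event: ",
         paste(unique(admix_children[duplicated(admix_children)]),
               collapse = ", "))
  if (any(admix$parent1 == admix$parent2))
    stop("admixture node must have two distinct parents: ",
         paste(admix$child[admix$parent1 == admix$parent2], collapse = ", "))
  parented <- c(drift_children, admix_children)
  roots <- setdiff(nodes, parented)
  if (length(roots) != 1L)
    stop("graph must have exactly one root (parentless node); found: ",
         if (length(roots)) paste(roots, collapse = ", ") else "none")
  if (!is.null(g$root) && g$root != roots)
    stop("declared root '", g$root, "' is not the parentless node ('",
         roots, "')")
  bad_a <- !is.na(admix$alpha) & (admix$alpha < 0 | admix$alpha > 1)
  if (any(bad_a))
    stop("admixture proportion outside [0, 1] for: ",
         paste(admix$child[bad_a], collapse = ", "))
  bad_l <- !is.na(edges$length) & edges$length < 0
  if (any(bad_l))
    stop("negative branch length on edge(s): ",
         paste(edges$name[bad_l], collapse = ", "))

  # topological order (Kahn); detects cycles
  parents_of <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges)))
    parents_of[[edges$child[i]]] <- c(parents_of[[edges$child[i]]],
                                      edges$parent[i])
  for (i in seq_len(nrow(admix)))
    parents_of[[admix$child[i]]] <- c(admix$parent1[i], admix$parent2[i])
  order <- character(0)
  queue <- roots
  g$nodes <- nodes
  kids_tmp <- graph_children(g)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    order <- c(order, v)
    for (w in unique(kids_tmp[[v]])) {
      if (all(parents_of[[w]] %in% order) && !(w %in% order) &&
          !(w %in% queue))
        queue <- c(queue, w)
    }
  }
  if (length(order) != length(nodes))
    stop("graph contains a cycle involving: ",
         paste(setdiff(nodes, order), collapse = ", "))

  g$root <- roots
  g$nodes <- nodes
  g$order <- order
  kids <- kids_tmp
  g$leaves <- nodes[vapply(kids, length, integer(1))[nodes] == 0L]
  if (length(g$leaves) < 2L) stop("graph must have at least two leaves")
  g
}

n_leaves <- function(g) length(g$leaves)
n_admix <- function(g) nrow(g$admix)

#' @export
print.admixture_graph <- function(x, ...) {
  cat("admixture_graph:", length(x$leaves), "leaves (",
      paste(x$leaves, collapse = ", "), "),", nrow(x$edges),
      "drift edges,", nrow(x$admix), "admixture event(s); root", x$root, "\n")
  invisible(x)
}

#' Parse an admixture graph from its text format
#'
#' The dialect has one directive per line:
#' \preformatted{
#'   root  R
#'   edge  <name>  <parent>  <child>  [<length>]
#'   admix <child> <parent1> <parent2> [<alpha>]
#' }
#' Lengths (f-statistic units) and proportions (fraction from `parent1`)
#' are optional; when omitted the parameter is free.  `#` starts a
#' comment.  The `root` line is optional when the root is implied.
#'
#' @param text Character vector of lines, a single string with newlines,
#'   or a file path (see [read_graph()]).
#' @return An [admixture_graph()].
#' @export
parse_graph <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("#.*$", "", text)
  edges <- list()
  admix <- list()
  root <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[ \t]+")[[1]]
    kw <- tok[1]
    if (kw == "root") {
      if (length(tok) != 2L)
        stop("line ", i, ": 'root' takes exactly one node name")
      if (!is.null(root)) stop("line ", i, ": multiple 'root' lines")
      root <- tok[2]
    } else if (kw == "edge") {
      if (!(length(tok) %in% 4:5))
        stop("line ", i, ": 'edge' needs name, parent, child and an ",
             "optional length")
      len <- if (length(tok) == 5L) parse_num(tok[5], i) else NA_real_
      edges[[length(edges) + 1L]] <-
        data.frame(name = tok[2], parent = tok[3], child = tok[4],
                   length = len, stringsAsFactors = FALSE)
    } else if (kw == "admix") {
      if (!(length(tok) %in% 4:5))
        stop("line ", i, ": 'admix' needs child, parent1, parent2 and an ",
             "optional proportion")
      a <- if (length(tok) == 5L) parse_alpha(tok[5], i) else NA_real_
      admix[[length(admix) + 1L]] <-
        data.frame(child = tok[2], parent1 = tok[3], parent2 = tok[4],
                   alpha = a, stringsAsFactors = FALSE)
    } else {
      stop("line ", i, ": unknown directive '", kw, "'")
    }
  }
  if (!length(edges)) stop("graph file contains no edges")
  admixture_graph(do.call(rbind, edges),
                  if (length(admix)) do.call(rbind, admix) else NULL,
                  root = root)
}

parse_num <- function(s, line) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("line ", line, ": '", s, "' is not a number")
  v
}

parse_alpha <- function(s, line) {
  pct <- grepl("%$", s)
  v <- suppressWarnings(as.numeric(sub("%$", "", s)))
  if (is.na(v)) stop("line ", line, ": '", s, "' is not a proportion")
  if (pct) v <- v / 100
  v
}

#' Read an admixture graph file
#'
#' @param path Path to a graph text file in the [parse_graph()] dialect.
#' @return An [admixture_graph()].
#' @export
read_graph <- function(path) parse_graph(readLines(path))

#' Serialize an admixture graph
#'
#' `format = "text"` emits the [parse_graph()] dialect and round-trips
#' exactly.  `format = "dot"` emits Graphviz DOT with drift edges labelled
#' by `1000 * length` rounded to the nearest integer (the conventional
#' rendering of f-statistic branch units) and admixture edges dashed,
#' labelled with the proportion as a whole-number percentage.
#'
#' @param graph An [admixture_graph()].
#' @param format `"text"` or `"dot"`.
#' @return A character vector of lines.
#' @export
serialize_graph <- function(graph, format = c("text", "dot")) {
  format <- match.arg(format)
  e <- graph$edges
  a <- graph$admix
  if (format == "text") {
    out <- paste("root", graph$root)
    for (i in seq_len(nrow(e))) {
      ln <- paste("edge", e$name[i], e$parent[i], e$child[i])
      if (!is.na(e$length[i]))
        ln <- paste(ln, format(e$length[i], digits = 15))
      out <- c(out, ln)
    }
    for (i in seq_len(nrow(a))) {
      ln <- paste("admix", a$child[i], a$parent1[i], a$parent2[i])
      if (!is.na(a$alpha[i]))
        ln <- paste(ln, format(a$alpha[i], digits = 15))
      out <- c(out, ln)
    }
    return(out)
  }
  lab <- function(l) if (is.na(l)) "?" else sprintf("%d", round(1000 * l))
  pct <- function(x) if (is.na(x)) "?%" else sprintf("%.0f%%", 100 * x)
  out <- c("digraph G {",
           "  node [shape=ellipse, fontsize=11];")
  for (lf in graph$leaves)
    out <- c(out, sprintf("  \"%s\" [shape=box];", lf))
  for (i in seq_len(nrow(e)))
    out <- c(out, sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                          e$parent[i], e$child[i], lab(e$length[i])))
  for (i in seq_len(nrow(a))) {
    out <- c(out, sprintf(
      "  \"%s\" -> \"%s\" [style=dashed, label=\"%s\"];",
      a$parent1[i], a$child[i], pct(a$alpha[i])))
    out <- c(out, sprintf(
      "  \"%s\" -> \"%s\" [style=dashed, label=\"%s\"];",
      a$parent2[i], a$child[i], pct(1 - a$alpha[i])))
  }
  c(out, "}")
}

#' Strip fitted values from a graph, keeping the topology
#'
#' Returns the same graph with every branch length and admixture
#' proportion marked free (`NA`), ready to be fitted.
#'
#' @param graph An [admixture_graph()].
#' @param free_lengths,free_alphas Which parameter sets to free.
#' @return An [admixture_graph()].
#' @export
free_topology <- function(graph, free_lengths = TRUE, free_alphas = TRUE) {
  e <- graph$edges
  a <- graph$admix
  if (free_lengths) e$length <- NA_real_
  if (free_alphas && nrow(a)) a$alpha <- NA_real_
  admixture_graph(e, if (nrow(a)) a else NULL, root = graph$root)
}

#' Re-root an admixture graph along a drift edge
#'
#' Places a new root at a point on the given drift edge, splitting it in
#' two, and reverses the drift edges on the path from the old root to the
#' new position.  Only valid when no admixture node lies on that path
#' (reversing an admixture edge has no meaning).  Expected f-statistics
#' are invariant to this operation.
#'
#' @param graph An [admixture_graph()].
#' @param edge Name of the drift edge on which to place the new root.
#' @param position Fraction of the edge's length assigned to the
#'   child-side piece.
#' @param root_name Name for the new root node.
#' @return An [admixture_graph()].
#' @export
reroot_graph <- function(graph, edge, position = 0.5, root_name = "newroot") {
  e <- graph$edges
  i <- match(edge, e$name)
  if (is.na(i)) stop("unknown drift edge '", edge, "'")
  if (root_name %in% graph$nodes) stop("node '", root_name, "' already exists")
  # path from old root down to e$parent[i]
  path <- integer(0)
  v <- e$parent[i]
  while (v != graph$root) {
    if (v %in% graph$admix$child)
      stop("cannot re-root across admixture node '", v, "'")
    j <- match(v, e$child)
    if (is.na(j)) stop("internal error: broken parent chain at '", v, "'")
    path <- c(path, j)
    v <- e$parent[j]
  }
  len <- e$length[i]
  child_part <- if (is.na(len)) NA_real_ else len * position
  parent_part <- if (is.na(len)) NA_real_ else len * (1 - position)
  new_e <- e[-i, , drop = FALSE]
  # reverse edges along the old-root path
  for (j in path) {
    k <- match(e$name[j], new_e$name)
    tmp <- new_e$parent[k]
    new_e$parent[k] <- new_e$child[k]
    new_e$child[k] <- tmp
  }
  new_e <- rbind(new_e,
                 data.frame(name = paste0(edge, "_c"), parent = root_name,
                            child = e$child[i], length = child_part,
                            stringsAsFactors = FALSE),
                 data.frame(name = paste0(edge, "_p"), parent = root_name,
                            child = e$parent[i], length = parent_part,
                            stringsAsFactors = FALSE))
  admixture_graph(new_e, if (nrow(graph$admix)) graph$admix else NULL,
                  root = root_name)
}
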