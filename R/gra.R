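#' Construct an undirected typed graph
#'
#' The substrate for global resource allocation (GRA) similarity: nodes
#' carry a type (disease, medication, ...), edges are untyped and
#' undirected. Self-loops and duplicate edges are collapsed away; node
#' insertion order does not affect any similarity computed from the graph.
#'
#' @param edges two-column character matrix or data.frame of node id pairs.
#' @param node_types named character vector mapping node id to type. Every
#'   endpoint must be present; isolated ids in `node_types` are kept as
#'   degree-0 nodes only if `keep_isolated = TRUE`.
#' @param keep_isolated keep typed nodes without edges (default `FALSE`,
#'   matching graph construction from triplets where only mentioned
#'   concepts become nodes).
#' @return object of class `kg_graph`: node ids, types, adjacency list and
#'   degrees.
#' @export
kg_graph <- function(edges, node_types, keep_isolated = FALSE) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L) stop("edges must have two columns")
  mode(edges) <- "character"
  if (length(edges)) {
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE] # no self-loops
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L])) # canonical orientation
    edges <- edges[!duplicated(paste(edges[, 1L], edges[, 2L], sep = "\r")), ,
                   drop = FALSE]
  }
  endpoint <- unique(as.vector(edges))
  missing <- setdiff(endpoint, names(node_types))
  if (length(missing)) {
    stop("no type for node(s): ", paste(missing, collapse = ", "))
  }
  nodes <- if (keep_isolated) names(node_types) else endpoint
  nodes <- sort(unique(nodes))
  idx <- stats::setNames(seq_along(nodes), nodes)
  adj <- vector("list", length(nodes))
  for (r in seq_len(nrow(edges))) {
    i <- idx[[edges[r, 1L]]]
    j <- idx[[edges[r, 2L]]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, function(x) sort(unique(x)))
  structure(
    list(nodes = nodes, types = node_types[nodes], adj = adj,
         degree = lengths(adj),
         edges = edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]),
    class = "kg_graph"
  )
}

#' @export
print.kg_graph <- function(x, ...) {
  cat(sprintf("<kg_graph> %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  tt <- table(x$types)
  for (t in names(tt)) cat(sprintf("  type %-12s %d node(s)\n", t, tt[[t]]))
  invisible(x)
}

as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(length(graph$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = graph$nodes)
  if (nrow(graph$edges)) g <- igraph::add_edges(g, t(graph$edges))
  g
}

.node_index <- function(graph, id) {
  i <- match(id, graph$nodes)
  if (is.na(i)) stop("node '", id, "' is not in the graph")
  i
}

#' Contribution of a single path
#'
#' A path's contribution is the reciprocal of the product of the degrees of
#' its intermediate nodes; a direct edge (no intermediates) contributes 1.
#' Degrees are counted on the full heterogeneous graph, so high-degree hub
#' nodes damp every path through them.
#'
#' @param graph a `kg_graph`.
#' @param path character vector of node ids, consecutive pairs must be
#'   edges of `graph`.
#' @return the contribution `c(p) = 1 / prod(degree(intermediates))`.
#' @export
path_contribution <- function(graph, path) {
  if (length(path) < 2L) stop("a path needs at least two nodes")
  idx <- vapply(path, .node_index, integer(1L), graph = graph)
  for (s in seq_len(length(idx) - 1L)) {
    if (!(idx[s + 1L] %in% graph$adj[[idx[s]]])) {
      stop("'", path[s], "' -- '", path[s + 1L], "' is not an edge")
    }
  }
  inner <- idx[-c(1L, length(idx))]
  1 / prod(graph$degree[inner])
}

# DFS over the adjacency list accumulating sum over simple paths i..j of
# length <= L of beta^length / prod(degree of intermediates). Iterative
# recursion through a closure; path lengths are tiny so R recursion is fine.
.gra_from <- function(graph, i, beta, max_length) {
  score <- numeric(length(graph$nodes))
  visited <- logical(length(graph$nodes))
  adj <- graph$adj
  deg <- graph$degree
  walk <- function(v, len, invprod) {
    for (w in adj[[v]]) {
      if (visited[w]) next
      score[w] <<- score[w] + beta^(len + 1L) * invprod
      if (len + 1L < max_length) {
        visited[w] <<- TRUE
        walk(w, len + 1L, invprod / deg[w])
        visited[w] <<- FALSE
      }
    }
  }
  visited[i] <- TRUE
  walk(i, 0L, 1)
  score[i] <- 0
  score
}

# Truncated walk series sum_{l=1..L} beta^l A (D^-1 A)^(l-1): interior
# steps are degree-normalised so a walk contributes the reciprocal product
# of its intermediate degrees, with revisits allowed.
.gra_walk_matrix <- function(graph, beta, max_length) {
  n <- length(graph$nodes)
  ei <- match(graph$edges[, 1L], graph$nodes)
  ej <- match(graph$edges[, 2L], graph$nodes)
  A <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = 1,
                            dims = c(n, n))
  Dinv <- Matrix::Diagonal(x = ifelse(graph$degree > 0, 1 / graph$degree, 0))
  S <- beta * A
  term <- A
  if (max_length > 1L) {
    for (l in 2:max_length) {
      term <- term %*% Dinv %*% A # one more degree-normalised interior step
      S <- S + beta^l * term
    }
  }
  S <- as.matrix(S)
  diag(S) <- 0
  dimnames(S) <- list(graph$nodes, graph$nodes)
  S
}

#' GRA similarity between two nodes
#'
#' The global resource allocation similarity is the sum over all paths of
#' length at most `max_length` between the two nodes of
#' `beta^length * path_contribution(path)`: many short paths through
#' low-degree intermediates mean high similarity. `mode = "simple_path"`
#' enumerates simple paths exactly by depth-first search; `mode = "walk"`
#' evaluates the truncated walk series `sum_l beta^l A (D^-1 A)^(l-1)`,
#' which admits revisiting walks and therefore upper-bounds the simple-path
#' score, but scales to dense graphs.
#'
#' @param graph a `kg_graph`.
#' @param i,j distinct node ids.
#' @param beta decay in (0, 1): the weight of a length-`l` path is
#'   `beta^l`, so shorter paths dominate.
#' @param max_length path-length horizon `L >= 1`.
#' @param mode `"simple_path"` (exact, default) or `"walk"`.
#' @return a non-negative similarity score; 0 if no path within the
#'   horizon.
#' @export
gra_pair <- function(graph, i, j, beta = 0.5, max_length = 3L,
                     mode = c("simple_path", "walk")) {
  mode <- match.arg(mode)
  .check_gra_params(beta, max_length)
  ii <- .node_index(graph, i)
  jj <- .node_index(graph, j)
  if (ii == jj) stop("similarity is defined for distinct nodes")
  if (mode == "simple_path") {
    .gra_from(graph, ii, beta, as.integer(max_length))[jj]
  } else {
    .gra_walk_matrix(graph, beta, as.integer(max_length))[ii, jj]
  }
}

.check_gra_params <- function(beta, max_length) {
  if (!(beta > 0 && beta < 1)) stop("beta must lie in (0, 1)")
  if (max_length < 1L) stop("max_length must be at least 1")
  invisible(TRUE)
}

#' Brute-force GRA reference
#'
#' Independent oracle: enumerates every simple path up to the horizon with
#' [igraph::all_simple_paths()] and sums the decayed contributions term by
#' term, sharing no traversal code with [gra_pair()]. Guarded to small
#' graphs because the enumeration is exponential.
#'
#' @inheritParams gra_pair
#' @param max_nodes refuse graphs larger than this (default 12).
#' @return similarity score.
#' @export
gra_bruteforce <- function(graph, i, j, beta = 0.5, max_length = 3L,
                           max_nodes = 12L) {
  .check_gra_params(beta, max_length)
  if (length(graph$nodes) > max_nodes) {
    stop("graph has ", length(graph$nodes), " nodes; brute force is guarded to ",
         max_nodes)
  }
  .node_index(graph, i)
  .node_index(graph, j)
  g <- as_igraph(graph)
  paths <- igraph::all_simple_paths(g, from = i, to = j, cutoff = max_length)
  total <- 0
  for (p in paths) {
    ids <- igraph::V(g)$name[as.integer(p)]
    l <- length(ids) - 1L
    total <- total + beta^l * path_contribution(graph, ids)
  }
  total
}

#' Pairwise GRA similarity matrix over a node subset
#'
#' Paths may traverse any node of the full graph, including nodes of other
#' types, so cross-type intermediates (e.g. a medication bridging two
#' diseases) contribute to within-type similarity.
#'
#' @inheritParams gra_pair
#' @param targets node ids to score (at least one); the matrix rows and
#'   columns follow this order.
#' @param diagonal value for `S[i, i]` (default 0; similarity is defined
#'   for distinct nodes). `"rowmax"` sets each diagonal entry to its row
#'   maximum, which conditions the matrix for factorization.
#' @param scale if `TRUE`, divide by the largest entry (when positive) so
#'   the matrix has unit maximum.
#' @return symmetric non-negative numeric matrix with `targets` dimnames.
#' @export
gra_matrix <- function(graph, targets, beta = 0.5, max_length = 3L,
                       mode = c("simple_path", "walk"), diagonal = 0,
                       scale = FALSE) {
  mode <- match.arg(mode)
  .check_gra_params(beta, max_length)
  if (length(targets) == 0L) stop("empty target set")
  idx <- vapply(targets, .node_index, integer(1L), graph = graph)
  n <- length(targets)
  if (mode == "walk") {
    S <- .gra_walk_matrix(graph, beta, as.integer(max_length))[idx, idx,
                                                               drop = FALSE]
  } else {
    S <- matrix(0, n, n)
    for (a in seq_len(n)) {
      row <- .gra_from(graph, idx[a], beta, as.integer(max_length))
      S[a, ] <- row[idx]
    }
    S <- (S + t(S)) / 2 # exact up to roundoff; enforce symmetry
  }
  dimnames(S) <- list(targets, targets)
  diag(S) <- 0
  if (identical(diagonal, "rowmax")) {
    diag(S) <- apply(S, 1L, max)
  } else {
    diag(S) <- diagonal
  }
  if (scale && max(S) > 0) S <- S / max(S)
  S
}
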