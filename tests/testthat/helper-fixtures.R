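# Shared fixture builders. Everything is generated in code under fixed
# seeds; no binary data ships with the package.

# two patient-centred views over three entities
toy_collection <- function(seed = 1, n1 = 4, n2 = 3, n3 = 5) {
  set.seed(seed)
  matrix_collection(list(
    view_matrix(matrix(rnorm(n1 * n2), n1, n2), "e1", "e2", id = "X1"),
    view_matrix(matrix(rnorm(n1 * n3), n1, n3), "e1", "e3", id = "X2")
  ))
}

# noiseless rank-k collection with known factors
planted_collection <- function(dims = c(e1 = 40, e2 = 30, e3 = 20), k = 2,
                               seed = 1) {
  set.seed(seed)
  u <- lapply(dims, function(d) matrix(rnorm(d * k), d, k))
  coll <- matrix_collection(list(
    view_matrix(u$e1 %*% t(u$e2), "e1", "e2", id = "X1"),
    view_matrix(u$e1 %*% t(u$e3), "e1", "e3", id = "X2")
  ))
  list(collection = coll, factors = u)
}

# Erdos-Renyi-style typed graph on n nodes; NULL when the draw has no edges
random_typed_graph <- function(n, p = 0.3, types = c("disease", "medication"),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pair <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- runif(nrow(pair)) < p
  if (!any(keep)) return(NULL)
  kg_graph(cbind(ids[pair[keep, 1]], ids[pair[keep, 2]]),
           setNames(sample(types, n, replace = TRUE), ids))
}

# independent walk-mode oracle: enumerate every walk of length <= L by
# recursion, normalising interior degrees, sharing nothing with gra_*
walk_score_oracle <- function(graph, i, j, beta, L) {
  ii <- match(i, graph$nodes)
  jj <- match(j, graph$nodes)
  total <- 0
  rec <- function(v, len, invprod) {
    if (len > 0 && v == jj) total <<- total + beta^len * invprod
    if (len == L) return()
    step <- if (len >= 1) invprod / graph$degree[v] else invprod
    for (w in graph$adj[[v]]) rec(w, len + 1L, step)
  }
  rec(ii, 0L, 1)
  total
}

demo_path <- function(file) system.file("extdata", file, package = "deepcmf")
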