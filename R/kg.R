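#' Filter subject-predicate-object triplets
#'
#' Applies the standard cleaning for literature-derived predication
#' extracts: drops ontological predicates that do not relate clinical
#' concepts directly (by default `PART_OF`, `LOCATION_OF`, `PROCESS_OF`),
#' drops negated assertions (predicates beginning with `NEG`), and
#' restricts both endpoints to a concept vocabulary. Predicate names are
#' upper-cased before matching.
#'
#' @param triplets data.frame with columns `subject`, `predicate`,
#'   `object` (see [read_triplets()]).
#' @param excluded_predicates predicate names to drop.
#' @param negation_prefix prefix marking negated predicates.
#' @param vocabulary allowed concept ids (character vector or the named
#'   type vector from [read_vocabulary()]); `NULL` disables the
#'   restriction.
#' @return list with `triplets` (the survivors, original order) and
#'   `tally`, a named integer vector with counts `kept`,
#'   `excluded_predicate`, `negation`, `out_of_vocabulary`.
#' @export
filter_triplets <- function(triplets,
                            excluded_predicates = c("PART_OF", "LOCATION_OF",
                                                    "PROCESS_OF"),
                            negation_prefix = "NEG",
                            vocabulary = NULL) {
  stopifnot(all(c("subject", "predicate", "object") %in% names(triplets)))
  pred <- toupper(triplets$predicate)
  drop_neg <- startsWith(pred, negation_prefix)
  drop_excl <- !drop_neg & pred %in% toupper(excluded_predicates)
  drop_oov <- rep(FALSE, nrow(triplets))
  if (!is.null(vocabulary)) {
    vocab <- if (!is.null(names(vocabulary))) names(vocabulary) else vocabulary
    drop_oov <- !drop_neg & !drop_excl &
      !(triplets$subject %in% vocab & triplets$object %in% vocab)
  }
  keep <- !(drop_neg | drop_excl | drop_oov)
  list(
    triplets = triplets[keep, , drop = FALSE],
    tally = c(kept = sum(keep),
              excluded_predicate = sum(drop_excl),
              negation = sum(drop_neg),
              out_of_vocabulary = sum(drop_oov))
  )
}

#' Build an undirected concept graph from filtered triplets
#'
#' Every subject or object becomes a node; an edge joins two concepts if
#' any predicate relates them, in either direction. Multiple triplets
#' between the same pair collapse to one edge: edges record only the
#' existence of a relation, not its type. Self-relations are dropped.
#'
#' @param triplets filtered triplet data.frame.
#' @param types named character vector mapping every mentioned concept to a
#'   node type; a missing concept is an error naming it.
#' @return a [kg_graph()].
#' @export
build_graph <- function(triplets, types) {
  mentioned <- unique(c(triplets$subject, triplets$object))
  missing <- setdiff(mentioned, names(types))
  if (length(missing)) {
    stop("concept(s) missing from the type map: ",
         paste(missing, collapse = ", "))
  }
  kg_graph(cbind(triplets$subject, triplets$object), types)
}

#' Per-type GRA similarity matrices
#'
#' For each node type present in the graph, computes the pairwise GRA
#' similarity matrix over that type's nodes. Similarities are computed on
#' the full heterogeneous graph, so paths through nodes of other types
#' contribute. Types with fewer than two nodes are omitted with a warning.
#'
#' @param graph a `kg_graph`.
#' @inheritParams gra_pair
#' @param ... further arguments to [gra_matrix()] (`diagonal`, `scale`).
#' @return named list of symmetric similarity matrices, one per type, node
#'   order sorted within type.
#' @export
type_similarity_matrices <- function(graph, beta = 0.5, max_length = 3L,
                                     mode = c("simple_path", "walk"), ...) {
  mode <- match.arg(mode)
  if (length(graph$nodes) == 0L) stop("empty graph")
  out <- list()
  for (tp in sort(unique(graph$types))) {
    members <- sort(graph$nodes[graph$types == tp])
    if (length(members) < 2L) {
      warning("type '", tp, "' has fewer than 2 nodes; omitted")
      next
    }
    out[[tp]] <- gra_matrix(graph, members, beta = beta,
                            max_length = max_length, mode = mode, ...)
  }
  out
}

#' Align a similarity matrix to a concept list
#'
#' Expands a per-type similarity matrix to the full column vocabulary of a
#' patient view: concepts present in the view but absent from the graph get
#' zero similarity rows/columns, so the square view's dimension matches the
#' patient view's column dimension.
#'
#' @param sim symmetric similarity matrix with concept-id dimnames.
#' @param concepts ordered concept ids of the target view.
#' @return square matrix over `concepts`.
#' @export
align_similarity <- function(sim, concepts) {
  out <- matrix(0, length(concepts), length(concepts),
                dimnames = list(concepts, concepts))
  shared <- intersect(concepts, rownames(sim))
  out[shared, shared] <- sim[shared, shared]
  out
}
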