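#' Construct a single view matrix
#'
#' A view is one relational matrix relating two entity types: rows index
#' instances of the row entity, columns instances of the column entity
#' (e.g. patient episodes by diseases). A collection of views over shared
#' entities is the input to collective matrix factorization.
#'
#' @param values numeric matrix (dense or a \pkg{Matrix} sparse matrix).
#' @param row_entity,col_entity entity identifiers (short strings). A view
#'   may relate an entity to itself (a square self-view, e.g. a
#'   disease-by-disease similarity matrix), in which case `values` must be
#'   square.
#' @param id view identifier; views in a collection are ordered by id.
#' @param value_kind one of `"real"`, `"count"`, `"binary"`. Binary views
#'   must contain only 0/1; count views only non-negative integers.
#' @return an object of class `view_matrix`.
#' @export
view_matrix <- function(values, row_entity, col_entity,
                        id = paste0(row_entity, "_", col_entity),
                        value_kind = c("real", "count", "binary")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("view '", id, "': values must be numeric")
  if (row_entity == col_entity && nrow(values) != ncol(values)) {
    stop("view '", id, "': self-view on entity '", row_entity,
         "' must be square")
  }
  v <- as.vector(values)
  if (value_kind == "binary" && !all(v %in% c(0, 1))) {
    stop("view '", id, "': binary view contains values outside {0, 1}")
  }
  if (value_kind == "count" && (any(v < 0) || any(v != round(v)))) {
    stop("view '", id, "': count view contains negative or non-integer values")
  }
  structure(
    list(id = as.character(id), row_entity = as.character(row_entity),
         col_entity = as.character(col_entity), values = values,
         value_kind = value_kind),
    class = "view_matrix"
  )
}

#' @export
print.view_matrix <- function(x, ...) {
  cat(sprintf("<view_matrix '%s'> %s x %s (%d x %d, %s)\n", x$id,
              x$row_entity, x$col_entity, nrow(x$values), ncol(x$values),
              x$value_kind))
  invisible(x)
}

#' Assemble views into a matrix collection
#'
#' Entity dimensions are inferred from the view shapes and cross-checked:
#' two views sharing an entity must agree on its dimension. The collection
#' is the "augmented multi-view" input: entity types may recur across
#' matrices in any pattern.
#'
#' @param views a list of [view_matrix()] objects with unique ids.
#' @return an object of class `matrix_collection` with elements `entities`
#'   (named integer vector of dimensions) and `views` (named list, ordered
#'   by view id).
#' @export
matrix_collection <- function(views) {
  if (inherits(views, "view_matrix")) views <- list(views)
  if (length(views) == 0L) stop("a collection needs at least one view")
  if (!all(vapply(views, inherits, logical(1L), "view_matrix"))) {
    stop("all elements must be view_matrix objects")
  }
  ids <- vapply(views, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate view ids: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))
  }
  views <- views[order(ids)]
  names(views) <- sort(ids)
  entities <- integer(0L)
  for (v in views) {
    for (side in list(c(v$row_entity, nrow(v$values)),
                      c(v$col_entity, ncol(v$values)))) {
      e <- side[[1L]]
      d <- as.integer(side[[2L]])
      if (is.na(entities[e])) {
        entities[e] <- d
      } else if (entities[e] != d) {
        stop("dimension conflict for entity '", e, "': view '", v$id,
             "' implies ", d, " but an earlier view implies ", entities[e])
      }
    }
  }
  coll <- structure(list(entities = entities, views = views),
                    class = "matrix_collection")
  diag <- validate_collection(coll)
  if (length(diag$errors)) stop(paste(diag$errors, collapse = "; "))
  for (w in diag$warnings) warning(w, call. = FALSE)
  coll
}

#' @export
print.matrix_collection <- function(x, ...) {
  cat(sprintf("<matrix_collection> %d entities, %d views\n",
              length(x$entities), length(x$views)))
  for (e in names(x$entities)) cat(sprintf("  entity %-12s d = %d\n", e,
                                           x$entities[[e]]))
  for (v in x$views) {
    cat(sprintf("  view %-10s %s x %s (%d x %d, %s)\n", v$id, v$row_entity,
                v$col_entity, nrow(v$values), ncol(v$values), v$value_kind))
  }
  invisible(x)
}

#' Validate a matrix collection
#'
#' Reports, never raises: returns invariant violations as errors
#' (undeclared entities, shape mismatches, entities in no view) and
#' diagnostics as warnings (disconnected entity-view graph, constant
#' columns in a view).
#'
#' @param collection a `matrix_collection` (or a bare list with `entities`
#'   and `views`, so partially built objects can be checked).
#' @return list with character vectors `errors` and `warnings`.
#' @export
validate_collection <- function(collection) {
  errors <- character(0L)
  warnings <- character(0L)
  ents <- collection$entities
  used <- character(0L)
  for (v in collection$views) {
    for (side in c("row_entity", "col_entity")) {
      e <- v[[side]]
      if (is.na(ents[e])) {
        errors <- c(errors, sprintf("view '%s': unknown entity '%s'", v$id, e))
      }
    }
    if (!is.na(ents[v$row_entity]) && nrow(v$values) != ents[v$row_entity]) {
      errors <- c(errors, sprintf(
        "view '%s': %d rows but entity '%s' has dimension %d",
        v$id, nrow(v$values), v$row_entity, ents[v$row_entity]))
    }
    if (!is.na(ents[v$col_entity]) && ncol(v$values) != ents[v$col_entity]) {
      errors <- c(errors, sprintf(
        "view '%s': %d columns but entity '%s' has dimension %d",
        v$id, ncol(v$values), v$col_entity, ents[v$col_entity]))
    }
    used <- c(used, v$row_entity, v$col_entity)
    const <- apply(v$values, 2L, function(col) length(unique(col)) == 1L)
    if (any(const)) {
      warnings <- c(warnings, sprintf("view '%s': %d constant column(s)",
                                      v$id, sum(const)))
    }
  }
  orphan <- setdiff(names(ents), used)
  for (e in orphan) {
    errors <- c(errors, sprintf("entity '%s' appears in no view", e))
  }
  # connectivity of the bipartite entity-view graph, via shared entities
  if (length(collection$views) > 1L) {
    vs <- collection$views
    n <- length(vs)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (length(intersect(c(vs[[i]]$row_entity, vs[[i]]$col_entity),
                             c(vs[[j]]$row_entity, vs[[j]]$col_entity)))) {
          g <- igraph::add_edges(g, c(i, j))
        }
      }
    }
    if (igraph::components(g)$no > 1L) {
      warnings <- c(warnings,
                    "entity-view graph is disconnected: the collection falls into independent groups")
    }
  }
  list(errors = errors, warnings = warnings)
}

#' Concatenated matrix for one entity
#'
#' Builds `C^(e)`: the side-by-side assembly of every view touching entity
#' `e`. Views with `e` as row entity contribute as-is; views with `e` as
#' column entity contribute their transpose; a square self-view contributes
#' exactly one block (as-is). Blocks are ordered by ascending view id, so
#' the layout is deterministic and each original view is recoverable from
#' its block.
#'
#' @param collection a `matrix_collection`.
#' @param entity entity id.
#' @return an object of class `concatenated_matrix` with elements `entity`,
#'   `values` (d_e by total width) and `blocks` (data.frame of view id,
#'   orientation and column offsets).
#' @export
concatenate_entity <- function(collection, entity) {
  if (is.na(collection$entities[entity])) {
    stop("unknown entity '", entity, "'")
  }
  blocks <- list()
  mats <- list()
  offset <- 0L
  for (v in collection$views) { # views are stored in ascending id order
    hit_row <- v$row_entity == entity
    hit_col <- v$col_entity == entity
    if (!hit_row && !hit_col) next
    m <- if (hit_row) v$values else t(v$values) # self-view: one block, as-is
    orientation <- if (hit_row) "as-is" else "transposed"
    blocks[[length(blocks) + 1L]] <- data.frame(
      view = v$id, orientation = orientation,
      from = offset + 1L, to = offset + ncol(m))
    offset <- offset + ncol(m)
    mats[[length(mats) + 1L]] <- m
  }
  if (length(mats) == 0L) stop("entity '", entity, "' appears in no view")
  structure(
    list(entity = entity, values = do.call(cbind, mats),
         blocks = do.call(rbind, blocks)),
    class = "concatenated_matrix"
  )
}

#' @export
print.concatenated_matrix <- function(x, ...) {
  cat(sprintf("<concatenated_matrix> entity '%s', %d x %d, %d block(s)\n",
              x$entity, nrow(x$values), ncol(x$values), nrow(x$blocks)))
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Recover an original view from a concatenated matrix
#'
#' Inverse of the block layout of [concatenate_entity()]: extracts the
#' named view's block and undoes the transpose if the entity sat on the
#' column side.
#'
#' @param concat a `concatenated_matrix`.
#' @param view view id present in `concat$blocks`.
#' @return the view's numeric matrix in its original orientation.
#' @export
extract_view_block <- function(concat, view) {
  b <- concat$blocks[concat$blocks$view == view, , drop = FALSE]
  if (nrow(b) == 0L) stop("view '", view, "' is not a block of this matrix")
  m <- concat$values[, b$from:b$to, drop = FALSE]
  if (b$orientation == "transposed") m <- t(m)
  m
}
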