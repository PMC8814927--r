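# File-format plumbing: YAML collection manifests with Matrix Market or CSV
# matrices, TSV triplet/vocabulary/edge lists. Matrix Market I/O goes
# through the Matrix package; nothing here is hand-parsed.

.read_matrix_file <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    as.matrix(Matrix::readMM(path))
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    storage.mode(m) <- "double"
    m
  }
}

.write_matrix_file <- function(m, path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  } else {
    df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)), m,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a matrix collection from a YAML manifest
#'
#' The manifest maps view id to `{file, row_entity, col_entity,
#' value_kind}`. Files may be Matrix Market (`.mtx`) or dense CSV with a
#' header row and row labels in the first column; paths are resolved
#' relative to the manifest.
#'
#' @param manifest path to a YAML manifest file.
#' @return a [matrix_collection()].
#' @export
read_collection <- function(manifest) {
  spec <- yaml::read_yaml(manifest)
  base <- dirname(manifest)
  views <- lapply(names(spec), function(id) {
    s <- spec[[id]]
    for (f in c("file", "row_entity", "col_entity")) {
      if (is.null(s[[f]])) stop("manifest entry '", id, "' lacks field '", f, "'")
    }
    view_matrix(.read_matrix_file(file.path(base, s$file)),
                row_entity = s$row_entity, col_entity = s$col_entity,
                id = id, value_kind = s$value_kind %||% "real")
  })
  matrix_collection(views)
}

#' Write a matrix collection to a directory with a YAML manifest
#'
#' @param collection a `matrix_collection`.
#' @param dir output directory (created if needed).
#' @param format `"mtx"` for Matrix Market or `"csv"`.
#' @return the manifest path, invisibly.
#' @export
write_collection <- function(collection, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- list()
  for (v in collection$views) {
    file <- paste0(v$id, ".", format)
    .write_matrix_file(v$values, file.path(dir, file))
    spec[[v$id]] <- list(file = file, row_entity = v$row_entity,
                         col_entity = v$col_entity, value_kind = v$value_kind)
  }
  path <- file.path(dir, "collection.yaml")
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Read knowledge-graph triplets from TSV
#'
#' Expects columns `SUBJECT_CUI`, `PREDICATE`, `OBJECT_CUI` (the layout of
#' a SemMedDB PREDICATION extract); extra columns are ignored.
#'
#' @param path TSV file path.
#' @return data.frame with columns `subject`, `predicate`, `object`.
#' @export
read_triplets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("SUBJECT_CUI", "PREDICATE", "OBJECT_CUI")
  if (!all(need %in% names(df))) {
    stop("triplet file must have columns ", paste(need, collapse = ", "))
  }
  data.frame(subject = as.character(df$SUBJECT_CUI),
             predicate = as.character(df$PREDICATE),
             object = as.character(df$OBJECT_CUI),
             stringsAsFactors = FALSE)
}

#' Read a concept vocabulary from TSV
#'
#' @param path TSV with columns `concept` and `type`.
#' @return named character vector mapping concept id to node type.
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("concept", "type") %in% names(df))) {
    stop("vocabulary file must have columns 'concept' and 'type'")
  }
  stats::setNames(as.character(df$type), as.character(df$concept))
}

#' Export latent factors as CSV files
#'
#' One file per entity, instances by latent dimensions, with header
#' `k0..k{k-1}` and instance ids in the first column.
#'
#' @param factors named list of factor matrices (as from [coef.dcmf()]).
#' @param dir output directory.
#' @return the written paths, invisibly.
#' @export
write_factors <- function(factors, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(factors), function(e) {
    m <- factors[[e]]
    colnames(m) <- paste0("k", seq_len(ncol(m)) - 1L)
    df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)), m)
    p <- file.path(dir, paste0(e, "_factors.csv"))
    utils::write.csv(df, p, row.names = FALSE)
    p
  }, character(1L))
  invisible(paths)
}
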