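#' Build a per-episode concept matrix from mention records
#'
#' Mention records (episode id, concept id, count) become one view: rows
#' follow the supplied episode order, columns the supplied concept order,
#' absent pairs are 0. Disease matrices are binary (presence/absence of
#' the concept anywhere in the episode's notes); medication, procedure and
#' lab matrices are count matrices (number of mentions). Duplicate
#' (episode, concept) records are summed before binarisation.
#'
#' @param mentions data.frame with columns `episode`, `concept`, `count`
#'   (a `type` column, if present, is ignored: filter before calling).
#' @param concept_type one of `"disease"`, `"medication"`, `"procedure"`,
#'   `"lab"`.
#' @param episodes ordered episode ids (matrix rows).
#' @param concepts ordered concept ids (matrix columns).
#' @param row_entity,id passed to [view_matrix()]; the column entity is the
#'   concept type.
#' @return a [view_matrix()] (binary for disease, count otherwise).
#' @export
concept_matrix <- function(mentions, concept_type = c("disease", "medication",
                                                      "procedure", "lab"),
                           episodes, concepts, row_entity = "episode",
                           id = paste0(row_entity, "_", concept_type)) {
  concept_type <- match.arg(concept_type)
  stopifnot(all(c("episode", "concept", "count") %in% names(mentions)))
  m <- matrix(0, length(episodes), length(concepts),
              dimnames = list(as.character(episodes), as.character(concepts)))
  if (nrow(mentions)) {
    ri <- match(as.character(mentions$episode), rownames(m))
    ci <- match(as.character(mentions$concept), colnames(m))
    if (anyNA(ri)) {
      stop("unknown episode id(s): ",
           paste(unique(mentions$episode[is.na(ri)]), collapse = ", "))
    }
    if (anyNA(ci)) {
      stop("unknown concept id(s): ",
           paste(unique(mentions$concept[is.na(ci)]), collapse = ", "))
    }
    if (any(mentions$count < 1)) stop("mention counts must be >= 1")
    for (r in seq_along(ri)) {
      m[ri[r], ci[r]] <- m[ri[r], ci[r]] + mentions$count[r]
    }
  }
  if (concept_type == "disease") {
    m <- (m > 0) * 1
    kind <- "binary"
  } else {
    kind <- "count"
  }
  view_matrix(m, row_entity = row_entity, col_entity = concept_type,
              id = id, value_kind = kind)
}

#' TF-IDF transform of a concept matrix
#'
#' Each concept is a term and each episode row a document:
#' `cell(i, j) = tf(i, j) * idf(j)`. The smooth inverse document frequency
#' is `idf(j) = ln((1 + N) / (1 + df_j)) + 1` with `N` the number of rows
#' and `df_j` the number of rows where concept `j` occurs, so it is finite
#' even for an all-zero column; the plain variant is
#' `idf(j) = ln(N / df_j) + 1`. Raw term frequency is the cell value
#' itself; the log variant uses `1 + ln(count)` for nonzero cells.
#' Zero cells always stay zero, so the support of the matrix is preserved.
#'
#' @param x a [view_matrix()] or non-negative numeric matrix.
#' @param tf `"raw"` or `"log"`.
#' @param idf `"smooth"` or `"plain"`.
#' @return same class as `x`, with real values; a `view_matrix` comes back
#'   with `value_kind = "real"` and a `tfidf` attribute recording the
#'   variants.
#' @export
tfidf <- function(x, tf = c("raw", "log"), idf = c("smooth", "plain")) {
  tf <- match.arg(tf)
  idf <- match.arg(idf)
  m <- if (inherits(x, "view_matrix")) x$values else as.matrix(x)
  if (any(m < 0)) stop("tf-idf requires non-negative input")
  n <- nrow(m)
  df <- colSums(m > 0)
  w <- if (idf == "smooth") {
    log((1 + n) / (1 + df)) + 1
  } else {
    ifelse(df > 0, log(n / df) + 1, 0) # empty columns stay zero either way
  }
  tfm <- if (tf == "raw") m else ifelse(m > 0, 1 + log(m), 0)
  out <- tfm * rep(w, each = n)
  dimnames(out) <- dimnames(m)
  if (inherits(x, "view_matrix")) {
    v <- view_matrix(out, row_entity = x$row_entity, col_entity = x$col_entity,
                     id = x$id, value_kind = "real")
    attr(v, "tfidf") <- c(tf = tf, idf = idf)
    v
  } else {
    out
  }
}
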