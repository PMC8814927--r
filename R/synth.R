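#' Specification of a synthetic multi-view study
#'
#' Defines the generative conditions for a synthetic cohort with known
#' latent structure: patient and concept counts, the planted rank, the view
#' topology, observation noise, the knowledge-graph edge model and the
#' label model. Every generator in the package draws from this object, and
#' each component (views, graph, labels) uses its own seeded stream so that
#' changing, say, the graph seed leaves the views untouched.
#'
#' Defaults describe a desk-scale cohort: 500 patient episodes; 40
#' diseases, 30 medications, 20 procedures and 15 labs; rank 3; moderate
#' observation noise; a graph whose edge odds increase with the cosine
#' similarity of the planted concept factors (so path-based similarity is
#' informative about the latent structure by construction); and binary
#' logistic labels with roughly 12\% prevalence, the order of class
#' imbalance typical of one-year mortality cohorts.
#'
#' @param n_patients number of patient episodes.
#' @param concepts named integer vector of per-type concept counts; names
#'   become entity ids.
#' @param rank planted latent rank `k*`.
#' @param noise_sd standard deviation of the Gaussian noise added to each
#'   view before any link transform.
#' @param binary_quantile binary views threshold the noisy real view at
#'   this empirical quantile (0.5 keeps density near one half).
#' @param count_scale count views apply `round(exp(count_scale * x))` to
#'   the noisy real view, giving skewed non-negative integers.
#' @param kg list: `intercept` and `slope` of the logistic edge model on
#'   factor cosine similarity, plus `fraction_negated` and
#'   `fraction_excluded`, the fractions of additional noise triplets with
#'   NEG-prefixed and excluded predicates emitted to exercise filtering.
#' @param labels list: `classes` (2 for binary), `scale` (coefficient
#'   scale), `prevalence` (target positive rate for binary labels; the
#'   default 0.5 keeps accuracy an informative comparison metric — set it
#'   to ~0.12 to emulate the imbalance of a one-year mortality cohort).
#' @param seed base seed; `kg_seed` and `label_seed` default to offsets of
#'   it but can be set independently.
#' @param kg_seed,label_seed per-component seeds.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_patients = 500L,
                       concepts = c(disease = 40L, medication = 30L,
                                    procedure = 20L, lab = 15L),
                       rank = 3L, noise_sd = 0.5, binary_quantile = 0.5,
                       count_scale = 0.5,
                       kg = list(intercept = -2, slope = 6,
                                 fraction_negated = 0.05,
                                 fraction_excluded = 0.05),
                       labels = list(classes = 2L, scale = 1,
                                     prevalence = 0.5),
                       seed = 1L, kg_seed = NULL, label_seed = NULL) {
  if (rank < 1L) stop("rank must be at least 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(n_patients >= 1L, all(concepts >= 1L))
  kg_def <- list(intercept = -2, slope = 6, fraction_negated = 0.05,
                 fraction_excluded = 0.05)
  kg_def[names(kg)] <- kg
  lab_def <- list(classes = 2L, scale = 1, prevalence = 0.5)
  lab_def[names(labels)] <- labels
  if (lab_def$classes < 2L) stop("label model needs at least 2 classes")
  structure(
    list(n_patients = as.integer(n_patients), concepts = concepts,
         rank = as.integer(rank), noise_sd = noise_sd,
         binary_quantile = binary_quantile, count_scale = count_scale,
         kg = kg_def, labels = lab_def, seed = as.integer(seed),
         kg_seed = as.integer(kg_seed %||% (seed + 1000L)),
         label_seed = as.integer(label_seed %||% (seed + 2000L))),
    class = "synth_spec"
  )
}

.concept_ids <- function(type, n) {
  sprintf("%s%03d", toupper(substr(type, 1L, 1L)), seq_len(n))
}

.apply_link <- function(raw, kind, spec) {
  switch(kind,
    real = raw,
    count = round(exp(spec$count_scale * raw)),
    binary = (raw > stats::quantile(raw, spec$binary_quantile)) * 1
  )
}

#' Simulate a multi-view collection from planted factors
#'
#' Draws a factor matrix `U*_e` (standard normal, `d_e` by `k*`) per
#' entity, then builds each declared view as `U*_r U*_c' + noise`,
#' transformed by the view's value kind: count views by exponentiation and
#' rounding, binary views by quantile thresholding. Ground truth is always
#' returned alongside the data.
#'
#' @param spec a [synth_spec()].
#' @param views view topology: a list of `list(row =, col =, kind =, id =)`
#'   entries over entity ids; defaults to the notes-style layout of one
#'   binary disease view and count medication/procedure views against
#'   patients.
#' @return list with `collection` (a [matrix_collection()]) and `factors`
#'   (named list of the true `U*_e`).
#' @export
simulate_collection <- function(spec = synth_spec(), views = NULL) {
  if (is.null(views)) {
    views <- list(
      list(row = "patient", col = "disease", kind = "binary",
           id = "notes_disease"),
      list(row = "patient", col = "medication", kind = "count",
           id = "notes_medication"),
      list(row = "patient", col = "procedure", kind = "count",
           id = "notes_procedure")
    )
  }
  dims <- c(patient = spec$n_patients, spec$concepts)
  wanted <- unique(unlist(lapply(views, function(v) c(v$row, v$col))))
  unknown <- setdiff(wanted, names(dims))
  if (length(unknown)) {
    stop("view topology references undeclared entity: ",
         paste(unknown, collapse = ", "))
  }
  set.seed(spec$seed)
  factors <- lapply(names(dims), function(e) {
    u <- matrix(stats::rnorm(dims[[e]] * spec$rank), dims[[e]], spec$rank)
    rownames(u) <- if (e == "patient") sprintf("ep%04d", seq_len(dims[[e]]))
                   else .concept_ids(e, dims[[e]])
    u
  })
  names(factors) <- names(dims)
  vms <- lapply(views, function(v) {
    raw <- tcrossprod(factors[[v$row]], factors[[v$col]])
    if (spec$noise_sd > 0) {
      raw <- raw + matrix(stats::rnorm(length(raw), sd = spec$noise_sd),
                          nrow(raw), ncol(raw))
    }
    m <- .apply_link(raw, v$kind, spec)
    dimnames(m) <- list(rownames(factors[[v$row]]),
                        rownames(factors[[v$col]]))
    view_matrix(m, v$row, v$col, id = v$id %||% paste0(v$row, "_", v$col),
                value_kind = v$kind)
  })
  list(collection = matrix_collection(vms), factors = factors[wanted])
}

#' Simulate a knowledge graph from concept factors
#'
#' Adds an edge between two concepts with probability
#' `plogis(intercept + slope * cosine)` of their true factor rows, so that
#' graph proximity reflects latent similarity and path-based similarity on
#' the graph is informative about the planted structure. Each edge is
#' emitted as an `ASSOCIATED_WITH` triplet; on top, configurable fractions
#' of NEG-prefixed and excluded-predicate noise triplets are emitted so
#' downstream filtering has something to remove.
#'
#' @param spec a [synth_spec()].
#' @param concept_factors named list of true factor matrices for the
#'   concept entities to include as graph nodes (typically disease,
#'   medication, procedure); row names are the concept ids.
#' @return list with `triplets` (data.frame), `types` (named node-type
#'   vector), `graph` (a [kg_graph()] built from the filtered edges) and
#'   `edge_prob` (the full probability matrix, for diagnostics).
#' @export
simulate_kg <- function(spec, concept_factors) {
  u <- do.call(rbind, unname(concept_factors))
  ids <- rownames(u)
  types <- stats::setNames(
    rep(names(concept_factors), vapply(concept_factors, nrow, integer(1L))),
    ids)
  nrm <- sqrt(rowSums(u * u))
  cosine <- tcrossprod(u / pmax(nrm, .Machine$double.eps))
  prob <- stats::plogis(spec$kg$intercept + spec$kg$slope * cosine)
  set.seed(spec$kg_seed)
  n <- length(ids)
  pairs <- which(upper.tri(prob), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < prob[pairs]
  edges <- pairs[keep, , drop = FALSE]
  triplets <- data.frame(subject = ids[edges[, 1L]],
                         predicate = "ASSOCIATED_WITH",
                         object = ids[edges[, 2L]],
                         stringsAsFactors = FALSE)
  n_edges <- nrow(triplets)
  noise <- function(k, preds) {
    if (k == 0L) return(NULL)
    data.frame(subject = ids[sample.int(n, k, replace = TRUE)],
               predicate = sample(preds, k, replace = TRUE),
               object = ids[sample.int(n, k, replace = TRUE)],
               stringsAsFactors = FALSE)
  }
  triplets <- rbind(
    triplets,
    noise(round(spec$kg$fraction_negated * n_edges),
          c("NEG_ASSOCIATED_WITH", "NEG_TREATS")),
    noise(round(spec$kg$fraction_excluded * n_edges),
          c("PART_OF", "LOCATION_OF", "PROCESS_OF"))
  )
  clean <- filter_triplets(triplets, vocabulary = types)
  graph <- build_graph(clean$triplets, types)
  list(triplets = triplets, types = types, graph = graph, edge_prob = prob)
}

#' Simulate labels from patient factors
#'
#' Binary labels follow a logistic model on the true patient factors: the
#' linear score is `scale * U* b` with standard-normal coefficients `b`,
#' the intercept is tuned so the expected positive rate matches the
#' requested prevalence, and labels are Bernoulli draws from the resulting
#' probabilities. Multiclass labels are the argmax of
#' `U* B` class scores. The returned Bayes accuracy is the accuracy of the
#' optimal rule that knows the generative model, estimated on a large
#' fresh Monte-Carlo holdout; it bounds what any classifier can reach.
#'
#' @param patient_factors true patient factor matrix (`n` by `k*`).
#' @param spec a [synth_spec()] (uses its `labels` model and `label_seed`).
#' @param n_holdout Monte-Carlo size for the Bayes-accuracy estimate.
#' @return list with `y` (labels: 0/1 vector or factor), `probabilities`
#'   (binary only), `coefficients`, `intercept`, `bayes_accuracy`.
#' @export
simulate_labels <- function(patient_factors, spec = synth_spec(),
                            n_holdout = 20000L) {
  lm <- spec$labels
  k <- ncol(patient_factors)
  set.seed(spec$label_seed)
  if (lm$classes == 2L) {
    b <- stats::rnorm(k)
    eta <- lm$scale * drop(patient_factors %*% b)
    icpt <- stats::uniroot(
      function(c0) mean(stats::plogis(eta + c0)) - lm$prevalence,
      interval = c(-30, 30))$root
    p <- stats::plogis(eta + icpt)
    y <- stats::rbinom(length(p), 1L, p)
    u_new <- matrix(stats::rnorm(n_holdout * k), n_holdout, k)
    p_new <- stats::plogis(lm$scale * drop(u_new %*% b) + icpt)
    bayes <- mean(pmax(p_new, 1 - p_new))
    list(y = y, probabilities = p, coefficients = b, intercept = icpt,
         bayes_accuracy = bayes)
  } else {
    B <- matrix(stats::rnorm(k * lm$classes), k, lm$classes) * lm$scale
    scores <- patient_factors %*% B
    y <- factor(max.col(scores, ties.method = "first"),
                levels = seq_len(lm$classes))
    list(y = y, coefficients = B, intercept = rep(0, lm$classes),
         bayes_accuracy = 1)
  }
}

#' Simulate the three cumulative study views
#'
#' Emulates the cumulative experimental layout: view 1 is the notes-style
#' concept matrices (binary disease, count medication/procedure) with
#' TF-IDF applied; view 2 adds one square GRA similarity view per concept
#' type, computed from a simulated knowledge graph whose edges reflect the
#' planted concept factors; view 3 further adds structured count views
#' (prescriptions and laboratory events) for the same patients. All three
#' collections share ids and ground truth.
#'
#' @param spec a [synth_spec()].
#' @param gra_beta,gra_max_length,gra_mode parameters for the GRA
#'   similarity matrices of view 2.
#' @return an object of class `dcmf_bundle`: list with `view1`, `view2`,
#'   `view3` (matrix collections), `labels` (see [simulate_labels()]),
#'   `factors` (ground truth), `kg` (triplets, graph), `similarities`, and
#'   the `spec`.
#' @export
simulate_bundle <- function(spec = synth_spec(), gra_beta = 0.5,
                            gra_max_length = 3L,
                            gra_mode = c("simple_path", "walk")) {
  gra_mode <- match.arg(gra_mode)
  base_views <- list(
    list(row = "patient", col = "disease", kind = "binary",
         id = "notes_disease"),
    list(row = "patient", col = "medication", kind = "count",
         id = "notes_medication"),
    list(row = "patient", col = "procedure", kind = "count",
         id = "notes_procedure"),
    list(row = "patient", col = "medication", kind = "count",
         id = "struct_medication"),
    list(row = "patient", col = "lab", kind = "count", id = "struct_lab")
  )
  sim <- simulate_collection(spec, base_views)
  notes_ids <- c("notes_disease", "notes_medication", "notes_procedure")
  notes <- lapply(sim$collection$views[notes_ids], tfidf)
  structured <- sim$collection$views[c("struct_medication", "struct_lab")]

  kg_types <- intersect(c("disease", "medication", "procedure"),
                        names(spec$concepts))
  kg <- simulate_kg(spec, sim$factors[kg_types])
  sims <- type_similarity_matrices(kg$graph, beta = gra_beta,
                                   max_length = gra_max_length,
                                   mode = gra_mode)
  sim_views <- lapply(names(sims), function(tp) {
    aligned <- align_similarity(sims[[tp]], rownames(sim$factors[[tp]]))
    view_matrix(aligned, tp, tp, id = paste0("kg_", tp), value_kind = "real")
  })

  bundle <- list(
    view1 = matrix_collection(notes),
    view2 = matrix_collection(c(notes, sim_views)),
    view3 = matrix_collection(c(notes, sim_views, structured)),
    labels = simulate_labels(sim$factors$patient, spec),
    factors = sim$factors, kg = kg, similarities = sims, spec = spec
  )
  class(bundle) <- "dcmf_bundle"
  bundle
}

#' @export
print.dcmf_bundle <- function(x, ...) {
  cat(sprintf("<dcmf_bundle> %d patients, rank %d, seed %d\n",
              x$spec$n_patients, x$spec$rank, x$spec$seed))
  for (v in paste0("view", 1:3)) {
    cat(sprintf("  %s: %d views, %d entities\n", v, length(x[[v]]$views),
                length(x[[v]]$entities)))
  }
  if (!is.null(x$labels$bayes_accuracy)) {
    cat(sprintf("  labels: prevalence %.3f, Bayes accuracy %.3f\n",
                mean(x$labels$y == 1), x$labels$bayes_accuracy))
  }
  invisible(x)
}

#' Write a bundle to disk as plain-text files
#'
#' Emits, per view level, a manifest plus Matrix Market files (via
#' [write_collection()]), the knowledge-graph triplets and vocabulary as
#' TSV, and the labels as CSV, so every file is consumable by the
#' file-based entry points.
#'
#' @param bundle a `dcmf_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in paste0("view", 1:3)) {
    write_collection(bundle[[v]], file.path(dir, v))
  }
  utils::write.table(
    data.frame(SUBJECT_CUI = bundle$kg$triplets$subject,
               PREDICATE = bundle$kg$triplets$predicate,
               OBJECT_CUI = bundle$kg$triplets$object),
    file.path(dir, "triplets.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(
    data.frame(concept = names(bundle$kg$types), type = bundle$kg$types),
    file.path(dir, "vocabulary.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.csv(
    data.frame(episode = rownames(bundle$factors$patient),
               label = bundle$labels$y),
    file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
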