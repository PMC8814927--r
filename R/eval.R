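#' Repeated random train/test splits
#'
#' The evaluation protocol: instances are split 90/10 into train and test,
#' repeated with independent seeded shuffles, and metrics are averaged
#' over the repeats.
#'
#' @param n instance count (must allow a non-empty test set).
#' @param train_fraction fraction of instances in the training set.
#' @param n_repeats number of independent splits.
#' @param seed seed; equal seeds give identical plans.
#' @return object of class `split_plan`: a list of `n_repeats` elements,
#'   each with integer vectors `train` and `test` partitioning `1..n`.
#' @export
make_splits <- function(n, train_fraction = 0.9, n_repeats = 3L, seed = 1L) {
  n_test <- round((1 - train_fraction) * n)
  if (n_test < 1L || n_test >= n) {
    stop("n = ", n, " with train_fraction = ", train_fraction,
         " leaves no usable test set")
  }
  set.seed(seed)
  plan <- lapply(seq_len(n_repeats), function(r) {
    idx <- sample.int(n)
    list(test = sort(idx[seq_len(n_test)]), train = sort(idx[-seq_len(n_test)]))
  })
  structure(plan, class = "split_plan", n = n, seed = seed)
}

#' Classification metrics
#'
#' Accuracy, macro F1 and weighted F1 from predictions, plus AUC from
#' scores for binary tasks. Per-class F1 is the harmonic mean of precision
#' and recall (0 when both are undefined); macro F1 averages F1 without
#' weights over the classes present in the truth, weighted F1 weights each
#' class by its support. AUC is the Mann-Whitney rank statistic of the
#' scores, equivalent to the area under the ROC curve with the tie
#' convention of mid-ranks.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels (same alphabet).
#' @param scores optional numeric scores for the positive class (binary
#'   tasks); supplying them requests AUC.
#' @param positive the label counted as positive for AUC (default: the
#'   larger of the two sorted labels, i.e. `1` for 0/1).
#' @return named numeric vector with `accuracy`, `macro_f1`, `weighted_f1`
#'   and, when scores are given, `auc`. A single-class truth with scores
#'   supplied is an error (AUC undefined).
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL,
                                   positive = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  classes <- sort(unique(y_true))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1L))
  support <- as.numeric(table(factor(y_true, levels = classes)))
  out <- c(accuracy = mean(y_true == y_pred),
           macro_f1 = mean(f1),
           weighted_f1 = sum(f1 * support) / sum(support))
  if (!is.null(scores)) {
    if (length(classes) < 2L) {
      stop("AUC is undefined: the truth contains a single class")
    }
    if (length(classes) > 2L) stop("AUC is only computed for binary tasks")
    positive <- positive %||% classes[2L]
    pos <- y_true == positive
    r <- rank(scores)
    n1 <- sum(pos)
    n0 <- sum(!pos)
    out["auc"] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out
}

#' Stacked denoising autoencoder baseline
#'
#' The single-source representation-learning baseline: a denoising
#' autoencoder with one hidden layer, sigmoid encoding and linear decoding,
#' trained with RMSprop on mean squared error to reconstruct the
#' uncorrupted input from a masked (dropout-corrupted) copy. The bottleneck
#' encodings of the clean input are the representations. Unlike the
#' collective model it accepts exactly one matrix, so it cannot ingest
#' square knowledge-graph views.
#'
#' @param x numeric matrix (instances by features).
#' @param embedding_dim bottleneck width (the reference setting at full
#'   scale is 300; it must be below the input width).
#' @param corruption fraction of input entries zeroed per presentation.
#' @param epochs,batch_size,learning_rate RMSprop settings.
#' @param seed seed; equal seeds give identical representations.
#' @return object of class `sdae` with `encoding` (instances by
#'   `embedding_dim`), `history` (per-epoch mean training loss) and the
#'   network parameters.
#' @export
sdae <- function(x, embedding_dim = 300L, corruption = 0.4, epochs = 20L,
                 batch_size = 32L, learning_rate = 1e-3, seed = 1L) {
  x <- as.matrix(x)
  if (embedding_dim >= ncol(x)) {
    stop("embedding_dim = ", embedding_dim,
         " must be below the input width (", ncol(x), ")")
  }
  if (corruption < 0 || corruption >= 1) stop("corruption must be in [0, 1)")
  set.seed(seed)
  nets <- list(
    enc = list(nn_layer(ncol(x), embedding_dim, "sigmoid")),
    dec = list(nn_layer(embedding_dim, ncol(x), "linear"))
  )
  state <- opt_init(nets)
  history <- numeric(epochs)
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    order <- sample.int(n)
    losses <- numeric(0L)
    for (start in seq(1L, n, by = batch_size)) {
      rows <- order[start:min(start + batch_size - 1L, n)]
      xb <- x[rows, , drop = FALSE]
      mask <- if (corruption > 0) {
        matrix(stats::rbinom(length(xb), 1L, 1 - corruption),
               nrow(xb), ncol(xb))
      } else 1
      ea <- nn_forward(nets$enc, xb * mask)
      da <- nn_forward(nets$dec, ea[[length(ea)]])
      xhat <- da[[length(da)]]
      losses <- c(losses, mean((xhat - xb)^2))
      bk_dec <- nn_backward(nets$dec, da, 2 * (xhat - xb) / length(xb))
      bk_enc <- nn_backward(nets$enc, ea, bk_dec$d_input)
      step <- opt_step_rmsprop(nets, list(enc = bk_enc$grads,
                                          dec = bk_dec$grads),
                               state, lr = learning_rate)
      nets <- step$nets
      state <- step$state
    }
    history[ep] <- mean(losses)
  }
  enc_clean <- nn_output(nets$enc, x)
  rownames(enc_clean) <- rownames(x)
  structure(list(encoding = enc_clean, history = history, nets = nets,
                 embedding_dim = embedding_dim, corruption = corruption),
            class = "sdae")
}

#' @export
print.sdae <- function(x, ...) {
  cat(sprintf(
    "<sdae> %d x %d encoding, corruption %.2f, final training loss %.6g\n",
    nrow(x$encoding), ncol(x$encoding), x$corruption,
    utils::tail(x$history, 1L)))
  invisible(x)
}

#' Nonneural collective factorization baseline (alternating least squares)
#'
#' A minimal classical collective matrix factorization: one shared factor
#' matrix per entity, squared loss on every view, ridge-regularised
#' alternating least-squares sweeps. For entity `e` with concatenated
#' matrix `C^(e)` and stacked opposite factors `B`, each update solves the
#' ridge system `U_e = C^(e) B (B'B + lambda I)^{-1}` (self-views
#' contribute with the current factor on the opposite side). This is a
#' self-contained reimplementation of the nonneural baseline, not a
#' wrapper around any existing CMF package.
#'
#' @param collection a [matrix_collection()].
#' @param k latent dimension.
#' @param lambda ridge penalty.
#' @param n_iter number of alternating sweeps over the entities.
#' @param seed seed for factor initialisation.
#' @return object of class `cmf_als` with `factors` (named list),
#'   `history` (objective per sweep: sum of squared view residuals) and
#'   `view_errors`.
#' @export
cmf_als <- function(collection, k = 10L, lambda = 1e-2, n_iter = 20L,
                    seed = 1L) {
  stopifnot(inherits(collection, "matrix_collection"))
  set.seed(seed)
  dims <- collection$entities
  factors <- lapply(names(dims), function(e) {
    matrix(stats::rnorm(dims[[e]] * k, sd = 0.1), dims[[e]], k)
  })
  names(factors) <- names(dims)
  objective <- function() {
    sum(vapply(collection$views, function(v) {
      sum((v$values - tcrossprod(factors[[v$row_entity]],
                                 factors[[v$col_entity]]))^2)
    }, numeric(1L)))
  }
  history <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    for (e in names(dims)) {
      Cs <- list()
      Bs <- list()
      for (v in collection$views) {
        if (v$row_entity == e) {
          Cs[[length(Cs) + 1L]] <- v$values
          Bs[[length(Bs) + 1L]] <- factors[[v$col_entity]]
        } else if (v$col_entity == e) {
          Cs[[length(Cs) + 1L]] <- t(v$values)
          Bs[[length(Bs) + 1L]] <- factors[[v$row_entity]]
        }
      }
      C <- do.call(cbind, Cs)
      B <- do.call(rbind, Bs)
      factors[[e]] <- C %*% B %*% solve(crossprod(B) + lambda * diag(k))
    }
    history[it] <- objective()
  }
  ve <- vapply(collection$views, function(v) {
    x <- v$values
    norm(x - tcrossprod(factors[[v$row_entity]],
                        factors[[v$col_entity]]), "F") /
      max(norm(x, "F"), .Machine$double.eps)
  }, numeric(1L))
  structure(list(factors = factors, history = history, view_errors = ve,
                 k = k, lambda = lambda),
            class = "cmf_als")
}

#' @export
print.cmf_als <- function(x, ...) {
  cat(sprintf("<cmf_als> k = %d, %d sweep(s), objective %.6g\n", x$k,
              length(x$history), utils::tail(x$history, 1L)))
  invisible(x)
}

# ---- experiment runner -----------------------------------------------------

#' Standardize every view of a collection
#'
#' Centers each view's columns and divides by the view's overall standard
#' deviation, the usual preprocessing before a low-rank fit: raw
#' non-negative views (TF-IDF, counts, adjacency-like similarity matrices)
#' carry a large mean/density component that would otherwise occupy one
#' latent dimension in every factor. All views come back as `value_kind
#' "real"`.
#'
#' @param collection a `matrix_collection`.
#' @return a new `matrix_collection` with standardized values.
#' @export
standardize_collection <- function(collection) {
  views <- lapply(unname(collection$views), function(v) {
    m <- scale(v$values, center = TRUE, scale = FALSE)
    m <- m / max(stats::sd(m), .Machine$double.eps)
    attr(m, "scaled:center") <- NULL
    view_matrix(m, v$row_entity, v$col_entity, id = v$id,
                value_kind = "real")
  })
  suppressWarnings(matrix_collection(views))
}

.fit_classifier <- function(x, y, kind) {
  x <- as.data.frame(x)
  names(x) <- paste0("f", seq_along(x))
  binary <- length(unique(y)) == 2L && all(y %in% c(0, 1))
  if (kind == "lr") {
    if (binary) {
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = cbind(y = y, x), family = stats::binomial()))
      function(newx) {
        newx <- as.data.frame(newx)
        names(newx) <- names(x)
        p <- suppressWarnings(
          stats::predict(fit, newdata = newx, type = "response"))
        list(class = as.integer(p > 0.5), score = p)
      }
    } else {
      yf <- as.factor(y)
      fit <- nnet::multinom(y ~ ., data = cbind(y = yf, x), trace = FALSE)
      function(newx) {
        newx <- as.data.frame(newx)
        names(newx) <- names(x)
        list(class = as.character(stats::predict(fit, newdata = newx)),
             score = NULL)
      }
    }
  } else if (kind == "rf") {
    yf <- as.factor(y)
    fit <- randomForest::randomForest(x, yf)
    function(newx) {
      newx <- as.data.frame(newx)
      names(newx) <- names(x)
      p <- stats::predict(fit, newdata = newx, type = "prob")
      cls <- as.character(stats::predict(fit, newdata = newx))
      list(class = if (binary) as.integer(cls) else cls,
           score = if (binary) p[, "1"] else NULL)
    }
  } else {
    stop("unknown classifier: ", kind)
  }
}

#' Subset one entity's instances in every view
#'
#' Keeps only the given instances of `entity`, restricting the rows (or
#' columns) of every view that touches it; other views are untouched. Used
#' to build the training collection for supervised fits, whose held-out
#' patients must not enter training.
#'
#' @param collection a `matrix_collection`.
#' @param entity entity id.
#' @param idx integer indices of the instances to keep.
#' @return a new `matrix_collection`.
#' @export
subset_entity_rows <- function(collection, entity, idx) {
  views <- lapply(collection$views, function(v) {
    m <- v$values
    if (v$row_entity == entity && v$col_entity == entity) {
      m <- m[idx, idx, drop = FALSE]
    } else if (v$row_entity == entity) {
      m <- m[idx, , drop = FALSE]
    } else if (v$col_entity == entity) {
      m <- m[, idx, drop = FALSE]
    }
    view_matrix(m, v$row_entity, v$col_entity, id = v$id,
                value_kind = v$value_kind)
  })
  matrix_collection(unname(views))
}

.valid_experiment_arms <- paste(
  "valid (model, view, classifier) combinations:",
  "sdae at view 1 with lr/rf;",
  "cmf and dcmf at any view with lr/rf;",
  "dcmf_supervised at any view with classifier 'none'")

#' Run one experiment arm
#'
#' Mirrors the comparison protocol: representations are learned per model,
#' a downstream classifier is trained on the training split of each repeat
#' and evaluated on the held-out split, and metrics are averaged over the
#' repeats. Unsupervised arms (`sdae`, `cmf`, `dcmf`) learn
#' representations once from all instances (transductively) and hand them
#' to the classifier; the supervised arm (`dcmf_supervised`) is end to
#' end: it refits on each training split with the labels attached and
#' predicts the held-out patients through its task head, so it takes
#' `classifier = "none"`. The SDAE accepts a single matrix only and is
#' therefore restricted to view 1 (it cannot ingest the square
#' knowledge-graph views of views 2 and 3).
#'
#' @param bundle a `dcmf_bundle` from [simulate_bundle()] (or any list
#'   with `view1..view3` collections and `labels$y` for the patient
#'   entity).
#' @param view view level 1, 2 or 3.
#' @param model one of `"sdae"`, `"cmf"`, `"dcmf"`, `"dcmf_supervised"`.
#' @param classifier `"lr"`, `"rf"`, or `"none"` (supervised arm only).
#' @param n_repeats,split_seed split protocol (90/10 by default).
#' @param latent_dim,epochs,learning_rate,weight_decay,activation,loss_weights
#'   settings for the factorization models. The defaults make the
#'   bottleneck genuinely compressive (below the generator's default rank)
#'   and upweight the task term, whose per-element mean is small relative
#'   to the summed reconstruction terms.
#' @param model_seed seed for representation learning.
#' @param sdae_dim,sdae_epochs bottleneck width and epochs for the SDAE
#'   arm.
#' @param entity the labelled entity (default `"patient"`).
#' @param standardize standardize all views before any model sees them
#'   (default `TRUE`; see [standardize_collection()]). Centering uses all
#'   instances' inputs, consistent with the transductive
#'   representation-learning protocol; labels of held-out instances are
#'   never used.
#' @return object of class `metrics_report`: `per_repeat` (data.frame of
#'   metrics by repeat) and `mean` (named vector), plus the arm
#'   description.
#' @export
run_experiment <- function(bundle, view = 1L,
                           model = c("dcmf", "dcmf_supervised", "cmf",
                                     "sdae"),
                           classifier = c("lr", "rf", "none"),
                           n_repeats = 3L, split_seed = 1L,
                           latent_dim = 2L, epochs = 400L,
                           learning_rate = 5e-3, weight_decay = 1e-6,
                           activation = "tanh",
                           loss_weights = c(entity = 1, view = 1, task = 2),
                           model_seed = 1L, sdae_dim = 32L,
                           sdae_epochs = 20L, entity = "patient",
                           standardize = TRUE) {
  model <- match.arg(model)
  classifier <- match.arg(classifier)
  if (model == "sdae" && view != 1L) {
    stop("the SDAE cannot be used when knowledge-graph matrices are present; ",
         .valid_experiment_arms)
  }
  if (model == "dcmf_supervised" && classifier != "none") {
    stop("the supervised model predicts through its own head; ",
         .valid_experiment_arms)
  }
  if (model != "dcmf_supervised" && classifier == "none") {
    stop("unsupervised representations need a downstream classifier; ",
         .valid_experiment_arms)
  }
  collection <- bundle[[paste0("view", view)]]
  if (standardize) collection <- standardize_collection(collection)
  y <- bundle$labels$y
  n <- collection$entities[[entity]]
  stopifnot(length(y) == n)
  splits <- make_splits(n, n_repeats = n_repeats, seed = split_seed)
  cfg <- dcmf_config(latent_dim = latent_dim, epochs = epochs,
                     learning_rate = learning_rate,
                     weight_decay = weight_decay, activation = activation,
                     loss_weights = loss_weights, seed = model_seed)

  rows <- list()
  if (model == "dcmf_supervised") {
    binary <- all(y %in% c(0, 1))
    for (r in seq_along(splits)) {
      sp <- splits[[r]]
      train_coll <- subset_entity_rows(collection, entity, sp$train)
      task <- dcmf_task(if (binary) y[sp$train] else
        factor(y[sp$train], levels = sort(unique(y))), entity)
      fit <- dcmf(train_coll, cfg, task)
      full_concat <- concatenate_entity(collection, entity)$values
      score <- predict(fit, full_concat[sp$test, , drop = FALSE])
      cls <- predict(fit, full_concat[sp$test, , drop = FALSE],
                     type = "class")
      rows[[r]] <- .repeat_metrics(y[sp$test], cls,
                                   if (binary) score[, 1L] else NULL, r)
    }
  } else {
    reps <- switch(model,
      dcmf = coef(dcmf(collection, cfg), entity),
      cmf = cmf_als(collection, k = latent_dim, seed = model_seed,
                    n_iter = 25L)$factors[[entity]],
      sdae = sdae(concatenate_entity(collection, entity)$values,
                  embedding_dim = sdae_dim, epochs = sdae_epochs,
                  seed = model_seed)$encoding
    )
    for (r in seq_along(splits)) {
      sp <- splits[[r]]
      clf <- .fit_classifier(reps[sp$train, , drop = FALSE], y[sp$train],
                             classifier)
      pred <- clf(reps[sp$test, , drop = FALSE])
      rows[[r]] <- .repeat_metrics(y[sp$test], pred$class, pred$score, r)
    }
  }
  per_repeat <- do.call(rbind, rows)
  means <- colMeans(per_repeat[, setdiff(names(per_repeat), "repeat."),
                               drop = FALSE], na.rm = TRUE)
  structure(list(model = model, view = view, classifier = classifier,
                 per_repeat = per_repeat, mean = means),
            class = "metrics_report")
}

.repeat_metrics <- function(y_true, y_pred, scores, r) {
  # AUC is undefined on a single-class held-out split: report NA there
  # rather than failing the repeat.
  use_scores <- !is.null(scores) && length(unique(y_true)) == 2L
  m <- classification_metrics(y_true, y_pred,
                              scores = if (use_scores) scores)
  data.frame(repeat. = r, accuracy = m[["accuracy"]],
             macro_f1 = m[["macro_f1"]], weighted_f1 = m[["weighted_f1"]],
             auc = if (use_scores) m[["auc"]] else NA_real_)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s, view %d, classifier %s (%d repeats)\n",
              x$model, x$view, x$classifier, nrow(x$per_repeat)))
  m <- x$mean
  cat(sprintf("  accuracy %.4f | macro F1 %.4f | weighted F1 %.4f",
              m[["accuracy"]], m[["macro_f1"]], m[["weighted_f1"]]))
  if (!is.na(m[["auc"]])) cat(sprintf(" | AUC %.4f", m[["auc"]]))
  cat("\n")
  invisible(x)
}

#' Run a grid of experiment arms
#'
#' Convenience wrapper over [run_experiment()]: runs every valid
#' combination of the requested views, models and classifiers and returns
#' a long-format table of per-repeat metrics.
#'
#' @param bundle a `dcmf_bundle`.
#' @param views,models,classifiers vectors of levels to cross; invalid
#'   combinations are skipped silently.
#' @param ... passed to [run_experiment()].
#' @return data.frame with columns `model`, `view`, `classifier`,
#'   `repeat.`, metric columns.
#' @export
run_experiment_grid <- function(bundle, views = 1:3,
                                models = c("sdae", "cmf", "dcmf",
                                           "dcmf_supervised"),
                                classifiers = c("lr", "rf"), ...) {
  out <- list()
  for (v in views) {
    for (m in models) {
      cls <- if (m == "dcmf_supervised") "none"
             else if (m == "sdae" && v != 1L) character(0L)
             else classifiers
      for (cl in cls) {
        rep <- run_experiment(bundle, view = v, model = m, classifier = cl,
                              ...)
        out[[length(out) + 1L]] <- cbind(
          data.frame(model = m, view = v, classifier = cl),
          rep$per_repeat)
      }
    }
  }
  do.call(rbind, out)
}
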