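#' Training configuration for collective matrix factorization
#'
#' Defaults follow the reported experimental settings for the deep
#' collective model: a single hidden (bottleneck) layer per entity
#' autoencoder, tanh activations, Adam with learning rate 1e-5 and weight
#' decay 1e-6. The learning rate is deliberately conservative for large
#' real matrices; synthetic desk-scale problems converge much faster with
#' a larger rate, which every example in this package sets explicitly.
#'
#' @param latent_dim bottleneck width `k`: the dimension of every entity's
#'   latent representation.
#' @param hidden_sizes integer vector of extra encoder layer widths between
#'   the input and the bottleneck (decoder mirrors them). `NULL` (default)
#'   means the bottleneck is the only hidden layer.
#' @param activation `"tanh"` (default), `"sigmoid"` or `"linear"`. The
#'   linear mode turns the model into a collective linear factorization and
#'   is used for exact-recovery checks.
#' @param learning_rate,weight_decay,epochs,optimizer optimizer settings;
#'   `optimizer` is `"adam"` or `"rmsprop"`.
#' @param lr_decay per-epoch multiplicative learning-rate decay in (0, 1].
#'   The default 1 keeps the rate constant; a value slightly below 1
#'   (e.g. `0.9997`) anneals the step size, which settles oscillation near
#'   the optimum in exact-recovery settings.
#' @param loss_weights named non-negative numeric vector
#'   `c(entity = , view = , task = )` weighting the entity-reconstruction,
#'   view-reconstruction and task terms of the joint objective.
#' @param seed integer seed controlling parameter initialisation; fits with
#'   equal seeds are bit-identical.
#' @return an object of class `dcmf_config`.
#' @export
dcmf_config <- function(latent_dim = 10L, hidden_sizes = NULL,
                        activation = c("tanh", "sigmoid", "linear"),
                        learning_rate = 1e-5, weight_decay = 1e-6,
                        epochs = 100L,
                        loss_weights = c(entity = 1, view = 1, task = 1),
                        seed = 1L, optimizer = c("adam", "rmsprop"),
                        lr_decay = 1) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  lw <- c(entity = 1, view = 1, task = 1)
  lw[names(loss_weights)] <- loss_weights
  if (any(lw < 0)) stop("loss weights must be non-negative")
  if (latent_dim < 1L) stop("latent_dim must be positive")
  if (epochs < 0L) stop("epochs must be non-negative")
  if (!(lr_decay > 0 && lr_decay <= 1)) stop("lr_decay must lie in (0, 1]")
  structure(
    list(latent_dim = as.integer(latent_dim),
         hidden_sizes = as.integer(hidden_sizes),
         activation = activation, learning_rate = learning_rate,
         weight_decay = weight_decay, epochs = as.integer(epochs),
         loss_weights = lw, seed = as.integer(seed), optimizer = optimizer,
         lr_decay = lr_decay),
    class = "dcmf_config"
  )
}

#' Supervised task specification
#'
#' Attaches labels for one entity (most often patient episodes) so that a
#' task head — one affine layer on that entity's bottleneck — is trained
#' jointly with all autoencoders. Head activation and loss follow the task:
#' sigmoid + cross-entropy for binary, softmax + cross-entropy for
#' multiclass, independent sigmoids + cross-entropy for multilabel, linear
#' + mean squared error for regression.
#'
#' @param labels for `"binary"` a 0/1 vector (or 2-level factor); for
#'   `"multiclass"` a factor or integer vector; for `"multilabel"` a 0/1
#'   matrix (instances by labels); for `"regression"` a numeric vector.
#' @param target_entity entity id the labels refer to; label count must
#'   equal that entity's dimension.
#' @param kind task kind, `"auto"` guesses from the labels.
#' @return an object of class `dcmf_task`.
#' @export
dcmf_task <- function(labels, target_entity,
                      kind = c("auto", "binary", "multiclass", "multilabel",
                               "regression")) {
  kind <- match.arg(kind)
  if (kind == "auto") {
    kind <- if (is.matrix(labels)) "multilabel"
    else if (is.factor(labels)) {
      if (nlevels(labels) > 2L) "multiclass" else "binary"
    } else if (all(labels %in% c(0, 1))) "binary"
    else if (is.numeric(labels) && any(labels != round(labels))) "regression"
    else "multiclass"
  }
  levels <- NULL
  if (kind == "binary") {
    if (is.factor(labels)) {
      levels <- levels(labels)
      labels <- as.numeric(labels) - 1
    }
    if (!all(labels %in% c(0, 1))) stop("binary labels must be 0/1")
    y <- matrix(as.numeric(labels), ncol = 1L)
  } else if (kind == "multiclass") {
    labels <- as.factor(labels)
    levels <- levels(labels)
    if (length(levels) < 2L) stop("multiclass task needs at least 2 classes")
    y <- matrix(0, length(labels), length(levels))
    y[cbind(seq_along(labels), as.integer(labels))] <- 1
  } else if (kind == "multilabel") {
    y <- as.matrix(labels)
    if (!all(y %in% c(0, 1))) stop("multilabel matrix must be 0/1")
    levels <- colnames(y) %||% paste0("label", seq_len(ncol(y)))
  } else {
    y <- matrix(as.numeric(labels), ncol = 1L)
  }
  structure(
    list(target_entity = as.character(target_entity), y = y, kind = kind,
         levels = levels,
         head_activation = switch(kind, binary = "sigmoid",
                                  multiclass = "softmax",
                                  multilabel = "sigmoid",
                                  regression = "linear"),
         loss = if (kind == "regression") "mean_squared_error"
                else "cross_entropy"),
    class = "dcmf_task"
  )
}

.entity_architecture <- function(width, config) {
  k <- config$latent_dim
  enc_sizes <- c(width, config$hidden_sizes, k)
  dec_sizes <- c(k, rev(config$hidden_sizes), width)
  enc_act <- rep(config$activation, length(enc_sizes) - 1L)
  dec_act <- c(rep(config$activation, length(dec_sizes) - 2L), "linear")
  list(enc = list(sizes = enc_sizes, act = enc_act),
       dec = list(sizes = dec_sizes, act = dec_act))
}

#' Initialise an untrained collective model
#'
#' Builds one autoencoder per entity: the input width is the column count
#' of the entity's concatenated matrix `C^(e)`, the bottleneck width is
#' `latent_dim`. With a task, one extra affine layer maps the target
#' entity's bottleneck to the outputs. All parameters are drawn from the
#' seeded generator in a fixed order (encoders and decoders in entity
#' order, head last), so equal seeds give bit-identical models and the
#' head draw never perturbs the autoencoder initialisation.
#'
#' @param collection a [matrix_collection()].
#' @param config a [dcmf_config()].
#' @param task optional [dcmf_task()].
#' @return an untrained object of class `dcmf` (zero epochs of history);
#'   its factors are the encodings under the initial parameters.
#' @export
dcmf_init <- function(collection, config = dcmf_config(), task = NULL) {
  stopifnot(inherits(collection, "matrix_collection"))
  if (!is.null(task)) {
    stopifnot(inherits(task, "dcmf_task"))
    d <- collection$entities[task$target_entity]
    if (is.na(d)) stop("task target entity '", task$target_entity,
                       "' is not in the collection")
    if (nrow(task$y) != d) {
      stop("task has ", nrow(task$y), " labels but entity '",
           task$target_entity, "' has dimension ", d)
    }
  }
  entity_order <- names(collection$entities)
  concats <- lapply(entity_order, concatenate_entity, collection = collection)
  names(concats) <- entity_order
  widths <- vapply(concats, function(cc) ncol(cc$values), integer(1L))
  too_wide <- widths[widths <= config$latent_dim]
  if (length(too_wide)) {
    stop("latent_dim = ", config$latent_dim,
         " is not below the concatenated input width of entity '",
         names(too_wide)[1L], "' (", too_wide[[1L]], ")")
  }
  if (config$latent_dim >= min(collection$entities)) {
    warning("latent_dim >= the smallest entity dimension: factorized views ",
            "are not low-rank", call. = FALSE)
  }
  set.seed(config$seed)
  nets <- list()
  for (e in entity_order) {
    arch <- .entity_architecture(widths[[e]], config)
    nets[[paste0("enc.", e)]] <- nn_mlp(arch$enc$sizes, arch$enc$act)
    nets[[paste0("dec.", e)]] <- nn_mlp(arch$dec$sizes, arch$dec$act)
  }
  if (!is.null(task)) {
    nets[["head"]] <- list(nn_layer(config$latent_dim, ncol(task$y),
                                    task$head_activation))
  }
  model <- structure(
    list(collection = collection, config = config, task = task,
         entity_order = entity_order, concats = concats, nets = nets,
         history = NULL, trained_epochs = 0L, factors = NULL),
    class = "dcmf"
  )
  model$factors <- .dcmf_encode_all(model)
  model
}

.dcmf_encode_all <- function(model) {
  out <- lapply(model$entity_order, function(e) {
    u <- nn_output(model$nets[[paste0("enc.", e)]], model$concats[[e]]$values)
    rownames(u) <- rownames(model$concats[[e]]$values)
    u
  })
  stats::setNames(out, model$entity_order)
}

.task_loss <- function(task, p, y) {
  eps <- 1e-12
  switch(task$loss,
    cross_entropy = if (task$head_activation == "softmax") {
      -mean(log(pmax(rowSums(p * y), eps)))
    } else {
      -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
    },
    mean_squared_error = mean((p - y)^2)
  )
}

# Joint forward/backward pass over every autoencoder, every view term and
# the optional task head. Gradients with respect to each bottleneck U_e
# accumulate from three sources: the entity reconstruction (through the
# decoder), every view factorization U_r U_c', and the head.
.dcmf_pass <- function(model, want_grads = TRUE) {
  cfg <- model$config
  w <- cfg$loss_weights
  nets <- model$nets
  enc_acts <- list()
  dec_acts <- list()
  U <- list()
  dU <- list()
  grads <- if (want_grads) lapply(nets, nn_zero_grads) else NULL
  entity_losses <- numeric(0L)
  for (e in model$entity_order) {
    C <- model$concats[[e]]$values
    ea <- nn_forward(nets[[paste0("enc.", e)]], C)
    U[[e]] <- ea[[length(ea)]]
    da <- nn_forward(nets[[paste0("dec.", e)]], U[[e]])
    Chat <- da[[length(da)]]
    entity_losses[e] <- mean((Chat - C)^2)
    enc_acts[[e]] <- ea
    dec_acts[[e]] <- da
    if (want_grads) {
      bk <- nn_backward(nets[[paste0("dec.", e)]], da,
                        2 * w[["entity"]] * (Chat - C) / length(C))
      grads[[paste0("dec.", e)]] <- bk$grads
      dU[[e]] <- bk$d_input
    }
  }
  view_losses <- numeric(0L)
  for (v in model$collection$views) {
    r <- v$row_entity
    cc <- v$col_entity
    R <- tcrossprod(U[[r]], U[[cc]])
    view_losses[v$id] <- mean((R - v$values)^2)
    if (want_grads) {
      G <- 2 * w[["view"]] * (R - v$values) / length(v$values)
      if (r == cc) { # self-view: both sides share one factor
        dU[[r]] <- dU[[r]] + G %*% U[[r]] + crossprod(G, U[[r]])
      } else {
        dU[[r]] <- dU[[r]] + G %*% U[[cc]]
        dU[[cc]] <- dU[[cc]] + crossprod(G, U[[r]])
      }
    }
  }
  task_loss <- NA_real_
  if (!is.null(model$task)) {
    task <- model$task
    ep <- task$target_entity
    ha <- nn_forward(nets[["head"]], U[[ep]])
    p <- ha[[length(ha)]]
    task_loss <- .task_loss(task, p, task$y)
    if (want_grads) {
      n <- nrow(task$y)
      dz <- switch(paste(task$loss, task$head_activation),
        "cross_entropy softmax" = (p - task$y) / n,
        "cross_entropy sigmoid" = (p - task$y) / length(task$y),
        "mean_squared_error linear" = 2 * (p - task$y) / length(task$y)
      )
      bk <- nn_backward(nets[["head"]], ha, w[["task"]] * dz, d_is_dz = TRUE)
      grads[["head"]] <- bk$grads
      dU[[ep]] <- dU[[ep]] + bk$d_input
    }
  }
  if (want_grads) {
    for (e in model$entity_order) {
      grads[[paste0("enc.", e)]] <-
        nn_backward(nets[[paste0("enc.", e)]], enc_acts[[e]], dU[[e]])$grads
    }
  }
  total <- w[["entity"]] * sum(entity_losses) +
    w[["view"]] * sum(view_losses) +
    (if (is.na(task_loss)) 0 else w[["task"]] * task_loss)
  list(entity_losses = entity_losses, view_losses = view_losses,
       task_loss = task_loss, total = total, grads = grads, U = U)
}

#' Fit a deep collective matrix factorization model
#'
#' The joint objective is the weighted sum, over all entities, of the
#' entity-reconstruction loss (mean squared error between `C^(e)` and the
#' autoencoder's decoding), over all views, of the view-reconstruction loss
#' (mean squared error between `X_m` and `U_r U_c'`), and, when a task is
#' supplied, of the task loss on the head outputs. All autoencoders are
#' trained collectively: every full-batch optimizer step updates every
#' network from the joint gradient, which is what couples the entity
#' representations across views. The bottleneck activations after training
#' are the latent factors.
#'
#' @inheritParams dcmf_init
#' @return an object of class `dcmf` with per-epoch loss `history`
#'   (data.frame), latent `factors` (one `d_e` by `k` matrix per entity)
#'   and, for supervised fits, the trained task head. Methods: `print`,
#'   `summary`, [coef.dcmf()], [predict.dcmf()], [fitted.dcmf()],
#'   [residuals.dcmf()], `plot`.
#' @examples
#' u <- matrix(rnorm(40), 20, 2)
#' v <- matrix(rnorm(16), 8, 2)
#' coll <- matrix_collection(list(
#'   view_matrix(u %*% t(v), "rows", "cols", id = "X1")))
#' fit <- dcmf(coll, dcmf_config(latent_dim = 2, activation = "linear",
#'                               learning_rate = 0.02, epochs = 500))
#' summary(fit)
#' @export
dcmf <- function(collection, config = dcmf_config(), task = NULL) {
  model <- dcmf_init(collection, config, task)
  dcmf_train(model, epochs = config$epochs)
}

#' Continue training a collective model
#'
#' Runs further optimizer epochs on an existing model, extending its loss
#' history; `dcmf()` is `dcmf_init()` followed by this.
#'
#' @param model a `dcmf` object.
#' @param epochs number of additional epochs.
#' @return the updated model.
#' @export
dcmf_train <- function(model, epochs) {
  cfg <- model$config
  state <- model$opt_state %||% opt_init(model$nets)
  history <- model$history
  for (ep in seq_len(epochs)) {
    pass <- .dcmf_pass(model, want_grads = TRUE)
    if (!is.finite(pass$total)) {
      terms <- c(pass$entity_losses, pass$view_losses,
                 task = unname(pass$task_loss))
      terms <- terms[!is.na(terms)]
      worst <- names(terms)[which.max(abs(terms))] %||% "total"
      stop("training diverged at epoch ", model$trained_epochs + ep,
           ": non-finite loss (worst term: ", worst, ")")
    }
    history <- rbind(history, data.frame(
      epoch = model$trained_epochs + ep,
      entity = sum(pass$entity_losses),
      view = sum(pass$view_losses),
      task = unname(pass$task_loss),
      total = pass$total
    ))
    decay <- cfg$lr_decay %||% 1
    step <- opt_step(cfg$optimizer, nets = model$nets, grads = pass$grads,
                     state = state,
                     lr = cfg$learning_rate *
                       decay^(model$trained_epochs + ep - 1L),
                     weight_decay = cfg$weight_decay)
    model$nets <- step$nets
    state <- step$state
  }
  model$opt_state <- state
  model$history <- history
  model$trained_epochs <- model$trained_epochs + epochs
  model$factors <- .dcmf_encode_all(model)
  model
}

#' Loss breakdown of a model at its current parameters
#'
#' Recomputes every term of the joint objective: per-entity reconstruction
#' losses, per-view factorization losses, the task loss (if any), and
#' their weighted total.
#'
#' @param model a `dcmf` object.
#' @return object of class `dcmf_loss`: list with `entity_losses`,
#'   `view_losses`, `task_loss`, `weights`, `total`.
#' @export
dcmf_objective <- function(model) {
  stopifnot(inherits(model, "dcmf"))
  pass <- .dcmf_pass(model, want_grads = FALSE)
  structure(
    list(entity_losses = pass$entity_losses, view_losses = pass$view_losses,
         task_loss = pass$task_loss, weights = model$config$loss_weights,
         total = pass$total),
    class = "dcmf_loss"
  )
}

#' @export
print.dcmf_loss <- function(x, ...) {
  cat("<dcmf_loss> total =", format(x$total), "\n")
  cat("  entity:", paste(sprintf("%s=%.4g", names(x$entity_losses),
                                 x$entity_losses), collapse = " "), "\n")
  cat("  view:  ", paste(sprintf("%s=%.4g", names(x$view_losses),
                                 x$view_losses), collapse = " "), "\n")
  if (!is.na(x$task_loss)) cat("  task:  ", format(x$task_loss), "\n")
  invisible(x)
}

#' Encode an entity's concatenated matrix into latent factors
#'
#' Applies the entity's trained encoder. With `newdata = NULL` the stored
#' training input is encoded, which reproduces the model's stored factors;
#' new rows must be supplied in the same concatenated coordinates (same
#' column blocks, same width).
#'
#' @param model a `dcmf` object.
#' @param entity entity id.
#' @param newdata optional numeric matrix with the entity's concatenated
#'   input width.
#' @return numeric matrix, rows by `latent_dim`.
#' @export
encode_entity <- function(model, entity, newdata = NULL) {
  stopifnot(inherits(model, "dcmf"))
  enc <- model$nets[[paste0("enc.", entity)]]
  if (is.null(enc)) stop("no encoder for entity '", entity, "'")
  x <- if (is.null(newdata)) model$concats[[entity]]$values
       else as.matrix(newdata)
  width <- nrow(enc[[1L]]$W)
  if (ncol(x) != width) {
    stop("input has ", ncol(x), " columns but the '", entity,
         "' encoder expects ", width)
  }
  nn_output(enc, x)
}

#' Low-rank view reconstruction from two latent factors
#'
#' @param u_row,u_col factor matrices with a common latent dimension; the
#'   reconstruction is `u_row %*% t(u_col)`, of rank at most `k`.
#' @return the reconstructed matrix.
#' @export
reconstruct_view <- function(u_row, u_col = u_row) {
  u_row <- as.matrix(u_row)
  u_col <- as.matrix(u_col)
  if (ncol(u_row) != ncol(u_col)) {
    stop("latent dimensions differ: ", ncol(u_row), " vs ", ncol(u_col))
  }
  tcrossprod(u_row, u_col)
}

#' Extract latent factors
#'
#' @param object a fitted `dcmf` model.
#' @param entity optional entity id; default returns the named list of all
#'   factor matrices.
#' @param ... unused.
#' @return a `d_e` by `k` matrix, or a named list of them.
#' @export
coef.dcmf <- function(object, entity = NULL, ...) {
  if (is.null(entity)) object$factors else object$factors[[entity]]
}

#' @rdname coef.dcmf
#' @export
extract_representations <- function(object, ...) coef(object, ...)

#' Reconstructed views of a fitted model
#'
#' @param object a `dcmf` model.
#' @param view optional view id; default all views.
#' @param ... unused.
#' @return a reconstructed matrix, or a named list of them.
#' @export
fitted.dcmf <- function(object, view = NULL, ...) {
  one <- function(v) {
    reconstruct_view(object$factors[[v$row_entity]],
                     object$factors[[v$col_entity]])
  }
  if (!is.null(view)) return(one(object$collection$views[[view]]))
  lapply(object$collection$views, one)
}

#' @export
residuals.dcmf <- function(object, ...) {
  fit <- fitted(object)
  lapply(names(fit), function(id) {
    object$collection$views[[id]]$values - fit[[id]]
  }) |> stats::setNames(names(fit))
}

#' Per-view relative Frobenius reconstruction error
#'
#' `||X_m - U_r U_c'||_F / ||X_m||_F` for every view: the scale-free
#' measure of how well the collective factorization explains each matrix.
#'
#' @param model a `dcmf` model.
#' @return named numeric vector, one entry per view.
#' @export
view_errors <- function(model) {
  fit <- fitted(model)
  vapply(names(fit), function(id) {
    x <- model$collection$views[[id]]$values
    norm(x - fit[[id]], "F") / max(norm(x, "F"), .Machine$double.eps)
  }, numeric(1L))
}

#' Predict from a supervised collective model
#'
#' Encodes new rows of the target entity with its trained encoder and
#' applies the task head. New rows must be given in concatenated-input
#' coordinates: the same column blocks (views) used in training, in the
#' same order.
#'
#' @param object a supervised `dcmf` model (fitted with a task).
#' @param newdata numeric matrix of new target-entity rows in concatenated
#'   coordinates; `NULL` re-submits the training input.
#' @param type `"score"` for per-class scores in `[0, 1]` (softmax rows
#'   sum to 1) or the regression response; `"class"` for hard labels.
#' @param ... unused.
#' @return a score matrix with one column per output (class labels as
#'   column names where known), or a label vector for `type = "class"`.
#' @export
predict.dcmf <- function(object, newdata = NULL,
                         type = c("score", "class"), ...) {
  type <- match.arg(type)
  task <- object$task
  if (is.null(task)) stop("model has no task head: fit with a dcmf_task")
  u <- encode_entity(object, task$target_entity, newdata)
  p <- nn_output(object$nets[["head"]], u)
  colnames(p) <- if (task$kind == "binary") utils::tail(task$levels, 1L) %||%
    "1" else task$levels
  if (type == "score") return(p)
  if (task$kind == "regression") stop("type = 'class' needs a classification task")
  if (task$kind == "multiclass") {
    lab <- task$levels[max.col(p, ties.method = "first")]
    factor(lab, levels = task$levels)
  } else if (task$kind == "binary") {
    as.integer(p[, 1L] > 0.5)
  } else {
    (p > 0.5) * 1
  }
}

#' @export
print.dcmf <- function(x, ...) {
  cat(sprintf("<dcmf> %d entities, %d views, k = %d, %s\n",
              length(x$entity_order), length(x$collection$views),
              x$config$latent_dim,
              if (is.null(x$task)) "unsupervised"
              else paste0("supervised (", x$task$kind, " on '",
                          x$task$target_entity, "')")))
  cat(sprintf("  trained %d epoch(s)", x$trained_epochs))
  if (x$trained_epochs > 0L) {
    cat(sprintf(", final total loss %.6g",
                x$history$total[nrow(x$history)]))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.dcmf <- function(object, ...) {
  out <- list(model = object, view_errors = view_errors(object),
              objective = dcmf_objective(object))
  class(out) <- "summary.dcmf"
  out
}

#' @export
print.summary.dcmf <- function(x, ...) {
  print(x$model)
  cat("  relative Frobenius view errors:\n")
  for (id in names(x$view_errors)) {
    cat(sprintf("    %-12s %.4f\n", id, x$view_errors[[id]]))
  }
  print(x$objective)
  invisible(x)
}

#' @export
plot.dcmf <- function(x, log = "y", ...) {
  h <- x$history
  if (is.null(h) || nrow(h) == 0L) stop("no training history to plot")
  graphics::plot(h$epoch, h$total, type = "l", log = log,
                 xlab = "epoch", ylab = "loss", ...)
  graphics::lines(h$epoch, h$entity, lty = 2L)
  graphics::lines(h$epoch, h$view, lty = 3L)
  graphics::legend("topright", legend = c("total", "entity", "view"),
                   lty = 1:3, bty = "n")
  invisible(x)
}

#' Seeded random search over training hyperparameters
#'
#' A small helper replacing automated hyperparameter schedulers: draws
#' candidate settings from given ranges, fits each with a derived seed and
#' returns them ranked by final total loss (or task loss for supervised
#' fits).
#'
#' @param collection a [matrix_collection()].
#' @param n number of candidate configurations.
#' @param latent_dim candidate bottleneck widths to sample from.
#' @param learning_rate range (log-uniform) for the learning rate.
#' @param epochs epochs per candidate fit.
#' @param task optional [dcmf_task()].
#' @param seed seed for the search itself.
#' @param ... fixed arguments passed on to [dcmf_config()].
#' @return data.frame of candidates with their final losses, best first,
#'   with the best fitted model in attribute `"best"`.
#' @export
dcmf_random_search <- function(collection, n = 8L, latent_dim = c(2L, 16L),
                               learning_rate = c(1e-4, 1e-1), epochs = 200L,
                               task = NULL, seed = 1L, ...) {
  set.seed(seed)
  ks <- sample(seq(min(latent_dim), max(latent_dim)), n, replace = TRUE)
  lrs <- exp(stats::runif(n, log(min(learning_rate)),
                          log(max(learning_rate))))
  rows <- list()
  best <- NULL
  for (i in seq_len(n)) {
    cfg <- dcmf_config(latent_dim = ks[i], learning_rate = lrs[i],
                       epochs = epochs, seed = seed + i, ...)
    fit <- dcmf(collection, cfg, task)
    final <- fit$history$total[nrow(fit$history)]
    score <- if (!is.null(task)) fit$history$task[nrow(fit$history)] else final
    rows[[i]] <- data.frame(latent_dim = ks[i], learning_rate = lrs[i],
                            total = final, score = score)
    if (is.null(best) || score < attr(best, "score")) {
      attr(fit, "score") <- score
      best <- fit
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$score), ]
  attr(out, "best") <- best
  out
}
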