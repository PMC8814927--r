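# Minimal feed-forward engine used by the collective autoencoders and the
# SDAE baseline: affine layers with elementwise activations, manual
# backpropagation, Adam and RMSprop updates. Parameters live in plain lists
# of layers so the whole model is copyable and seeded runs are bit
# reproducible. Deliberately full-batch friendly: matrices at desk scale are
# small enough that vectorised BLAS calls dominate.

.nn_act <- function(name) {
  switch(name,
    tanh    = list(f = tanh, dfda = function(a) 1 - a * a),
    sigmoid = list(f = stats::plogis, dfda = function(a) a * (1 - a)),
    linear  = list(f = identity, dfda = function(a) 1),
    softmax = list(f = .nn_softmax, dfda = NULL), # only as a head output
    stop("unknown activation: ", name)
  )
}

.nn_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Fan-in scaled uniform initialisation; draws consume the current RNG stream
# in layer order, which is what makes seeded model builds reproducible.
nn_layer <- function(n_in, n_out, activation = "linear") {
  s <- 1 / sqrt(n_in)
  list(
    W = matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out),
    b = rep(0, n_out),
    activation = activation
  )
}

nn_mlp <- function(sizes, activations) {
  stopifnot(length(activations) == length(sizes) - 1L)
  lapply(seq_along(activations), function(i) {
    nn_layer(sizes[[i]], sizes[[i + 1L]], activations[[i]])
  })
}

# Forward pass storing every layer output: a[[1]] is the input, a[[i + 1]]
# the output of layer i.
nn_forward <- function(layers, x) {
  a <- vector("list", length(layers) + 1L)
  a[[1L]] <- x
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    z <- a[[i]] %*% l$W
    z <- z + rep(l$b, each = nrow(z))
    a[[i + 1L]] <- .nn_act(l$activation)$f(z)
  }
  a
}

nn_output <- function(layers, x) {
  a <- nn_forward(layers, x)
  a[[length(a)]]
}

# Backward pass: d_out is dLoss/d(final activation) unless `d_is_dz = TRUE`,
# in which case it is dLoss/d(final pre-activation) (used for softmax and
# sigmoid cross-entropy heads where the combined gradient is simpler).
nn_backward <- function(layers, acts, d_out, d_is_dz = FALSE) {
  grads <- vector("list", length(layers))
  d <- d_out
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (i == length(layers) && d_is_dz) {
      dz <- d
    } else {
      dz <- d * .nn_act(l$activation)$dfda(acts[[i + 1L]])
    }
    grads[[i]] <- list(W = crossprod(acts[[i]], dz), b = colSums(dz))
    d <- tcrossprod(dz, l$W)
  }
  list(grads = grads, d_input = d)
}

nn_zero_grads <- function(layers) {
  lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

# ---- optimisers over a named list of layer stacks ("nets") -----------------

opt_init <- function(nets) {
  zeros <- lapply(nets, nn_zero_grads)
  list(t = 0L, m = zeros, v = zeros)
}

# Adam with decoupled-from-nothing classic L2 weight decay added to the raw
# gradient (the convention of the original formulation).
opt_step_adam <- function(nets, grads, state, lr, weight_decay = 0,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (n in names(nets)) {
    for (i in seq_along(nets[[n]])) {
      for (p in c("W", "b")) {
        g <- grads[[n]][[i]][[p]] + weight_decay * nets[[n]][[i]][[p]]
        m <- beta1 * state$m[[n]][[i]][[p]] + (1 - beta1) * g
        v <- beta2 * state$v[[n]][[i]][[p]] + (1 - beta2) * g * g
        state$m[[n]][[i]][[p]] <- m
        state$v[[n]][[i]][[p]] <- v
        nets[[n]][[i]][[p]] <- nets[[n]][[i]][[p]] -
          lr * (m / c1) / (sqrt(v / c2) + eps)
      }
    }
  }
  list(nets = nets, state = state)
}

opt_step_rmsprop <- function(nets, grads, state, lr, weight_decay = 0,
                             rho = 0.9, eps = 1e-8) {
  state$t <- state$t + 1L
  for (n in names(nets)) {
    for (i in seq_along(nets[[n]])) {
      for (p in c("W", "b")) {
        g <- grads[[n]][[i]][[p]] + weight_decay * nets[[n]][[i]][[p]]
        v <- rho * state$v[[n]][[i]][[p]] + (1 - rho) * g * g
        state$v[[n]][[i]][[p]] <- v
        nets[[n]][[i]][[p]] <- nets[[n]][[i]][[p]] - lr * g / sqrt(v + eps)
      }
    }
  }
  list(nets = nets, state = state)
}

opt_step <- function(optimizer, ...) {
  switch(optimizer,
    adam = opt_step_adam(...),
    rmsprop = opt_step_rmsprop(...),
    stop("unknown optimizer: ", optimizer)
  )
}
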