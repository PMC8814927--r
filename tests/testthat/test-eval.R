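test_that("split plans partition instances and differ across repeats", {
  plan <- make_splits(100, n_repeats = 3, seed = 2)
  for (sp in plan) {
    expect_length(sp$test, 10L)
    expect_length(sp$train, 90L)
    expect_setequal(c(sp$train, sp$test), 1:100)
  }
  expect_identical(plan, make_splits(100, n_repeats = 3, seed = 2))

  big <- make_splits(1000, n_repeats = 3, seed = 3)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_lt(jac(big[[1]]$test, big[[2]]$test), 1)
  expect_lt(jac(big[[2]]$test, big[[3]]$test), 1)

  expect_error(make_splits(5, train_fraction = 0.95), "no usable test set")
})

test_that("metrics match an independent confusion-matrix recomputation", {
  oracle <- function(y, p) {
    classes <- sort(unique(y))
    cm <- table(factor(y, classes), factor(p, classes))
    f1 <- numeric(length(classes))
    for (i in seq_along(classes)) {
      prec <- if (sum(cm[, i]) > 0) cm[i, i] / sum(cm[, i]) else 0
      rec <- if (sum(cm[i, ]) > 0) cm[i, i] / sum(cm[i, ]) else 0
      f1[i] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }
    sup <- rowSums(cm)
    c(accuracy = sum(diag(cm)) / sum(cm), macro_f1 = mean(f1),
      weighted_f1 = sum(f1 * sup) / sum(sup))
  }
  set.seed(17)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    n <- sample(20:60, 1)
    y <- sample(letters[1:k], n, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- sample(letters[1:k], n, replace = TRUE)
    got <- classification_metrics(y, p)
    expect_equal(got[c("accuracy", "macro_f1", "weighted_f1")], oracle(y, p))
  }
})

test_that("AUC equals the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(n) + y
    got <- classification_metrics(y, as.integer(s > 0.5), scores = s)[["auc"]]
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("metric edge cases behave as defined", {
  y <- c("a", "b", "a", "b")
  expect_equal(unname(classification_metrics(y, y)[1:3]), c(1, 1, 1))
  # constant scores on balanced binary truth: chance-level AUC
  m <- classification_metrics(c(0, 1, 0, 1), c(0, 0, 0, 0),
                              scores = rep(0.3, 4))
  expect_equal(m[["auc"]], 0.5)
  expect_error(classification_metrics(c(1, 1), c(1, 0), scores = c(1, 2)),
               "single class")

  # hand-worked 3-class fixture
  y3 <- c(rep("a", 4), rep("b", 3), rep("c", 3))
  p3 <- c("a", "a", "b", "c", "b", "b", "a", "c", "c", "b")
  # per class: a: tp2 fp1 fn2 -> f1 = 4/7; b: tp2 fp2 fn1 -> 4/7;
  #            c: tp2 fp1 fn1 -> 2/3
  got <- classification_metrics(y3, p3)
  expect_equal(got[["accuracy"]], 0.6)
  expect_equal(got[["macro_f1"]], (4 / 7 + 4 / 7 + 2 / 3) / 3)
  expect_equal(got[["weighted_f1"]],
               (4 * 4 / 7 + 3 * 4 / 7 + 3 * 2 / 3) / 10)
})

test_that("the SDAE learns, is seeded, and rejects wide embeddings", {
  set.seed(19)
  x <- matrix(rnorm(120 * 3), 120, 3) %*% t(matrix(rnorm(20 * 3), 20, 3)) +
    matrix(rnorm(120 * 20, sd = 0.2), 120, 20)
  for (s in 1:3) {
    fit <- sdae(x, embedding_dim = 4, epochs = 15, seed = s)
    expect_lt(tail(fit$history, 1), fit$history[1])
  }
  f1 <- sdae(x, embedding_dim = 4, epochs = 5, seed = 7)
  f2 <- sdae(x, embedding_dim = 4, epochs = 5, seed = 7)
  expect_identical(f1$encoding, f2$encoding)
  expect_equal(dim(f1$encoding), c(120L, 4L))

  # zero corruption reduces to a plain autoencoder (mask plays no role)
  f0 <- sdae(x, embedding_dim = 4, epochs = 5, corruption = 0, seed = 7)
  expect_true(all(is.finite(f0$encoding)))

  expect_error(sdae(x, embedding_dim = 20), "below the input width")
})

test_that("alternating least squares factorizes collections", {
  pl <- planted_collection(dims = c(e1 = 25, e2 = 15, e3 = 10), k = 2,
                           seed = 9)
  fit <- cmf_als(pl$collection, k = 2, n_iter = 30, seed = 1)
  expect_false(is.unsorted(rev(fit$history))) # objective non-increasing
  expect_lt(max(fit$view_errors), 0.05)       # noiseless planted rank
  expect_named(fit$factors, names(pl$collection$entities))
})

test_that("experiment arms enforce the valid combination set", {
  sp <- synth_spec(n_patients = 60,
                   concepts = c(disease = 10, medication = 8, procedure = 6,
                                lab = 5), seed = 12)
  b <- simulate_bundle(sp)
  expect_error(run_experiment(b, view = 2, model = "sdae"),
               "cannot be used when knowledge-graph matrices")
  expect_error(run_experiment(b, view = 1, model = "dcmf_supervised",
                              classifier = "lr"), "its own head")
  expect_error(run_experiment(b, view = 1, model = "dcmf",
                              classifier = "none"), "downstream classifier")
})

test_that("experiment reports are reproducible and complete", {
  sp <- synth_spec(n_patients = 60,
                   concepts = c(disease = 10, medication = 8, procedure = 6,
                                lab = 5), seed = 12)
  b <- simulate_bundle(sp)
  r1 <- run_experiment(b, view = 1, model = "dcmf", classifier = "lr",
                       n_repeats = 2, epochs = 60)
  r2 <- run_experiment(b, view = 1, model = "dcmf", classifier = "lr",
                       n_repeats = 2, epochs = 60)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_equal(nrow(r1$per_repeat), 2L)
  expect_equal(r1$mean[["accuracy"]], mean(r1$per_repeat$accuracy))
  expect_true(all(r1$per_repeat$accuracy >= 0 &
                    r1$per_repeat$accuracy <= 1))

  sup <- run_experiment(b, view = 1, model = "dcmf_supervised",
                        classifier = "none", n_repeats = 2, epochs = 60)
  expect_equal(nrow(sup$per_repeat), 2L)

  grid <- run_experiment_grid(b, views = 1:2, models = c("sdae", "dcmf"),
                              classifiers = "lr", n_repeats = 1,
                              epochs = 40, sdae_dim = 8)
  # sdae valid at view 1 only; dcmf at both
  expect_equal(nrow(grid), 3L)
  expect_setequal(paste(grid$model, grid$view),
                  c("sdae 1", "dcmf 1", "dcmf 2"))
})
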