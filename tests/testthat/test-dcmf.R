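test_that("reconstruction is the factor product", {
  expect_equal(reconstruct_view(diag(2), diag(c(2, 3))),
               matrix(c(2, 0, 0, 3), 2, 2))
  expect_equal(reconstruct_view(matrix(c(1, 2), 2, 1),
                                matrix(c(3, 4), 2, 1)),
               matrix(c(3, 6, 4, 8), 2, 2))
  # brute-force triple loop on random factors
  set.seed(5)
  ur <- matrix(rnorm(21), 7, 3)
  uc <- matrix(rnorm(15), 5, 3)
  slow <- matrix(0, 7, 5)
  for (i in 1:7) for (j in 1:5) for (f in 1:3) {
    slow[i, j] <- slow[i, j] + ur[i, f] * uc[j, f]
  }
  expect_equal(reconstruct_view(ur, uc), slow)
  expect_error(reconstruct_view(ur, uc[, 1:2]), "latent dimensions differ")
})

test_that("initialisation is seeded, checked, and encodes zero to zero", {
  coll <- toy_collection()
  cfg <- dcmf_config(latent_dim = 2, seed = 9)
  m1 <- dcmf_init(coll, cfg)
  m2 <- dcmf_init(coll, cfg)
  expect_identical(m1$nets, m2$nets)
  expect_identical(m1$factors, m2$factors)

  # biases start at zero, so a zero input maps to the zero factor
  z <- encode_entity(m1, "e1", matrix(0, 3, 8))
  expect_true(all(z == 0))

  expect_error(encode_entity(m1, "e1", matrix(0, 3, 5)), "expects 8")
  expect_error(dcmf_init(coll, dcmf_config(latent_dim = 4)),
               "not below the concatenated input width")
  expect_warning(dcmf_init(toy_collection(n1 = 10, n2 = 3, n3 = 9),
                           dcmf_config(latent_dim = 3)),
                 "smallest entity dimension")
})

test_that("an untrained model's factors are its initial encodings", {
  coll <- toy_collection()
  fit <- dcmf(coll, dcmf_config(latent_dim = 2, epochs = 0, seed = 3))
  expect_null(fit$history)
  expect_equal(fit$trained_epochs, 0L)
  for (e in names(coll$entities)) {
    expect_equal(unname(coef(fit, e)), unname(encode_entity(fit, e)))
  }
})

test_that("the objective equals an independent longhand recomputation", {
  set.seed(14)
  for (rep in 1:3) {
    coll <- toy_collection(seed = rep)
    w <- c(entity = runif(1, 0.2, 2), view = runif(1, 0.2, 2),
           task = runif(1, 0.2, 2))
    task <- dcmf_task(rbinom(4, 1, 0.5), "e1")
    fit <- dcmf_init(coll, dcmf_config(latent_dim = 2, seed = rep,
                                       loss_weights = w), task)
    obj <- dcmf_objective(fit)

    # longhand: plain %*% and tanh straight from the stored parameters
    affine <- function(x, l) tanh(sweep(x %*% l$W, 2, l$b, "+"))
    affine_lin <- function(x, l) sweep(x %*% l$W, 2, l$b, "+")
    lE <- lR <- numeric(0)
    U <- list()
    for (e in names(coll$entities)) {
      C <- concatenate_entity(coll, e)$values
      U[[e]] <- affine(C, fit$nets[[paste0("enc.", e)]][[1]])
      Chat <- affine_lin(U[[e]], fit$nets[[paste0("dec.", e)]][[1]])
      lE[e] <- sum((Chat - C)^2) / length(C)
    }
    for (v in coll$views) {
      R <- U[[v$row_entity]] %*% t(U[[v$col_entity]])
      lR[v$id] <- sum((R - v$values)^2) / length(v$values)
    }
    hl <- fit$nets[["head"]][[1]]
    p <- 1 / (1 + exp(-affine_lin(U[["e1"]], hl)))
    lT <- -mean(task$y * log(p) + (1 - task$y) * log(1 - p))

    expect_equal(obj$entity_losses, lE, tolerance = 1e-9)
    expect_equal(obj$view_losses, lR, tolerance = 1e-9)
    expect_equal(obj$task_loss, lT, tolerance = 1e-9)
    expect_equal(obj$total,
                 w[["entity"]] * sum(lE) + w[["view"]] * sum(lR) +
                   w[["task"]] * lT,
                 tolerance = 1e-9)
  }
})

test_that("zero task weight reproduces the unsupervised trajectory", {
  coll <- toy_collection(seed = 6)
  cfg0 <- dcmf_config(latent_dim = 2, epochs = 40, learning_rate = 1e-2,
                      seed = 2, loss_weights = c(task = 0))
  cfg1 <- dcmf_config(latent_dim = 2, epochs = 40, learning_rate = 1e-2,
                      seed = 2)
  sup <- dcmf(coll, cfg0, dcmf_task(c(0, 1, 0, 1), "e1"))
  uns <- dcmf(coll, cfg1)
  expect_identical(sup$factors, uns$factors)
  for (e in names(coll$entities)) {
    expect_identical(sup$nets[[paste0("enc.", e)]],
                     uns$nets[[paste0("enc.", e)]])
  }
  expect_identical(sup$history$entity, uns$history$entity)
  expect_identical(sup$history$view, uns$history$view)
})

test_that("training is reproducible and mostly monotone", {
  coll <- toy_collection(seed = 10)
  cfg <- dcmf_config(latent_dim = 2, epochs = 120, learning_rate = 5e-3,
                     seed = 4)
  f1 <- dcmf(coll, cfg)
  f2 <- dcmf(coll, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$factors, f2$factors)

  drops <- diff(f1$history$total) <= 1e-12
  expect_gte(mean(drops), 0.9)
  expect_lt(f1$history$total[nrow(f1$history)], f1$history$total[1])
})

test_that("noiseless low-rank collections are recovered", {
  pl <- planted_collection(dims = c(e1 = 20, e2 = 15, e3 = 10), k = 2,
                           seed = 2)
  fit <- dcmf(pl$collection,
              dcmf_config(latent_dim = 2, activation = "linear",
                          learning_rate = 0.02, epochs = 1500, seed = 1))
  expect_lt(mean(view_errors(fit)), 0.05)

  # the single-matrix special case: two coupled autoencoders factorizing X
  set.seed(12)
  x <- matrix(rnorm(30 * 2), 30, 2) %*% t(matrix(rnorm(12 * 2), 12, 2))
  single <- matrix_collection(list(view_matrix(x, "rows", "cols", id = "X")))
  sfit <- dcmf(single, dcmf_config(latent_dim = 2, activation = "linear",
                                   learning_rate = 0.02, epochs = 1500,
                                   seed = 1))
  expect_length(sfit$factors, 2L)
  expect_lt(view_errors(sfit)[["X"]],  0.05)
  expect_equal(dim(coef(sfit, "rows")), c(30L, 2L))
})

test_that("a non-finite loss aborts with a diagnostic naming the epoch", {
  # squared residuals of this view overflow double precision immediately
  coll <- suppressWarnings(matrix_collection(list(
    view_matrix(matrix(1e200 + seq_len(12), 4, 3), "a", "b", id = "huge"))))
  expect_error(
    dcmf(coll, dcmf_config(latent_dim = 2, activation = "linear",
                           epochs = 10, seed = 1)),
    "diverged at epoch [0-9]+")
})

test_that("stored factors satisfy the re-encoding invariant", {
  coll <- toy_collection(seed = 13)
  fit <- dcmf(coll, dcmf_config(latent_dim = 2, epochs = 60,
                                learning_rate = 1e-2, seed = 7))
  for (e in names(coll$entities)) {
    expect_equal(unname(coef(fit, e)),
                 unname(encode_entity(fit, e,
                                      fit$concats[[e]]$values)))
  }
  reps <- extract_representations(fit)
  expect_named(reps, names(coll$entities))

  # CSV round trip within float formatting
  dir <- withr::local_tempdir()
  write_factors(reps, dir)
  back <- utils::read.csv(file.path(dir, "e1_factors.csv"))
  expect_equal(as.matrix(back[, -1]), coef(fit, "e1"),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("supervised prediction is deterministic and normalised", {
  set.seed(31)
  n <- 60
  u <- matrix(rnorm(n * 2), n, 2)
  v <- matrix(rnorm(10 * 2), 10, 2)
  x <- u %*% t(v) + matrix(rnorm(n * 10, sd = 0.1), n, 10)
  coll <- matrix_collection(list(view_matrix(x, "p", "d", id = "X")))
  y <- as.integer(u[, 1] > 0)     # labels: sign of the first true factor
  ycl <- factor(ifelse(y == 1, "hi", "lo"))

  # binary head
  fitb <- dcmf(coll, dcmf_config(latent_dim = 2, epochs = 300,
                                 learning_rate = 1e-2, seed = 2,
                                 loss_weights = c(task = 2)),
               dcmf_task(y, "p"))
  expect_error(predict(dcmf(coll, dcmf_config(latent_dim = 2, epochs = 0))),
               "no task head")
  s1 <- predict(fitb)
  s2 <- predict(fitb, concatenate_entity(coll, "p")$values)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))

  # multiclass softmax head: rows sum to one
  fitm <- dcmf(coll, dcmf_config(latent_dim = 2, epochs = 100,
                                 learning_rate = 1e-2, seed = 2),
               dcmf_task(factor(c("a", "b", "c"))[1 + (seq_len(n) %% 3)],
                         "p", kind = "multiclass"))
  pm <- predict(fitm)
  expect_equal(rowSums(pm), rep(1, n), tolerance = 1e-6)
  expect_s3_class(predict(fitm, type = "class"), "factor")

  # held-out accuracy beats the majority rate on the sign task
  tr <- 1:45
  te <- 46:60
  trc <- subset_entity_rows(coll, "p", tr)
  fit_tr <- dcmf(trc, dcmf_config(latent_dim = 2, epochs = 300,
                                  learning_rate = 1e-2, seed = 2,
                                  loss_weights = c(task = 2)),
                 dcmf_task(y[tr], "p"))
  ph <- predict(fit_tr, concatenate_entity(coll, "p")$values[te, ],
                type = "class")
  expect_gt(mean(ph == y[te]), max(mean(y[te]), 1 - mean(y[te])) - 1e-9)
  expect_gt(mean(ph == y[te]), 0.5)
})

test_that("the random-search helper ranks candidates by loss", {
  coll <- toy_collection(seed = 20)
  rs <- dcmf_random_search(coll, n = 3, latent_dim = c(2, 2),
                           learning_rate = c(1e-3, 1e-2), epochs = 30,
                           seed = 5)
  expect_equal(nrow(rs), 3L)
  expect_false(is.unsorted(rs$score))
  expect_s3_class(attr(rs, "best"), "dcmf")
})
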