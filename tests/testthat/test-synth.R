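test_that("simulation is deterministic with independent component streams", {
  topo <- list(
    list(row = "patient", col = "disease", kind = "binary", id = "D"),
    list(row = "patient", col = "medication", kind = "count", id = "M"))
  sp <- synth_spec(n_patients = 60, concepts = c(disease = 12,
                                                 medication = 10), seed = 3)
  a <- simulate_collection(sp, topo)
  b <- simulate_collection(sp, topo)
  expect_identical(a, b)

  # changing only the graph seed leaves views and labels untouched
  sp2 <- synth_spec(n_patients = 60, concepts = c(disease = 12,
                                                  medication = 10),
                    seed = 3, kg_seed = 99)
  b2 <- simulate_collection(sp2, topo)
  expect_identical(a$collection, b2$collection)
  kg_a <- simulate_kg(sp, a$factors[c("disease", "medication")])
  kg_b <- simulate_kg(sp2, a$factors[c("disease", "medication")])
  expect_false(identical(kg_a$triplets, kg_b$triplets))
  expect_identical(simulate_labels(a$factors$patient, sp),
                   simulate_labels(a$factors$patient, sp2))
})

test_that("noiseless real views have the planted rank", {
  sp <- synth_spec(n_patients = 30, concepts = c(disease = 12), rank = 2,
                   noise_sd = 0, seed = 5)
  sim <- simulate_collection(sp, views = list(
    list(row = "patient", col = "disease", kind = "real", id = "V")))
  expect_equal(qr(sim$collection$views$V$values)$rank, 2L)
})

test_that("binary views thresholded at the median are half dense", {
  sp <- synth_spec(n_patients = 200, concepts = c(disease = 30), seed = 8)
  sim <- simulate_collection(sp, views = list(
    list(row = "patient", col = "disease", kind = "binary", id = "B")))
  expect_equal(mean(sim$collection$views$B$values), 0.5, tolerance = 0.02)

  # count views are non-negative integers
  simc <- simulate_collection(sp, views = list(
    list(row = "patient", col = "disease", kind = "count", id = "K")))
  v <- simc$collection$views$K$values
  expect_true(all(v >= 0) && all(v == round(v)))

  expect_error(simulate_collection(sp, views = list(
    list(row = "patient", col = "ghost", kind = "real", id = "G"))),
    "undeclared entity")
})

test_that("the simulated graph reflects the planted similarity structure", {
  sp <- synth_spec(n_patients = 20,
                   concepts = c(disease = 30, medication = 30), seed = 2)
  sim <- simulate_collection(sp, views = list(
    list(row = "patient", col = "disease", kind = "real", id = "A"),
    list(row = "patient", col = "medication", kind = "real", id = "B")))
  kg <- simulate_kg(sp, sim$factors[c("disease", "medication")])

  # noise triplets appear at roughly the configured fractions
  n_assoc <- sum(kg$triplets$predicate == "ASSOCIATED_WITH")
  n_neg <- sum(startsWith(kg$triplets$predicate, "NEG"))
  expect_equal(n_neg, round(0.05 * n_assoc), tolerance = 0.5)

  # GRA similarity on the 60-node graph rank-correlates with true cosine
  S <- gra_matrix(kg$graph, kg$graph$nodes, beta = 0.5, max_length = 3,
                  mode = "walk")
  u <- do.call(rbind, sim$factors[c("disease", "medication")])
  u <- u[kg$graph$nodes, ]
  cosine <- tcrossprod(u / sqrt(rowSums(u^2)))
  ut <- upper.tri(S)
  expect_gt(cor(S[ut], cosine[ut], method = "spearman"), 0)
})

test_that("label simulation matches its logistic model", {
  set.seed(1)
  u <- matrix(rnorm(2000 * 3), 2000, 3)

  # zero coefficient scale: every probability is the target prevalence
  sp0 <- synth_spec(labels = list(scale = 0, prevalence = 0.5), seed = 4)
  l0 <- simulate_labels(u, sp0)
  expect_true(all(abs(l0$probabilities - 0.5) < 1e-12))
  expect_equal(mean(l0$y), 0.5, tolerance = 0.05)

  # huge scale: the task becomes separable
  sp_big <- synth_spec(labels = list(scale = 50), seed = 4)
  expect_gt(simulate_labels(u, sp_big)$bayes_accuracy, 0.95)

  # reported Bayes accuracy matches a direct Monte-Carlo with the known rule
  sp1 <- synth_spec(labels = list(scale = 1), seed = 4)
  l1 <- simulate_labels(u, sp1)
  p <- l1$probabilities
  direct <- mean(ifelse(p > 0.5, p, 1 - p)) # P(Bayes rule correct | eta)
  expect_equal(l1$bayes_accuracy, direct, tolerance = 0.02)

  # prevalence targeting
  sp12 <- synth_spec(labels = list(prevalence = 0.12), seed = 4)
  expect_equal(mean(simulate_labels(u, sp12)$probabilities), 0.12,
               tolerance = 1e-6)

  # multiclass argmax labels are deterministic given the factors
  spm <- synth_spec(labels = list(classes = 3), seed = 4)
  lm1 <- simulate_labels(u, spm)
  expect_s3_class(lm1$y, "factor")
  expect_equal(nlevels(lm1$y), 3L)
  expect_equal(lm1$bayes_accuracy, 1)
})

test_that("the three study views nest as cumulative augmentations", {
  sp <- synth_spec(n_patients = 80,
                   concepts = c(disease = 12, medication = 10,
                                procedure = 8, lab = 6), seed = 6)
  b <- simulate_bundle(sp)
  expect_length(b$view1$views, 3L)
  expect_length(b$view2$views, 6L) # exactly three more square views
  sq <- Filter(function(v) v$row_entity == v$col_entity, b$view2$views)
  expect_length(sq, 3L)
  expect_length(b$view3$views, 8L)

  w <- vapply(paste0("view", 1:3), function(v) {
    ncol(concatenate_entity(b[[v]], "patient")$values)
  }, integer(1L))
  expect_gte(w[["view2"]], w[["view1"]]) # square views spare the patient rows
  expect_gt(w[["view3"]], w[["view2"]])
  total_width <- vapply(paste0("view", 1:3), function(v) {
    sum(vapply(names(b[[v]]$entities), function(e) {
      ncol(concatenate_entity(b[[v]], e)$values)
    }, integer(1L)))
  }, integer(1L))
  expect_true(all(diff(total_width) > 0))

  # every view-1 matrix carries TF-IDF metadata and real values
  for (v in b$view1$views) expect_equal(v$value_kind, "real")

  # written bundles load back through the manifest reader without errors
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  for (lvl in paste0("view", 1:3)) {
    rc <- read_collection(file.path(dir, lvl, "collection.yaml"))
    expect_identical(rc$entities[names(b[[lvl]]$entities)],
                     b[[lvl]]$entities)
    expect_identical(validate_collection(rc)$errors, character(0))
  }
  tr <- read_triplets(file.path(dir, "triplets.tsv"))
  expect_equal(nrow(tr), nrow(b$kg$triplets))
})
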