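toy_params <- function(d0 = 4, h = 3, out = 3, zdim = h, seed = 2) {
  set.seed(seed)
  list(W1 = matrix(rnorm(h * d0), h, d0), b = rnorm(h),
       W2 = matrix(rnorm(out * zdim), out, zdim))
}

test_that("local encoding is max-over-time pooled ELU convolution", {
  voc <- paste0("w", 1:4)
  sp <- rand_space(voc, dim = 4, seed = 1)
  zero <- list(W1 = matrix(0, 3, 4), b = rep(0, 3), W2 = diag(3))
  expect_equal(encode_local(c("w1", "w2"), sp, zero), rep(0, 3))

  par <- toy_params()
  # single token: no pooling effect
  x <- embedding_lookup(sp, "w1")[1, ]
  elu <- function(v) ifelse(v > 0, v, exp(v) - 1)
  expect_equal(encode_local("w1", sp, par),
               as.vector(elu(par$W1 %*% x + par$b)))
  # identity weights: elementwise max of ELU over the window
  idp <- list(W1 = diag(4), b = rep(0, 4), W2 = diag(4))
  x1 <- embedding_lookup(sp, "w1")[1, ]
  x2 <- embedding_lookup(sp, "w2")[1, ]
  expect_equal(encode_local(c("w1", "w2"), sp, idp),
               pmax(elu(x1), elu(x2)))
  # empty window falls back to the zero hidden vector
  expect_equal(encode_local(character(0), sp, par), rep(0, 3))
})

test_that("global context is the IDF-weighted mean excluding the target", {
  voc <- c("w1", "abb", "w2")
  sp <- rand_space(voc, dim = 4, seed = 3)
  idf1 <- flat_idf(voc, 1)
  g <- global_context(c("w1", "abb", "w2"), 2L, sp, idf1)
  expect_equal(g, (embedding_lookup(sp, "w1")[1, ] +
                     embedding_lookup(sp, "w2")[1, ]) / 2)
  # a document holding only the abbreviation gives the zero vector
  expect_equal(global_context("abb", 1L, sp, idf1), rep(0, 4))
  # explicit weights 1 and 3
  idf2 <- tibble::tibble(token = c("w1", "w2"), idf = c(1, 3))
  g2 <- global_context(c("w1", "abb", "w2"), 2L, sp, idf2)
  expect_equal(g2, (1 * embedding_lookup(sp, "w1")[1, ] +
                      3 * embedding_lookup(sp, "w2")[1, ]) / 4)
})

test_that("sample encoding is ReLU + L2 normalization with a zero guard", {
  par <- list(W1 = diag(2), b = rep(0, 2), W2 = diag(2))
  expect_equal(encode_sample(c(3, 4), params = par), c(0.6, 0.8))
  # all-negative pre-activation: zero vector, no division error
  expect_equal(encode_sample(c(-1, -2), params = par), c(0, 0))
  # unit norm whenever nonzero
  set.seed(8)
  for (rep in 1:20) {
    p <- toy_params(d0 = 4, h = 3, out = 5, zdim = 3, seed = rep)
    e <- encode_sample(rnorm(3), params = p)
    expect_true(abs(sqrt(sum(e^2)) - 1) < 1e-9 || all(e == 0))
  }
  expect_error(encode_sample(c(1, 2, 3), params = par), "dimension")
})

test_that("classification softmax matches the brute-force oracle", {
  expect_equal(classify(c(1, 0), rbind(c(1, 0), c(0, 1))),
               c(0.73106, 0.26894), tolerance = 1e-5)
  # identical rows give uniform probabilities
  expect_equal(classify(c(0.3, 0.7), rbind(c(1, 1), c(1, 1), c(1, 1))),
               rep(1 / 3, 3))
  # degenerate single-expansion matrix
  expect_equal(classify(c(1, 2), matrix(c(5, 5), 1, 2)), 1)
  set.seed(17)
  for (rep in 1:100) {
    k <- sample(2:8, 1)
    d <- sample(2:6, 1)
    H <- matrix(rnorm(k * d), k, d)
    e <- rnorm(d)
    expect_equal(classify(e, H), softmax_oracle(as.vector(H %*% e)),
                 tolerance = 1e-12)
  }
})

test_that("effective concept embeddings are ancestor sums", {
  chain <- chain_ontology(c("a", "b", "c"))
  H_raw <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  hier <- list(H_raw = H_raw, ontology = chain)
  expect_equal(effective_concept_embedding(hier, "a"), 1)   # root: raw only
  expect_equal(effective_concept_embedding(hier, "c"), 6)   # 1 + 2 + 3
  # a concept with no raw row inherits its ancestors' sum
  hier2 <- list(H_raw = H_raw[c("a", "b"), , drop = FALSE], ontology = chain)
  expect_equal(effective_concept_embedding(hier2, "c"), 3)
  # neither raw row nor hierarchy ancestors: error
  lone <- chain_ontology("x")
  expect_error(effective_concept_embedding(
    list(H_raw = matrix(0, 0, 1, dimnames = list(character(0), NULL)),
         ontology = lone), "x"), "neither")

  # random DAGs vs an independent ancestor-set traversal oracle
  set.seed(23)
  for (rep in 1:20) {
    onto <- generate_ontology(15, max_children = 3, seed = rep)
    ids <- onto$nodes$concept_id
    H <- matrix(rnorm(length(ids) * 3), length(ids), 3,
                dimnames = list(ids, NULL))
    hh <- list(H_raw = H, ontology = onto)
    cc <- sample(ids, 1)
    oracle <- H[cc, ]
    for (an in ancestors(onto, cc)) oracle <- oracle + H[an, ]
    expect_equal(effective_concept_embedding(hh, cc), oracle,
                 tolerance = 1e-12)
  }
})

test_that("batched forward pass equals the single-sample operations", {
  st <- small_study()
  samp <- samples_from_gold(st$eval_corpus$gold[1:12, ],
                            preprocess_corpus(st$eval_corpus$notes,
                                              st$lexicon))
  par <- toy_params(d0 = 40, h = 10, out = 7, zdim = 50, seed = 4)
  H <- matrix(rnorm(3 * 7), 3, 7)
  inp <- abbrevx:::prepare_encoder_inputs(samp, st$space, st$idf, TRUE)
  fw <- abbrevx:::encoder_forward(par, H, inp)
  for (i in seq_len(nrow(samp))) {
    v <- encode_local(samp$window[[i]], st$space, par)
    g <- global_context(samp$document_tokens[[i]],
                        samp$abbrev_positions[[i]], st$space, st$idf)
    p <- classify(encode_sample(v, g, par), H)
    expect_equal(fw$p[, i], p, tolerance = 1e-12)
  }
})

test_that("one gradient step moves a concept and its ancestors identically", {
  # two leaf classes on separate branches; each branch has a private
  # ancestor chain, so the target's ancestors receive exactly its gradient
  onto <- ontology(
    nodes = tibble::tibble(concept_id = c("r", "a1", "a2", "c1", "c2"),
                           name = paste("n", 1:5)),
    edges = tibble::tibble(child_id = c("a1", "a2", "c1", "c2"),
                           parent_id = c("r", "r", "a1", "a2")))
  classes <- c("c1", "c2")
  closure <- sort(c("r", "a1", "a2", "c1", "c2"))
  A <- abbrevx:::ancestor_matrix(onto, closure)
  A_class <- A[classes, , drop = FALSE]
  voc <- paste0("w", 1:6)
  sp <- rand_space(voc, dim = 4, seed = 5)
  idf <- flat_idf(voc)
  samp <- tibble::tibble(label = "c1",
                         window = list(c("w1", "w2")),
                         document_tokens = list(c("w1", "w2", "w3")),
                         abbrev_positions = list(3L))
  inp <- abbrevx:::prepare_encoder_inputs(samp, sp, idf, TRUE, classes)
  par <- toy_params(d0 = 4, h = 3, out = 4, zdim = 7, seed = 6)
  H_raw <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(closure, NULL))
  H_eff <- as.matrix(A_class %*% H_raw)
  fw <- abbrevx:::encoder_forward(par, H_eff, inp)
  gr <- abbrevx:::encoder_backward(par, H_eff, inp, fw)
  dH_raw <- as.matrix(Matrix::crossprod(A_class, gr$dH))
  rownames(dH_raw) <- closure
  # target c1 and its exclusive ancestor a1 move by the same increment
  expect_equal(dH_raw["c1", ], dH_raw["a1", ], tolerance = 1e-12)
  expect_equal(dH_raw["c2", ], dH_raw["a2", ], tolerance = 1e-12)
  # the shared root accumulates both branches' gradients
  expect_equal(dH_raw["r", ], dH_raw["c1", ] + dH_raw["c2", ],
               tolerance = 1e-12)
  # and the increments are nonzero
  expect_gt(max(abs(dH_raw["c1", ])), 0)
})

test_that("hierarchical pretraining learns above chance and inherits", {
  st <- small_study()
  inv <- st$inventory
  concepts <- character(0)
  for (a in unique(inv$abbreviation)) {
    concepts <- union(concepts, select_pretraining_concepts(
      a, inv, st$ontology, st$space, delta = 2.6))
  }
  pre <- pretrain_hierarchy(
    st$docs, concepts, st$ontology, st$space, st$idf,
    config = default_train_config(hidden_dim = 24, output_dim = 24,
                                  epochs = 30, pretrain_lr = 0.05,
                                  pretrain_batch_size = 64,
                                  samples_per_concept = 80, seed = 4))
  # concepts absent from all sentences (e.g. inner nodes) get pure
  # inheritance: effective = sum of ancestors' raws
  absent <- setdiff(rownames(pre$hier$H_raw), pre$classes)
  expect_gt(length(absent), 0)
  # held-out concept prediction beats chance by a wide margin:
  # validation loss well below log(n_classes)
  expect_lt(pre$validation_loss, log(length(pre$classes)) * 0.6)
})

test_that("abbreviation training fits separable data and is deterministic", {
  fx <- separable_samples()
  cfg <- tiny_train_config()
  m <- train_abbrev_model(fx$ts, fx$space, fx$idf, cfg)
  train_rows <- fx$ts[fx$ts$split == "train", ]
  pr <- predict_expansion(train_rows, m, fx$space, fx$idf)
  expect_equal(mean(pr$predicted == pr$label), 1)
  # held-out accuracy 1.0 on the separable fixture
  pt <- predict_expansion(fx$test, m, fx$space, fx$idf)
  expect_equal(mean(pt$predicted == pt$label), 1)
  # probabilities are simplex vectors
  expect_true(all(abs(vapply(pt$probabilities, sum, numeric(1)) - 1) < 1e-9))

  m2 <- train_abbrev_model(fx$ts, fx$space, fx$idf, cfg)
  expect_identical(m$validation_loss, m2$validation_loss)
  expect_identical(m$H, m2$H)
})

test_that("pretrained weights transfer into the abbreviation model", {
  st <- small_study()
  inv <- st$inventory
  a <- inv$abbreviation[[1]]
  concepts <- select_pretraining_concepts(a, inv, st$ontology, st$space,
                                          delta = 2.6)
  pre <- pretrain_hierarchy(
    st$docs, concepts, st$ontology, st$space, st$idf,
    config = default_train_config(hidden_dim = 24, output_dim = 24,
                                  epochs = 5, pretrain_batch_size = 128,
                                  samples_per_concept = 40, seed = 4))
  rel <- relatives_for_abbreviation(a, inv, st$ontology, st$space, st$docs)
  ts <- suppressWarnings(build_training_set(
    st$direct, a, inv, "relatives", relatives = rel, docs = st$docs,
    target_per_expansion = 30, seed = 5))
  # lr = 0 freezes the copied weights, exposing the initialization contract
  frozen <- suppressWarnings(train_abbrev_model(
    ts, st$space, st$idf,
    default_train_config(hidden_dim = 24, output_dim = 24, epochs = 1,
                         lr = 0, seed = 4),
    init = pre))
  expect_identical(frozen$params$W1, pre$params$W1)
  expect_identical(frozen$params$W2, pre$params$W2)
  cids <- inv$concept_id[inv$abbreviation == a]
  for (i in seq_along(cids)) {
    expect_equal(frozen$H[i, ], effective_concept_embedding(pre$hier,
                                                            cids[[i]]),
                 tolerance = 1e-12)
  }
})

test_that("prediction rejects foreign abbreviations and handles edge windows", {
  fx <- separable_samples()
  m <- train_abbrev_model(fx$ts, fx$space, fx$idf, tiny_train_config())
  bad <- fx$test
  bad$abbreviation <- "other"
  expect_error(predict_expansion(bad, m, fx$space, fx$idf), "not trained")
  # an empty local window falls back to global context without crashing
  edge <- fx$test[1, ]
  edge$window <- list(character(0))
  out <- predict_expansion(edge, m, fx$space, fx$idf)
  expect_true(out$predicted %in% m$expansions)
})

test_that("model checkpoints round-trip through plain text", {
  fx <- separable_samples()
  m <- train_abbrev_model(fx$ts, fx$space, fx$idf, tiny_train_config())
  dir <- withr::local_tempdir()
  write_model(m, dir)
  back <- read_model(dir)
  expect_equal(back$H, m$H, tolerance = 1e-12)
  expect_equal(back$params$W1, m$params$W1, tolerance = 1e-12)
  pr1 <- predict_expansion(fx$test, m, fx$space, fx$idf)
  pr2 <- predict_expansion(fx$test, back, fx$space, fx$idf)
  expect_equal(pr1$predicted, pr2$predicted)
})

test_that("global context ablation: document-level senses need g", {
  fx <- global_only_samples()
  test_rows <- fx$ts[fx$ts$split == "test", ]
  m_global <- train_abbrev_model(fx$ts, fx$space, fx$idf,
                                 tiny_train_config(use_global = TRUE))
  m_local <- train_abbrev_model(fx$ts, fx$space, fx$idf,
                                tiny_train_config(use_global = FALSE))
  acc <- function(m) {
    pr <- predict_expansion(test_rows, m, fx$space, fx$idf)
    mean(pr$predicted == pr$label)
  }
  expect_gt(acc(m_global), acc(m_local))
  expect_gt(acc(m_global), 0.9)
})
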