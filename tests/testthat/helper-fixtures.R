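# Shared fixtures, built once per test session.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# A small but complete simulated study with trained embeddings: 3
# abbreviations, one rare never-written-out sense, subword skip-gram space.
small_study <- function() {
  cached("small_study", {
    study <- simulate_study(n_abbreviations = 3, n_notes = 250,
                            n_eval_notes = 45, seed = 7)
    lex <- c(study$ontology$nodes$name, study$inventory$expansion)
    docs <- preprocess_corpus(study$corpus$notes, lex)
    c(study, list(
      lexicon = lex,
      docs = docs,
      direct = reverse_substitute(docs, study$inventory),
      idf = compute_idf(docs),
      space = train_embeddings(docs, dim = 40, seed = 3, epochs = 8)
    ))
  })
}

# Deterministic random embedding space over a fixed vocabulary.
rand_space <- function(vocab, dim = 8, seed = 1, scale = 1) {
  set.seed(seed)
  embedding_space(matrix(rnorm(length(vocab) * dim, sd = scale),
                         length(vocab), dim,
                         dimnames = list(vocab, NULL)))
}

flat_idf <- function(vocab, w = 1) {
  out <- tibble::tibble(token = vocab, idf = rep(w, length(vocab)))
  attr(out, "n_docs") <- length(vocab)
  out
}

# Chain ontology r -> a -> b -> ... (ids given root-first).
chain_ontology <- function(ids) {
  ontology(
    nodes = tibble::tibble(concept_id = ids,
                           name = paste("node", ids)),
    edges = tibble::tibble(child_id = ids[-1],
                           parent_id = ids[-length(ids)])
  )
}

tiny_train_config <- function(...) {
  default_train_config(hidden_dim = 16, output_dim = 16, epochs = 25,
                       lr = 0.05, batch_size = 16, seed = 1, ...)
}

# Linearly separable two-sense fixture: each sense's windows come from its
# own token cluster with well-separated embeddings.
separable_samples <- function(n_per_sense = 30, n_test = 10, seed = 5) {
  set.seed(seed)
  vocA <- paste0("alpha", 1:6)
  vocB <- paste0("beta", 1:6)
  vocab <- c(vocA, vocB, "filler")
  dim <- 8
  M <- matrix(0, length(vocab), dim, dimnames = list(vocab, NULL))
  M[vocA, 1:4] <- matrix(rnorm(length(vocA) * 4, mean = 2, sd = 0.2),
                         length(vocA), 4)
  M[vocB, 5:8] <- matrix(rnorm(length(vocB) * 4, mean = 2, sd = 0.2),
                         length(vocB), 4)
  space <- embedding_space(M)
  mk <- function(n, voc, label, split) {
    tibble::tibble(
      note_id = paste0("n", seq_len(n), label),
      abbreviation = "zz",
      label = label,
      window = replicate(n, sample(voc, 3, replace = TRUE),
                         simplify = FALSE),
      document_tokens = replicate(n, c(sample(voc, 5, replace = TRUE),
                                       "zz"), simplify = FALSE),
      abbrev_positions = replicate(n, 6L, simplify = FALSE),
      provenance = "direct",
      split = split
    )
  }
  train <- dplyr::bind_rows(mk(n_per_sense, vocA, "sense a", "train"),
                            mk(n_per_sense, vocB, "sense b", "train"))
  val <- dplyr::bind_rows(mk(5, vocA, "sense a", "validation"),
                          mk(5, vocB, "sense b", "validation"))
  test <- dplyr::bind_rows(mk(n_test, vocA, "sense a", "test"),
                           mk(n_test, vocB, "sense b", "test"))
  ts <- structure(dplyr::bind_rows(train, val, test),
                  abbreviation = "zz",
                  expansions = c("sense a", "sense b"),
                  strategy = "control",
                  class = c("tbl_df", "tbl", "data.frame"))
  list(ts = ts, space = space, idf = flat_idf(vocab),
       test = test)
}

# Fixture whose senses share identical local windows and differ only in
# document-level vocabulary: local context is uninformative by construction.
global_only_samples <- function(n_per_sense = 40, n_test = 15, seed = 6) {
  set.seed(seed)
  shared <- paste0("common", 1:4)
  docA <- paste0("topicA", 1:6)
  docB <- paste0("topicB", 1:6)
  vocab <- c(shared, docA, docB)
  dim <- 8
  M <- matrix(rnorm(length(vocab) * dim, sd = 0.1), length(vocab), dim,
              dimnames = list(vocab, NULL))
  M[docA, 1:4] <- M[docA, 1:4] + 2
  M[docB, 5:8] <- M[docB, 5:8] + 2
  space <- embedding_space(M)
  fixed_window <- c("common1", "common2", "common3")
  mk <- function(n, docvoc, label, split) {
    tibble::tibble(
      note_id = paste0("n", seq_len(n), label),
      abbreviation = "qq",
      label = label,
      window = replicate(n, fixed_window, simplify = FALSE),
      document_tokens = replicate(n, c("qq", fixed_window,
                                       sample(docvoc, 6, replace = TRUE)),
                                  simplify = FALSE),
      abbrev_positions = replicate(n, 1L, simplify = FALSE),
      provenance = "direct",
      split = split
    )
  }
  ts <- structure(
    dplyr::bind_rows(
      mk(n_per_sense, docA, "sense a", "train"),
      mk(n_per_sense, docB, "sense b", "train"),
      mk(6, docA, "sense a", "validation"),
      mk(6, docB, "sense b", "validation"),
      mk(n_test, docA, "sense a", "test"),
      mk(n_test, docB, "sense b", "test")
    ),
    abbreviation = "qq",
    expansions = c("sense a", "sense b"),
    strategy = "control",
    class = c("tbl_df", "tbl", "data.frame")
  )
  list(ts = ts, space = space, idf = flat_idf(vocab))
}

# Independent softmax oracle used throughout the equation tests.
softmax_oracle <- function(x) {
  ex <- exp(x)
  ex / sum(ex)
}

# Independent one-sided signed-rank p-value by full enumeration.
wilcoxon_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mean(vs >= v_obs)
}

# thin aliases onto internals used by several tests
join_tok <- function(x) abbrevx:::join_phrase(x)
concept_names_fixture <- function(onto, ids) abbrevx:::concept_name(onto, ids)
build_study_ontology_fixture <- function(n_slots = 4, siblings = 2, seed = 11) {
  abbrevx:::build_study_ontology(n_slots, siblings_per_sense = siblings,
                                 seed = seed)
}
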