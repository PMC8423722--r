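test_that("preprocess_note lowercases, splits and joins multi-word concepts", {
  out <- preprocess_note("Scheduled for in vitro fertilization.",
                         concept_lexicon = "in vitro fertilization")
  expect_equal(out, list(c("scheduled", "for", "in_vitro_fertilization")))

  expect_equal(preprocess_note(""), list())
  expect_equal(preprocess_note("   "), list())

  # longest-match-first, left to right, over overlapping lexicon entries
  out2 <- preprocess_note("intravenous fluid bolus",
                          concept_lexicon = c("intravenous fluid",
                                              "fluid bolus"))
  expect_equal(out2, list(c("intravenous_fluid", "bolus")))

  # sentence boundaries at terminal punctuation and newlines
  out3 <- preprocess_note("First one. Second; third\nfourth!")
  expect_length(out3, 4)
})

test_that("longest-match joining agrees with a scan oracle on random cases", {
  # oracle: independent greedy re-implementation over explicit token walks
  greedy_oracle <- function(tokens, seqs) {
    out <- character(0)
    i <- 1
    while (i <= length(tokens)) {
      best <- 0
      for (s in seqs) {
        k <- length(s)
        if (k > best && i + k - 1 <= length(tokens) &&
            identical(tokens[i:(i + k - 1)], s)) best <- k
      }
      if (best > 0) {
        out <- c(out, paste(tokens[i:(i + best - 1)], collapse = "_"))
        i <- i + best
      } else {
        out <- c(out, tokens[[i]])
        i <- i + 1
      }
    }
    out
  }
  set.seed(42)
  voc <- c("aa", "bb", "cc", "dd")
  for (rep in 1:25) {
    toks <- sample(voc, 8, replace = TRUE)
    seqs <- list(sample(voc, 2), sample(voc, 3))
    lex <- vapply(seqs, paste, character(1), collapse = " ")
    got <- preprocess_note(paste(toks, collapse = " "), lex)[[1]]
    expect_equal(got, greedy_oracle(toks, seqs))
  }
})

test_that("reverse substitution replaces long forms and labels them", {
  inv <- tibble::tibble(abbreviation = "ivf",
                        expansion = "intravenous fluid",
                        concept_id = NA_character_)
  docs <- preprocess_corpus(
    tibble::tibble(note_id = "n1",
                   text = "Patient was administered intravenous fluid."),
    concept_lexicon = inv$expansion)
  samp <- reverse_substitute(docs, inv)
  expect_equal(nrow(samp), 1)
  expect_equal(samp$label, "intravenous fluid")
  expect_equal(samp$document_tokens[[1]],
               c("patient", "was", "administered", "ivf"))
  expect_equal(samp$window[[1]], c("patient", "was", "administered"))
  expect_equal(samp$abbrev_positions[[1]], 4L)

  # sentences without inventory expansions contribute nothing
  docs2 <- preprocess_corpus(
    tibble::tibble(note_id = "n2", text = "No mention here."),
    concept_lexicon = inv$expansion)
  expect_equal(nrow(reverse_substitute(docs2, inv)), 0)

  # two distinct expansion occurrences yield exactly two samples
  inv2 <- dplyr::bind_rows(inv, tibble::tibble(
    abbreviation = "ra", expansion = "right atrium",
    concept_id = NA_character_))
  docs3 <- preprocess_corpus(
    tibble::tibble(note_id = "n3",
                   text = "intravenous fluid given near right atrium"),
    concept_lexicon = inv2$expansion)
  expect_equal(nrow(reverse_substitute(docs3, inv2)), 2)
})

test_that("reverse substitution conserves occurrences and leaves no residue", {
  st <- small_study()
  flat <- lapply(st$docs$sentences, function(s) unlist(s, use.names = FALSE))
  exp_tokens <- join_tok(st$inventory$expansion)
  n_occ <- sum(vapply(flat, function(f) sum(f %in% exp_tokens), numeric(1)))
  expect_equal(nrow(st$direct), n_occ)
  # round-trip: no sample document still contains its own long form
  residue <- mapply(function(doc, lab) join_tok(lab) %in% doc,
                    st$direct$document_tokens, st$direct$label)
  expect_false(any(residue))
})

test_that("inventory collisions with the abbreviation are rejected", {
  expect_error(
    validate_inventory(tibble::tibble(abbreviation = "it",
                                      expansion = "it")),
    "circular")
})

test_that("IDF follows ln(N/df) with zero for unseen tokens", {
  docs <- tibble::tibble(
    note_id = paste0("n", 1:10),
    sentences = c(
      replicate(10, list(c("always", "here")), simplify = FALSE)[1:9],
      list(list(c("always", "here", "once")))
    )
  )
  idf <- compute_idf(docs)
  expect_equal(idf_lookup(idf, "always"), 0)
  expect_equal(idf_lookup(idf, "once"), log(10), tolerance = 1e-12)
  expect_equal(idf_lookup(idf, "once"), 2.302585, tolerance = 1e-6)
  expect_equal(idf_lookup(idf, "neverseen"), 0)
  # non-increasing in document frequency
  st <- small_study()
  idf2 <- compute_idf(st$docs)
  df <- table(unlist(lapply(st$docs$sentences,
                            function(s) unique(unlist(s)))))
  ord <- order(as.numeric(df[idf2$token]))
  expect_true(all(diff(idf2$idf[ord]) <= 1e-12))
})
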