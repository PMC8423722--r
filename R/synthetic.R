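#' Synthetic ontologies, sense inventories and note corpora
#'
#' Real clinical corpora with gold abbreviation labels are access-restricted,
#' so the package ships a generator that emulates the statistical structure
#' the disambiguation pipeline depends on: multi-sense abbreviations whose
#' senses live in distinct lexical contexts, sense-specific probabilities of
#' being written out long-form (the source of reverse-substitution frequency
#' bias -- a sense that is never written out contributes no direct training
#' data), and an ontology in which the siblings of a sense's concept appear
#' in the same contexts as the sense itself, so that sampling relatives can
#' stand in for the missing sense.
#'
#' @name synthetic
NULL

# two disjoint syllable pools keep ontology-name words and context-lexicon
# words from colliding
.syll_onto <- c("ra", "ne", "lo", "ti", "mu", "sa", "ke", "di", "po", "va",
                "zu", "be", "fi", "go", "hy", "xa", "ce", "du", "ma", "ri")
.syll_lex <- c("ble", "cro", "dre", "fla", "gri", "plo", "sta", "tru", "vre",
               "klo", "mne", "pra", "sno", "twi", "bru", "gla", "pri", "sle")

make_words <- function(n, syllables, n_syll = 3) {
  out <- character(0)
  i <- 0
  while (length(out) < n) {
    i <- i + 1
    w <- paste(sample(syllables, n_syll, replace = TRUE), collapse = "")
    out <- unique(c(out, w))
    if (i > n * 200) abort("word pool exhausted")
  }
  out[seq_len(n)]
}

#' Generate a random concept ontology
#'
#' Builds a rooted tree of `n_concepts` concepts with unique multi-word
#' names. Children of the same parent share a family stem word (their names
#' begin with it), mirroring how sibling concepts in medical terminologies
#' tend to share lexical heads; this is what makes embedding-space
#' neighborhoods of a concept align with its ontological siblings.
#'
#' @param n_concepts Number of concepts (>= 1).
#' @param max_children Maximum children per node.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An [ontology()].
#' @export
generate_ontology <- function(n_concepts, max_children = 3, seed = 1) {
  assert_count(n_concepts, "n_concepts")
  assert_count(max_children, "max_children")
  with_seed(derive_seed(seed, "ontology"), {
    ids <- sprintf("C%04d", seq_len(n_concepts))
    words <- make_words(3 * n_concepts + 4, .syll_onto)
    wi <- 0
    take_word <- function() {
      wi <<- wi + 1
      words[[wi]]
    }
    stems <- setNames(rep(NA_character_, n_concepts), ids)
    names_out <- character(n_concepts)
    names_out[[1]] <- paste(take_word(), take_word())
    parent_of <- rep(NA_character_, n_concepts)
    n_children <- setNames(integer(n_concepts), ids)
    if (n_concepts > 1) {
      for (i in 2:n_concepts) {
        eligible <- ids[seq_len(i - 1)][n_children[seq_len(i - 1)] < max_children]
        p <- if (length(eligible) == 1) eligible else sample(eligible, 1)
        parent_of[[i]] <- p
        n_children[[p]] <- n_children[[p]] + 1L
        if (is.na(stems[[p]])) stems[[p]] <- take_word()
        extra <- if (runif(1) < 0.5) take_word() else
          paste(take_word(), take_word())
        names_out[[i]] <- paste(stems[[p]], extra)
      }
    }
    ontology(
      nodes = tibble(concept_id = ids, name = names_out),
      edges = tibble(
        child_id = ids[!is.na(parent_of)],
        parent_id = parent_of[!is.na(parent_of)]
      )
    )
  })
}

#' Simulate a sense inventory over an ontology
#'
#' Each abbreviation gets 2-3 senses; each sense is tied to a distinct leaf
#' concept whose parent has further children (the sense's siblings), its
#' expansion phrase is the concept's name, and it receives a private context
#' lexicon (disjoint across senses). One designated rare sense per inventory
#' has `write_out_prob = 0`: its long form never appears in generated text,
#' which is exactly the failure mode that relative sampling addresses.
#'
#' @param onto An [ontology()] with enough branching; `simulate_study()`
#'   builds a suitable one.
#' @param n_abbreviations Number of abbreviations.
#' @param senses_range Range (min, max) of senses per abbreviation.
#' @param write_out_range Range from which ordinary senses' write-out
#'   probabilities are drawn.
#' @param lexicon_size Context words per sense.
#' @param n_rare Number of rare senses (write_out_prob 0), default 1.
#' @param seed Integer seed.
#' @return A tibble of sense specifications with columns `abbreviation`,
#'   `expansion`, `concept_id`, `write_out_prob`, `lexicon` (list column).
#' @export
simulate_sense_specs <- function(onto, n_abbreviations = 10,
                                 senses_range = c(2, 3),
                                 write_out_range = c(0.4, 0.8),
                                 lexicon_size = 12, n_rare = 1, seed = 1) {
  with_seed(derive_seed(seed, "senses"), {
    # candidate sense concepts: leaves whose parent has >= 2 children
    kids <- split(onto$edges$child_id, onto$edges$parent_id)
    parents_ok <- names(kids)[vapply(kids, length, integer(1)) >= 2]
    leaves <- setdiff(onto$nodes$concept_id, onto$edges$parent_id)
    pool <- list()
    for (p in sample(parents_ok)) {
      ch <- intersect(kids[[p]], leaves)
      if (length(ch) >= 2) pool[[length(pool) + 1L]] <- sort(ch)[[1]]
    }
    pool <- unlist(pool) %||% character(0)
    n_senses <- pmin(
      pmax(senses_range[[1]],
           sample(senses_range[[1]]:senses_range[[2]], n_abbreviations,
                  replace = TRUE)),
      senses_range[[2]]
    )
    if (sum(n_senses) > length(pool)) {
      abort(sprintf(
        "ontology supports only %d senses (need %d); grow the ontology",
        length(pool), sum(n_senses)))
    }
    abbrevs <- make_abbreviations(n_abbreviations)
    lex_words <- make_words(lexicon_size * sum(n_senses), .syll_lex)
    rows <- list()
    k <- 0
    for (a in seq_len(n_abbreviations)) {
      for (s in seq_len(n_senses[[a]])) {
        k <- k + 1
        cid <- pool[[k]]
        stem <- strsplit(concept_name(onto, cid), " ")[[1]][[1]]
        lex <- c(lex_words[(k - 1) * lexicon_size + seq_len(lexicon_size - 1)],
                 stem)
        rows[[k]] <- tibble(
          abbreviation = abbrevs[[a]],
          expansion = concept_name(onto, cid),
          concept_id = cid,
          write_out_prob = runif(1, write_out_range[[1]], write_out_range[[2]]),
          lexicon = list(lex)
        )
      }
    }
    specs <- dplyr::bind_rows(rows)
    if (n_rare > 0) {
      rare_idx <- cumsum(n_senses)[seq_len(min(n_rare, n_abbreviations))]
      specs$write_out_prob[rare_idx] <- 0
    }
    validate_sense_specs(specs)
  })
}

make_abbreviations <- function(n) {
  out <- character(0)
  i <- 0
  while (length(out) < n) {
    i <- i + 1
    a <- paste(sample(letters, sample(2:3, 1), replace = TRUE), collapse = "")
    out <- unique(c(out, a))
    if (i > n * 500) abort("abbreviation pool exhausted")
  }
  out[seq_len(n)]
}

#' Validate a sense specification table
#'
#' Checks the structural invariants the generator promises: at least one
#' expansion per abbreviation, write-out probabilities in \[0, 1\], pairwise
#' distinct expansions within an abbreviation, and context lexicons of
#' distinct senses overlapping by less than `max_overlap` (Jaccard-style
#' fraction of the smaller lexicon).
#'
#' @param specs A sense-spec tibble as from [simulate_sense_specs()].
#' @param max_overlap Maximum allowed pairwise lexicon overlap fraction.
#' @return `specs`, invisibly coerced to a tibble, or an error.
#' @export
validate_sense_specs <- function(specs, max_overlap = 0.2) {
  specs <- as_tibble(specs)
  need <- c("abbreviation", "expansion", "concept_id", "write_out_prob",
            "lexicon")
  stopifnot(all(need %in% names(specs)))
  if (nrow(specs) == 0) abort("empty sense specification")
  if (any(specs$write_out_prob < 0 | specs$write_out_prob > 1)) {
    abort("write_out_prob must be in [0, 1]")
  }
  dup <- duplicated(specs[c("abbreviation", "expansion")])
  if (any(dup)) abort("expansions of one abbreviation must be distinct")
  n <- nrow(specs)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- specs$lexicon[[i]]; b <- specs$lexicon[[j]]
        ov <- length(intersect(a, b)) / min(length(a), length(b))
        if (ov >= max_overlap) {
          abort(sprintf(
            "context lexicons of senses %d and %d overlap by %.2f (>= %.2f)",
            i, j, ov, max_overlap))
        }
      }
    }
  }
  specs
}

#' @rdname simulate_sense_specs
#' @param specs A sense-spec tibble.
#' @return `specs_to_inventory()` returns the sense inventory tibble
#'   (`abbreviation`, `expansion`, `concept_id`) consumed downstream.
#' @export
specs_to_inventory <- function(specs) {
  validate_inventory(specs[c("abbreviation", "expansion", "concept_id")])
}

#' Generate a synthetic note corpus with gold labels
#'
#' Each note is about one sense: its sentences are bags of 3-10 words from
#' the sense's context lexicon. One or more sentences mention the sense,
#' rendered written-out with probability `write_out_prob` and as the bare
#' abbreviation otherwise (in which case a gold label is recorded). Sibling
#' concepts of the sense's concept also appear written out in sentences drawn
#' from the same lexicon, giving the relative-sampling strategy material.
#'
#' Gold label positions index tokens of the preprocessed document (multi-word
#' names joined to single `_` tokens), matching [preprocess_corpus()].
#'
#' @param specs A sense-spec tibble (see [simulate_sense_specs()]).
#' @param onto The [ontology()] the specs reference.
#' @param n_notes Number of notes.
#' @param seed Integer seed.
#' @param mentions_per_note How many sense mentions each note carries.
#' @param sibling_prob Probability that a note includes a written-out sibling
#'   concept sentence.
#' @param write_out_override If non-`NULL`, overrides every sense's write-out
#'   probability (0 gives a fully abbreviated, fully labeled corpus -- the
#'   shape used for held-out evaluation).
#' @param balanced If `TRUE` senses are cycled through evenly rather than
#'   drawn at random.
#' @return A list with tibbles `notes` (`note_id`, `text`) and `gold`
#'   (`note_id`, `sentence_idx`, `token_idx`, `abbreviation`, `expansion`).
#' @export
generate_corpus <- function(specs, onto, n_notes, seed = 1,
                            mentions_per_note = 2, sibling_prob = 0.6,
                            write_out_override = NULL, balanced = FALSE) {
  specs <- validate_sense_specs(specs)
  assert_count(n_notes, "n_notes")
  assert_concept(onto, specs$concept_id)
  kids <- split(onto$edges$child_id, onto$edges$parent_id)
  parent_of <- setNames(onto$edges$parent_id, onto$edges$child_id)
  sibs_of <- lapply(specs$concept_id, function(cid) {
    p <- parent_of[[cid]]
    if (is.null(p) || is.na(p)) return(character(0))
    setdiff(kids[[p]], cid)
  })
  wo <- if (is.null(write_out_override)) specs$write_out_prob else
    rep(write_out_override, nrow(specs))

  with_seed(derive_seed(seed, "corpus"), {
    notes <- vector("list", n_notes)
    gold <- vector("list", n_notes)
    for (i in seq_len(n_notes)) {
      si <- if (balanced) ((i - 1) %% nrow(specs)) + 1 else
        sample.int(nrow(specs), 1)
      lex <- specs$lexicon[[si]]
      sents <- list()      # token vectors in preprocessed (joined) space
      raw <- character(0)  # rendered sentence strings
      glab <- list()
      add_plain <- function() {
        w <- sample(lex, sample(3:10, 1), replace = TRUE)
        sents[[length(sents) + 1L]] <<- w
        raw[[length(raw) + 1L]] <<- paste(w, collapse = " ")
      }
      add_mention <- function() {
        nw <- sample(3:10, 1)
        w <- sample(lex, nw, replace = TRUE)
        pos <- sample.int(nw + 1, 1)
        written <- runif(1) < wo[[si]]
        mention_raw <- if (written) specs$expansion[[si]] else
          specs$abbreviation[[si]]
        mention_tok <- if (written) join_phrase(specs$expansion[[si]]) else
          specs$abbreviation[[si]]
        toks <- append(w, mention_tok, after = pos - 1)
        sents[[length(sents) + 1L]] <<- toks
        raw[[length(raw) + 1L]] <<-
          paste(append(w, mention_raw, after = pos - 1), collapse = " ")
        if (!written) {
          glab[[length(glab) + 1L]] <<- tibble(
            sentence_idx = length(sents), token_idx = pos,
            abbreviation = specs$abbreviation[[si]],
            expansion = specs$expansion[[si]]
          )
        }
      }
      add_sibling <- function() {
        sibs <- sibs_of[[si]]
        if (length(sibs) == 0) return(invisible())
        sib <- if (length(sibs) == 1) sibs else sample(sibs, 1)
        nm <- concept_name(onto, sib)
        nw <- sample(3:9, 1)
        w <- sample(lex, nw, replace = TRUE)
        pos <- sample.int(nw + 1, 1)
        sents[[length(sents) + 1L]] <<- append(w, join_phrase(nm),
                                               after = pos - 1)
        raw[[length(raw) + 1L]] <<-
          paste(append(w, nm, after = pos - 1), collapse = " ")
      }
      add_plain()
      for (m in seq_len(mentions_per_note)) add_mention()
      if (runif(1) < sibling_prob) add_sibling()
      if (runif(1) < sibling_prob) add_sibling()
      add_plain()
      # shuffle sentence order, remapping gold sentence indices
      ord <- sample.int(length(sents))
      remap <- match(seq_along(sents), ord)
      nid <- sprintf("note%05d", i)
      notes[[i]] <- tibble(note_id = nid,
                           text = paste0(paste(raw[ord], collapse = ". "), "."))
      if (length(glab) > 0) {
        g <- dplyr::bind_rows(glab)
        g$sentence_idx <- remap[g$sentence_idx]
        g <- dplyr::mutate(g, note_id = nid, .before = 1)
        gold[[i]] <- g
      }
    }
    list(
      notes = dplyr::bind_rows(notes),
      gold = dplyr::bind_rows(gold) %||%
        tibble(note_id = character(), sentence_idx = integer(),
               token_idx = integer(), abbreviation = character(),
               expansion = character())
    )
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper that builds a deliberately branched ontology (one
#' parent per sense, each with `siblings_per_sense + 1` children), a sense
#' inventory with one rare never-written-out sense, a training corpus, and a
#' balanced fully-abbreviated evaluation corpus.
#'
#' @param n_abbreviations,senses_range,lexicon_size,n_rare,write_out_range
#'   Passed to [simulate_sense_specs()].
#' @param siblings_per_sense Pure sibling concepts per sense (>= 1).
#' @param n_notes,n_eval_notes Training / evaluation corpus sizes.
#' @param seed Integer seed.
#' @return A list: `ontology`, `specs`, `inventory`, `corpus` (notes + gold),
#'   `eval_corpus` (notes + gold).
#' @export
simulate_study <- function(n_abbreviations = 10, senses_range = c(2, 3),
                           siblings_per_sense = 2, lexicon_size = 12,
                           n_rare = 1, write_out_range = c(0.4, 0.8),
                           n_notes = 400, n_eval_notes = 120, seed = 1) {
  onto <- build_study_ontology(
    n_slots = n_abbreviations * senses_range[[2]],
    siblings_per_sense = siblings_per_sense,
    seed = derive_seed(seed, "study-onto")
  )
  specs <- simulate_sense_specs(
    onto, n_abbreviations = n_abbreviations, senses_range = senses_range,
    write_out_range = write_out_range, lexicon_size = lexicon_size,
    n_rare = n_rare, seed = derive_seed(seed, "study-senses")
  )
  corpus <- generate_corpus(specs, onto, n_notes = n_notes,
                            seed = derive_seed(seed, "study-corpus"))
  eval_corpus <- generate_corpus(
    specs, onto, n_notes = n_eval_notes,
    seed = derive_seed(seed, "study-eval"),
    mentions_per_note = 1, write_out_override = 0, balanced = TRUE
  )
  list(ontology = onto, specs = specs,
       inventory = specs_to_inventory(specs),
       corpus = corpus, eval_corpus = eval_corpus)
}

# Root -> one parent per sense slot -> (1 sense leaf + siblings) per parent.
build_study_ontology <- function(n_slots, siblings_per_sense = 2, seed = 1) {
  with_seed(derive_seed(seed, "study-tree"), {
    per <- siblings_per_sense + 1
    n <- 1 + n_slots + n_slots * per
    ids <- sprintf("C%04d", seq_len(n))
    words <- make_words(2 + n_slots + n_slots * per * 2, .syll_onto)
    wi <- 0
    take_word <- function() {
      wi <<- wi + 1
      words[[wi]]
    }
    names_out <- character(n)
    child <- character(0); parent <- character(0)
    names_out[[1]] <- paste(take_word(), take_word())
    k <- 1
    for (s in seq_len(n_slots)) {
      k <- k + 1
      pid <- ids[[k]]
      stem <- take_word()
      names_out[[k]] <- paste(stem, take_word())
      child <- c(child, pid); parent <- c(parent, ids[[1]])
      for (j in seq_len(per)) {
        k <- k + 1
        names_out[[k]] <- paste(stem, take_word())
        child <- c(child, ids[[k]]); parent <- c(parent, pid)
      }
    }
    ontology(nodes = tibble(concept_id = ids, name = names_out),
             edges = tibble(child_id = child, parent_id = parent))
  })
}

#' Write / read synthetic corpora
#'
#' Notes are serialized as JSON-lines (`{"note_id": ..., "text": ...}` per
#' line); gold labels as TSV.
#'
#' @param corpus A list with `notes` and `gold` tibbles, as returned by
#'   [generate_corpus()].
#' @param notes_file,gold_file Output paths.
#' @export
write_corpus <- function(corpus, notes_file, gold_file = NULL) {
  lines <- vapply(seq_len(nrow(corpus$notes)), function(i) {
    jsonlite::toJSON(list(note_id = corpus$notes$note_id[[i]],
                          text = corpus$notes$text[[i]]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, notes_file)
  if (!is.null(gold_file)) {
    readr::write_tsv(corpus$gold, gold_file, progress = FALSE)
  }
  invisible(corpus)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(notes_file, gold_file = NULL) {
  recs <- lapply(readLines(notes_file), jsonlite::fromJSON)
  notes <- tibble(
    note_id = vapply(recs, function(r) as.character(r$note_id), character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1))
  )
  gold <- if (!is.null(gold_file)) {
    readr::read_tsv(gold_file, col_types = "ciicc", progress = FALSE)
  }
  list(notes = notes, gold = gold)
}
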