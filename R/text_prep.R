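#' Tokenization and note preprocessing
#'
#' Notes are lowercased, split into sentences at terminal punctuation
#' (`.?!;`) or newlines, and split into tokens on any run of characters that
#' is not alphanumeric or `_`. Multi-word concept names from `concept_lexicon`
#' are then replaced by a single `_`-joined token using a left-to-right,
#' longest-match-first scan, so that e.g. "in vitro fertilization" becomes the
#' single token `in_vitro_fertilization` wherever it occurs.
#'
#' @param text A single character string (one note).
#' @param concept_lexicon Character vector of multi-word names to join
#'   (single-word entries are allowed and left as-is).
#' @return A list of character vectors, one per sentence. Empty text yields an
#'   empty list.
#' @examples
#' preprocess_note(
#'   "Scheduled for in vitro fertilization.",
#'   concept_lexicon = "in vitro fertilization"
#' )
#' @export
preprocess_note <- function(text, concept_lexicon = character()) {
  sents <- tokenize_string(text)
  if (length(concept_lexicon) == 0) return(sents)
  lex <- build_join_index(concept_lexicon)
  lapply(sents, join_concepts, lex = lex)
}

# Lowercase, sentence-split, tokenize. Returns list of token vectors.
tokenize_string <- function(text) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) return(list())
  text <- tolower(text)
  sents <- strsplit(text, "[.?!;\n]+")[[1]]
  toks <- lapply(sents, function(s) {
    t <- strsplit(s, "[^a-z0-9_]+")[[1]]
    t[nzchar(t)]
  })
  toks[vapply(toks, length, integer(1)) > 0]
}

# Index multi-word names by first token; per first token, candidate token
# sequences sorted longest first so the scan is longest-match.
build_join_index <- function(concept_lexicon) {
  seqs <- lapply(unique(concept_lexicon), function(nm) {
    s <- tokenize_string(nm)
    if (length(s) == 0) NULL else s[[1]]
  })
  seqs <- Filter(function(s) length(s) >= 2, seqs)
  if (length(seqs) == 0) return(list())
  first <- vapply(seqs, `[[`, character(1), 1)
  idx <- split(seqs, first)
  lapply(idx, function(cands) cands[order(-vapply(cands, length, integer(1)))])
}

join_concepts <- function(tokens, lex) {
  if (length(lex) == 0 || length(tokens) == 0) return(tokens)
  out <- character(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    cands <- lex[[tokens[[i]]]]
    matched <- FALSE
    if (!is.null(cands)) {
      for (cand in cands) {
        k <- length(cand)
        if (i + k - 1L <= n && identical(tokens[i:(i + k - 1L)], cand)) {
          out <- c(out, paste(cand, collapse = "_"))
          i <- i + k
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) {
      out <- c(out, tokens[[i]])
      i <- i + 1L
    }
  }
  out
}

#' Preprocess a corpus of notes
#'
#' @param corpus A data frame with columns `note_id` and `text`.
#' @param concept_lexicon Character vector of multi-word concept names to join
#'   into single `_` tokens (usually the ontology's names plus the inventory's
#'   expansions).
#' @return A tibble with columns `note_id` and `sentences` (a list column of
#'   token vectors).
#' @export
preprocess_corpus <- function(corpus, concept_lexicon = character()) {
  stopifnot(all(c("note_id", "text") %in% names(corpus)))
  lex <- build_join_index(concept_lexicon)
  tibble(
    note_id = as.character(corpus$note_id),
    sentences = lapply(corpus$text, function(tx) {
      lapply(tokenize_string(tx), join_concepts, lex = lex)
    })
  )
}

doc_tokens <- function(sentences) {
  unlist(sentences, use.names = FALSE) %||% character()
}

#' Read and validate a sense inventory
#'
#' The sense inventory maps each abbreviation to its candidate expansions and
#' (optionally) ontology concept ids. Expansions equal to their own
#' abbreviation are rejected: reverse substitution would be circular for them.
#'
#' @param path A TSV file with columns `abbreviation`, `expansion`,
#'   `concept_id` (the last may be empty).
#' @return A tibble with those columns (`concept_id` is `NA` when absent).
#' @export
read_inventory <- function(path) {
  inv <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  validate_inventory(inv)
}

#' @param inventory A data frame with columns `abbreviation`, `expansion` and
#'   optionally `concept_id`.
#' @rdname read_inventory
#' @export
validate_inventory <- function(inventory) {
  inventory <- as_tibble(inventory)
  stopifnot(all(c("abbreviation", "expansion") %in% names(inventory)))
  if (!"concept_id" %in% names(inventory)) inventory$concept_id <- NA_character_
  inventory$abbreviation <- tolower(as.character(inventory$abbreviation))
  inventory$expansion <- tolower(as.character(inventory$expansion))
  clash <- inventory$abbreviation == join_phrase(inventory$expansion) |
    inventory$abbreviation == inventory$expansion
  if (any(clash)) {
    abort(paste0(
      "expansion identical to its abbreviation (circular under reverse ",
      "substitution): ",
      paste(unique(inventory$abbreviation[clash]), collapse = ", ")
    ))
  }
  dup <- duplicated(inventory[c("abbreviation", "expansion")])
  if (any(dup)) abort("duplicate (abbreviation, expansion) pairs in inventory")
  inventory
}

#' Generate labeled training samples by reverse substitution
#'
#' Scans preprocessed documents for occurrences of inventory expansions (in
#' their `_`-joined single-token form) and emits one labeled sample per
#' occurrence: the written-out expansion is replaced by its abbreviation, the
#' replaced expansion becomes the label, and the tokens around the occurrence
#' (up to `window_size` on each side within the sentence, target excluded)
#' become the local context window. Occurrences of the bare abbreviation
#' itself are not labeled -- their sense is unknown.
#'
#' @param docs A preprocessed corpus from [preprocess_corpus()]. The concept
#'   lexicon used there must include the inventory expansions so they appear
#'   as single tokens.
#' @param inventory A sense inventory (see [read_inventory()]).
#' @param window_size Tokens kept on each side of the target (default 3).
#' @return A tibble of labeled samples with columns `note_id`, `abbreviation`,
#'   `label`, `window` (list), `document_tokens` (list), `abbrev_positions`
#'   (list of integer indices into `document_tokens`), `provenance` ("direct").
#' @export
reverse_substitute <- function(docs, inventory, window_size = 3) {
  assert_count(window_size, "window_size")
  inventory <- validate_inventory(inventory)
  exp_token <- join_phrase(inventory$expansion)
  tok_map <- setNames(seq_len(nrow(inventory)), exp_token)

  rows <- list()
  for (d in seq_len(nrow(docs))) {
    sents <- docs$sentences[[d]]
    flat <- doc_tokens(sents)
    hits_doc <- which(flat %in% exp_token)
    if (length(hits_doc) == 0) next
    offsets <- cumsum(c(0L, vapply(sents, length, integer(1))))
    for (s in seq_along(sents)) {
      toks <- sents[[s]]
      hits <- which(toks %in% exp_token)
      for (h in hits) {
        inv_row <- inventory[tok_map[[toks[[h]]]], ]
        # replace every occurrence of this expansion in the document
        same <- which(flat == toks[[h]])
        doc2 <- flat
        doc2[same] <- inv_row$abbreviation
        win <- toks[setdiff(
          max(1L, h - window_size):min(length(toks), h + window_size), h)]
        rows[[length(rows) + 1L]] <- tibble(
          note_id = docs$note_id[[d]],
          abbreviation = inv_row$abbreviation,
          label = inv_row$expansion,
          window = list(win),
          document_tokens = list(doc2),
          abbrev_positions = list(as.integer(same)),
          provenance = "direct",
          relative_concept = NA_character_,
          relative_distance = NA_real_
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      note_id = character(), abbreviation = character(), label = character(),
      window = list(), document_tokens = list(), abbrev_positions = list(),
      provenance = character(), relative_concept = character(),
      relative_distance = numeric()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Inverse document frequency table
#'
#' IDF weights are `log(N / df)` with `N` the number of documents and `df` the
#' number of documents containing the token (natural log, no smoothing).
#' Tokens never seen get weight 0 at lookup time.
#'
#' @param docs A preprocessed corpus from [preprocess_corpus()].
#' @return A tibble with columns `token` and `idf`, carrying the corpus
#'   document count as attribute `n_docs`.
#' @export
compute_idf <- function(docs) {
  if (nrow(docs) == 0) abort("need at least one document")
  n <- nrow(docs)
  df <- table(unlist(lapply(docs$sentences, function(s) unique(doc_tokens(s))),
                     use.names = FALSE))
  out <- tibble(token = names(df), idf = log(n / as.numeric(df)))
  attr(out, "n_docs") <- n
  out
}

#' @param idf An IDF table from [compute_idf()].
#' @param tokens Character vector of tokens.
#' @rdname compute_idf
#' @return `idf_lookup()` returns a numeric vector of weights (0 for unseen
#'   tokens).
#' @export
idf_lookup <- function(idf, tokens) {
  w <- setNames(idf$idf, idf$token)[tokens]
  w[is.na(w)] <- 0
  unname(w)
}

#' @rdname compute_idf
#' @param path File path for the TSV serialization.
#' @export
write_idf <- function(idf, path) {
  readr::write_tsv(idf, path, progress = FALSE)
  invisible(idf)
}

#' @rdname compute_idf
#' @export
read_idf <- function(path) {
  out <- readr::read_tsv(path, col_types = "cd", progress = FALSE)
  attr(out, "n_docs") <- NA_integer_
  out
}
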