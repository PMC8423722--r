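#' Embed an ontology concept
#'
#' A concept's vector is the embedding of its `_`-joined name token. When the
#' joined name never occurred in the training corpus the space's fallback
#' applies (subword composition, then mean of known constituent words, then
#' zero).
#'
#' @param onto An [ontology()].
#' @param space An [embedding_space()].
#' @param concept A concept id (or vector of ids).
#' @return A `length(concept) x dim` matrix of concept vectors.
#' @export
concept_vector <- function(onto, space, concept) {
  assert_concept(onto, concept)
  toks <- join_phrase(concept_name(onto, concept))
  v <- embedding_lookup(space, toks)
  rownames(v) <- concept
  v
}

#' Nearest ontology relatives of an expansion
#'
#' Ranks concepts by Euclidean distance between the expansion phrase's vector
#' and each concept's vector, returning the `k` nearest (the expansion's own
#' concept, when known, is excluded from these `k`). If the expansion itself
#' occurs in the corpus it is additionally listed as its own relative at the
#' pseudo-distance `epsilon`, so that real sentences of the expansion
#' dominate sampling whenever they exist. Distance ties break by concept id.
#'
#' @param expansion The expansion phrase.
#' @param onto An [ontology()].
#' @param space An [embedding_space()].
#' @param k Number of relatives (default 10).
#' @param epsilon Self pseudo-distance (default 0.001).
#' @param corpus_count Number of corpus occurrences of the expansion's long
#'   form; the self entry is added only when positive.
#' @param own_concept The expansion's own concept id, or `NA`.
#' @return A tibble (`concept_id`, `name`, `distance`, `is_self`) ordered by
#'   distance, carrying the expansion as attribute `expansion`.
#' @export
nearest_relatives <- function(expansion, onto, space, k = 10,
                              epsilon = 0.001, corpus_count = 0,
                              own_concept = NA_character_) {
  assert_count(k, "k")
  if (!is.numeric(epsilon) || epsilon <= 0) abort("`epsilon` must be > 0")
  if (nrow(onto$nodes) == 0) abort("empty ontology")
  target <- embedding_lookup(space, join_phrase(expansion))[1, ]
  cand <- concept_ids(onto)
  if (!is.na(own_concept)) cand <- setdiff(cand, own_concept)
  cv <- concept_vector(onto, space, cand)
  d <- sqrt(rowSums(sweep(cv, 2, target)^2))
  ord <- order(d, cand)
  keep <- ord[seq_len(min(k, length(cand)))]
  out <- tibble(
    concept_id = cand[keep],
    name = concept_name(onto, cand[keep]),
    distance = unname(d[keep]),
    is_self = FALSE
  )
  if (corpus_count > 0) {
    self_id <- if (!is.na(own_concept)) own_concept else
      paste0("self:", join_phrase(expansion))
    self_nm <- if (!is.na(own_concept)) concept_name(onto, own_concept) else
      expansion
    out <- dplyr::bind_rows(
      tibble(concept_id = self_id, name = self_nm, distance = epsilon,
             is_self = TRUE),
      out
    )
    out <- out[order(out$distance, out$concept_id), ]
  }
  attr(out, "expansion") <- expansion
  out
}

#' Relative sets for every expansion of an abbreviation
#'
#' @param abbreviation The abbreviation token.
#' @param inventory A sense inventory.
#' @param docs A preprocessed corpus (used to count long-form occurrences).
#' @inheritParams nearest_relatives
#' @return A named list of relative tibbles, one per expansion.
#' @export
relatives_for_abbreviation <- function(abbreviation, inventory, onto, space,
                                       docs, k = 10, epsilon = 0.001) {
  inventory <- validate_inventory(inventory)
  rows <- inventory[inventory$abbreviation == abbreviation, ]
  if (nrow(rows) == 0) abort(paste0("abbreviation not in inventory: ",
                                    abbreviation))
  flat <- unlist(lapply(docs$sentences, doc_tokens), use.names = FALSE)
  counts <- table(flat)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    tok <- join_phrase(rows$expansion[[i]])
    cnt <- if (tok %in% names(counts)) as.integer(counts[[tok]]) else 0L
    nearest_relatives(rows$expansion[[i]], onto, space, k = k,
                      epsilon = epsilon, corpus_count = cnt,
                      own_concept = rows$concept_id[[i]])
  })
  setNames(out, rows$expansion)
}

#' Select the concept set for hierarchical pretraining
#'
#' For an abbreviation, takes every expansion's own concept together with all
#' concepts within Euclidean distance `delta` of the expansion's vector
#' (union over expansions), then closes the set upward: the lowest common
#' ancestor of the set and every ancestor on the paths up to it are added, so
#' the pretraining sub-ontology is rooted.
#'
#' @param abbreviation The abbreviation token.
#' @param inventory A sense inventory containing the abbreviation.
#' @param onto An [ontology()].
#' @param space An [embedding_space()].
#' @param delta Neighborhood radius (default 2.6).
#' @return Character vector of concept ids (sorted).
#' @export
select_pretraining_concepts <- function(abbreviation, inventory, onto, space,
                                        delta = 2.6) {
  if (!is.numeric(delta) || delta < 0) abort("`delta` must be >= 0")
  inventory <- validate_inventory(inventory)
  rows <- inventory[inventory$abbreviation == abbreviation, ]
  if (nrow(rows) == 0) abort(paste0("abbreviation not in inventory: ",
                                    abbreviation))
  cand <- concept_ids(onto)
  cv <- concept_vector(onto, space, cand)
  sel <- character(0)
  for (i in seq_len(nrow(rows))) {
    target <- embedding_lookup(space, join_phrase(rows$expansion[[i]]))[1, ]
    d <- sqrt(rowSums(sweep(cv, 2, target)^2))
    sel <- union(sel, cand[d <= delta])
    if (!is.na(rows$concept_id[[i]])) sel <- union(sel, rows$concept_id[[i]])
  }
  if (length(sel) == 0) abort("no concepts selected; is the inventory linked?")
  lca <- lowest_common_ancestor(onto, sel)
  up <- character(0)
  for (cc in sel) {
    anc <- ancestors(onto, cc)
    on_path <- anc[vapply(anc, function(a) {
      a == lca || lca %in% ancestors(onto, a)
    }, logical(1))]
    up <- union(up, on_path)
  }
  sort(union(union(sel, up), lca))
}
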