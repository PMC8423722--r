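#' Construct a concept ontology
#'
#' An ontology is a rooted directed acyclic graph of medical concepts: each
#' concept has a unique identifier, a (typically multi-word) name, and zero or
#' more parents. It abstracts hierarchical terminologies such as the UMLS
#' Metathesaurus; any rooted DAG given as a parent edge list works.
#'
#' @param nodes A data frame with columns `concept_id` and `name`.
#' @param edges A data frame with columns `child_id` and `parent_id`. May have
#'   zero rows for a single-concept ontology.
#' @return An object of class `abbrev_ontology`: a list with tibbles `nodes`
#'   and `edges` plus a precomputed parent map.
#' @examples
#' onto <- ontology(
#'   nodes = tibble::tibble(
#'     concept_id = c("C1", "C2", "C3"),
#'     name = c("body fluid", "intravenous fluid", "amniotic fluid")
#'   ),
#'   edges = tibble::tibble(child_id = c("C2", "C3"), parent_id = c("C1", "C1"))
#' )
#' ancestors(onto, "C2")
#' @export
ontology <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot(all(c("concept_id", "name") %in% names(nodes)))
  if (nrow(edges) > 0) {
    stopifnot(all(c("child_id", "parent_id") %in% names(edges)))
  } else {
    edges <- tibble(child_id = character(), parent_id = character())
  }
  nodes$concept_id <- as.character(nodes$concept_id)
  nodes$name <- as.character(nodes$name)
  if (anyDuplicated(nodes$concept_id)) abort("duplicate concept ids")
  unknown <- setdiff(c(edges$child_id, edges$parent_id), nodes$concept_id)
  if (length(unknown) > 0) {
    abort(paste0("edge references unknown concept(s): ",
                 paste(unknown, collapse = ", ")))
  }
  parents <- split(as.character(edges$parent_id), as.character(edges$child_id))
  obj <- structure(
    list(nodes = nodes, edges = edges, parents = parents),
    class = "abbrev_ontology"
  )
  check_acyclic(obj)
  obj
}

#' @export
print.abbrev_ontology <- function(x, ...) {
  cat(sprintf("<abbrev_ontology: %d concepts, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

check_acyclic <- function(onto) {
  state <- setNames(integer(length(onto$nodes$concept_id)),
                    onto$nodes$concept_id)
  visit <- function(id) {
    if (state[[id]] == 1L) abort("parent links contain a cycle")
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    for (p in onto$parents[[id]] %||% character()) visit(p)
    state[[id]] <<- 2L
    invisible()
  }
  for (id in onto$nodes$concept_id) visit(id)
  invisible(onto)
}

concept_ids <- function(onto) onto$nodes$concept_id

concept_name <- function(onto, ids) {
  nm <- setNames(onto$nodes$name, onto$nodes$concept_id)
  unname(nm[ids])
}

assert_concept <- function(onto, concept) {
  missing <- setdiff(concept, onto$nodes$concept_id)
  if (length(missing) > 0) {
    abort(paste0("unknown concept id(s): ", paste(missing, collapse = ", ")))
  }
  invisible(concept)
}

#' Ancestors of a concept
#'
#' Transitive closure over parent links. Each ancestor is reported once even
#' when reachable along several paths (set semantics, DAG-safe); the concept
#' itself is excluded.
#'
#' @param onto An [ontology()].
#' @param concept A concept id present in the ontology.
#' @return Character vector of ancestor concept ids (possibly empty), sorted.
#' @export
ancestors <- function(onto, concept) {
  assert_concept(onto, concept)
  seen <- character()
  frontier <- onto$parents[[concept]] %||% character()
  while (length(frontier) > 0) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- unlist(lapply(frontier, function(p) onto$parents[[p]]),
                       use.names = FALSE)
    if (is.null(frontier)) frontier <- character()
  }
  sort(seen)
}

# Depth = number of distinct ancestors; equals path length to the root in a
# tree and gives a deterministic depth notion on DAGs.
concept_depth <- function(onto, concept) {
  length(ancestors(onto, concept))
}

#' Lowest common ancestor of a set of concepts
#'
#' The common ancestor (a concept counts as an ancestor of itself here) with
#' the greatest depth; depth is the size of a concept's ancestor set. Ties are
#' broken by lexicographic concept id so the result is deterministic.
#'
#' @param onto An [ontology()].
#' @param concepts Character vector of concept ids.
#' @return A single concept id.
#' @export
lowest_common_ancestor <- function(onto, concepts) {
  assert_concept(onto, concepts)
  concepts <- unique(concepts)
  if (length(concepts) == 1) return(concepts)
  common <- Reduce(intersect, lapply(concepts, function(cc) {
    c(cc, ancestors(onto, cc))
  }))
  if (length(common) == 0) abort("concepts share no common ancestor")
  depths <- vapply(common, function(cc) concept_depth(onto, cc), numeric(1))
  cands <- sort(common[depths == max(depths)])
  cands[[1]]
}

# Sparse ancestor-closure matrix over `ids`: M[i, j] = 1 iff ids[j] is ids[i]
# or one of its ancestors. Used to turn raw hierarchy embeddings into
# effective (ancestor-sum) embeddings with one sparse product.
ancestor_matrix <- function(onto, ids) {
  assert_concept(onto, ids)
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    anc <- intersect(c(ids[[i]], ancestors(onto, ids[[i]])), ids)
    ii <- c(ii, rep(i, length(anc)))
    jj <- c(jj, idx[anc])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n),
                       dimnames = list(ids, ids))
}

#' Read / write an ontology as TSV edge and name lists
#'
#' `read_ontology()` expects a names file with columns `concept_id`, `name`
#' and an edges file with columns `child_id`, `parent_id`.
#'
#' @param nodes_file,edges_file Paths to tab-separated files.
#' @return An [ontology()].
#' @export
read_ontology <- function(nodes_file, edges_file) {
  nodes <- readr::read_tsv(nodes_file, col_types = "cc", progress = FALSE)
  edges <- readr::read_tsv(edges_file, col_types = "cc", progress = FALSE)
  ontology(nodes, edges)
}

#' @param onto An [ontology()].
#' @rdname read_ontology
#' @export
write_ontology <- function(onto, nodes_file, edges_file) {
  readr::write_tsv(onto$nodes, nodes_file, progress = FALSE)
  readr::write_tsv(onto$edges, edges_file, progress = FALSE)
  invisible(onto)
}
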