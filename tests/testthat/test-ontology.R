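test_that("ancestor sets use transitive closure with set semantics", {
  chain <- chain_ontology(c("a", "b", "c"))
  expect_equal(ancestors(chain, "a"), character(0))
  expect_equal(ancestors(chain, "c"), c("a", "b"))

  # diamond: two parents sharing a grandparent, counted once
  diamond <- ontology(
    nodes = tibble::tibble(concept_id = c("g", "p1", "p2", "x"),
                           name = paste("name", 1:4)),
    edges = tibble::tibble(child_id = c("p1", "p2", "x", "x"),
                           parent_id = c("g", "g", "p1", "p2"))
  )
  expect_equal(ancestors(diamond, "x"), c("g", "p1", "p2"))
  expect_error(ancestors(chain, "zz"), "unknown concept")
  # cycles are rejected at construction
  expect_error(ontology(
    nodes = tibble::tibble(concept_id = c("a", "b"), name = c("x", "y")),
    edges = tibble::tibble(child_id = c("a", "b"), parent_id = c("b", "a"))
  ), "cycle")
})

test_that("ancestor count equals depth in generated trees", {
  onto <- generate_ontology(40, max_children = 3, seed = 9)
  depth_oracle <- function(id) {
    d <- 0
    while (!is.null(onto$parents[[id]])) {
      id <- onto$parents[[id]][[1]]
      d <- d + 1
    }
    d
  }
  for (id in onto$nodes$concept_id) {
    expect_length(ancestors(onto, id), depth_oracle(id))
  }
})

test_that("lowest common ancestor matches a brute-force oracle", {
  chain <- chain_ontology(c("a", "b", "c"))
  expect_equal(lowest_common_ancestor(chain, "c"), "c")  # idempotent
  sib <- build_study_ontology_fixture(n_slots = 3)
  kids <- split(sib$edges$child_id, sib$edges$parent_id)
  some_parent <- setdiff(names(kids), sib$nodes$concept_id[[1]])[[1]]
  expect_equal(lowest_common_ancestor(sib, kids[[some_parent]][1:2]),
               some_parent)
  # a set containing an ancestor of all others reduces to that ancestor
  expect_equal(lowest_common_ancestor(chain, c("a", "b", "c")), "a")

  # random trees vs. intersection-of-ancestor-sets with max depth
  lca_oracle <- function(onto, ids) {
    sets <- lapply(ids, function(i) c(i, ancestors(onto, i)))
    common <- Reduce(intersect, sets)
    depths <- vapply(common, function(cc) length(ancestors(onto, cc)),
                     numeric(1))
    sort(common[depths == max(depths)])[[1]]
  }
  set.seed(31)
  for (rep in 1:10) {
    onto <- generate_ontology(25, max_children = 3, seed = rep)
    ids <- sample(onto$nodes$concept_id, sample(2:4, 1))
    expect_equal(lowest_common_ancestor(onto, ids), lca_oracle(onto, ids))
  }
})

test_that("concept vectors come from joined names with fallback", {
  onto <- ontology(
    nodes = tibble::tibble(concept_id = c("c1", "c2"),
                           name = c("renal fluid", "novel thing")),
    edges = tibble::tibble(child_id = "c2", parent_id = "c1"))
  M <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("renal_fluid", "novel", "thing"), NULL))
  sp <- embedding_space(M)
  expect_equal(concept_vector(onto, sp, "c1")[1, ], M["renal_fluid", ])
  # unseen joined name: mean of known constituent words
  expect_equal(concept_vector(onto, sp, "c2")[1, ],
               colMeans(M[c("novel", "thing"), ]))
  expect_error(concept_vector(onto, sp, "c9"), "unknown concept")
})

test_that("nearest relatives agree with exhaustive distance sorting", {
  # planted 2-D geometry: distances exactly 1, 2, 3 from the origin
  onto <- ontology(
    nodes = tibble::tibble(concept_id = c("near", "mid", "far"),
                           name = c("tok one", "tok two", "tok three")),
    edges = tibble::tibble(child_id = c("mid", "far"),
                           parent_id = c("near", "near")))
  M <- rbind(tok_one = c(1, 0), tok_two = c(0, 2), tok_three = c(3, 0),
             query = c(0, 0))
  sp <- embedding_space(M)
  rel <- nearest_relatives("query", onto, sp, k = 2)
  expect_equal(rel$concept_id, c("near", "mid"))
  expect_equal(rel$distance, c(1, 2))

  # k >= |concepts| returns everything
  expect_equal(nrow(nearest_relatives("query", onto, sp, k = 10)), 3)

  # the epsilon self-entry appears when the expansion is in the corpus
  rel2 <- nearest_relatives("query", onto, sp, k = 2, epsilon = 0.001,
                            corpus_count = 5, own_concept = "far")
  expect_true(any(rel2$is_self))
  expect_equal(rel2$distance[rel2$is_self], 0.001)
  expect_false("far" %in% rel2$concept_id[!rel2$is_self])

  # oracle equivalence on a larger random instance
  st <- small_study()
  onto_big <- st$ontology
  expn <- st$inventory$expansion[[1]]
  rel3 <- nearest_relatives(expn, onto_big, st$space, k = 10,
                            own_concept = st$inventory$concept_id[[1]])
  target <- embedding_lookup(st$space, join_tok(expn))[1, ]
  cand <- setdiff(onto_big$nodes$concept_id, st$inventory$concept_id[[1]])
  d <- vapply(cand, function(cc) {
    sqrt(sum((concept_vector(onto_big, st$space, cc)[1, ] - target)^2))
  }, numeric(1))
  oracle <- cand[order(d, cand)][1:10]
  expect_equal(rel3$concept_id, oracle)
  expect_true(all(diff(rel3$distance) >= -1e-12))
})

test_that("pretraining concept selection honors the delta neighborhood", {
  st <- small_study()
  inv <- st$inventory
  a <- inv$abbreviation[[1]]
  # delta = 0: own concepts plus the ancestor path to their LCA
  sel0 <- select_pretraining_concepts(a, inv, st$ontology, st$space,
                                      delta = 0)
  own <- inv$concept_id[inv$abbreviation == a]
  lca <- lowest_common_ancestor(st$ontology, own)
  expect_true(all(own %in% sel0))
  expect_true(lca %in% sel0)

  # enormous delta captures the whole ontology
  sel_all <- select_pretraining_concepts(a, inv, st$ontology, st$space,
                                         delta = 1e6)
  expect_setequal(sel_all, st$ontology$nodes$concept_id)

  # brute-force check of the within-delta set
  delta <- 1.0
  sel <- select_pretraining_concepts(a, inv, st$ontology, st$space,
                                     delta = delta)
  for (i in which(inv$abbreviation == a)) {
    target <- embedding_lookup(st$space, join_tok(inv$expansion[[i]]))[1, ]
    for (cc in st$ontology$nodes$concept_id) {
      d <- sqrt(sum((concept_vector(st$ontology, st$space, cc)[1, ] -
                       target)^2))
      if (d <= delta) expect_true(cc %in% sel)
    }
  }
})
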