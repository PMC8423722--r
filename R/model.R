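#' Effective concept embedding under the ancestor-sum rule
#'
#' During hierarchical pretraining each concept `c` has a raw embedding row
#' `H'_c`; its effective classifier embedding is
#' `H_c = H'_c + sum over the ancestor set of c of H'_a`, each distinct
#' ancestor contributing once (DAG-safe). A concept with no raw row inherits
#' its ancestors' sum (raw part treated as zero).
#'
#' @param hier A hierarchy-embedding object as returned by
#'   [pretrain_hierarchy()]: a list with `H_raw` (matrix, rownames = concept
#'   ids) and `ontology`.
#' @param concept A concept id.
#' @return A numeric vector (the embedding).
#' @export
effective_concept_embedding <- function(hier, concept) {
  assert_concept(hier$ontology, concept)
  rows <- rownames(hier$H_raw)
  anc <- intersect(ancestors(hier$ontology, concept), rows)
  has_raw <- concept %in% rows
  if (!has_raw && length(anc) == 0) {
    abort(paste0("concept has neither a raw embedding nor ancestors in the ",
                 "hierarchy: ", concept))
  }
  out <- if (has_raw) hier$H_raw[concept, ] else rep(0, ncol(hier$H_raw))
  if (length(anc) > 0) {
    out <- out + colSums(hier$H_raw[anc, , drop = FALSE])
  }
  unname(out)
}

# Occurrence-level samples for the concept-prediction pretraining task: each
# occurrence of a concept's joined name yields one sample; the concept token
# is excluded from both the window and the global-context average.
concept_occurrence_samples <- function(docs, concepts, onto, window_size = 3,
                                       max_per_concept = 1000, seed = 1) {
  names_tok <- join_phrase(concept_name(onto, concepts))
  tok2cid <- setNames(concepts, names_tok)
  rows <- list()
  for (d in seq_len(nrow(docs))) {
    sents <- docs$sentences[[d]]
    flat <- doc_tokens(sents)
    if (!any(flat %in% names_tok)) next
    off <- cumsum(c(0L, vapply(sents, length, integer(1))))
    for (s in seq_along(sents)) {
      toks <- sents[[s]]
      for (h in which(toks %in% names_tok)) {
        win <- toks[setdiff(
          max(1L, h - window_size):min(length(toks), h + window_size), h)]
        rows[[length(rows) + 1L]] <- tibble(
          note_id = docs$note_id[[d]],
          label = tok2cid[[toks[[h]]]],
          window = list(win),
          document_tokens = list(flat),
          abbrev_positions = list(off[[s]] + h)
        )
      }
    }
  }
  if (length(rows) == 0) abort("no corpus occurrences for any concept")
  out <- dplyr::bind_rows(rows)
  with_seed(derive_seed(seed, "pretrain-cap"), {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$label), function(ix) {
      if (length(ix) <= max_per_concept) ix else sample(ix, max_per_concept)
    }), use.names = FALSE)
    out[sort(keep), ]
  })
}

#' Pretrain the encoder on ontology concept prediction
#'
#' Trains the same encoder architecture as the abbreviation model on the task
#' of predicting which ontology concept is mentioned given its context, with
#' classifier rows tied through the ancestor-sum rule: the effective
#' embedding of each class is its raw row plus its ancestors' raw rows, and
#' gradients flow to the concept's raw row and to each ancestor's raw row by
#' the same amount. Concepts absent from all training sentences thereby still
#' receive meaningful embeddings through inheritance.
#'
#' @param docs A preprocessed corpus.
#' @param concepts Concept ids to pretrain over (e.g. from
#'   [select_pretraining_concepts()]); ancestors are added as raw rows
#'   automatically.
#' @param onto An [ontology()].
#' @param space An [embedding_space()].
#' @param idf An IDF table.
#' @param config Training configuration; see [default_train_config()].
#'   Pretraining defaults follow the study protocol: learning rate 0.002,
#'   batch size 2048, local window of 3, global context on, 1000 samples per
#'   concept, 90/10 train/validation split.
#' @return A list with `params` (encoder weights), `hier` (`H_raw` +
#'   `ontology`, consumable by [effective_concept_embedding()]), `classes`,
#'   and `history`.
#' @export
pretrain_hierarchy <- function(docs, concepts, onto, space, idf,
                               config = default_train_config()) {
  if (length(concepts) == 0) abort("empty concept set")
  assert_concept(onto, concepts)
  cfg <- utils::modifyList(
    default_nn_config(lr = 0.002, batch_size = 2048, use_global = TRUE),
    config[intersect(names(config), c("hidden_dim", "output_dim",
                                      "use_global", "pretrain_lr",
                                      "pretrain_batch_size", "epochs",
                                      "seed", "window_size",
                                      "samples_per_concept"))]
  )
  if (!is.null(config$pretrain_lr)) cfg$lr <- config$pretrain_lr
  if (!is.null(config$pretrain_batch_size)) {
    cfg$batch_size <- config$pretrain_batch_size
  }
  samp <- concept_occurrence_samples(
    docs, concepts, onto,
    window_size = cfg$window_size %||% 3,
    max_per_concept = cfg$samples_per_concept %||% 1000,
    seed = derive_seed(cfg$seed, "pretrain-samples")
  )
  classes <- sort(unique(samp$label))
  closure <- sort(Reduce(union, lapply(classes, function(cc) {
    c(cc, ancestors(onto, cc))
  })))
  A <- ancestor_matrix(onto, closure)
  A_class <- A[classes, , drop = FALSE]
  # 90/10 split, stratified by concept
  with_seed(derive_seed(cfg$seed, "pretrain-split"), {
    val_idx <- unlist(lapply(split(seq_len(nrow(samp)), samp$label),
                             function(ix) {
      if (length(ix) < 2) return(integer(0))
      sample(ix, max(1L, floor(0.1 * length(ix))))
    }), use.names = FALSE)
  })
  tr <- samp[setdiff(seq_len(nrow(samp)), val_idx), ]
  va <- samp[val_idx, ]
  train_in <- prepare_encoder_inputs(tr, space, idf, cfg$use_global, classes)
  val_in <- if (nrow(va) > 0) {
    prepare_encoder_inputs(va, space, idf, cfg$use_global, classes)
  }
  fit <- fit_encoder(train_in, val_in, length(classes), cfg,
                     hier = list(A_class = A_class))
  H_raw <- fit$H_raw
  rownames(H_raw) <- closure
  list(
    params = fit$params,
    hier = list(H_raw = H_raw, ontology = onto),
    classes = classes,
    best_epoch = fit$best_epoch,
    validation_loss = fit$best_loss,
    history = fit$history
  )
}

#' Default training configuration
#'
#' Collects the tunable training knobs with the study-protocol defaults:
#' embedding dim 100, hidden and output dims 100, local window of 3 tokens
#' per side, 100 epochs at learning rate 0.01 (batch 64) for abbreviation
#' models, learning rate 0.002 at batch 2048 for pretraining, global context
#' enabled.
#'
#' @param ... Overrides.
#' @return A named list.
#' @export
default_train_config <- function(...) {
  cfg <- list(hidden_dim = 100, output_dim = 100, use_global = TRUE,
              window_size = 3, lr = 0.01, epochs = 100, batch_size = 64,
              pretrain_lr = 0.002, pretrain_batch_size = 2048,
              samples_per_concept = 1000, seed = 1)
  utils::modifyList(cfg, list(...))
}

#' Train a disambiguation model for one abbreviation
#'
#' Minimizes the cross-entropy of the softmax over expansion dot products on
#' the training split, records validation loss per epoch, and keeps the
#' weights of the best epoch. One model is trained per abbreviation.
#'
#' @param training_set A training set from [build_training_set()].
#' @param space An [embedding_space()].
#' @param idf An IDF table.
#' @param config See [default_train_config()].
#' @param init Optional result of [pretrain_hierarchy()]; when supplied the
#'   convolution and fully-connected weights are copied from it and expansion
#'   rows whose sense has a concept id are initialized with the hierarchy's
#'   effective embeddings.
#' @return An object of class `abbrev_model`.
#' @export
train_abbrev_model <- function(training_set, space, idf,
                               config = default_train_config(), init = NULL) {
  cfg <- utils::modifyList(default_nn_config(), config[
    intersect(names(config), c("hidden_dim", "output_dim", "use_global",
                               "lr", "epochs", "batch_size", "seed"))])
  expansions <- attr(training_set, "expansions")
  concept_ids <- attr(training_set, "concept_ids")
  if (is.null(expansions)) expansions <- sort(unique(training_set$label))
  if (length(expansions) < 2) abort("need at least two candidate expansions")
  tr <- training_set[training_set$split == "train", ]
  if (nrow(tr) == 0) abort("empty training split")
  missing_cls <- setdiff(expansions, unique(tr$label))
  if (length(missing_cls) > 0) {
    warn(paste0("expansion(s) with no training samples: ",
                paste(missing_cls, collapse = ", ")))
  }
  va <- training_set[training_set$split == "validation", ]
  train_in <- prepare_encoder_inputs(tr, space, idf, cfg$use_global,
                                     expansions)
  val_in <- if (nrow(va) > 0) {
    prepare_encoder_inputs(va, space, idf, cfg$use_global, expansions)
  }
  init_par <- NULL
  H_init <- NULL
  if (!is.null(init)) {
    init_par <- init$params
    with_seed(derive_seed(cfg$seed, "H-init"), {
      H_init <- matrix(rnorm(length(expansions) * cfg$output_dim, sd = 0.1),
                       length(expansions), cfg$output_dim)
    })
    if (!is.null(concept_ids)) {
      for (i in seq_along(expansions)) {
        cid <- concept_ids[[i]]
        if (!is.na(cid) &&
            (cid %in% rownames(init$hier$H_raw) ||
             length(intersect(ancestors(init$hier$ontology, cid),
                              rownames(init$hier$H_raw))) > 0)) {
          H_init[i, ] <- effective_concept_embedding(init$hier, cid)
        }
      }
    }
  }
  fit <- fit_encoder(train_in, val_in, length(expansions), cfg,
                     init = init_par, H_init = H_init)
  structure(
    list(
      abbreviation = attr(training_set, "abbreviation"),
      expansions = expansions,
      concept_ids = concept_ids,
      params = fit$params,
      H = fit$H,
      config = cfg,
      strategy = attr(training_set, "strategy"),
      temperature = attr(training_set, "temperature"),
      best_epoch = fit$best_epoch,
      validation_loss = fit$best_loss,
      history = fit$history
    ),
    class = "abbrev_model"
  )
}

#' @export
print.abbrev_model <- function(x, ...) {
  cat(sprintf(
    "<abbrev_model '%s': %d expansions, strategy %s, best epoch %d (loss %.4f)>\n",
    x$abbreviation, length(x$expansions), x$strategy %||% "?",
    x$best_epoch, x$validation_loss))
  invisible(x)
}

#' Predict expansions for abbreviation occurrences
#'
#' Runs the full pipeline (local encoding, global context, fused embedding,
#' softmax classification) and labels each occurrence with the expansion of
#' largest probability; ties break toward the lowest inventory row.
#'
#' @param samples A samples tibble (e.g. from [samples_from_gold()]) with
#'   `window`, `document_tokens`, `abbrev_positions` columns.
#' @param model An `abbrev_model`.
#' @param space,idf Embedding space and IDF table used at training time.
#' @return `samples` with added columns `predicted` and `probabilities`
#'   (list column of named numeric vectors).
#' @export
predict_expansion <- function(samples, model, space, idf) {
  if (nrow(samples) == 0) {
    return(dplyr::mutate(samples, predicted = character(0),
                         probabilities = list()))
  }
  if (!is.null(samples$abbreviation) &&
      any(samples$abbreviation != model$abbreviation)) {
    abort("samples contain abbreviations this model was not trained for")
  }
  inputs <- prepare_encoder_inputs(samples, space, idf,
                                   model$config$use_global)
  fw <- encoder_forward(model$params, model$H, inputs)
  pred_idx <- apply(fw$p, 2, which.max)
  samples$predicted <- model$expansions[pred_idx]
  samples$probabilities <- lapply(seq_len(ncol(fw$p)), function(i) {
    setNames(fw$p[, i], model$expansions)
  })
  samples
}

#' @rdname predict_expansion
#' @param object An `abbrev_model`.
#' @param newdata A samples tibble.
#' @param ... Passed on (`space`, `idf` required).
#' @export
predict.abbrev_model <- function(object, newdata, space, idf, ...) {
  predict_expansion(newdata, object, space, idf)
}

#' Build inference samples from gold-labeled occurrences
#'
#' Converts gold labels (note id, sentence index, token index) into the same
#' sample shape used for training: a local window around the abbreviation
#' (token itself excluded), the full document tokens, and the abbreviation
#' positions to exclude from the global context.
#'
#' @param gold A gold-label tibble (`note_id`, `sentence_idx`, `token_idx`,
#'   `abbreviation`, `expansion`).
#' @param docs The preprocessed corpus the labels index into.
#' @param window_size Tokens per side (default 3).
#' @return A samples tibble with a `label` column holding the gold expansion.
#' @export
samples_from_gold <- function(gold, docs, window_size = 3) {
  doc_idx <- match(gold$note_id, docs$note_id)
  if (anyNA(doc_idx)) abort("gold labels reference unknown note ids")
  rows <- lapply(seq_len(nrow(gold)), function(i) {
    sents <- docs$sentences[[doc_idx[[i]]]]
    s <- gold$sentence_idx[[i]]
    h <- gold$token_idx[[i]]
    toks <- sents[[s]]
    if (toks[[h]] != gold$abbreviation[[i]]) {
      abort(sprintf("gold label %d does not point at its abbreviation", i))
    }
    flat <- doc_tokens(sents)
    off <- cumsum(c(0L, vapply(sents, length, integer(1))))
    tibble(
      note_id = gold$note_id[[i]],
      abbreviation = gold$abbreviation[[i]],
      label = gold$expansion[[i]],
      window = list(toks[setdiff(
        max(1L, h - window_size):min(length(toks), h + window_size), h)]),
      document_tokens = list(flat),
      abbrev_positions = list(off[[s]] + h),
      provenance = "gold"
    )
  })
  dplyr::bind_rows(rows)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain-text directories: CSV weight matrices plus a JSON
#' manifest recording the expansion order, dimensions and configuration
#' hash, so runs are reproducible and diffable.
#'
#' @param model An `abbrev_model`.
#' @param dir Checkpoint directory (created if needed).
#' @export
write_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, f) {
    utils::write.table(m, file.path(dir, f), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  wm(model$params$W1, "W1.csv")
  wm(matrix(model$params$b, nrow = 1), "b.csv")
  wm(model$params$W2, "W2.csv")
  wm(model$H, "H.csv")
  manifest <- list(
    abbreviation = model$abbreviation,
    expansions = model$expansions,
    concept_ids = model$concept_ids,
    strategy = model$strategy,
    temperature = model$temperature,
    best_epoch = model$best_epoch,
    validation_loss = model$validation_loss,
    config = model$config[c("hidden_dim", "output_dim", "use_global",
                            "lr", "epochs", "batch_size", "seed")],
    config_hash = rlang::hash(model$config)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(model)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  rm_ <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = ","))
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  structure(
    list(
      abbreviation = manifest$abbreviation,
      expansions = manifest$expansions,
      concept_ids = if (!is.null(manifest$concept_ids)) {
        as.character(manifest$concept_ids)
      },
      params = list(W1 = unname(rm_("W1.csv")),
                    b = as.numeric(rm_("b.csv")),
                    W2 = unname(rm_("W2.csv"))),
      H = unname(rm_("H.csv")),
      config = manifest$config,
      strategy = manifest$strategy,
      temperature = manifest$temperature,
      best_epoch = manifest$best_epoch,
      validation_loss = manifest$validation_loss,
      history = NULL
    ),
    class = "abbrev_model"
  )
}
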