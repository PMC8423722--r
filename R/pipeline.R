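#' Run configuration for the disambiguation pipeline
#'
#' Builds the configuration consumed by [run_stage()]. Defaults mirror the
#' study protocol: embedding dim 100, window 3, epsilon 0.001, temperature
#' bounds \[0.5, 2\] with 25 TPE iterations, 1000 samples per expansion,
#' delta 2.6, 100 epochs at learning rate 0.01 for abbreviation models,
#' pretraining at learning rate 0.002 with batch 2048, 999 bootstrap
#' resamples. Every numeric knob can be overridden via `...` or a YAML file.
#'
#' @param path Optional YAML config file; values in `...` override it.
#' @param ... Named overrides.
#' @return A named list of class `abbrev_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    output_dir = "abbrevx_run",
    corpus_file = NULL, gold_file = NULL,
    inventory_file = NULL, ontology_nodes_file = NULL,
    ontology_edges_file = NULL,
    strategy = "relatives",
    window_size = 3,
    embedding_dim = 100,
    embedding_epochs = 5,
    epsilon = 0.001,
    k_relatives = 10,
    temperature = 1,
    temperature_bounds = c(0.5, 2),
    optimize_temperature = FALSE,
    bo_iterations = 25,
    bo_seeds = 1,
    target_per_expansion = 1000,
    delta = 2.6,
    hidden_dim = 100,
    output_dim = 100,
    epochs = 100,
    lr = 0.01,
    batch_size = 64,
    pretrain_lr = 0.002,
    pretrain_batch_size = 2048,
    pretrain_epochs = 30,
    samples_per_concept = 1000,
    global_context = TRUE,
    pretrain = FALSE,
    bootstrap_resamples = 999,
    n_abbreviations = 10,
    senses_range = c(2, 3),
    n_notes = 400,
    n_eval_notes = 120,
    seed = 1
  )
  if (!is.null(path)) {
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  dots <- list(...)
  if (length(dots) > 0) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown) > 0) {
      abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    cfg <- utils::modifyList(cfg, dots)
  }
  numeric_pos <- c("window_size", "embedding_dim", "epsilon", "bo_iterations",
                   "target_per_expansion", "delta", "epochs", "lr",
                   "batch_size", "pretrain_lr", "pretrain_batch_size",
                   "bootstrap_resamples")
  for (k in numeric_pos) {
    if (any(cfg[[k]] <= 0)) abort(paste0("config `", k, "` must be positive"))
  }
  if (!cfg$strategy %in% c("control", "swr", "relatives")) {
    abort("strategy must be one of control, swr, relatives")
  }
  structure(cfg, class = c("abbrev_config", "list"))
}

stage_paths <- function(cfg) {
  d <- cfg$output_dir
  list(
    dir = d,
    notes = file.path(d, "corpus.jsonl"),
    gold = file.path(d, "gold.tsv"),
    eval_notes = file.path(d, "eval_corpus.jsonl"),
    eval_gold = file.path(d, "eval_gold.tsv"),
    inventory = file.path(d, "inventory.tsv"),
    onto_nodes = file.path(d, "ontology_nodes.tsv"),
    onto_edges = file.path(d, "ontology_edges.tsv"),
    embeddings = file.path(d, "embeddings.w2v"),
    embeddings_ngrams = file.path(d, "embeddings_ngrams.w2v"),
    idf = file.path(d, "idf.tsv"),
    samples = file.path(d, "direct_samples.jsonl"),
    training = file.path(d, "training_sets"),
    pretrain = file.path(d, "pretrain"),
    models = file.path(d, "models"),
    predictions = file.path(d, "predictions.tsv"),
    report_tsv = file.path(d, "report.tsv"),
    report_json = file.path(d, "report.json"),
    compare = file.path(d, "comparison.json")
  )
}

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("missing artifact '%s'; run stage `%s` first",
                  path, stage))
  }
  invisible(path)
}

write_manifest <- function(cfg, stage, inputs = character()) {
  p <- stage_paths(cfg)
  sums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  jsonlite::write_json(
    list(stage = stage, seed = cfg$seed,
         config_hash = rlang::hash(unclass(cfg)),
         input_checksums = sums,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(p$dir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA)
}

slugify <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

write_samples_jsonl <- function(samples, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(samples))) {
    writeLines(as.character(jsonlite::toJSON(list(
      note_id = samples$note_id[[i]],
      abbreviation = samples$abbreviation[[i]],
      label = samples$label[[i]],
      window = samples$window[[i]],
      document_tokens = samples$document_tokens[[i]],
      abbrev_positions = samples$abbrev_positions[[i]],
      provenance = samples$provenance[[i]]
    ), auto_unbox = FALSE)), con)
  }
  invisible(samples)
}

read_samples_jsonl <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  dplyr::bind_rows(lapply(recs, function(r) {
    tibble(
      note_id = as.character(r$note_id),
      abbreviation = as.character(r$abbreviation),
      label = as.character(r$label),
      window = list(as.character(unlist(r$window))),
      document_tokens = list(as.character(unlist(r$document_tokens))),
      abbrev_positions = list(as.integer(unlist(r$abbrev_positions))),
      provenance = as.character(r$provenance),
      relative_concept = NA_character_,
      relative_distance = NA_real_
    )
  }))
}

# Reload the shared prepared state (docs, space, idf, inventory, ontology)
# that several stages need.
load_prepared <- function(cfg) {
  p <- stage_paths(cfg)
  for (f in c(p$notes, p$inventory, p$onto_nodes, p$embeddings, p$idf)) {
    require_artifact(f, if (f %in% c(p$embeddings, p$idf)) "prepare" else
      "simulate")
  }
  onto <- read_ontology(p$onto_nodes, p$onto_edges)
  inventory <- read_inventory(p$inventory)
  corpus <- read_corpus(p$notes, p$gold)
  lexicon <- c(onto$nodes$name, inventory$expansion)
  docs <- preprocess_corpus(corpus$notes, lexicon)
  list(onto = onto, inventory = inventory, corpus = corpus, docs = docs,
       space = read_word2vec(p$embeddings, p$embeddings_ngrams),
       idf = read_idf(p$idf),
       lexicon = lexicon)
}

#' Run one pipeline stage
#'
#' Orchestrates the end-to-end workflow on disk. Stages, in order:
#' `simulate` (synthetic ontology/inventory/corpora), `prepare`
#' (preprocessing, embeddings, IDF, direct reverse-substitution samples),
#' `augment` (per-abbreviation training sets under the configured strategy),
#' `pretrain` (hierarchical concept pretraining), `train` (one model per
#' abbreviation), `evaluate` (predictions + accuracy report on the held-out
#' evaluation corpus), `compare` (Wilcoxon comparison of two report files).
#' Each stage writes its artifacts plus a manifest (seed, config hash, input
#' checksums) into the output directory and fails with an actionable message
#' naming the missing stage when run out of order.
#'
#' @param stage One of `"simulate"`, `"prepare"`, `"augment"`, `"pretrain"`,
#'   `"train"`, `"evaluate"`, `"compare"`.
#' @param config An [run_config()].
#' @param compare_with For `compare`: path to another run's `report.tsv` (the
#'   current run is model A, the other run model B).
#' @return Invisibly, a stage-specific result (e.g. the eval report).
#' @export
run_stage <- function(stage = c("simulate", "prepare", "augment", "pretrain",
                                "train", "evaluate", "compare"),
                      config = run_config(), compare_with = NULL) {
  stage <- match.arg(stage)
  cfg <- config
  p <- stage_paths(cfg)
  dir.create(p$dir, recursive = TRUE, showWarnings = FALSE)
  result <- switch(
    stage,
    simulate = {
      study <- simulate_study(
        n_abbreviations = cfg$n_abbreviations,
        senses_range = cfg$senses_range,
        n_notes = cfg$n_notes, n_eval_notes = cfg$n_eval_notes,
        seed = cfg$seed)
      write_corpus(study$corpus, p$notes, p$gold)
      write_corpus(study$eval_corpus, p$eval_notes, p$eval_gold)
      readr::write_tsv(study$inventory, p$inventory, progress = FALSE)
      write_ontology(study$ontology, p$onto_nodes, p$onto_edges)
      study
    },
    prepare = {
      require_artifact(p$notes, "simulate")
      onto <- read_ontology(p$onto_nodes, p$onto_edges)
      inventory <- read_inventory(p$inventory)
      corpus <- read_corpus(p$notes, p$gold)
      lexicon <- c(onto$nodes$name, inventory$expansion)
      docs <- preprocess_corpus(corpus$notes, lexicon)
      space <- train_embeddings(docs, dim = cfg$embedding_dim,
                                seed = derive_seed(cfg$seed, "embeddings"),
                                epochs = cfg$embedding_epochs)
      write_word2vec(space, p$embeddings, p$embeddings_ngrams)
      idf <- compute_idf(docs)
      write_idf(idf, p$idf)
      direct <- reverse_substitute(docs, inventory,
                                   window_size = cfg$window_size)
      write_samples_jsonl(direct, p$samples)
      direct
    },
    augment = {
      require_artifact(p$samples, "prepare")
      st <- load_prepared(cfg)
      direct <- read_samples_jsonl(p$samples)
      dir.create(p$training, showWarnings = FALSE)
      for (a in unique(st$inventory$abbreviation)) {
        rel <- if (cfg$strategy == "relatives") {
          relatives_for_abbreviation(a, st$inventory, st$onto, st$space,
                                     st$docs, k = cfg$k_relatives,
                                     epsilon = cfg$epsilon)
        }
        ts <- withCallingHandlers(
          build_training_set(
            direct, a, st$inventory, strategy = cfg$strategy,
            relatives = rel, docs = st$docs,
            target_per_expansion = cfg$target_per_expansion,
            temperature = cfg$temperature, window_size = cfg$window_size,
            seed = derive_seed(cfg$seed, paste0("augment-", a))),
          warning = function(w) invokeRestart("muffleWarning"))
        write_samples_jsonl(
          dplyr::mutate(ts, provenance = paste0(.data$provenance, ":",
                                                .data$split)),
          file.path(p$training, paste0(slugify(a), ".jsonl")))
      }
      invisible(NULL)
    },
    pretrain = {
      require_artifact(p$samples, "prepare")
      st <- load_prepared(cfg)
      concepts <- character(0)
      for (a in unique(st$inventory$abbreviation)) {
        concepts <- union(concepts, select_pretraining_concepts(
          a, st$inventory, st$onto, st$space, delta = cfg$delta))
      }
      pre <- pretrain_hierarchy(
        st$docs, concepts, st$onto, st$space, st$idf,
        config = default_train_config(
          hidden_dim = cfg$hidden_dim, output_dim = cfg$output_dim,
          use_global = cfg$global_context, epochs = cfg$pretrain_epochs,
          pretrain_lr = cfg$pretrain_lr,
          pretrain_batch_size = cfg$pretrain_batch_size,
          samples_per_concept = cfg$samples_per_concept,
          window_size = cfg$window_size,
          seed = derive_seed(cfg$seed, "pretrain")))
      dir.create(p$pretrain, showWarnings = FALSE)
      utils::write.table(pre$params$W1, file.path(p$pretrain, "W1.csv"),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      utils::write.table(matrix(pre$params$b, 1),
                         file.path(p$pretrain, "b.csv"),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      utils::write.table(pre$params$W2, file.path(p$pretrain, "W2.csv"),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      utils::write.table(
        cbind(rownames(pre$hier$H_raw), as.data.frame(pre$hier$H_raw)),
        file.path(p$pretrain, "H_raw.csv"),
        sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
      pre
    },
    train = {
      require_artifact(p$training, "augment")
      st <- load_prepared(cfg)
      init <- NULL
      if (cfg$pretrain) {
        require_artifact(file.path(p$pretrain, "W1.csv"), "pretrain")
        rd <- function(f) as.matrix(utils::read.table(
          file.path(p$pretrain, f), sep = ","))
        hr <- utils::read.table(file.path(p$pretrain, "H_raw.csv"),
                                sep = ",", stringsAsFactors = FALSE)
        H_raw <- as.matrix(hr[, -1])
        rownames(H_raw) <- hr[[1]]
        init <- list(params = list(W1 = unname(rd("W1.csv")),
                                   b = as.numeric(rd("b.csv")),
                                   W2 = unname(rd("W2.csv"))),
                     hier = list(H_raw = unname_cols(H_raw),
                                 ontology = st$onto))
      }
      dir.create(p$models, showWarnings = FALSE)
      for (a in unique(st$inventory$abbreviation)) {
        f <- file.path(p$training, paste0(slugify(a), ".jsonl"))
        require_artifact(f, "augment")
        raw <- read_samples_jsonl(f)
        parts <- strsplit(raw$provenance, ":", fixed = TRUE)
        raw$split <- vapply(parts, `[[`, character(1), 2)
        raw$provenance <- vapply(parts, `[[`, character(1), 1)
        inv_a <- st$inventory[st$inventory$abbreviation == a, ]
        ts <- structure(raw, abbreviation = a,
                        expansions = inv_a$expansion,
                        concept_ids = inv_a$concept_id,
                        strategy = cfg$strategy,
                        class = class(raw))
        model <- withCallingHandlers(
          train_abbrev_model(
            ts, st$space, st$idf,
            config = default_train_config(
              hidden_dim = cfg$hidden_dim, output_dim = cfg$output_dim,
              use_global = cfg$global_context, lr = cfg$lr,
              epochs = cfg$epochs, batch_size = cfg$batch_size,
              seed = derive_seed(cfg$seed, paste0("train-", a))),
            init = init),
          warning = function(w) invokeRestart("muffleWarning"))
        write_model(model, file.path(p$models, slugify(a)))
      }
      invisible(NULL)
    },
    evaluate = {
      require_artifact(p$models, "train")
      require_artifact(p$eval_notes, "simulate")
      st <- load_prepared(cfg)
      eval_corpus <- read_corpus(p$eval_notes, p$eval_gold)
      eval_docs <- preprocess_corpus(eval_corpus$notes, st$lexicon)
      gold <- eval_corpus$gold
      preds <- list()
      for (a in unique(gold$abbreviation)) {
        mdir <- file.path(p$models, slugify(a))
        require_artifact(file.path(mdir, "manifest.json"), "train")
        model <- read_model(mdir)
        samp <- samples_from_gold(gold[gold$abbreviation == a, ], eval_docs,
                                  window_size = cfg$window_size)
        preds[[a]] <- predict_expansion(samp, model, st$space, st$idf)
      }
      predictions <- dplyr::bind_rows(preds)
      readr::write_tsv(
        dplyr::select(predictions, "note_id", "abbreviation", "label",
                      "predicted"),
        p$predictions, progress = FALSE)
      report <- score_predictions(predictions, st$inventory,
                                  bootstrap = cfg$bootstrap_resamples,
                                  seed = derive_seed(cfg$seed, "evaluate"))
      write_eval_report(report, p$report_tsv, p$report_json)
      report
    },
    compare = {
      require_artifact(p$report_tsv, "evaluate")
      if (is.null(compare_with)) abort("`compare_with` report path required")
      require_artifact(compare_with, "evaluate")
      a <- readr::read_tsv(p$report_tsv, show_col_types = FALSE,
                           progress = FALSE)
      b <- readr::read_tsv(compare_with, show_col_types = FALSE,
                           progress = FALSE)
      joined <- dplyr::inner_join(a, b, by = "abbreviation",
                                  suffix = c("_a", "_b"))
      cmp <- compare_models(joined$accuracy_a, joined$accuracy_b)
      cmp$macro_a <- mean(joined$accuracy_a)
      cmp$macro_b <- mean(joined$accuracy_b)
      jsonlite::write_json(cmp, p$compare, auto_unbox = TRUE, digits = NA)
      cmp
    }
  )
  write_manifest(cfg, stage)
  invisible(result)
}

unname_cols <- function(m) {
  colnames(m) <- NULL
  m
}
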