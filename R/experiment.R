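#' Rare-sense recovery experiment
#'
#' Runs the package's headline comparison on simulated data: for each seed, a
#' corpus is generated in which every abbreviation has one sense that is
#' never written out long-form (so reverse substitution alone yields zero
#' training samples for it) but whose ontology siblings do appear written
#' out. A control model (direct reverse-substitution samples only) and a
#' relatives model (temperature-softmax augmentation from embedding-space
#' relatives) are trained per abbreviation and scored on a balanced,
#' fully-abbreviated held-out corpus.
#'
#' @param n_abbreviations Abbreviations per simulated study.
#' @param senses_range Senses per abbreviation (min, max).
#' @param n_notes,n_eval_notes Training / evaluation corpus sizes.
#' @param target_per_expansion Training samples per expansion.
#' @param embedding_dim,hidden_dim,output_dim Model dimensions.
#' @param embedding_epochs,epochs Embedding / classifier training epochs.
#' @param temperature Sampling temperature for the relatives strategy.
#' @param use_global Include the global note context.
#' @param n_seeds Number of independent replicates.
#' @param seed Master seed.
#' @return A list with `per_seed` (tibble: seed, macro/micro per strategy),
#'   `mean_gap` (mean relatives - control macro difference), and `reports`
#'   (the last seed's `abbrev_eval` objects).
#' @export
rare_sense_experiment <- function(n_abbreviations = 10,
                                  senses_range = c(2, 3),
                                  n_notes = 600, n_eval_notes = 150,
                                  target_per_expansion = 80,
                                  embedding_dim = 40, hidden_dim = 40,
                                  output_dim = 40, embedding_epochs = 10,
                                  epochs = 80, temperature = 1,
                                  use_global = TRUE, n_seeds = 5, seed = 1) {
  rows <- list()
  reports <- NULL
  for (si in seq_len(n_seeds)) {
    s <- derive_seed(seed, paste0("rare-exp", si))
    study <- simulate_study(
      n_abbreviations = n_abbreviations, senses_range = senses_range,
      n_rare = n_abbreviations,   # one never-written-out sense per abbrev
      n_notes = n_notes, n_eval_notes = n_eval_notes, seed = s)
    lex <- c(study$ontology$nodes$name, study$inventory$expansion)
    docs <- preprocess_corpus(study$corpus$notes, lex)
    direct <- reverse_substitute(docs, study$inventory)
    idf <- compute_idf(docs)
    space <- train_embeddings(docs, dim = embedding_dim,
                              seed = derive_seed(s, "emb"),
                              epochs = embedding_epochs)
    eval_docs <- preprocess_corpus(study$eval_corpus$notes, lex)
    gold <- study$eval_corpus$gold
    cfg <- default_train_config(
      hidden_dim = hidden_dim, output_dim = output_dim,
      use_global = use_global, epochs = epochs,
      seed = derive_seed(s, "cfg"))
    reports <- list()
    for (strat in c("control", "relatives")) {
      preds <- list()
      for (a in unique(study$inventory$abbreviation)) {
        rel <- if (strat == "relatives") {
          relatives_for_abbreviation(a, study$inventory, study$ontology,
                                     space, docs)
        }
        ts <- withCallingHandlers(
          build_training_set(direct, a, study$inventory, strategy = strat,
                             relatives = rel, docs = docs,
                             target_per_expansion = target_per_expansion,
                             temperature = temperature,
                             seed = derive_seed(s, paste0("ts-", a))),
          warning = function(w) invokeRestart("muffleWarning"))
        m <- withCallingHandlers(
          train_abbrev_model(ts, space, idf, cfg),
          warning = function(w) invokeRestart("muffleWarning"))
        samp <- samples_from_gold(gold[gold$abbreviation == a, ], eval_docs)
        preds[[a]] <- predict_expansion(samp, m, space, idf)
      }
      reports[[strat]] <- score_predictions(dplyr::bind_rows(preds),
                                            study$inventory)
    }
    rows[[si]] <- tibble(
      seed_index = si,
      macro_control = reports$control$macro,
      micro_control = reports$control$micro,
      macro_relatives = reports$relatives$macro,
      micro_relatives = reports$relatives$micro
    )
  }
  per_seed <- dplyr::bind_rows(rows)
  list(per_seed = per_seed,
       mean_gap = mean(per_seed$macro_relatives - per_seed$macro_control),
       reports = reports)
}
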