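#' Temperature-softmax sampling distribution over relatives
#'
#' Each relative `r` of an expansion is sampled with probability
#' `p_r = exp(-d_r / T) / sum_R exp(-d_R / T)` where `d_r` is its Euclidean
#' distance from the expansion and `T` is the temperature: small `T`
#' concentrates sampling on the nearest relative (in particular on the
#' epsilon self-entry when the expansion occurs in the corpus), large `T`
#' approaches uniform sampling over relatives.
#'
#' @param relatives A relatives tibble from [nearest_relatives()] (columns
#'   `concept_id`, `distance`, ...).
#' @param temperature Positive temperature `T`.
#' @return The tibble with an added `probability` column (sums to 1).
#' @export
sampling_distribution <- function(relatives, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      temperature <= 0) {
    abort("`temperature` must be a single positive number")
  }
  if (nrow(relatives) == 0) abort("empty relative set")
  s <- -relatives$distance / temperature
  s <- s - max(s)
  p <- exp(s)
  relatives$probability <- p / sum(p)
  relatives
}

#' Assign train/validation/test splits
#'
#' Splits the direct reverse-substitution pool 60/20/20 per expansion
#' (stratified, seeded). Augmented samples never enter validation or test;
#' those splits always consist of direct samples only.
#'
#' @param samples A direct-sample tibble from [reverse_substitute()].
#' @param fractions Train/validation/test fractions (must sum to 1).
#' @param seed Integer seed.
#' @return `samples` with a `split` column.
#' @export
split_samples <- function(samples, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  samples$split <- NA_character_
  with_seed(derive_seed(seed, "split"), {
    for (ix in split(seq_len(nrow(samples)), samples$label)) {
      n <- length(ix)
      shuffled <- if (n == 1) ix else sample(ix)
      n_tr <- ceiling(fractions[[1]] * n)
      n_va <- floor(fractions[[2]] * n)
      lab <- rep("train", n)
      if (n_tr < n) lab[(n_tr + 1):min(n, n_tr + n_va)] <- "validation"
      if (n_tr + n_va < n) lab[(n_tr + n_va + 1):n] <- "test"
      samples$split[shuffled] <- lab
    }
  })
  samples
}

# Index of corpus occurrences of each relative's joined name:
# tibble(concept_id, doc, sentence, pos)
relative_occurrence_index <- function(docs, relatives_all) {
  toks <- unique(unlist(lapply(relatives_all, function(r) {
    join_phrase(r$name)
  }), use.names = FALSE))
  hits <- list()
  for (d in seq_len(nrow(docs))) {
    sents <- docs$sentences[[d]]
    for (s in seq_along(sents)) {
      w <- which(sents[[s]] %in% toks)
      for (h in w) {
        hits[[length(hits) + 1L]] <- tibble(
          token = sents[[s]][[h]], doc = d, sentence = s, pos = h)
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(token = character(), doc = integer(), sentence = integer(),
                  pos = integer()))
  }
  dplyr::bind_rows(hits)
}

#' Build a per-abbreviation training set
#'
#' Three strategies:
#' * `control`: the direct reverse-substitution samples as-is, capped at
#'   `target_per_expansion` per expansion. Senses never written out in the
#'   corpus end up with zero training samples -- the failure mode that
#'   motivates augmentation.
#' * `swr`: direct samples resampled with replacement so every expansion has
#'   exactly `target_per_expansion` training samples.
#' * `relatives`: for each expansion, `target_per_expansion` samples are
#'   drawn by repeatedly picking a relative from the temperature-softmax
#'   distribution, picking one corpus sentence containing that relative
#'   uniformly, replacing the relative's token with the abbreviation and
#'   labeling with the target expansion. The epsilon self-entry draws from
#'   the expansion's own direct training samples. Relatives with no corpus
#'   sentence are dropped and the distribution renormalized.
#'
#' Splits cover the direct pool 60/20/20; augmented draws only ever join the
#' training split.
#'
#' @param direct_samples Direct samples for one abbreviation from
#'   [reverse_substitute()].
#' @param abbreviation The abbreviation token.
#' @param inventory The sense inventory (fixes the expansion order).
#' @param strategy One of `"control"`, `"swr"`, `"relatives"`.
#' @param relatives Named list of relative tibbles per expansion (from
#'   [relatives_for_abbreviation()]); required for `strategy = "relatives"`.
#' @param docs Preprocessed corpus; required for `strategy = "relatives"`.
#' @param target_per_expansion Per-expansion sample target/cap (default
#'   1000).
#' @param temperature Sampling temperature (relatives strategy).
#' @param window_size Tokens per side for relative-drawn windows.
#' @param seed Integer seed; the build is deterministic given it.
#' @return A samples tibble with `split` column and attributes
#'   `abbreviation`, `expansions`, `concept_ids`, `strategy`, `temperature`.
#' @export
build_training_set <- function(direct_samples, abbreviation, inventory,
                               strategy = c("control", "swr", "relatives"),
                               relatives = NULL, docs = NULL,
                               target_per_expansion = 1000, temperature = 1,
                               window_size = 3, seed = 1) {
  strategy <- match.arg(strategy)
  inventory <- validate_inventory(inventory)
  inv <- inventory[inventory$abbreviation == abbreviation, ]
  if (nrow(inv) == 0) abort(paste0("abbreviation not in inventory: ",
                                   abbreviation))
  expansions <- inv$expansion
  direct <- direct_samples[direct_samples$abbreviation == abbreviation, ]
  direct <- split_samples(direct, seed = derive_seed(seed, "splits"))
  pools <- split(seq_len(nrow(direct)), direct$label)

  train_rows <- list()
  with_seed(derive_seed(seed, paste0("build-", strategy)), {
    for (ei in seq_along(expansions)) {
      expn <- expansions[[ei]]
      pool <- pools[[expn]] %||% integer(0)
      pool_tr <- pool[direct$split[pool] == "train"]
      if (strategy %in% c("control", "swr") && length(pool_tr) == 0) {
        warn(paste0("expansion with zero direct training samples: ", expn))
        next
      }
      if (strategy == "control") {
        take <- if (length(pool_tr) > target_per_expansion) {
          sample(pool_tr, target_per_expansion)
        } else pool_tr
        train_rows[[ei]] <- direct[take, ]
      } else if (strategy == "swr") {
        take <- sample(pool_tr, target_per_expansion, replace = TRUE)
        train_rows[[ei]] <- direct[take, ]
      } else {
        rel <- relatives[[expn]]
        if (is.null(rel)) abort(paste0("no relative set for expansion: ",
                                       expn))
        if (is.null(docs)) abort("`docs` required for the relatives strategy")
        occ <- relative_occurrence_index(docs, list(rel))
        avail_tok <- unique(occ$token)
        rel_tok <- join_phrase(rel$name)
        usable <- (rel$is_self & length(pool_tr) > 0) |
          (!rel$is_self & rel_tok %in% avail_tok)
        rel_use <- rel[usable, ]
        if (nrow(rel_use) == 0) {
          warn(paste0("no usable relatives for expansion: ", expn))
          next
        }
        dist <- sampling_distribution(rel_use, temperature)
        picks <- sample.int(nrow(dist), target_per_expansion, replace = TRUE,
                            prob = dist$probability)
        drawn <- vector("list", target_per_expansion)
        for (j in seq_len(target_per_expansion)) {
          ri <- picks[[j]]
          if (dist$is_self[[ri]]) {
            src <- direct[sample(pool_tr, 1), ]
            src$provenance <- "relative"
            src$relative_concept <- dist$concept_id[[ri]]
            src$relative_distance <- dist$distance[[ri]]
            src$split <- "train"
            drawn[[j]] <- src
          } else {
            tok <- join_phrase(dist$name[[ri]])
            cand <- which(occ$token == tok)
            o <- occ[cand[[sample.int(length(cand), 1)]], ]
            sents <- docs$sentences[[o$doc]]
            toks <- sents[[o$sentence]]
            h <- o$pos
            flat <- doc_tokens(sents)
            off <- cumsum(c(0L, vapply(sents, length, integer(1))))
            # substitute every occurrence of the relative AND of the target
            # expansion's own long form, mirroring direct RS
            flat_pos <- which(flat == tok | flat == join_phrase(expn))
            doc2 <- flat
            doc2[flat_pos] <- abbreviation
            win <- toks[setdiff(
              max(1L, h - window_size):min(length(toks), h + window_size), h)]
            drawn[[j]] <- tibble(
              note_id = docs$note_id[[o$doc]],
              abbreviation = abbreviation,
              label = expn,
              window = list(win),
              document_tokens = list(doc2),
              abbrev_positions = list(flat_pos),
              provenance = "relative",
              relative_concept = dist$concept_id[[ri]],
              relative_distance = dist$distance[[ri]],
              split = "train"
            )
          }
        }
        train_rows[[ei]] <- dplyr::bind_rows(drawn)
      }
    }
  })
  heldout <- direct[direct$split != "train", ]
  out <- dplyr::bind_rows(c(train_rows, list(heldout)))
  if (strategy %in% c("control", "swr")) {
    # direct train rows already carry split == "train"
  } else {
    out$split[is.na(out$split)] <- "train"
  }
  structure(out,
            abbreviation = abbreviation,
            expansions = expansions,
            concept_ids = inv$concept_id,
            strategy = strategy,
            temperature = if (strategy == "relatives") temperature,
            class = c("tbl_df", "tbl", "data.frame"))
}

#' Select the sampling temperature by Bayesian optimization
#'
#' Runs `n_iterations` trials of a tree-structured Parzen estimator over
#' `log2(T)` in `log2(bounds)` (the bounds default to `[2^-1, 2]`). Each
#' trial builds a relatives training set at the proposed temperature, trains
#' the disambiguation model, and scores mean cross-entropy on the direct
#' validation split; the trial with the lowest validation loss wins. The
#' whole search can be repeated over `n_seeds` seeds, reporting the seed with
#' median validation loss for a typical-run estimate.
#'
#' @inheritParams build_training_set
#' @param space,idf Embedding space and IDF table.
#' @param config Training configuration ([default_train_config()]).
#' @param bounds Temperature bounds, default `c(0.5, 2)`.
#' @param n_iterations TPE trials (default 25).
#' @param n_seeds Number of independent searches (default 1; 15 matches the
#'   median-seed protocol).
#' @param seed Integer master seed.
#' @return A list: `temperature`, `model`, `validation_loss`, `trials`
#'   (tibble of all trials), `seed_results`.
#' @export
optimize_temperature <- function(direct_samples, abbreviation, inventory,
                                 relatives, docs, space, idf,
                                 config = default_train_config(),
                                 bounds = c(0.5, 2), n_iterations = 25,
                                 n_seeds = 1, target_per_expansion = 1000,
                                 window_size = 3, seed = 1) {
  stopifnot(length(bounds) == 2, bounds[[1]] <= bounds[[2]], bounds[[1]] > 0)
  one_search <- function(search_seed) {
    lo <- log2(bounds[[1]]); hi <- log2(bounds[[2]])
    xs <- numeric(0); ys <- numeric(0)
    trials <- vector("list", n_iterations)
    best <- list(loss = Inf)
    # common random numbers across trials: every trial shares the same
    # sampling and training seeds, so loss differences reflect only T
    build_seed <- derive_seed(search_seed, "trial-build")
    fit_seed <- derive_seed(search_seed, "trial-fit")
    for (it in seq_len(n_iterations)) {
      x <- tpe_propose(xs, ys, lo, hi,
                       seed = derive_seed(search_seed, paste0("tpe", it)))
      temp <- 2^x
      res <- tryCatch({
        ts <- build_training_set(
          direct_samples, abbreviation, inventory, strategy = "relatives",
          relatives = relatives, docs = docs,
          target_per_expansion = target_per_expansion,
          temperature = temp, window_size = window_size,
          seed = build_seed)
        cfg <- utils::modifyList(config, list(seed = fit_seed))
        m <- train_abbrev_model(ts, space, idf, cfg)
        list(model = m, loss = m$validation_loss)
      }, error = function(e) {
        warn(paste0("trial failed (", conditionMessage(e), ")"))
        NULL
      })
      if (is.null(res)) next
      xs <- c(xs, x); ys <- c(ys, res$loss)
      trials[[it]] <- tibble(iteration = it, temperature = temp,
                             validation_loss = res$loss)
      if (res$loss < best$loss) {
        best <- list(loss = res$loss, temperature = temp, model = res$model)
      }
    }
    list(temperature = best$temperature, model = best$model,
         validation_loss = best$loss, trials = dplyr::bind_rows(trials))
  }
  results <- lapply(seq_len(n_seeds), function(i) {
    one_search(derive_seed(seed, paste0("search", i)))
  })
  losses <- vapply(results, `[[`, numeric(1), "validation_loss")
  pick <- order(losses)[ceiling(length(losses) / 2)]  # median-loss seed
  out <- results[[pick]]
  out$seed_results <- tibble(seed_index = seq_len(n_seeds),
                             validation_loss = losses)
  out
}

# Minimal 1-D tree-structured Parzen estimator on a bounded interval.
# The observed trials are split at the gamma-quantile of the loss into a
# "good" and a "bad" set; both get Gaussian kernel density estimates and the
# next point maximizes the density ratio l(x)/g(x) over candidates drawn
# from l. Startup probes the two bounds first (so the search dominates the
# endpoint grid by construction), then samples uniformly.
tpe_propose <- function(xs, ys, lo, hi, seed, gamma = 0.25,
                        n_startup = 5, n_candidates = 24) {
  with_seed(derive_seed(seed, "tpe-propose"), {
    if (lo == hi) return(lo)
    if (length(xs) == 0) return(lo)
    if (length(xs) == 1) return(hi)
    if (length(xs) < n_startup) return(runif(1, lo, hi))
    cut <- stats::quantile(ys, gamma, names = FALSE, type = 7)
    good <- xs[ys <= cut]
    bad <- xs[ys > cut]
    if (length(bad) == 0) bad <- xs
    bw <- max((hi - lo) / 5, 1e-3)
    mix_sample <- function(centers, n) {
      pmin(hi, pmax(lo, sample(centers, n, replace = TRUE) +
                      rnorm(n, sd = bw)))
    }
    mix_dens <- function(centers, x) {
      # uniform prior component keeps densities bounded away from zero
      base <- 1 / (hi - lo)
      kde <- vapply(x, function(xx) {
        mean(stats::dnorm(xx, mean = centers, sd = bw))
      }, numeric(1))
      0.1 * base + 0.9 * kde
    }
    cand <- mix_sample(good, n_candidates)
    score <- mix_dens(good, cand) / mix_dens(bad, cand)
    cand[[which.max(score)]]
  })
}
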