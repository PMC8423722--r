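#' Token embedding spaces
#'
#' An embedding space maps tokens to fixed-dimension real vectors. The default
#' training backend is a subword skip-gram model (see [train_embeddings()]),
#' but any matrix with token rownames can be wrapped, which is convenient for
#' small deterministic spaces in tests and toy analyses.
#'
#' Lookup rule for a token not in the vocabulary: (1) if the space carries
#' subword (character n-gram) vectors, the token is composed as the mean of
#' its known n-gram vectors; (2) otherwise, for `_`-joined tokens, the mean of
#' the known constituent unigram vectors; (3) failing both, the zero vector.
#'
#' @param vectors A numeric matrix, one row per token, rownames = tokens.
#' @param ngram_vectors Optional matrix of character n-gram vectors (rownames
#'   are n-grams of the `<token>` form, including boundary markers).
#' @param ngram_range Integer vector `c(min, max)` of n-gram lengths.
#' @return An object of class `embedding_space`.
#' @export
embedding_space <- function(vectors, ngram_vectors = NULL,
                            ngram_range = c(3L, 5L)) {
  vectors <- as.matrix(vectors)
  if (is.null(rownames(vectors))) abort("`vectors` needs token rownames")
  structure(
    list(
      dim = ncol(vectors),
      vectors = vectors,
      ngram_vectors = ngram_vectors,
      ngram_range = as.integer(ngram_range)
    ),
    class = "embedding_space"
  )
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space: %d tokens, dim %d%s>\n",
              nrow(x$vectors), x$dim,
              if (!is.null(x$ngram_vectors)) ", subword" else ""))
  invisible(x)
}

token_ngrams <- function(token, nmin, nmax) {
  padded <- paste0("<", token, ">")
  n <- nchar(padded)
  out <- character(0)
  for (k in nmin:nmax) {
    if (k > n) break
    out <- c(out, substring(padded, seq_len(n - k + 1), seq(k, n)))
  }
  unique(out)
}

#' Look up token vectors
#'
#' @param space An [embedding_space()].
#' @param tokens Character vector.
#' @return A `length(tokens) x dim` matrix (unseen tokens follow the fallback
#'   rule described in [embedding_space()]).
#' @export
embedding_lookup <- function(space, tokens) {
  out <- matrix(0, nrow = length(tokens), ncol = space$dim,
                dimnames = list(tokens, NULL))
  if (length(tokens) == 0) return(out)
  known <- tokens %in% rownames(space$vectors)
  if (any(known)) out[known, ] <- space$vectors[tokens[known], , drop = FALSE]
  for (i in which(!known)) {
    out[i, ] <- oov_vector(space, tokens[[i]])
  }
  out
}

oov_vector <- function(space, token) {
  if (!is.null(space$ngram_vectors)) {
    gr <- token_ngrams(token, space$ngram_range[[1]], space$ngram_range[[2]])
    gr <- gr[gr %in% rownames(space$ngram_vectors)]
    if (length(gr) > 0) {
      return(colMeans(space$ngram_vectors[gr, , drop = FALSE]))
    }
  }
  if (grepl("_", token, fixed = TRUE)) {
    parts <- split_phrase_token(token)[[1]]
    parts <- parts[parts %in% rownames(space$vectors)]
    if (length(parts) > 0) {
      return(colMeans(space$vectors[parts, , drop = FALSE]))
    }
  }
  rep(0, space$dim)
}

#' Train subword skip-gram embeddings
#'
#' A compact fastText-style trainer: skip-gram with negative sampling where
#' each vocabulary word's input representation is the mean of a word vector
#' and its character n-gram vectors, so that morphologically related tokens
#' (including `_`-joined multi-word concepts) share structure and unseen
#' tokens can be composed from their n-grams.
#'
#' @param docs A preprocessed corpus from [preprocess_corpus()].
#' @param dim Embedding dimension (default 100).
#' @param seed Integer seed; training is deterministic given the seed.
#' @param window Maximum skip-gram context window (a per-position width is
#'   drawn uniformly from `1:window`, as in word2vec).
#' @param epochs Passes over the corpus.
#' @param negative Negative samples per positive pair.
#' @param lr Initial learning rate, linearly decayed to 10% over training.
#' @param min_count Minimum token frequency for vocabulary inclusion.
#' @param subword Use character n-gram subword vectors (default TRUE).
#' @param ngram_range n-gram lengths, default 3..5.
#' @return An [embedding_space()].
#' @export
train_embeddings <- function(docs, dim = 100, seed = 1, window = 5,
                             epochs = 5, negative = 5, lr = 0.05,
                             min_count = 1, subword = TRUE,
                             ngram_range = c(3L, 5L)) {
  if (nrow(docs) == 0) abort("corpus is empty")
  sents <- unlist(lapply(docs$sentences, identity), recursive = FALSE)
  sents <- Filter(function(s) length(s) >= 2, sents)
  if (length(sents) == 0) abort("corpus has no multi-token sentences")

  counts <- table(unlist(sents, use.names = FALSE))
  vocab <- names(counts)[counts >= min_count]
  if (length(vocab) < 2) abort("vocabulary too small to train")
  vocab <- sort(vocab)
  V <- length(vocab)
  widx <- setNames(seq_len(V), vocab)

  # component table: each word maps to itself + its n-grams
  if (subword) {
    grams <- lapply(vocab, token_ngrams, nmin = ngram_range[[1]],
                    nmax = ngram_range[[2]])
    gvocab <- sort(unique(unlist(grams, use.names = FALSE)))
    G <- length(gvocab)
    gidx <- setNames(seq_len(G), gvocab)
    comp_j <- c(seq_len(V),
                V + unlist(lapply(grams, function(g) unname(gidx[g])),
                           use.names = FALSE))
    comp_i <- c(seq_len(V),
                rep(seq_len(V), vapply(grams, length, integer(1))))
  } else {
    G <- 0
    gvocab <- character(0)
    comp_i <- seq_len(V)
    comp_j <- seq_len(V)
  }
  A <- Matrix::sparseMatrix(i = comp_i, j = comp_j, x = 1,
                            dims = c(V, V + G))
  A <- A / Matrix::rowSums(A)  # mean over components

  unig <- as.numeric(counts[vocab])^0.75
  unig <- unig / sum(unig)

  with_seed(derive_seed(seed, "skipgram"), {
    Z <- matrix(runif((V + G) * dim, -0.5, 0.5) / dim, nrow = V + G)
    O <- matrix(0, nrow = V, ncol = dim)

    ids <- lapply(sents, function(s) unname(widx[s[s %in% vocab]]))
    ids <- Filter(function(s) length(s) >= 2, ids)

    # materialize (center, context) pairs once; reshuffled each epoch
    pair_c <- integer(0); pair_o <- integer(0)
    for (s in ids) {
      n <- length(s)
      b <- sample.int(window, n, replace = TRUE)
      for (t in seq_len(n)) {
        lo <- max(1L, t - b[[t]]); hi <- min(n, t + b[[t]])
        ctx <- setdiff(lo:hi, t)
        pair_c <- c(pair_c, rep(s[[t]], length(ctx)))
        pair_o <- c(pair_o, s[ctx])
      }
    }
    np <- length(pair_c)
    batch <- 512L
    total_steps <- epochs * ceiling(np / batch)
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(np)
      pc <- pair_c[ord]; po <- pair_o[ord]
      starts <- seq(1L, np, by = batch)
      for (st in starts) {
        step <- step + 1L
        cur_lr <- lr * max(0.1, 1 - step / total_steps)
        sel <- st:min(st + batch - 1L, np)
        cb <- pc[sel]; ob <- po[sel]
        B <- length(sel)
        Ab <- A[cb, , drop = FALSE]
        U <- as.matrix(Ab %*% Z)                       # B x dim inputs
        negm <- matrix(sample.int(V, B * negative, replace = TRUE,
                                  prob = unig), nrow = B)
        dU <- matrix(0, B, dim)
        dO_idx <- c(ob, as.vector(negm))
        dO_val <- matrix(0, B * (1 + negative), dim)
        # positive pairs
        Oo <- O[ob, , drop = FALSE]
        gpos <- 1 / (1 + exp(-rowSums(U * Oo))) - 1    # sigmoid(s) - 1
        dU <- dU + gpos * Oo
        dO_val[seq_len(B), ] <- gpos * U
        # negative pairs
        for (k in seq_len(negative)) {
          nk <- negm[, k]
          On <- O[nk, , drop = FALSE]
          gneg <- 1 / (1 + exp(-rowSums(U * On)))      # sigmoid(s) - 0
          dU <- dU + gneg * On
          dO_val[B * k + seq_len(B), ] <- gneg * U
        }
        upd_O <- rowsum(dO_val, dO_idx)
        O[as.integer(rownames(upd_O)), ] <-
          O[as.integer(rownames(upd_O)), ] - cur_lr * upd_O
        dZ <- as.matrix(Matrix::crossprod(Ab, dU))
        nz <- which(rowSums(abs(dZ)) > 0)
        Z[nz, ] <- Z[nz, ] - cur_lr * dZ[nz, , drop = FALSE]
      }
    }
    word_vecs <- as.matrix(A %*% Z)
    rownames(word_vecs) <- vocab
    ngv <- NULL
    if (subword) {
      ngv <- Z[V + seq_len(G), , drop = FALSE]
      rownames(ngv) <- gvocab
    }
    embedding_space(word_vecs, ngram_vectors = ngv, ngram_range = ngram_range)
  })
}

#' Import / export embeddings in word2vec text format
#'
#' The first line holds the vocabulary size and dimension; each further line
#' is a token followed by its vector components, space separated. Subword
#' n-gram vectors are not round-tripped through this format.
#'
#' @param space An [embedding_space()].
#' @param path File path.
#' @export
write_word2vec <- function(space, path, ngram_path = NULL) {
  write_vec_table <- function(mat, f) {
    con <- file(f, open = "wt")
    on.exit(close(con))
    writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
    lines <- vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], sprintf("%.8g", mat[i, ])), collapse = " ")
    }, character(1))
    writeLines(lines, con)
  }
  write_vec_table(space$vectors, path)
  if (!is.null(ngram_path) && !is.null(space$ngram_vectors)) {
    write_vec_table(space$ngram_vectors, ngram_path)
  }
  invisible(space)
}

#' @rdname write_word2vec
#' @param ngram_path Optional companion file for the subword n-gram vectors;
#'   when given, `write_word2vec()` stores them there and `read_word2vec()`
#'   restores a subword-capable space from the pair.
#' @export
read_word2vec <- function(path, ngram_path = NULL) {
  read_vec_table <- function(f) {
    lines <- readLines(f)
    hdr <- as.integer(strsplit(lines[[1]], " ")[[1]])
    parts <- lapply(strsplit(trimws(lines[-1]), "[ \t]+"), function(p) {
      p[nzchar(p)]
    })
    toks <- vapply(parts, `[[`, character(1), 1)
    mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
    rownames(mat) <- toks
    stopifnot(nrow(mat) == hdr[[1]], ncol(mat) == hdr[[2]])
    mat
  }
  ngv <- if (!is.null(ngram_path) && file.exists(ngram_path)) {
    read_vec_table(ngram_path)
  }
  embedding_space(read_vec_table(path), ngram_vectors = ngv)
}
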