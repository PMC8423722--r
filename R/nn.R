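#' Encoder building blocks
#'
#' The disambiguation network encodes an abbreviation occurrence in three
#' steps: (1) a width-1 convolution with ELU activation over the local token
#' window, max-pooled over time into a single hidden vector `v`; (2) an
#' optional global context `g`, the IDF-weighted mean of all word embeddings
#' in the note excluding the abbreviation itself; (3) a fully connected layer
#' with ReLU and L2 normalization mapping `v` (or `[v; g]`) to the final
#' sample embedding `e`. Classification takes the dot product of `e` with a
#' per-expansion embedding matrix `H` and applies a softmax.
#'
#' These exported functions compute each step for a single sample; training
#' uses an equivalent batched path.
#'
#' @name encoder
NULL

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

#' @rdname encoder
#' @param window Character vector of window tokens (may be empty).
#' @param space An [embedding_space()].
#' @param params Encoder parameters: a list with `W1` (hidden x dim), `b`
#'   (hidden), `W2` (out x zdim).
#' @return `encode_local()` returns the pooled hidden vector `v`
#'   (`max over t of ELU(W1 x_t + b)`); an empty window gives the zero
#'   vector.
#' @export
encode_local <- function(window, space, params) {
  h <- nrow(params$W1)
  if (length(window) == 0) return(rep(0, h))
  X <- t(embedding_lookup(space, window))       # dim x T
  if (nrow(X) != ncol(params$W1)) abort("token vectors of wrong dimension")
  act <- elu(params$W1 %*% X + params$b)
  apply(act, 1, max)
}

#' @rdname encoder
#' @param document_tokens All tokens of the note.
#' @param abbrev_positions Integer indices of the abbreviation occurrence(s)
#'   in `document_tokens`; these positions are excluded from the average.
#' @param idf An IDF table from [compute_idf()].
#' @return `global_context()` returns the IDF-weighted mean embedding of the
#'   remaining tokens (zero vector when the weight mass is zero).
#' @export
global_context <- function(document_tokens, abbrev_positions, space, idf) {
  keep <- setdiff(seq_along(document_tokens), abbrev_positions)
  if (length(keep) == 0) return(rep(0, space$dim))
  toks <- document_tokens[keep]
  w <- idf_lookup(idf, toks)
  if (sum(w) == 0) return(rep(0, space$dim))
  U <- embedding_lookup(space, toks)
  colSums(U * w) / sum(w)
}

#' @rdname encoder
#' @param v Local pooled vector from `encode_local()`.
#' @param g Optional global context vector; when supplied the layer input is
#'   the concatenation `[v; g]`.
#' @return `encode_sample()` returns the L2-normalized
#'   `ReLU(W2 z) / ||ReLU(W2 z)||`; if the ReLU output is identically zero
#'   the zero vector is returned unnormalized.
#' @export
encode_sample <- function(v, g = NULL, params) {
  z <- c(v, g)
  if (length(z) != ncol(params$W2)) abort("dimension mismatch with W2")
  r <- pmax(as.vector(params$W2 %*% z), 0)
  n <- sqrt(sum(r^2))
  if (n == 0) return(r)
  r / n
}

#' @rdname encoder
#' @param e Encoded sample vector.
#' @param H Expansion embedding matrix, one row per candidate expansion.
#' @return `classify()` returns the softmax probability vector
#'   `p(c | e) = exp(H_c . e) / sum_c' exp(H_c' . e)`.
#' @export
classify <- function(e, H) {
  s <- as.vector(H %*% e)
  s <- s - max(s)
  p <- exp(s)
  p / sum(p)
}

# ---- batched training engine --------------------------------------------

default_nn_config <- function(...) {
  cfg <- list(hidden_dim = 100, output_dim = 100, use_global = TRUE,
              lr = 0.01, epochs = 100, batch_size = 64, seed = 1)
  utils::modifyList(cfg, list(...))
}

# Precompute per-sample tensors: padded window embeddings and global vectors.
prepare_encoder_inputs <- function(samples, space, idf, use_global = TRUE,
                                   labels = NULL) {
  n <- nrow(samples)
  d0 <- space$dim
  maxT <- max(1L, vapply(samples$window, length, integer(1)))
  X <- matrix(0, d0, n * maxT)
  valid <- rep(FALSE, n * maxT)
  for (i in seq_len(n)) {
    win <- samples$window[[i]]
    if (length(win) == 0) next
    cols <- (i - 1L) * maxT + seq_along(win)
    X[, cols] <- t(embedding_lookup(space, win))
    valid[cols] <- TRUE
  }
  G <- NULL
  if (use_global) {
    G <- matrix(0, d0, n)
    for (i in seq_len(n)) {
      G[, i] <- global_context(samples$document_tokens[[i]],
                               samples$abbrev_positions[[i]], space, idf)
    }
  }
  y <- if (!is.null(labels)) match(samples$label, labels) else NULL
  list(X = X, valid = valid, maxT = maxT, n = n, G = G, y = y, d0 = d0)
}

subset_inputs <- function(inputs, idx) {
  maxT <- inputs$maxT
  cols <- as.vector(outer(seq_len(maxT), (idx - 1L) * maxT, `+`))
  list(X = inputs$X[, cols, drop = FALSE],
       valid = inputs$valid[cols],
       maxT = maxT, n = length(idx),
       G = if (!is.null(inputs$G)) inputs$G[, idx, drop = FALSE],
       y = inputs$y[idx], d0 = inputs$d0)
}

init_encoder_params <- function(d0, hidden, out, zdim) {
  glorot <- function(nr, nc) {
    s <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -s, s), nr, nc)
  }
  list(W1 = glorot(hidden, d0), b = rep(0, hidden), W2 = glorot(out, zdim))
}

# Forward pass over a prepared batch. Returns probabilities, loss and the
# caches needed for the backward pass. `H` is the (n_class x out) classifier.
encoder_forward <- function(par, H, batch) {
  h <- nrow(par$W1)
  B <- batch$n
  maxT <- batch$maxT
  pre <- par$W1 %*% batch$X + par$b                      # h x (B*maxT)
  act <- elu(pre)
  act[, !batch$valid] <- -Inf
  arr <- array(act, c(h, maxT, B))
  v <- arr[, 1, , drop = FALSE]
  dim(v) <- c(h, B)
  argm <- matrix(1L, h, B)
  if (maxT > 1) {
    for (t in 2:maxT) {
      sl <- arr[, t, , drop = FALSE]
      dim(sl) <- c(h, B)
      better <- sl > v
      v[better] <- sl[better]
      argm[better] <- t
    }
  }
  empty <- !is.finite(v)          # columns of all-padding samples
  v[empty] <- 0
  z <- if (!is.null(batch$G)) rbind(v, batch$G) else v
  r <- pmax(par$W2 %*% z, 0)                             # out x B
  nrm <- sqrt(colSums(r^2))
  e <- r
  nz <- nrm > 0
  if (any(nz)) e[, nz] <- sweep(r[, nz, drop = FALSE], 2, nrm[nz], `/`)
  s <- H %*% e                                            # C x B
  s <- sweep(s, 2, apply(s, 2, max))
  p <- exp(s)
  p <- sweep(p, 2, colSums(p), `/`)
  loss <- if (!is.null(batch$y)) {
    -mean(log(pmax(p[cbind(batch$y, seq_len(B))], 1e-300)))
  }
  list(p = p, loss = loss, v = v, z = z, r = r, nrm = nrm, e = e,
       pre = pre, argm = argm, empty = empty)
}

encoder_backward <- function(par, H, batch, fw) {
  h <- nrow(par$W1)
  B <- batch$n
  maxT <- batch$maxT
  dlog <- fw$p
  dlog[cbind(batch$y, seq_len(B))] <- dlog[cbind(batch$y, seq_len(B))] - 1
  dlog <- dlog / B
  dH <- dlog %*% t(fw$e)
  de <- t(H) %*% dlog                                    # out x B
  dr <- matrix(0, nrow(fw$r), B)
  nz <- fw$nrm > 0
  if (any(nz)) {
    en <- fw$e[, nz, drop = FALSE]
    den <- de[, nz, drop = FALSE]
    dr[, nz] <- sweep(den - sweep(en, 2, colSums(en * den), `*`),
                      2, fw$nrm[nz], `/`)
  }
  dr[fw$r <= 0] <- 0
  dW2 <- dr %*% t(fw$z)
  dz <- t(par$W2) %*% dr
  dv <- dz[seq_len(h), , drop = FALSE]
  dv[fw$empty] <- 0
  rows <- rep(seq_len(h), B)
  cols <- rep((seq_len(B) - 1L) * maxT, each = h) + as.vector(fw$argm)
  pre_at <- fw$pre[cbind(rows, cols)]
  dact <- as.vector(dv) * elu_grad(pre_at)
  dact[as.vector(fw$empty)] <- 0
  M <- matrix(0, h, B * maxT)
  M[cbind(rows, cols)] <- dact
  dW1 <- M %*% t(batch$X)
  db <- rowSums(M)
  dG <- if (!is.null(batch$G)) dz[(h + 1):nrow(dz), , drop = FALSE]
  list(dW1 = dW1, db = db, dW2 = dW2, dH = dH, dG = dG)
}

# Mini-batch SGD over a prepared training set. `classifier` is either a
# plain dense H (trained directly) or an ancestor-sum structure
# (list(A = sparse closure over raw rows, H_raw)) where gradients on the
# effective rows are pushed onto a raw matrix through t(A).
fit_encoder <- function(train, val, n_class, config, init = NULL,
                        hier = NULL, H_init = NULL) {
  cfg <- config
  with_seed(derive_seed(cfg$seed, "fit"), {
    d0 <- train$d0
    zdim <- if (!is.null(train$G)) cfg$hidden_dim + d0 else cfg$hidden_dim
    par <- if (!is.null(init)) {
      list(W1 = init$W1, b = init$b, W2 = init$W2)
    } else {
      init_encoder_params(d0, cfg$hidden_dim, cfg$output_dim, zdim)
    }
    if (!is.null(hier)) {
      H_raw <- if (!is.null(H_init)) H_init else
        matrix(rnorm(ncol(hier$A) * cfg$output_dim, sd = 0.1),
               ncol(hier$A), cfg$output_dim,
               dimnames = list(colnames(hier$A), NULL))
    } else {
      H <- if (!is.null(H_init)) H_init else
        matrix(rnorm(n_class * cfg$output_dim, sd = 0.1),
               n_class, cfg$output_dim)
    }
    eff_H <- function() {
      if (!is.null(hier)) as.matrix(hier$A_class %*% H_raw) else H
    }
    eval_loss <- function(inputs) {
      if (is.null(inputs) || inputs$n == 0) return(NA_real_)
      encoder_forward(par, eff_H(), inputs)$loss
    }
    best <- list(loss = Inf)
    history <- vector("list", cfg$epochs)
    n <- train$n
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tr_loss <- 0
      nb <- 0
      for (st in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[st:min(st + cfg$batch_size - 1L, n)]
        batch <- subset_inputs(train, idx)
        Hc <- eff_H()
        fw <- encoder_forward(par, Hc, batch)
        gr <- encoder_backward(par, Hc, batch, fw)
        par$W1 <- par$W1 - cfg$lr * gr$dW1
        par$b <- par$b - cfg$lr * gr$db
        par$W2 <- par$W2 - cfg$lr * gr$dW2
        if (!is.null(hier)) {
          H_raw <- H_raw - cfg$lr *
            as.matrix(Matrix::crossprod(hier$A_class, gr$dH))
        } else {
          H <- H - cfg$lr * gr$dH
        }
        tr_loss <- tr_loss + fw$loss
        nb <- nb + 1
      }
      vl <- eval_loss(val)
      score <- if (is.na(vl)) tr_loss / nb else vl
      history[[ep]] <- tibble(epoch = ep, train_loss = tr_loss / nb,
                              val_loss = vl)
      if (score < best$loss) {
        best <- list(loss = score, par = par,
                     H = if (is.null(hier)) H, H_raw = if (!is.null(hier)) H_raw,
                     epoch = ep)
      }
    }
    list(params = best$par, H = best$H, H_raw = best$H_raw,
         best_epoch = best$epoch, best_loss = best$loss,
         history = dplyr::bind_rows(history))
  })
}
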