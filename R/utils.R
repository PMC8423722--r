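#' @importFrom rlang abort warn %||% hash .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif setNames predict
#' @importFrom utils head tail
NULL

# Deterministic child seed: mixes a user seed with a stage label so that
# independent stages draw from independent streams. Kept below 2^31.
derive_seed <- function(seed, salt) {
  bytes <- utf8ToInt(salt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483629 + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Join a multi-word phrase into the single-token form used throughout:
# lowercased, alphanumeric tokens glued with "_".
join_phrase <- function(phrase) {
  vapply(as.character(phrase), function(p) {
    toks <- tokenize_string(p)
    if (length(toks) == 0) return("")
    paste(unlist(toks, use.names = FALSE), collapse = "_")
  }, character(1), USE.NAMES = FALSE)
}

split_phrase_token <- function(token) {
  strsplit(token, "_", fixed = TRUE)
}
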