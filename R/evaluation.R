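#' Score predictions with micro and macro accuracy
#'
#' Micro accuracy is the total number of correctly disambiguated occurrences
#' divided by the total number of test occurrences, pooled across
#' abbreviations; macro accuracy is the unweighted mean of per-abbreviation
#' accuracies and better reflects performance on imbalanced inventories.
#' Abbreviations with fewer than two candidate expansions are excluded when
#' an inventory is supplied (their disambiguation is trivial).
#'
#' @param predictions A data frame with columns `abbreviation`, `predicted`,
#'   `label` (the gold expansion).
#' @param inventory Optional sense inventory used for the two-or-more
#'   expansions exclusion rule; predictions for abbreviations absent from it
#'   are an error.
#' @param bootstrap Number of bootstrap resamples for per-abbreviation means
#'   (0 to skip; default 0).
#' @param seed Seed for the bootstrap.
#' @return An object of class `abbrev_eval`: a list with `per_abbreviation`
#'   (tibble), `micro`, `macro`, `n`.
#' @export
score_predictions <- function(predictions, inventory = NULL, bootstrap = 0,
                              seed = 1) {
  if (nrow(predictions) == 0) abort("no predictions to score")
  stopifnot(all(c("abbreviation", "predicted", "label") %in%
                  names(predictions)))
  if (!is.null(inventory)) {
    inventory <- validate_inventory(inventory)
    unknown <- setdiff(predictions$abbreviation, inventory$abbreviation)
    if (length(unknown) > 0) {
      abort(paste0("abbreviation(s) absent from inventory: ",
                   paste(unknown, collapse = ", ")))
    }
    n_exp <- table(inventory$abbreviation)
    keep <- predictions$abbreviation %in%
      names(n_exp)[n_exp >= 2]
    predictions <- predictions[keep, ]
    if (nrow(predictions) == 0) {
      abort("no predictions left after excluding single-expansion abbreviations")
    }
  }
  correct <- predictions$predicted == predictions$label
  per <- dplyr::summarise(
    dplyr::group_by(predictions, abbreviation = .data$abbreviation),
    n_samples = dplyr::n(),
    accuracy = mean(.data$predicted == .data$label),
    .groups = "drop"
  )
  if (bootstrap > 0) {
    bs <- lapply(split(correct, predictions$abbreviation), function(cc) {
      bootstrap_accuracy(cc, n_resamples = bootstrap,
                         seed = derive_seed(seed, "score-boot"))
    })
    per$bootstrap_mean <- vapply(per$abbreviation,
                                 function(a) bs[[a]]$mean, numeric(1))
    per$ci_lower <- vapply(per$abbreviation,
                           function(a) bs[[a]]$ci[[1]], numeric(1))
    per$ci_upper <- vapply(per$abbreviation,
                           function(a) bs[[a]]$ci[[2]], numeric(1))
  }
  structure(
    list(per_abbreviation = per,
         micro = mean(correct),
         macro = mean(per$accuracy),
         n = nrow(predictions)),
    class = "abbrev_eval"
  )
}

#' @export
print.abbrev_eval <- function(x, ...) {
  cat(sprintf("<abbrev_eval: %d samples, %d abbreviations>\n",
              x$n, nrow(x$per_abbreviation)))
  cat(sprintf("  micro accuracy: %.4f\n  macro accuracy: %.4f\n",
              x$micro, x$macro))
  invisible(x)
}

#' Bootstrap the accuracy of one abbreviation
#'
#' Resamples the (prediction, gold) pairs with replacement `n_resamples`
#' times (999 by default) and reports the mean resampled accuracy plus a
#' 2.5/97.5 percentile interval.
#'
#' @param correct Logical vector (or a data frame with `predicted` and
#'   `label` columns) marking correct predictions.
#' @param n_resamples Number of resamples (default 999).
#' @param seed Integer seed; results are reproducible given it.
#' @return A list with `mean`, `ci` (length-2 numeric), `n_resamples`.
#' @export
bootstrap_accuracy <- function(correct, n_resamples = 999, seed = 1) {
  if (is.data.frame(correct)) {
    correct <- correct$predicted == correct$label
  }
  n <- length(correct)
  if (n == 0) abort("need at least one prediction")
  with_seed(derive_seed(seed, "bootstrap"), {
    accs <- vapply(seq_len(n_resamples), function(i) {
      mean(correct[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    list(mean = mean(accs),
         ci = unname(stats::quantile(accs, c(0.025, 0.975))),
         n_resamples = n_resamples)
  })
}

#' One-sided Wilcoxon signed-rank comparison of paired accuracies
#'
#' Tests the alternative "model A is better than model B" on paired
#' per-abbreviation accuracies. Zero differences are dropped (standard
#' signed-rank practice); with `n <= 15` informative pairs the null
#' distribution is enumerated exactly over all sign assignments (ties in the
#' absolute differences get average ranks), above that a normal
#' approximation with tie correction and continuity correction is used. When
#' every difference is zero the comparison is undefined and `p = 1` is
#' returned with `all_zero = TRUE`.
#'
#' @param acc_a,acc_b Equal-length numeric vectors of per-abbreviation
#'   accuracies for models A and B.
#' @return A list with `p_value`, `statistic` (the positive-rank sum `V`),
#'   `n_used`, `method`, `all_zero`.
#' @export
compare_models <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) abort("paired vectors differ in length")
  d <- acc_a - acc_b
  d <- d[d != 0]
  if (length(d) == 0) {
    return(list(p_value = 1, statistic = NA_real_, n_used = 0L,
                method = "degenerate", all_zero = TRUE))
  }
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 15) {
    # exact: enumerate all 2^n sign assignments of the observed ranks
    stats_all <- signed_rank_enumeration(r)
    p <- mean(stats_all >= v)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - 0.5) / sqrt(sig2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal approximation"
  }
  list(p_value = p, statistic = v, n_used = n, method = method,
       all_zero = FALSE)
}

# All positive-rank sums over the 2^n sign assignments of ranks r.
signed_rank_enumeration <- function(r) {
  n <- length(r)
  sums <- 0
  for (i in seq_len(n)) {
    sums <- c(sums, sums + r[[i]])
  }
  sums
}

#' Write / read an evaluation report
#'
#' Per-abbreviation results as TSV plus a JSON summary with micro and macro
#' accuracy.
#'
#' @param report An `abbrev_eval` object.
#' @param tsv_file,json_file Output paths (either may be `NULL`).
#' @export
write_eval_report <- function(report, tsv_file = NULL, json_file = NULL) {
  if (!is.null(tsv_file)) {
    readr::write_tsv(report$per_abbreviation, tsv_file, progress = FALSE)
  }
  if (!is.null(json_file)) {
    jsonlite::write_json(
      list(micro = report$micro, macro = report$macro, n = report$n),
      json_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(tsv_file, json_file) {
  per <- readr::read_tsv(tsv_file, show_col_types = FALSE, progress = FALSE)
  summ <- jsonlite::fromJSON(json_file)
  structure(list(per_abbreviation = per, micro = summ$micro,
                 macro = summ$macro, n = summ$n),
            class = "abbrev_eval")
}
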