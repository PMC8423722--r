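#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidiers for fitted disambiguation models
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' summary of the fit.
#'
#' @param x An `abbrev_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.abbrev_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(epoch = integer(), train_loss = numeric(),
                  val_loss = numeric()))
  }
  x$history
}

#' @rdname tidy.abbrev_model
#' @export
#' @exportS3Method generics::glance
glance.abbrev_model <- function(x, ...) {
  tibble(
    abbreviation = x$abbreviation,
    n_expansions = length(x$expansions),
    strategy = x$strategy %||% NA_character_,
    temperature = x$temperature %||% NA_real_,
    best_epoch = x$best_epoch,
    validation_loss = x$validation_loss,
    n_parameters = length(x$params$W1) + length(x$params$b) +
      length(x$params$W2) + length(x$H)
  )
}

#' Tidiers for evaluation reports
#'
#' `tidy()` returns the per-abbreviation accuracy table; `glance()` the
#' micro/macro summary.
#'
#' @param x An `abbrev_eval`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.abbrev_eval <- function(x, ...) {
  x$per_abbreviation
}

#' @rdname tidy.abbrev_eval
#' @export
#' @exportS3Method generics::glance
glance.abbrev_eval <- function(x, ...) {
  tibble(micro = x$micro, macro = x$macro, n = x$n,
         n_abbreviations = nrow(x$per_abbreviation))
}

#' Plot a model's training history
#'
#' @param object An `abbrev_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.abbrev_model <- function(object, ...) {
  hist <- tidy(object)
  long <- tidyr::pivot_longer(hist, c("train_loss", "val_loss"),
                              names_to = "series", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(title = paste0("Training history: ", object$abbreviation),
                  x = "epoch", y = "cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-abbreviation accuracies of an evaluation
#'
#' @param object An `abbrev_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.abbrev_eval <- function(object, ...) {
  per <- object$per_abbreviation
  p <- ggplot2::ggplot(per, ggplot2::aes(
    x = stats::reorder(.data$abbreviation, .data$accuracy),
    y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$macro, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "accuracy",
                  title = sprintf("macro %.3f / micro %.3f",
                                  object$macro, object$micro)) +
    ggplot2::theme_minimal()
  if ("ci_lower" %in% names(per)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      width = 0.3)
  }
  p
}
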