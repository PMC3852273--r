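#' Tidy a LOOCV result
#'
#' @param x a `loocv_svm` object
#' @param ... unused
#' @return tibble: gene, label, predicted, fold
#' @method tidy loocv_svm
#' @export
tidy.loocv_svm <- function(x, ...) x$predictions

#' One-row summary of a LOOCV result
#'
#' @inheritParams tidy.loocv_svm
#' @return tibble with overall and per-class accuracy (%) and the SVM
#'   parameters
#' @method glance loocv_svm
#' @export
glance.loocv_svm <- function(x, ...) {
  pc <- x$per_class
  tibble::tibble(
    n = nrow(x$predictions),
    accuracy = x$accuracy,
    accuracy_positive = pc$accuracy[pc$label == 1L],
    accuracy_background = pc$accuracy[pc$label == 0L],
    kernel = x$params$kernel,
    cost = x$params$cost,
    gamma = x$params$gamma
  )
}

#' Tidy a motif pattern
#'
#' @param x a `motif_pattern`
#' @param ... unused
#' @return tibble of required cells: motif, bin, strand
#' @method tidy motif_pattern
#' @export
tidy.motif_pattern <- function(x, ...) x$cells

#' One-row summary of a motif pattern
#'
#' @inheritParams tidy.motif_pattern
#' @method glance motif_pattern
#' @export
glance.motif_pattern <- function(x, ...) {
  tibble::tibble(structure = x$structure, n_cells = nrow(x$cells),
                 n_motifs = length(unique(x$cells$motif)),
                 threshold = x$threshold, n_promoters = x$n_promoters)
}

#' Tidy a motif comparison
#'
#' @param x a `motif_comparison`
#' @param ... unused
#' @method tidy motif_comparison
#' @export
tidy.motif_comparison <- function(x, ...) {
  tibble::tibble(query = x$query, match = x$match, shift = x$shift,
                 orientation = x$orientation, score = x$score,
                 p_value = x$p_value, verdict = x$verdict)
}

#' Plot a bin-by-strand presence table
#'
#' Tile plot of presence fractions per motif and bin, faceted by strand.
#'
#' @param object a `presence_table` from [bin_presence()]
#' @param ... unused
#' @return a ggplot object
#' @method autoplot presence_table
#' @export
autoplot.presence_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$bin), y = .data$motif,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::facet_wrap(~strand, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "promoter bin (1 = TLS-proximal)", y = NULL,
                  fill = "presence") +
    ggplot2::theme_minimal()
}

#' Plot a motif pattern
#'
#' Tiles mark the required (motif, bin, strand) cells.
#'
#' @param object a `motif_pattern`
#' @param ... unused
#' @method autoplot motif_pattern
#' @export
autoplot.motif_pattern <- function(object, ...) {
  cells <- object$cells
  ggplot2::ggplot(cells, ggplot2::aes(x = factor(.data$bin, levels = 1:4),
                                      y = .data$motif)) +
    ggplot2::geom_tile(fill = "steelblue", color = "grey30") +
    ggplot2::facet_wrap(~strand, labeller = ggplot2::label_both) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "promoter bin (1 = TLS-proximal)", y = NULL,
                  title = paste0("required cells (presence > ",
                                 object$threshold, ")")) +
    ggplot2::theme_minimal()
}

#' Plot LOOCV accuracy by class
#'
#' @param object a `loocv_svm`
#' @param ... unused
#' @method autoplot loocv_svm
#' @export
autoplot.loocv_svm <- function(object, ...) {
  df <- object$per_class
  df$class <- ifelse(df$label == 1L, "positive", "background")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_hline(yintercept = object$accuracy, linetype = 2) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(y = "leave-one-out accuracy (%)", x = NULL,
                  title = sprintf("overall accuracy %.1f%%", object$accuracy)) +
    ggplot2::theme_minimal()
}
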