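#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a precision-recall curve
#'
#' Draws the step curve with the chance-level baseline as a dotted
#' horizontal line and the average precision in the subtitle.
#'
#' @param object A [pr_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  baseline <- pr_baseline(attr(object, "n_pos"), attr(object, "n_neg"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall,
                                       y = .data$precision)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_hline(yintercept = baseline, linetype = "dotted") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      subtitle = sprintf("average precision %.3f (baseline %.3f)",
                         average_precision(object), baseline)
    ) +
    ggplot2::theme_minimal()
}

#' Plot decile odds-ratio enrichment
#'
#' Bars of the per-decile odds ratio of pathogenic to benign variants
#' with 95% confidence-interval whiskers; the dotted line marks an odds
#' ratio of 1 (no enrichment).
#'
#' @param object An [odds_ratio_enrichment()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$bin <- sprintf("%.1f-%.1f", (df$decile - 1) / 10, df$decile / 10)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$odds_ratio)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Score decile", y = "Odds ratio (log scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a regional constraint profile
#'
#' Constraint scores of the model's retained regions along the genome,
#' on the display (log) scale, one panel per chromosome.
#'
#' @param object A `constraint_model`.
#' @param display `"log"` (default) for the -10 log10(1 - s) transform,
#'   `"raw"` for the normalized score.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.constraint_model <- function(object, display = c("log", "raw"),
                                      ...) {
  display <- match.arg(display)
  df <- object$regions
  df$y <- if (display == "log") log_display_score(df$constraint_score)
          else df$constraint_score
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$y)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "Genomic position (bp)",
      y = if (display == "log") "-10 log10(1 - constraint)"
          else "Constraint score"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation PR curves
#'
#' @param object A `splice_cv` from [cross_validate_ensemble()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splice_cv <- function(object, ...) {
  df <- purrr::map2(object$folds$curve, object$folds$fold,
                    ~ dplyr::mutate(tibble::as_tibble(.x),
                                    fold = factor(.y))) |>
    dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   color = .data$fold)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", color = "Fold") +
    ggplot2::theme_minimal()
}
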