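#' Precision-recall curve
#'
#' Computes precision and recall at every distinct observed score,
#' thresholds descending, predicting pathogenic when `score >= threshold`
#' (no interpolation between thresholds).
#'
#' @param scores Numeric prediction scores.
#' @param labels Character labels, `"pathogenic"` / `"benign"` (or a
#'   logical vector, `TRUE` = pathogenic).
#' @return A `pr_curve` tibble (`threshold`, `precision`, `recall`), with
#'   the class counts in attributes `n_pos` and `n_neg`.
#' @export
pr_curve <- function(scores, labels) {
  if (is.logical(labels)) {
    labels <- ifelse(labels, "pathogenic", "benign")
  }
  pos <- labels == "pathogenic"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("both classes are required for a precision-recall curve")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # cumulative confusion counts at each distinct threshold
  is_last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[is_last]
  n_called <- seq_along(s)[is_last]
  out <- tibble::tibble(
    threshold = s[is_last],
    precision = tp / n_called,
    recall = tp / n_pos
  )
  structure(out, class = c("pr_curve", class(out)),
            n_pos = n_pos, n_neg = n_neg)
}

#' Step-weighted average precision of a PR curve
#'
#' `sum_i (R_i - R_{i-1}) * P_i` over the curve's thresholds (descending,
#' so recall is non-decreasing), with `R_0 = 0`. Equals 1 exactly when
#' every pathogenic score strictly exceeds every benign score.
#'
#' @param curve A [pr_curve()].
#' @return Average precision in \[0, 1\].
#' @export
average_precision <- function(curve) {
  sum(diff(c(0, curve$recall)) * curve$precision)
}

#' Trapezoidal area under a PR curve
#'
#' A secondary summary: the trapezoid-rule area over (recall, precision)
#' points. The step-sum [average_precision()] is the primary metric.
#'
#' @param curve A [pr_curve()].
#' @return Area in \[0, 1\].
#' @export
pr_auc <- function(curve) {
  r <- c(0, curve$recall)
  p <- c(curve$precision[1], curve$precision)
  sum(diff(r) * (utils::head(p, -1) + p[-1]) / 2)
}

#' Baseline (chance-level) precision
#'
#' The precision of a random classifier: the pathogenic fraction of the
#' evaluation set, `P / (P + B)`.
#'
#' @param n_pathogenic,n_benign Class counts.
#' @return The baseline value.
#' @export
pr_baseline <- function(n_pathogenic, n_benign) {
  if (n_pathogenic + n_benign == 0) {
    rlang::abort("baseline undefined for an empty evaluation set")
  }
  n_pathogenic / (n_pathogenic + n_benign)
}

#' Decile bin assignment for scores in \[0, 1\]
#'
#' Bins are left-closed, right-open -- a score equal to a bin's lower
#' edge belongs to that bin -- except the last bin, which also includes
#' its upper edge so that a score of exactly 1.0 lands in bin 10.
#'
#' @param score Numeric scores in \[0, 1\].
#' @return Integer bin indices 1..10.
#' @export
decile_index <- function(score) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    rlang::abort("decile binning is defined on [0, 1]")
  }
  pmin(findInterval(score, seq(0, 1, by = 0.1), rightmost.closed = TRUE),
       10L)
}

#' Odds-ratio enrichment of pathogenic variants across score deciles
#'
#' For each decile i, forms the 2x2 table of pathogenic/benign counts in
#' versus outside the decile and computes
#' `OR_i = (A_i / B_i) / (C_i / D_i)` with the log-scale 95% confidence
#' interval `exp(ln OR +/- 1.96 * se)`,
#' `se = sqrt(1/A + 1/B + 1/C + 1/D)`. Deciles with any zero cell get the
#' Haldane-Anscombe correction (0.5 added to all four cells) and are
#' flagged.
#'
#' @param scores Prediction scores in \[0, 1\].
#' @param labels `"pathogenic"` / `"benign"` labels.
#' @return An `enrichment_table` tibble: `decile`, `A`, `B`, `C`, `D`,
#'   `odds_ratio`, `se`, `ci_lo`, `ci_hi`, `corrected`.
#' @export
odds_ratio_enrichment <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "pathogenic", "benign")
  pos <- labels == "pathogenic"
  if (!any(pos) || all(pos)) {
    rlang::abort("both classes are required for enrichment")
  }
  dec <- decile_index(scores)
  total_p <- sum(pos)
  total_b <- sum(!pos)
  out <- purrr::map(1:10, function(i) {
    a <- sum(pos & dec == i)
    b <- sum(!pos & dec == i)
    cc <- total_p - a
    d <- total_b - b
    corrected <- any(c(a, b, cc, d) == 0)
    if (corrected) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    or <- (a / b) / (cc / d)
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    tibble::tibble(
      decile = i, A = a, B = b, C = cc, D = d,
      odds_ratio = or, se = se,
      ci_lo = exp(log(or) - 1.96 * se),
      ci_hi = exp(log(or) + 1.96 * se),
      corrected = corrected
    )
  }) |>
    dplyr::bind_rows()
  structure(out, class = c("enrichment_table", class(out)),
            n_pos = total_p, n_neg = total_b)
}

#' Stratified variant subsets for evaluation
#'
#' Composable filtering rules matching the clinically motivated strata:
#' `"drop_canonical"` removes variants at the canonical acceptor/donor
#' dinucleotides (A-1, A-2, D+1, D+2); `"drop_splice_region"` removes the
#' whole splice region (up to 8 intronic and 3 exonic bases from a
#' junction, canonical sites included); `"low_spliceai"` keeps only
#' variants whose max splice-prediction score is below 0.2 (the range
#' routinely ignored when triaging by splice predictions alone).
#'
#' @param examples Tibble carrying `rel_pos` and (for `low_spliceai`) a
#'   `spliceai` column.
#' @param rules Character vector of rule names, applied in order.
#' @return The filtered tibble.
#' @export
subset_filter <- function(examples, rules) {
  known <- c("drop_canonical", "drop_splice_region", "low_spliceai")
  bad <- setdiff(rules, known)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown subset rule(s): ",
                        paste(bad, collapse = ", ")))
  }
  for (r in rules) {
    examples <- switch(
      r,
      drop_canonical =
        examples[!examples$rel_pos %in% canonical_site_labels(), ,
                 drop = FALSE],
      drop_splice_region =
        examples[!examples$rel_pos %in% splice_region_labels(), ,
                 drop = FALSE],
      low_spliceai =
        examples[examples$spliceai < 0.2, , drop = FALSE]
    )
  }
  examples
}

#' Evaluation report over methods and subsets
#'
#' Summarizes one or more score columns on an evaluation set (optionally
#' within a stratified subset) as a tidy report row per method: class
#' counts, step-sum average precision, trapezoidal PR area and baseline.
#'
#' @param examples Labeled evaluation tibble.
#' @param methods Named list mapping a method name to its score column.
#' @param subset Optional character vector of [subset_filter()] rules.
#' @return Tibble `method`, `subset`, `n_path`, `n_benign`,
#'   `avg_precision`, `pr_auc`, `baseline`.
#' @export
evaluation_report <- function(examples, methods, subset = character()) {
  if (length(subset) > 0) examples <- subset_filter(examples, subset)
  purrr::imap(methods, function(col, nm) {
    curve <- pr_curve(examples[[col]], examples$label)
    tibble::tibble(
      method = nm,
      subset = if (length(subset) == 0) "all" else
        paste(subset, collapse = "+"),
      n_path = attr(curve, "n_pos"),
      n_benign = attr(curve, "n_neg"),
      avg_precision = average_precision(curve),
      pr_auc = pr_auc(curve),
      baseline = pr_baseline(attr(curve, "n_pos"), attr(curve, "n_neg"))
    )
  }) |>
    dplyr::bind_rows()
}
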