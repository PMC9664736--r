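#' Score binning for summed splice delta scores
#'
#' The per-substitution summed score (AG + AL + DG + DL) lies in \[0, 4\]
#' and is discretized into contiguous half-open bins, the last bin closed.
#' The default is eight bins with finer resolution at low scores, where
#' the vast majority of sites fall. A single bin covering \[0, 4\]
#' produces the splicing-unaware model of constraint.
#'
#' @param edges Increasing numeric vector of bin edges starting at 0 and
#'   ending at 4; `length(edges) - 1` bins result.
#' @return A `score_binning` object.
#' @export
score_binning <- function(edges = default_score_bins()) {
  edges <- as.numeric(edges)
  if (length(edges) < 2 || edges[1] != 0 || edges[length(edges)] != 4 ||
      any(diff(edges) <= 0)) {
    rlang::abort("bin edges must increase from 0 to 4")
  }
  structure(list(edges = edges, n_bins = length(edges) - 1L),
            class = "score_binning")
}

#' Default eight-bin partition of the summed-score range
#' @return Numeric vector of nine edges.
#' @export
default_score_bins <- function() c(0, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0, 2.0, 4.0)

#' @export
print.score_binning <- function(x, ...) {
  cat("<score_binning>", x$n_bins, "bins:",
      paste(sprintf("[%g,%g%s", utils::head(x$edges, -1), x$edges[-1],
                    c(rep(")", x$n_bins - 1), "]")), collapse = " "), "\n")
  invisible(x)
}

#' Map summed scores to bin indices
#' @param score Numeric vector in \[0, 4\].
#' @param binning A [score_binning()].
#' @return Integer bin indices in `1:n_bins`.
#' @export
bin_index <- function(score, binning = score_binning()) {
  if (any(score < 0 | score > 4, na.rm = TRUE)) {
    rlang::abort("summed scores must lie in [0, 4]")
  }
  idx <- findInterval(score, binning$edges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  pmin(idx, binning$n_bins)
}

#' Summed splice score per substitution
#'
#' @param scores Score tibble with `ag`, `al`, `dg`, `dl` columns.
#' @return `scores` with a `sum_score` column (AG + AL + DG + DL).
#' @export
sum_delta_scores <- function(scores) {
  dplyr::mutate(scores,
                sum_score = .data$ag + .data$al + .data$dg + .data$dl)
}

#' Collapse per-substitution scores into one record per site
#'
#' At a site with no retained variant, the summed score is the maximum over
#' the (up to three) possible alternate alleles; at a site carrying a
#' retained variant, the summed score is that of the variant's own
#' ref-to-alt substitution. The informative flag records whether the site
#' carries any splicing signal at all (max summed score > 0).
#'
#' @param site_scores Score tibble from [read_site_scores()].
#' @param variants Retained variants from [filter_population_variants()],
#'   or `NULL` for a variant-free summary.
#' @param binning A [score_binning()].
#' @return Tibble with one row per scored site: `chrom`, `pos`, `ref`,
#'   `max_sum`, `has_variant`, `sum_score` (the value entering the model),
#'   `bin`, `informative`.
#' @export
summarize_sites <- function(site_scores, variants = NULL,
                            binning = score_binning()) {
  per_site <- site_scores |>
    sum_delta_scores() |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref) |>
    dplyr::summarise(max_sum = max(.data$sum_score), .groups = "drop")
  if (!is.null(variants) && nrow(variants) > 0) {
    vsc <- site_scores |>
      sum_delta_scores() |>
      dplyr::semi_join(dplyr::distinct(variants, .data$chrom, .data$pos,
                                       .data$ref, .data$alt),
                       by = c("chrom", "pos", "ref", "alt")) |>
      dplyr::group_by(.data$chrom, .data$pos, .data$ref) |>
      dplyr::summarise(var_sum = max(.data$sum_score), .groups = "drop")
    per_site <- dplyr::left_join(per_site, vsc,
                                 by = c("chrom", "pos", "ref"))
  } else {
    per_site$var_sum <- NA_real_
  }
  per_site |>
    dplyr::mutate(
      has_variant = !is.na(.data$var_sum),
      sum_score = dplyr::coalesce(.data$var_sum, .data$max_sum),
      bin = bin_index(.data$sum_score, binning),
      informative = .data$max_sum > 0
    ) |>
    dplyr::select(-"var_sum") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Restrict a site summary to modelled positions
#'
#' Keeps sites inside merged protein-coding gene intervals of the given
#' chromosome class, outside the exclusion mask and (on X) outside PAR
#' intervals. Sites lacking a score record never enter the summary, so no
#' further handling is needed for them.
#'
#' @param sites Site summary from [summarize_sites()].
#' @param genes Gene models.
#' @param genome A [genome_config()].
#' @param chrom_class `"autosome"` or `"X"`.
#' @param mask Optional exclusion-mask tibble.
#' @return The filtered site summary.
#' @export
restrict_sites <- function(sites, genes, genome, chrom_class = "autosome",
                           mask = NULL) {
  keep_chrom <- genome$chroms$chrom[genome$chroms$chrom_class == chrom_class]
  s <- sites[sites$chrom %in% keep_chrom, , drop = FALSE]
  spans <- gene_spans(genes[genes$chrom %in% keep_chrom, , drop = FALSE])
  s <- s[points_in_intervals(s$chrom, s$pos, spans), , drop = FALSE]
  if (!is.null(mask) && nrow(mask) > 0) {
    s <- s[!points_in_intervals(s$chrom, s$pos, mask), , drop = FALSE]
  }
  if (chrom_class == "X" && nrow(genome$par) > 0) {
    x_chrom <- genome$chroms$chrom[genome$chroms$chrom_class == "X"][1]
    par_ivs <- dplyr::mutate(genome$par, chrom = x_chrom)
    s <- s[!points_in_intervals(s$chrom, s$pos, par_ivs), , drop = FALSE]
  }
  s
}

#' Tally reference-to-alternate substitution counts per (ref, bin) cell
#'
#' Every processed site increments exactly one cell of the ref-allele by
#' score-bin grid, either as a site carrying a retained variant (`n_var`)
#' or as a site with none (`n_novar`).
#'
#' @param sites Restricted site summary (see [restrict_sites()]).
#' @param binning A [score_binning()].
#' @param chrom_class Label stored with the counts.
#' @return Tibble with `4 * n_bins` rows: `chrom_class`, `ref`, `bin`,
#'   `n_var`, `n_novar`.
#' @export
count_substitutions <- function(sites, binning = score_binning(),
                                chrom_class = "autosome") {
  grid <- tidyr::expand_grid(ref = c("A", "C", "G", "T"),
                             bin = seq_len(binning$n_bins))
  counts <- sites |>
    dplyr::group_by(.data$ref, .data$bin) |>
    dplyr::summarise(n_var = sum(.data$has_variant),
                     n_novar = sum(!.data$has_variant), .groups = "drop")
  grid |>
    dplyr::left_join(counts, by = c("ref", "bin")) |>
    dplyr::mutate(
      chrom_class = chrom_class,
      n_var = dplyr::coalesce(.data$n_var, 0L),
      n_novar = dplyr::coalesce(.data$n_novar, 0L)
    ) |>
    dplyr::select("chrom_class", "ref", "bin", "n_var", "n_novar")
}

#' Derive substitution probabilities and genome-wide bin proportions
#'
#' The per-cell substitution probability is the fraction of sites in that
#' (ref allele, score bin) cell that carry a retained variant; the
#' proportion is the cell's share of all processed sites. Empty cells get
#' probability 0 and are flagged (the downstream pseudocounts absorb the
#' degeneracy; no smoothing is applied).
#'
#' @param counts Count tibble from [count_substitutions()].
#' @param binning The [score_binning()] the counts were made under.
#' @return A `substitution_table`: the counts tibble with `p`,
#'   `proportion` and `empty` columns, carrying the binning and
#'   chromosome-class as attributes.
#' @export
substitution_table <- function(counts, binning = score_binning()) {
  total <- sum(counts$n_var) + sum(counts$n_novar)
  if (total == 0) rlang::abort("no sites tallied; cannot form probabilities")
  out <- counts |>
    dplyr::mutate(
      n_total = .data$n_var + .data$n_novar,
      empty = .data$n_total == 0L,
      p = dplyr::if_else(.data$empty, 0, .data$n_var / .data$n_total),
      proportion = .data$n_total / total
    )
  if (any(out$empty)) {
    rlang::warn(sprintf("%d of %d substitution cells are empty (p set to 0)",
                        sum(out$empty), nrow(out)))
  }
  structure(out, class = c("substitution_table", class(out)),
            binning = binning, chrom_class = counts$chrom_class[1])
}

#' Per-reference-allele no-substitution rate
#'
#' The probability that a site with a given reference allele carries no
#' variant, aggregated over score bins weighted by the within-allele site
#' distribution.
#'
#' @param table A [substitution_table()].
#' @return Tibble `ref`, `no_sub_rate`.
#' @export
no_substitution_rate <- function(table) {
  table |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$ref) |>
    dplyr::summarise(
      no_sub_rate = 1 - sum(.data$p * .data$n_total) /
        pmax(sum(.data$n_total), 1),
      .groups = "drop"
    )
}

#' Serialize a substitution table to TSV
#' @param table A [substitution_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_substitution_table <- function(table, path) {
  binning <- attr(table, "binning")
  out <- tibble::as_tibble(table) |>
    dplyr::mutate(
      bin_lo = binning$edges[.data$bin],
      bin_hi = binning$edges[.data$bin + 1L]
    ) |>
    dplyr::select("chrom_class", "ref", "bin", "bin_lo", "bin_hi",
                  "n_var", "n_novar", "p", "proportion")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a substitution table written by [write_substitution_table()]
#' @param path Path to the TSV.
#' @return A [substitution_table()].
#' @export
read_substitution_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  edges <- c(sort(unique(x$bin_lo)), max(x$bin_hi))
  binning <- score_binning(edges)
  counts <- dplyr::select(x, "chrom_class", "ref", "bin", "n_var", "n_novar")
  suppressWarnings(substitution_table(counts, binning))
}
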