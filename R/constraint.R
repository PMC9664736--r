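#' Informative-site critical value for the window filter
#'
#' The number of splicing-informative sites in a window is modeled as
#' Poisson with rate lambda equal to the genome-wide fraction of
#' protein-coding sites with a summed splice score above zero; a window is
#' usable only if its informative-site count clears the F-distribution
#' critical value 6.5415 (alpha = 0.025, quoted with 7 degrees of freedom
#' for the 8 proportion bins). The constant is carried as a fixed named
#' value rather than recomputed (see the methods vignette).
#' @export
INFORMATIVE_SITE_CUTOFF <- 6.5415

#' Window-filter configuration
#'
#' @param min_informative Minimum informative sites per window; the
#'   default is the critical value [INFORMATIVE_SITE_CUTOFF]
#'   (i.e., at least 7 integer sites).
#' @param min_coverage_frac Minimum fraction of window bases carrying a
#'   score record (default 0.8).
#' @param min_window Minimum window size in bp supporting the cutoff
#'   (default 50).
#' @param lambda Optional genome-wide informative-site rate; when given,
#'   [filter_windows()] checks that `lambda * min_window` clears the
#'   cutoff and warns otherwise.
#' @return A `window_filter_config` list.
#' @export
window_filter_config <- function(min_informative = INFORMATIVE_SITE_CUTOFF,
                                 min_coverage_frac = 0.8,
                                 min_window = 50L,
                                 lambda = NULL) {
  stopifnot(min_informative > 0, min_coverage_frac > 0, min_window > 0)
  structure(list(min_informative = min_informative,
                 min_coverage_frac = min_coverage_frac,
                 min_window = as.integer(min_window),
                 lambda = lambda),
            class = "window_filter_config")
}

#' Tile gene spans into candidate constraint regions
#'
#' In `"windowed"` mode each merged gene span is tiled 5' to 3' of the
#' chromosome with fixed-size windows (the final window is truncated at
#' the gene end); in `"per-gene"` mode one region per gene span is
#' emitted. On the X chromosome, windows overlapping a pseudoautosomal
#' interval are dropped.
#'
#' @param genes Gene models from [read_gene_models()].
#' @param window_size Window width in bp (windowed mode).
#' @param step Step between window starts; defaults to `window_size`
#'   (non-overlapping tiling). A smaller step yields overlapping windows,
#'   resolved at annotation time by the max-score rule.
#' @param mode `"windowed"` or `"per-gene"`.
#' @param genome Optional [genome_config()] supplying PAR intervals.
#' @param min_window Smallest window size the informative-site cutoff
#'   supports; `window_size` below it is a configuration error.
#' @return Region tibble: `region_id`, `chrom`, `start`, `end`,
#'   `gene_ids` (list), `chrom_class`.
#' @export
enumerate_windows <- function(genes, window_size = 50L, step = window_size,
                              mode = c("windowed", "per-gene"),
                              genome = NULL, min_window = 50L) {
  mode <- match.arg(mode)
  if (mode == "windowed" && window_size < min_window) {
    rlang::abort(paste0(
      "window_size below the minimum (", min_window,
      " bp) supported by the informative-site cutoff of ",
      INFORMATIVE_SITE_CUTOFF
    ))
  }
  if (mode == "per-gene") {
    regions <- tibble::tibble(
      chrom = genes$chrom, start = genes$start, end = genes$end,
      gene_ids = purrr::map(genes$gene_id, identity)
    )
  } else {
    regions <- purrr::pmap(
      list(genes$chrom, genes$start, genes$end, genes$gene_id),
      function(cc, s, e, gid) {
        starts <- seq.int(s, e - 1L, by = step)
        tibble::tibble(chrom = cc, start = starts,
                       end = pmin(starts + window_size, e),
                       gene_ids = purrr::map(starts, ~gid))
      }
    ) |>
      dplyr::bind_rows()
  }
  # collapse identical intervals arising from overlapping genes
  regions <- regions |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(
      gene_ids = list(sort(unique(unlist(.data$gene_ids)))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
  if (!is.null(genome)) {
    regions$chrom_class <- chrom_class_of(genome, regions$chrom)
    if (nrow(genome$par) > 0) {
      x_chrom <- genome$chroms$chrom[genome$chroms$chrom_class == "X"][1]
      par_ivs <- dplyr::mutate(genome$par, chrom = x_chrom)
      regions <- regions[!intervals_overlap_any(regions, par_ivs), ,
                         drop = FALSE]
    }
  } else {
    regions$chrom_class <- "autosome"
  }
  regions$region_id <- sprintf("%s:%d-%d", regions$chrom, regions$start,
                               regions$end)
  dplyr::select(regions, "region_id", "chrom", "start", "end",
                "gene_ids", "chrom_class")
}

#' Tally observed and expected counts per region
#'
#' For each region, `o_raw[i]` counts retained variants whose (ref allele,
#' score bin) is cell i, and `e_raw[i]` sums the substitution probability
#' of every region nucleotide assigned to cell i; the expectation uses
#' each nucleotide's reference allele and its summed splice score (the
#' variant-specific score at variant sites, else the max over alternate
#' alleles). Informative counts and score-coverage fractions feed the
#' window filter.
#'
#' @param regions Regions from [enumerate_windows()].
#' @param sites Restricted site summary from [restrict_sites()] (already
#'   holding the variant/no-variant call per site).
#' @param table A [substitution_table()] built on the same chromosome
#'   class and binning.
#' @return `regions` with list columns `o_raw`, `e_raw` (length
#'   `4 * n_bins` vectors) plus `n_obs`, `n_exp`, `n_informative`,
#'   `coverage_frac`.
#' @export
tally_regions <- function(regions, sites, table) {
  binning <- attr(table, "binning")
  n_cells <- 4L * binning$n_bins
  cell_of <- function(ref, bin) {
    (match(ref, c("A", "C", "G", "T")) - 1L) * binning$n_bins + bin
  }
  p_by_cell <- numeric(n_cells)
  p_by_cell[cell_of(table$ref, table$bin)] <- table$p
  sites$cell <- cell_of(sites$ref, sites$bin)
  ov <- points_overlap_join(sites$chrom, sites$pos, regions)
  zero <- numeric(n_cells)
  tal <- ov |>
    dplyr::mutate(
      cell = sites$cell[.data$point_idx],
      has_variant = sites$has_variant[.data$point_idx],
      informative = sites$informative[.data$point_idx]
    ) |>
    dplyr::group_by(.data$interval_idx) |>
    dplyr::summarise(
      o_raw = list(as.numeric(tabulate(.data$cell[.data$has_variant],
                                       nbins = n_cells))),
      e_raw = list({
        e <- numeric(n_cells)
        agg <- tapply(p_by_cell[.data$cell], .data$cell, sum)
        e[as.integer(names(agg))] <- as.numeric(agg)
        e
      }),
      n_sites = dplyr::n(),
      n_informative = sum(.data$informative),
      .groups = "drop"
    )
  m <- match(seq_len(nrow(regions)), tal$interval_idx)
  regions$o_raw <- purrr::map(m, ~ if (is.na(.x)) zero else tal$o_raw[[.x]])
  regions$e_raw <- purrr::map(m, ~ if (is.na(.x)) zero else tal$e_raw[[.x]])
  n_sites <- ifelse(is.na(m), 0L, tal$n_sites[m])
  regions$n_obs <- purrr::map_dbl(regions$o_raw, sum)
  regions$n_exp <- purrr::map_dbl(regions$e_raw, sum)
  regions$n_informative <- ifelse(is.na(m), 0L, tal$n_informative[m])
  regions$coverage_frac <- n_sites / (regions$end - regions$start)
  regions
}

#' Likelihood weights over the (ref allele, score bin) cells
#'
#' Builds the per-cell weight vector X for the weighted O/E statistic.
#' Schemes: `unweighted` (all 1), `linear` (the bin's representative
#' summed score, taken as the bin midpoint), `log`
#' (-10 log10 Proportion), `one_minus_proportion` (1 - Proportion),
#' `inverse_proportion` (1 / Proportion; the scheme the regional model
#' performs best under), and `inverse_substitution_rate` (1 / p).
#' Inverse schemes with a zero denominator set that cell's weight to 0
#' and flag it, so the cell contributes nothing.
#'
#' @param scheme Weight scheme name.
#' @param table A [substitution_table()] supplying proportions and
#'   substitution probabilities.
#' @return Tibble `ref`, `bin`, `cell`, `weight`, `flagged`.
#' @export
weight_vector <- function(scheme = c("inverse_proportion", "unweighted",
                                     "linear", "log",
                                     "one_minus_proportion",
                                     "inverse_substitution_rate"),
                          table) {
  scheme <- match.arg(scheme)
  binning <- attr(table, "binning")
  mid <- (binning$edges[table$bin] + binning$edges[table$bin + 1L]) / 2
  prop <- table$proportion
  p <- table$p
  w <- switch(
    scheme,
    unweighted = rep(1, nrow(table)),
    linear = mid,
    log = ifelse(prop > 0, -10 * log10(prop), 0),
    one_minus_proportion = 1 - prop,
    inverse_proportion = ifelse(prop > 0, 1 / prop, 0),
    inverse_substitution_rate = ifelse(p > 0, 1 / p, 0)
  )
  flagged <- switch(
    scheme,
    log = prop == 0,
    inverse_proportion = prop == 0,
    inverse_substitution_rate = p == 0,
    rep(FALSE, nrow(table))
  )
  tibble::tibble(
    ref = table$ref, bin = table$bin,
    cell = (match(table$ref, c("A", "C", "G", "T")) - 1L) * binning$n_bins +
      table$bin,
    weight = w, flagged = flagged, scheme = scheme
  ) |>
    dplyr::arrange(.data$cell)
}

#' Weighted observed/expected statistic for one region
#'
#' Computes `sum_i X[i] * (O[i] - E[i]) / E[i]` over the allele-by-bin
#' cells, after adding the default pseudocount of 1.0 to both the
#' observed and expected raw counts of every cell (`O = 1 + o_raw`,
#' `E = 1 + e_raw`). The pseudocounts center the null at exactly 0 and
#' give the statistic a continuous negative range: more negative means
#' fewer variants than expected, i.e. stronger constraint.
#'
#' @param o_raw,e_raw Numeric vectors of raw per-cell observed counts and
#'   expected sums.
#' @param weights Weight tibble from [weight_vector()], or a bare numeric
#'   vector of per-cell weights.
#' @return The signed weighted O/E value.
#' @export
weighted_oe <- function(o_raw, e_raw, weights) {
  w <- if (is.data.frame(weights)) weights$weight[order(weights$cell)]
       else weights
  stopifnot(length(o_raw) == length(e_raw), length(w) == length(o_raw))
  sum(w * (o_raw - e_raw) / (1 + e_raw))
}

#' Add the weighted O/E statistic to tallied regions
#' @param regions Tallied regions from [tally_regions()].
#' @param weights Weight tibble from [weight_vector()].
#' @return `regions` with an `oe` column.
#' @export
region_oe <- function(regions, weights) {
  w <- weights$weight[order(weights$cell)]
  regions$oe <- purrr::map2_dbl(regions$o_raw, regions$e_raw,
                                function(o, e) sum(w * (o - e) / (1 + e)))
  regions
}

#' Drop uninformative windows
#'
#' Retains regions whose informative-site count clears the critical value
#' and whose score-coverage fraction is at least the configured minimum.
#'
#' @param regions Tallied regions.
#' @param config A [window_filter_config()].
#' @return The retained regions.
#' @export
filter_windows <- function(regions, config = window_filter_config()) {
  if (!is.null(config$lambda)) {
    if (config$lambda * config$min_window < config$min_informative) {
      rlang::warn(sprintf(
        "expected informative sites per %d bp window (%.2f) falls below the cutoff %.4f",
        config$min_window, config$lambda * config$min_window,
        config$min_informative))
    }
  }
  regions[regions$n_informative >= config$min_informative &
            regions$coverage_frac >= config$min_coverage_frac, ,
          drop = FALSE]
}

#' Shift single-exon-gene regions toward tolerance
#'
#' Single-exon genes undergo no splicing, so their raw O/E values are
#' shifted in the positive (tolerant) direction. By default the shift
#' moves the single-exon mean O/E up to the 80th percentile of the
#' multi-exon O/E distribution (never downward); a fixed `delta` may be
#' supplied instead. Only regions lying wholly within single-exon genes
#' are affected.
#'
#' @param regions Regions with an `oe` column.
#' @param genes Gene models (for the `single_exon` flag).
#' @param delta Optional fixed positive shift.
#' @return `regions` with adjusted `oe` and a logical `single_exon_adj`
#'   column.
#' @export
adjust_single_exon <- function(regions, genes, delta = NULL) {
  se_genes <- genes$gene_id[genes$single_exon]
  se_spans <- gene_spans(genes[genes$single_exon, , drop = FALSE])
  is_se <- purrr::map_lgl(seq_len(nrow(regions)), function(i) {
    gids <- regions$gene_ids[[i]]
    if (!all(gids %in% se_genes)) return(FALSE)
    any(se_spans$chrom == regions$chrom[i] &
          se_spans$start <= regions$start[i] &
          se_spans$end >= regions$end[i])
  })
  regions$single_exon_adj <- is_se
  if (!any(is_se)) return(regions)
  if (is.null(delta)) {
    if (all(is_se)) {
      rlang::abort("no multi-exon regions available to anchor the single-exon shift")
    }
    q80 <- stats::quantile(regions$oe[!is_se], 0.8, names = FALSE)
    delta <- max(0, q80 - mean(regions$oe[is_se]))
  }
  regions$oe[is_se] <- regions$oe[is_se] + delta
  regions
}

#' Rank-normalize raw O/E values into the constraint score
#'
#' Raw O/E values are sorted from largest to smallest and assigned evenly
#' spaced scores in \[0, 1\]: the smallest (most negative, most
#' variant-depleted) O/E receives 1.0 -- the most constrained region --
#' and the largest receives 0.0. Ties receive the mean of their ranks.
#'
#' @param regions Retained regions with an `oe` column (at least two).
#' @param window_size,step,scheme,chrom_class,provenance Metadata stored
#'   on the model.
#' @return A `constraint_model` object holding the scored region tibble
#'   (`constraint_score` column added) and the normalization metadata.
#' @export
normalize_constraint <- function(regions, window_size = NA_integer_,
                                 step = NA_integer_,
                                 scheme = NA_character_,
                                 chrom_class = "autosome",
                                 provenance = list()) {
  n <- nrow(regions)
  if (n < 2) rlang::abort("need at least two regions to normalize")
  r <- rank(regions$oe, ties.method = "average")
  regions$constraint_score <- (n - r) / (n - 1)
  structure(
    list(regions = regions, window_size = window_size, step = step,
         scheme = scheme, chrom_class = chrom_class,
         provenance = provenance),
    class = "constraint_model"
  )
}

#' @export
print.constraint_model <- function(x, ...) {
  cat("<constraint_model>", x$chrom_class, "|", nrow(x$regions),
      "regions | window", x$window_size, "bp | weights:", x$scheme, "\n")
  invisible(x)
}

#' Look up the constraint score covering genomic positions
#'
#' Returns the normalized score of the retained region containing each
#' position; where overlapping windows cover a position (step smaller
#' than window), the maximum score is returned. Positions covered by no
#' retained region get `NA`.
#'
#' @param model A `constraint_model`.
#' @param chrom,pos Parallel vectors of chromosome names and 0-based
#'   positions.
#' @return Numeric vector of scores (NA when absent).
#' @export
score_position <- function(model, chrom, pos) {
  regions <- model$regions
  ov <- points_overlap_join(chrom, pos, regions)
  out <- rep(NA_real_, length(pos))
  if (nrow(ov) > 0) {
    best <- ov |>
      dplyr::mutate(score = regions$constraint_score[.data$interval_idx]) |>
      dplyr::group_by(.data$point_idx) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop")
    out[best$point_idx] <- best$score
  }
  out
}

#' Region id assigned to genomic positions (max-score rule)
#' @inheritParams score_position
#' @return Character vector of region ids (NA when uncovered).
#' @export
region_at_position <- function(model, chrom, pos) {
  regions <- model$regions
  ov <- points_overlap_join(chrom, pos, regions)
  out <- rep(NA_character_, length(pos))
  if (nrow(ov) > 0) {
    best <- ov |>
      dplyr::mutate(score = regions$constraint_score[.data$interval_idx],
                    rid = regions$region_id[.data$interval_idx]) |>
      dplyr::group_by(.data$point_idx) |>
      dplyr::arrange(dplyr::desc(.data$score), .data$rid,
                     .by_group = TRUE) |>
      dplyr::summarise(rid = dplyr::first(.data$rid), .groups = "drop")
    out[best$point_idx] <- best$rid
  }
  out
}

#' Annotate a variant table with constraint scores
#' @param variants Tibble with `chrom` and 0-based `pos`.
#' @param model A `constraint_model` (or list of models keyed by
#'   chromosome class, e.g. the result of [fit_splice_constraint()]).
#' @return `variants` with `constraint` and `constraint_region` columns.
#' @export
annotate_constraint <- function(variants, model) {
  models <- if (inherits(model, "constraint_model")) list(model) else model
  variants$constraint <- NA_real_
  variants$constraint_region <- NA_character_
  for (m in models) {
    if (!inherits(m, "constraint_model")) next
    sel <- is.na(variants$constraint)
    if (!any(sel)) break
    sc <- score_position(m, variants$chrom[sel], variants$pos[sel])
    rid <- region_at_position(m, variants$chrom[sel], variants$pos[sel])
    variants$constraint[sel] <- sc
    variants$constraint_region[sel] <- rid
  }
  variants
}

#' Display transform for constraint scores
#'
#' Maps a constraint score s to `-10 * log10(1 - s)`, spreading the top
#' of the scale for plotting; a score of exactly 1 maps to `cap`.
#'
#' @param score Scores in \[0, 1\].
#' @param cap Display value for score 1 (default 60).
#' @return Transformed values.
#' @export
log_display_score <- function(score, cap = 60) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    rlang::abort("constraint scores must lie in [0, 1]")
  }
  ifelse(score == 1, cap, -10 * log10(1 - score))
}
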