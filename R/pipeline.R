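#' Fit the regional splicing-constraint model end to end
#'
#' Runs the whole constraint pipeline on a set of inputs: filters the
#' population callset, summarizes splice scores per site, builds the
#' substitution probability table, tiles genes into windows, tallies
#' observed/expected counts, computes the likelihood-weighted O/E
#' statistic, filters uninformative windows, applies the single-exon
#' adjustment and rank-normalizes scores. Autosomes and the X chromosome
#' are modeled separately throughout (separate substitution tables,
#' separate normalizations); PAR intervals are excluded from X.
#'
#' @param data A list (or `synthetic_bundle`) with elements `genome`
#'   ([genome_config()]), `genes`, `site_scores`, `variants`, and
#'   optionally `coverage`, `mask`, `truth`, `reference`.
#' @param window_size,step Window tiling parameters (bp); `step` defaults
#'   to `window_size`.
#' @param scheme Likelihood-weight scheme (see [weight_vector()]).
#' @param binning A [score_binning()].
#' @param mode `"windowed"` or `"per-gene"`.
#' @param min_coverage_frac Minimum score-coverage fraction per window.
#' @param min_informative Informative-site cutoff (default
#'   [INFORMATIVE_SITE_CUTOFF]).
#' @param single_exon_delta Optional fixed single-exon O/E shift.
#' @return A `splice_constraint_fit`: list with `models` (per chromosome
#'   class), `tables` (substitution tables), `weights`, `filtered`
#'   variants, `binning` and the call parameters.
#' @export
fit_splice_constraint <- function(data, window_size = 50L,
                                  step = window_size,
                                  scheme = "inverse_proportion",
                                  binning = score_binning(),
                                  mode = "windowed",
                                  min_coverage_frac = 0.8,
                                  min_informative = INFORMATIVE_SITE_CUTOFF,
                                  single_exon_delta = NULL) {
  genome <- data$genome
  genes <- data$genes
  filtered <- filter_population_variants(
    data$variants, genes, data$site_scores,
    coverage = data$coverage, mask = data$mask, truth = data$truth,
    reference = data$reference
  )
  sites_all <- summarize_sites(data$site_scores, filtered, binning)
  classes <- intersect(c("autosome", "X"),
                       unique(chrom_class_of(genome, genes$chrom)))
  models <- list()
  tables <- list()
  weights <- list()
  for (cls in classes) {
    cls_chroms <- genome$chroms$chrom[genome$chroms$chrom_class == cls]
    g <- genes[genes$chrom %in% cls_chroms, , drop = FALSE]
    if (nrow(g) == 0) next
    sites <- restrict_sites(sites_all, g, genome, cls, mask = data$mask)
    if (nrow(sites) == 0) next
    tab <- substitution_table(count_substitutions(sites, binning, cls),
                              binning)
    lambda <- mean(sites$informative)
    regions <- enumerate_windows(g, window_size, step, mode, genome,
                                 min_window = min(window_size, 50L))
    regions <- tally_regions(regions, sites, tab)
    w <- weight_vector(scheme, tab)
    regions <- region_oe(regions, w)
    cfg <- window_filter_config(min_informative = min_informative,
                                min_coverage_frac = min_coverage_frac,
                                min_window = window_size, lambda = lambda)
    kept <- filter_windows(regions, cfg)
    if (nrow(kept) < 2) {
      rlang::warn(paste0("fewer than two ", cls,
                         " regions survive the window filter; class skipped"))
      next
    }
    kept <- adjust_single_exon(kept, g, delta = single_exon_delta)
    models[[cls]] <- normalize_constraint(
      kept, window_size = window_size, step = step, scheme = scheme,
      chrom_class = cls,
      provenance = list(lambda = lambda,
                        n_sites = nrow(sites),
                        discards = filter_discards(filtered))
    )
    tables[[cls]] <- tab
    weights[[cls]] <- w
  }
  structure(
    list(models = models, tables = tables, weights = weights,
         filtered = filtered, binning = binning,
         params = list(window_size = window_size, step = step,
                       scheme = scheme, mode = mode,
                       min_coverage_frac = min_coverage_frac,
                       min_informative = min_informative)),
    class = "splice_constraint_fit"
  )
}

#' @export
print.splice_constraint_fit <- function(x, ...) {
  cat("<splice_constraint_fit> window", x$params$window_size,
      "bp | weights:", x$params$scheme, "\n")
  for (cls in names(x$models)) {
    cat("  ", cls, ":", nrow(x$models[[cls]]$regions), "regions\n")
  }
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.splice_constraint_fit <- function(x, ...) {
  purrr::map(x$models, ~ .x$regions) |>
    dplyr::bind_rows() |>
    dplyr::select("region_id", "chrom", "start", "end", "chrom_class",
                  "oe", "constraint_score", "n_obs", "n_exp",
                  "n_informative", "coverage_frac")
}

#' @rdname tidiers
#' @export
glance.splice_constraint_fit <- function(x, ...) {
  regs <- tidy(x)
  tibble::tibble(
    n_regions = nrow(regs),
    n_autosome = sum(regs$chrom_class == "autosome"),
    n_x = sum(regs$chrom_class == "X"),
    window_size = x$params$window_size,
    scheme = x$params$scheme,
    median_oe = stats::median(regs$oe),
    n_variants_retained = nrow(x$filtered)
  )
}

#' @rdname tidiers
#' @export
tidy.constraint_model <- function(x, ...) {
  dplyr::select(x$regions, "region_id", "chrom", "start", "end",
                "oe", "constraint_score", "n_obs", "n_exp",
                "n_informative", "coverage_frac")
}

#' @rdname tidiers
#' @export
glance.constraint_model <- function(x, ...) {
  tibble::tibble(
    chrom_class = x$chrom_class,
    n_regions = nrow(x$regions),
    window_size = x$window_size,
    scheme = x$scheme,
    median_oe = stats::median(x$regions$oe),
    min_oe = min(x$regions$oe),
    max_oe = max(x$regions$oe)
  )
}
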