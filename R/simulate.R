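#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the constraint model
#' assumes: protein-coding genes with exon/intron structure on both
#' strands, a splice-score track peaking at exon junctions with a heavy
#' cryptic-site tail in the background, population variation arising at
#' per-reference-allele substitution rates, and purifying selection
#' implemented as a depletion factor `depletion` multiplying the variant
#' probability at high-scoring sites of "constrained" genes. Truth-set
#' variants are planted at high-score constrained loci (pathogenic) and
#' low-score loci (benign) and are excluded from the population callset
#' (the leakage control applied to real callsets).
#'
#' @param seed Integer seed; the whole bundle is a deterministic function
#'   of the configuration.
#' @param n_genes Autosomal gene count.
#' @param n_genes_x X-chromosome gene count (one is placed inside PAR1 to
#'   exercise the PAR exclusion; 0 disables the X chromosome).
#' @param frac_constrained Fraction of autosomal genes under splicing
#'   constraint.
#' @param depletion Depletion factor d in (0, 1\]: variant probability at
#'   high-score sites of constrained genes is multiplied by d (d = 1
#'   means no selection).
#' @param exons_per_gene,exon_len,intron_len Integer ranges (length-2
#'   vectors) sampled uniformly per gene / feature.
#' @param intergenic Gap between genes (bp).
#' @param mu Named per-reference-allele baseline variant rates.
#' @param motif_threshold Summed-score value at or above which a site
#'   counts as high-score for the depletion rule.
#' @param unscored_rate Fraction of genic sites left without a score
#'   record.
#' @param n_pathogenic,n_benign Truth-set sizes.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 42L,
                              n_genes = 40L,
                              n_genes_x = 6L,
                              frac_constrained = 0.2,
                              depletion = 0.1,
                              exons_per_gene = c(4L, 7L),
                              exon_len = c(90L, 160L),
                              intron_len = c(70L, 150L),
                              intergenic = 300L,
                              mu = c(A = 0.18, C = 0.25, G = 0.27,
                                     T = 0.12),
                              motif_threshold = 0.4,
                              unscored_rate = 0.03,
                              n_pathogenic = 40L,
                              n_benign = 160L) {
  stopifnot(depletion > 0, depletion <= 1,
            frac_constrained >= 0, frac_constrained <= 1,
            all(mu > 0), all(mu < 1),
            all(c("A", "C", "G", "T") %in% names(mu)))
  structure(as.list(environment()), class = "simulation_config")
}

# Split summed scores (each <= 4) into four delta scores, each <= 1.
split_sum_into_deltas <- function(s) {
  n <- length(s)
  u <- matrix(stats::runif(4 * n), ncol = 4)
  d <- u / rowSums(u) * s
  for (it in 1:4) {
    excess <- rowSums(pmax(d - 1, 0))
    d <- pmin(d, 1)
    headroom <- 1 - d
    hr_tot <- rowSums(headroom)
    redo <- excess > 1e-12 & hr_tot > 0
    if (!any(redo)) break
    d[redo, ] <- d[redo, , drop = FALSE] +
      headroom[redo, , drop = FALSE] / hr_tot[redo] * excess[redo]
  }
  pmin(d, 1)
}

# Background summed-score mixture: a zero mass, a bulk of weak sites and
# a cryptic-site tail reaching into every score bin.
background_sum <- function(n) {
  comp <- sample.int(6, n, replace = TRUE,
                     prob = c(0.20, 0.30, 0.12, 0.10, 0.22, 0.06))
  lo <- c(0, 0, 0.1, 0.4, 0.8, 2.5)[comp]
  hi <- c(0, 0.1, 0.4, 0.8, 2.5, 4)[comp]
  stats::runif(n, lo, hi)
}

#' Generate a synthetic input bundle
#'
#' Produces an in-memory bundle of mutually consistent inputs -- genome
#' configuration, reference sequences, gene models, per-substitution
#' splice scores, population variants, coverage, exclusion mask and a
#' labeled truth set -- entirely determined by the configuration seed.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_bundle` list with elements `genome`, `reference`
#'   (named character vector of sequences), `genes`, `gene_classes`
#'   (planted constrained/tolerant labels), `site_scores`, `variants`,
#'   `coverage`, `mask`, `truth`, `config`.
#' @export
simulate_bundle <- function(config = simulation_config()) {
  withr::with_seed(config$seed, simulate_bundle_impl(config))
}

simulate_bundle_impl <- function(cfg) {
  nt <- c("A", "C", "G", "T")
  make_gene <- function(gid, chrom, offset, strand) {
    # ~10% of genes are single-exon (no splicing; exercises the
    # single-exon O/E adjustment), with a longer exon
    if (stats::runif(1) < 0.1) {
      n_ex <- 1L
      ex_len <- sample(300:500, 1)
    } else {
      n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1)
      ex_len <- sample(cfg$exon_len[1]:cfg$exon_len[2], n_ex,
                       replace = TRUE)
    }
    in_len <- if (n_ex > 1) {
      sample(cfg$intron_len[1]:cfg$intron_len[2], n_ex - 1, replace = TRUE)
    } else integer(0)
    starts <- offset + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    tibble::tibble(
      gene_id = gid, chrom = chrom, strand = strand,
      start = starts[1], end = ends[n_ex],
      exons = list(tibble::tibble(start = starts, end = ends))
    )
  }
  lay_out <- function(chrom, ids, strands, offset0) {
    genes <- vector("list", length(ids))
    offset <- offset0
    for (i in seq_along(ids)) {
      g <- make_gene(ids[i], chrom, offset, strands[i])
      genes[[i]] <- g
      offset <- g$end + cfg$intergenic
    }
    dplyr::bind_rows(genes)
  }
  auto_ids <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  strands <- rep(c("+", "-"), length.out = cfg$n_genes)
  genes <- lay_out("chr1", auto_ids, strands, cfg$intergenic)
  par <- NULL
  if (cfg$n_genes_x > 0) {
    x_ids <- sprintf("XGENE%02d", seq_len(cfg$n_genes_x))
    x_strands <- rep(c("+", "-"), length.out = cfg$n_genes_x)
    gx <- lay_out("chrX", x_ids, x_strands, cfg$intergenic)
    # PAR1 covers the first X gene entirely; its windows must vanish
    par <- tibble::tibble(start = 0L, end = gx$end[1] + 50L)
    genes <- dplyr::bind_rows(genes, gx)
  }
  genes$single_exon <- purrr::map_int(genes$exons, nrow) == 1L
  genes$cds <- genes$exons
  chrom_len <- genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$end) + cfg$intergenic,
                     .groups = "drop")
  genome <- genome_config(chrom_len$chrom, chrom_len$len, par = par)
  reference <- purrr::map_chr(chrom_len$len, function(l) {
    paste(sample(nt, l, replace = TRUE), collapse = "")
  })
  names(reference) <- chrom_len$chrom

  # constraint against splicing is only meaningful for spliced genes:
  # the planted constrained set is drawn from multi-exon autosomal genes
  multi_auto <- genes$gene_id[!genes$single_exon &
                                genes$gene_id %in% auto_ids]
  constrained <- sort(sample(multi_auto,
                             min(round(cfg$frac_constrained * cfg$n_genes),
                                 length(multi_auto))))
  gene_classes <- tibble::tibble(
    gene_id = genes$gene_id,
    constrained = genes$gene_id %in% constrained
  )

  # per-genic-site table with junction-aware site classes
  site_tbl <- purrr::pmap(
    list(genes$chrom, genes$gene_id, genes$start, genes$end, genes$exons),
    function(cc, gid, s, e, ex) {
      pos <- s:(e - 1L)
      # distance to nearest internal junction, split exonic/intronic
      bnd <- sort(c(ex$start[-1], ex$end[-nrow(ex)]))
      in_ex <- points_in_intervals(rep(cc, length(pos)), pos,
                                   dplyr::mutate(ex, chrom = cc))
      if (length(bnd) == 0) {
        dist <- rep(Inf, length(pos))
      } else {
        up <- findInterval(pos, bnd)
        d_right <- ifelse(up < length(bnd), bnd[pmin(up + 1L, length(bnd))] - pos, Inf)
        d_left <- ifelse(up >= 1, pos - bnd[pmax(up, 1L)] + 1L, Inf)
        dist <- pmin(d_left, d_right)
      }
      klass <- dplyr::case_when(
        !in_ex & dist <= 2 ~ "canonical",
        !in_ex & dist <= 8 ~ "splice_region",
        in_ex & dist <= 3 ~ "splice_region",
        .default = "background"
      )
      tibble::tibble(chrom = cc, pos = pos, gene_id = gid, klass = klass)
    }
  ) |>
    dplyr::bind_rows() |>
    dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  site_tbl$ref <- purrr::map2_chr(site_tbl$chrom, site_tbl$pos,
                                  function(cc, p) substr(reference[[cc]],
                                                         p + 1L, p + 1L))
  n_site <- nrow(site_tbl)
  site_tbl$target_sum <- NA_real_
  can <- site_tbl$klass == "canonical"
  spr <- site_tbl$klass == "splice_region"
  bgd <- site_tbl$klass == "background"
  site_tbl$target_sum[can] <- stats::runif(sum(can), 1.5, 3.5)
  site_tbl$target_sum[spr] <- stats::runif(sum(spr), 0.4, 2.0)
  site_tbl$target_sum[bgd] <- background_sum(sum(bgd))
  site_tbl$scored <- stats::runif(n_site) >= cfg$unscored_rate

  # expand to one record per alternate allele
  scored <- site_tbl[site_tbl$scored, , drop = FALSE]
  n_sc <- nrow(scored)
  alts <- t(vapply(scored$ref, function(r) setdiff(nt, r), character(3)))
  # one alt carries the site's target sum; the others a damped version
  frac <- cbind(1, matrix(stats::runif(2 * n_sc, 0.05, 0.9), ncol = 2))
  shuf <- t(apply(matrix(stats::runif(3 * n_sc), ncol = 3), 1, order))
  f_shuffled <- matrix(frac[cbind(rep(seq_len(n_sc), times = 3),
                                  as.vector(shuf))], ncol = 3)
  alt_sum_mat <- scored$target_sum * f_shuffled
  long <- tibble::tibble(
    chrom = rep(scored$chrom, each = 3),
    pos = rep(scored$pos, each = 3),
    ref = rep(scored$ref, each = 3),
    alt = as.vector(t(alts)),
    alt_sum = as.vector(t(alt_sum_mat))
  )
  deltas <- split_sum_into_deltas(long$alt_sum)
  site_scores <- tibble::tibble(
    chrom = long$chrom, pos = long$pos, ref = long$ref, alt = long$alt,
    ag = deltas[, 1], al = deltas[, 2], dg = deltas[, 3], dl = deltas[, 4]
  )

  # population variants under per-ref rates and planted depletion
  site_tbl <- dplyr::left_join(site_tbl, gene_classes, by = "gene_id")
  high <- site_tbl$target_sum >= cfg$motif_threshold & site_tbl$scored
  p_var <- unname(cfg$mu[site_tbl$ref]) *
    ifelse(site_tbl$constrained & high, cfg$depletion, 1)
  has_var <- stats::runif(n_site) < p_var
  var_sites <- site_tbl[has_var, , drop = FALSE]
  var_alt_idx <- sample.int(3, nrow(var_sites), replace = TRUE)
  var_alts <- vapply(seq_len(nrow(var_sites)), function(i) {
    setdiff(nt, var_sites$ref[i])[var_alt_idx[i]]
  }, character(1))
  variants <- tibble::tibble(
    chrom = var_sites$chrom, pos = var_sites$pos, ref = var_sites$ref,
    alt = var_alts,
    ac = 1L + stats::rpois(nrow(var_sites), 1.2),
    filter = ifelse(stats::runif(nrow(var_sites)) < 0.02, "LowQual",
                    "PASS")
  )

  coverage <- tibble::tibble(
    chrom = site_tbl$chrom, pos = site_tbl$pos,
    fraction_10x = ifelse(stats::runif(n_site) < 0.015,
                          stats::runif(n_site, 0.10, 0.45),
                          stats::runif(n_site, 0.85, 1.00))
  )

  # mask: one qualifying interval over a tolerant gene, one intergenic,
  # one below-threshold record that must be ignored by the reader
  tol_gene <- genes[genes$gene_id ==
                      setdiff(auto_ids, constrained)[1], ]
  mask_raw <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1"),
    start = c(tol_gene$start + 10L, 5L, tol_gene$start + 200L),
    end = c(tol_gene$start + 60L, 55L, tol_gene$start + 260L),
    identity = c(0.97, 0.99, 0.80)
  )
  mask <- merge_intervals(mask_raw[mask_raw$identity >= 0.95,
                                   c("chrom", "start", "end")])
  attr(mask, "identity_threshold") <- 0.95

  # truth set: pathogenic at high-score constrained loci, benign at
  # low-score loci; planted correlated spliceosome-classifier scores
  auto_scored <- site_tbl$scored & site_tbl$chrom == "chr1"
  path_pool <- which(auto_scored & site_tbl$constrained &
                       site_tbl$target_sum >= cfg$motif_threshold)
  ben_pool <- which(auto_scored & !site_tbl$constrained &
                      site_tbl$target_sum < 0.4)
  n_path <- min(cfg$n_pathogenic, length(path_pool))
  n_ben <- min(cfg$n_benign, length(ben_pool))
  pick_truth <- function(idx, label, squirls_shape) {
    ss <- site_tbl[idx, , drop = FALSE]
    recs <- site_scores |>
      dplyr::semi_join(ss, by = c("chrom", "pos")) |>
      sum_delta_scores() |>
      dplyr::group_by(.data$chrom, .data$pos, .data$ref) |>
      dplyr::slice_max(.data$sum_score, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    tibble::tibble(
      chrom = recs$chrom, pos = recs$pos, ref = recs$ref, alt = recs$alt,
      label = label,
      ag = recs$ag, al = recs$al, dg = recs$dg, dl = recs$dl,
      squirls_max = stats::rbeta(nrow(recs), squirls_shape[1],
                                 squirls_shape[2]),
      cadd = stats::rnorm(nrow(recs),
                          ifelse(label == "pathogenic", 25, 8), 4)
    )
  }
  truth <- dplyr::bind_rows(
    pick_truth(sample(path_pool, n_path), "pathogenic", c(6, 2)),
    pick_truth(sample(ben_pool, n_ben), "benign", c(2, 6))
  )
  # leakage control: truth variants never appear in the population VCF
  variants <- dplyr::anti_join(variants, truth, by = c("chrom", "pos"))

  genes_out <- dplyr::select(genes, "gene_id", "chrom", "strand",
                             "start", "end", "single_exon", "exons",
                             "cds") |>
    dplyr::arrange(.data$chrom, .data$start)
  structure(
    list(genome = genome, reference = reference, genes = genes_out,
         gene_classes = gene_classes, site_scores = site_scores,
         variants = variants, coverage = coverage, mask = mask,
         truth = truth, config = cfg),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle> seed", x$config$seed, "|",
      nrow(x$genes), "genes |", nrow(x$variants), "population variants |",
      nrow(x$truth), "truth variants\n")
  invisible(x)
}

#' Planted constraint labels for scored regions
#'
#' Emits the ground-truth class for every region a constraint model
#' scores: a region is `constrained` when it overlaps a gene planted as
#' constrained, `tolerant` otherwise. Used to score parameter recovery.
#'
#' @param bundle A `synthetic_bundle`.
#' @param regions Region tibble (with `gene_ids` list column).
#' @return `regions` with a logical `constrained` column.
#' @export
ground_truth_labels <- function(bundle, regions) {
  constrained <- bundle$gene_classes$gene_id[bundle$gene_classes$constrained]
  regions$constrained <- purrr::map_lgl(regions$gene_ids,
                                        ~ any(.x %in% constrained))
  regions
}

#' Write a synthetic bundle to standard file formats
#'
#' Writes FASTA (reference), GTF (gene models), TSVs (site scores,
#' coverage, truth set, gene classes), VCF (population variants), BED
#' (mask) and a plain-text manifest recording the configuration, into a
#' directory.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rlang::check_installed("Biostrings")
  seqs <- Biostrings::DNAStringSet(bundle$reference)
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fa"))
  write_gene_models_gtf(bundle$genes, file.path(dir, "genes.gtf"))
  write_site_scores(bundle$site_scores, file.path(dir, "site_scores.tsv"))
  write_variants_vcf(bundle$variants, file.path(dir, "population.vcf"),
                     genome = bundle$genome)
  write_coverage(bundle$coverage, file.path(dir, "coverage.tsv"))
  readr::write_tsv(
    dplyr::mutate(tibble::as_tibble(bundle$mask),
                  identity = attr(bundle$mask, "identity_threshold")),
    file.path(dir, "mask.bed"), col_names = FALSE)
  write_truth_set(bundle$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(bundle$gene_classes, file.path(dir, "gene_classes.tsv"))
  readr::write_tsv(bundle$genome$chroms, file.path(dir, "genome.tsv"))
  if (nrow(bundle$genome$par) > 0) {
    readr::write_tsv(bundle$genome$par, file.path(dir, "par.tsv"))
  }
  cfg <- bundle$config
  cfg <- cfg[sort(names(cfg))]
  manifest <- c(
    "format=spliceoe_bundle/1",
    paste0("build=", bundle$genome$build),
    purrr::imap_chr(cfg, function(v, nm) {
      paste0(nm, "=", paste(unname(v), collapse = ","))
    })
  )
  readr::write_lines(manifest, file.path(dir, "MANIFEST.txt"))
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#' @param dir Bundle directory.
#' @return A list with the same elements as a `synthetic_bundle` (minus
#'   the configuration, which is only echoed in the manifest).
#' @export
read_bundle <- function(dir) {
  rlang::check_installed("Biostrings")
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  reference <- as.character(seqs)
  par <- NULL
  par_path <- file.path(dir, "par.tsv")
  if (file.exists(par_path)) {
    par <- readr::read_tsv(par_path, show_col_types = FALSE)
  }
  gpath <- file.path(dir, "genome.tsv")
  if (file.exists(gpath)) {
    ch <- readr::read_tsv(gpath, show_col_types = FALSE)
    genome <- genome_config(ch$chrom, ch$length,
                            chrom_class = ch$chrom_class, par = par)
  } else {
    genome <- genome_config(names(reference), nchar(reference), par = par)
  }
  genes <- read_gene_models(file.path(dir, "genes.gtf"), genome)
  list(
    genome = genome,
    reference = reference,
    genes = genes,
    site_scores = read_site_scores(file.path(dir, "site_scores.tsv")),
    variants = read_population_vcf(file.path(dir, "population.vcf")),
    coverage = read_coverage(file.path(dir, "coverage.tsv")),
    mask = read_exclusion_mask(file.path(dir, "mask.bed")),
    truth = read_truth_set(file.path(dir, "truth.tsv")),
    gene_classes = readr::read_tsv(file.path(dir, "gene_classes.tsv"),
                                   show_col_types = FALSE)
  )
}
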