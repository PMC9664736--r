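#' Filter a population callset down to constraint-model variants
#'
#' Applies the full set of inclusion criteria used to build the
#' substitution model. A variant is retained iff it:
#' is a single-nucleotide A/C/G/T substitution; carries a PASS filter;
#' has allele count >= 1; passes coverage (>= 10X in >= 50% of samples);
#' has a reference allele matching the reference sequence; falls inside a
#' merged protein-coding gene interval; has a splice-score record for its
#' ref/alt pair; overlaps no exclusion-mask interval; and is absent from
#' the labeled truth set (leakage control). The criteria are independent,
#' so their order of application does not change the retained set.
#'
#' @param variants Tibble from [read_population_vcf()].
#' @param genes Gene models from [read_gene_models()].
#' @param site_scores Score table from [read_site_scores()].
#' @param coverage Coverage table from [read_coverage()]; `NULL` means all
#'   sites pass.
#' @param mask Exclusion mask from [read_exclusion_mask()]; `NULL` for none.
#' @param truth Truth set tibble; `NULL` for none.
#' @param reference Optional named character vector (or list) of
#'   chromosome sequences; when supplied, variant REF alleles are checked
#'   against it, otherwise against the ref recorded in the score track.
#'   Mismatches are excluded and tallied, not fatal.
#'
#' @return The retained variants with a `gene_ids` list column (all
#'   overlapping genes; a variant in overlapping genes is still a single
#'   row, so shared sequence is never double-counted). A per-criterion
#'   discard tally is attached as the `discards` attribute.
#' @export
filter_population_variants <- function(variants, genes, site_scores,
                                       coverage = NULL, mask = NULL,
                                       truth = NULL, reference = NULL) {
  v <- variants
  n <- nrow(v)
  crit <- list()
  crit$snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L &
    v$ref %in% c("A", "C", "G", "T") & v$alt %in% c("A", "C", "G", "T") &
    v$ref != v$alt
  crit$pass_filter <- v$filter == "PASS"
  crit$allele_count <- !is.na(v$ac) & v$ac >= 1L

  if (is.null(coverage)) {
    crit$coverage <- rep(TRUE, n)
  } else {
    cov <- dplyr::left_join(
      v[, c("chrom", "pos")], coverage,
      by = c("chrom", "pos")
    )
    crit$coverage <- !is.na(cov$fraction_10x) & cov$fraction_10x >= 0.5
  }

  if (!is.null(reference)) {
    ref_at <- purrr::map2_chr(v$chrom, v$pos, function(cc, p) {
      seqc <- reference[[cc]]
      if (is.null(seqc) || p < 0 || p >= nchar(seqc)) return(NA_character_)
      substr(seqc, p + 1L, p + 1L)
    })
    crit$ref_match <- !is.na(ref_at) & ref_at == v$ref
  } else {
    score_ref <- site_scores |>
      dplyr::distinct(.data$chrom, .data$pos, .data$ref)
    j <- dplyr::left_join(v[, c("chrom", "pos")], score_ref,
                          by = c("chrom", "pos"), suffix = c("", ".s"))
    crit$ref_match <- is.na(j$ref) | j$ref == v$ref
  }

  spans <- gene_spans(genes)
  ov <- points_overlap_join(v$chrom, v$pos, spans)
  crit$in_gene <- seq_len(n) %in% ov$point_idx

  scored_keys <- paste(site_scores$chrom, site_scores$pos,
                       site_scores$ref, site_scores$alt)
  crit$scored <- paste(v$chrom, v$pos, v$ref, v$alt) %in% scored_keys

  if (is.null(mask) || nrow(mask) == 0) {
    crit$unmasked <- rep(TRUE, n)
  } else {
    crit$unmasked <- !points_in_intervals(v$chrom, v$pos, mask)
  }

  if (is.null(truth) || nrow(truth) == 0) {
    crit$not_in_truth <- rep(TRUE, n)
  } else {
    truth_keys <- paste(truth$chrom, truth$pos, truth$ref, truth$alt)
    crit$not_in_truth <- !(paste(v$chrom, v$pos, v$ref, v$alt) %in% truth_keys)
  }

  keep <- Reduce(`&`, crit)
  gene_map <- ov |>
    dplyr::mutate(gene_id = spans$gene_id[.data$interval_idx]) |>
    dplyr::group_by(.data$point_idx) |>
    dplyr::summarise(gene_ids = list(.data$gene_id), .groups = "drop")
  out <- v[keep, , drop = FALSE]
  gi <- gene_map$gene_ids[match(which(keep), gene_map$point_idx)]
  out$gene_ids <- purrr::map(gi, ~ if (is.null(.x)) character() else .x)
  discards <- tibble::tibble(
    criterion = names(crit),
    n_failed = purrr::map_int(crit, ~ sum(!.x))
  )
  attr(out, "discards") <- discards
  out
}

#' Per-criterion discard tally of a filtered callset
#' @param filtered Result of [filter_population_variants()].
#' @return Tibble `criterion`, `n_failed`.
#' @export
filter_discards <- function(filtered) attr(filtered, "discards")

#' Label variant positions relative to exon--intron junctions
#'
#' Classifies each genic position against the merged exon structure of its
#' gene, strand-aware, into exactly one of: `A-1`, `A-2`, `D+1`, `D+2`
#' (the canonical acceptor and donor dinucleotides), `splice_region_intronic`
#' (3--8 intronic bases from a junction), `splice_region_exonic` (<= 3
#' exonic bases), `intronic` / `exonic` (<= 10 bases), or `deep_intronic` /
#' `deep_exonic` (> 10 bases). The acceptor side of the transcript-first
#' exon and the donor side of the transcript-last exon do not participate
#' in splicing and are never canonical sites.
#'
#' @param variants Tibble with `chrom`, `pos` (0-based) and a `gene_id`
#'   column naming the gene to classify against.
#' @param genes Gene models from [read_gene_models()].
#' @return `variants` with a `rel_pos` character column added.
#' @export
annotate_relative_position <- function(variants, genes) {
  idx <- match(variants$gene_id, genes$gene_id)
  if (anyNA(idx)) rlang::abort("variant gene_id not found among gene models")
  variants$rel_pos <- purrr::map2_chr(
    seq_len(nrow(variants)), idx,
    function(i, gi) {
      relative_position(variants$pos[i], genes$exons[[gi]],
                        genes$strand[gi],
                        gene_start = genes$start[gi],
                        gene_end = genes$end[gi])
    }
  )
  variants
}

# Classify a single 0-based position against merged, genomically sorted
# exons of one gene. Exposed for exhaustive enumeration in tests.
relative_position <- function(pos, exons, strand,
                              gene_start = min(exons$start),
                              gene_end = max(exons$end)) {
  if (pos < gene_start || pos >= gene_end) {
    rlang::abort("position lies outside the gene span")
  }
  n <- nrow(exons)
  in_exon <- which(exons$start <= pos & pos < exons$end)
  if (length(in_exon) == 1) {
    j <- in_exon
    # distance 1 = the exonic base adjacent to the junction
    d_left <- pos - exons$start[j] + 1L   # junction iff j > 1
    d_right <- exons$end[j] - pos         # junction iff j < n
    cand <- c(if (j > 1) d_left, if (j < n) d_right)
    if (length(cand) == 0) return("deep_exonic")  # single-exon gene
    k <- min(cand)
    if (k <= 3) return("splice_region_exonic")
    if (k <= 10) return("exonic")
    return("deep_exonic")
  }
  # outside all exons but inside the span ends: no junction nearby
  if (pos < exons$start[1] || pos >= exons$end[n]) return("deep_intronic")
  # intronic: find flanking exons
  j <- max(which(exons$end <= pos))       # upstream (genomic-left) exon
  d_left <- pos - exons$end[j] + 1L       # distance into intron from left exon
  d_right <- exons$start[j + 1] - pos     # distance from right exon
  # genomic-left junction is a donor on + strand, an acceptor on -
  left_is_donor <- strand == "+"
  if (d_left < d_right || (d_left == d_right && !left_is_donor)) {
    k <- d_left
    side <- if (left_is_donor) "D" else "A"
  } else {
    k <- d_right
    side <- if (left_is_donor) "A" else "D"
  }
  if (k <= 2) {
    return(if (side == "A") paste0("A-", k) else paste0("D+", k))
  }
  if (k <= 8) return("splice_region_intronic")
  if (k <= 10) return("intronic")
  "deep_intronic"
}

canonical_site_labels <- function() c("A-1", "A-2", "D+1", "D+2")

splice_region_labels <- function() {
  c(canonical_site_labels(), "splice_region_intronic", "splice_region_exonic")
}
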