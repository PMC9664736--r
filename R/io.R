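#' Read per-site splice-prediction delta scores
#'
#' The score table holds one record per reference-to-alternate substitution
#' with the four delta scores: acceptor gain (AG), acceptor loss (AL),
#' donor gain (DG), donor loss (DL), each in \[0, 1\]. Positions in the
#' file are 1-based and converted to the internal 0-based convention.
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `ag`, `al`,
#'   `dg`, `dl`.
#' @return A tibble with 0-based `pos` and the four delta-score columns.
#' @export
read_site_scores <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = "c", pos = "i", ref = "c", alt = "c",
                         ag = "d", al = "d", dg = "d", dl = "d"
                       ))
  validate_site_scores(dplyr::mutate(x, pos = .data$pos - 1L))
}

validate_site_scores <- function(x) {
  sc <- as.matrix(x[, c("ag", "al", "dg", "dl")])
  if (any(sc < 0 | sc > 1)) {
    rlang::abort("delta scores must lie in [0, 1]")
  }
  if (!all(x$ref %in% c("A", "C", "G", "T")) ||
      !all(x$alt %in% c("A", "C", "G", "T"))) {
    rlang::abort("score records must be single-nucleotide A/C/G/T")
  }
  x
}

#' Write a site-score table (inverse of [read_site_scores()])
#' @param scores Tibble as returned by [read_site_scores()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_scores <- function(scores, path) {
  out <- dplyr::mutate(scores, pos = .data$pos + 1L)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a population variant callset from VCF
#'
#' Parses a gnomAD-style VCF (via the vcfR package), decomposes
#' multi-allelic records into biallelic rows, keeps single-nucleotide
#' REF/ALT pairs, extracts the allele count (`AC`) INFO field and the
#' FILTER status, and drops Y-chromosome records. Positions become
#' 0-based.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `ac`, `filter`.
#' @export
read_population_vcf <- function(path) {
  rlang::check_installed("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  names(fix) <- tolower(names(fix))
  info <- vcfR::extract.info(v, element = "AC")
  fix$ac_raw <- info
  out <- fix |>
    dplyr::mutate(row_id = dplyr::row_number()) |>
    tidyr::separate_longer_delim(c("alt", "ac_raw"), delim = ",") |>
    dplyr::transmute(
      chrom = .data$chrom,
      pos = as.integer(.data$pos) - 1L,
      ref = .data$ref,
      alt = .data$alt,
      ac = suppressWarnings(as.integer(.data$ac_raw)),
      filter = dplyr::coalesce(.data$filter, "PASS")
    ) |>
    dplyr::filter(
      nchar(.data$ref) == 1L, nchar(.data$alt) == 1L,
      !grepl("Y$", .data$chrom)
    )
  out$ac[is.na(out$ac)] <- 1L
  out
}

#' Write variants as a minimal VCF
#'
#' Emits a spec-conformant VCF body with declared INFO headers for the
#' allele count and, when present, the summed splice score and score-bin
#' annotations produced by the filtering step.
#'
#' @param variants Tibble with `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `ac`, `filter`, and optionally `sum_score` and `bin`.
#' @param path Output path (plain text).
#' @param genome Optional [genome_config()] used to emit contig headers.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, genome = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=spliceoe",
    '##INFO=<ID=AC,Number=A,Type=Integer,Description="Allele count">'
  )
  if ("sum_score" %in% names(variants)) {
    hdr <- c(hdr,
      '##INFO=<ID=SUMSCORE,Number=A,Type=Float,Description="Summed splice delta score for this ref/alt">',
      '##INFO=<ID=SCOREBIN,Number=A,Type=Integer,Description="Splice score bin index">')
  }
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          genome$chroms$chrom, genome$chroms$length))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("AC=%d", variants$ac)
  if ("sum_score" %in% names(variants)) {
    info <- sprintf("AC=%d;SUMSCORE=%.6g;SCOREBIN=%d",
                    variants$ac, variants$sum_score, variants$bin)
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  variants$chrom, variants$pos + 1L, variants$ref,
                  variants$alt, variants$filter, info)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read a per-position coverage summary
#'
#' The coverage contract is a per-position table with the fraction of
#' samples covered at 10X or more; a site passes when that fraction is at
#' least 0.5.
#'
#' @param path TSV with columns `chrom`, `pos` (1-based), `fraction_10x`.
#' @return Tibble with 0-based `pos` and `fraction_10x`.
#' @export
read_coverage <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", pos = "i",
                                          fraction_10x = "d")) |>
    dplyr::mutate(pos = .data$pos - 1L)
}

#' Write a coverage summary (inverse of [read_coverage()])
#' @param coverage Tibble with `chrom`, `pos` (0-based), `fraction_10x`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  readr::write_tsv(dplyr::mutate(coverage, pos = .data$pos + 1L), path)
  invisible(path)
}

#' Build an exclusion mask from repeat-annotation BED files
#'
#' Segmental-duplication and self-chain annotations with high sequence
#' identity mark regions where read mapping (and therefore the variant
#' callset) is unreliable; intervals at or above the identity threshold
#' are excluded from the constraint model.
#'
#' @param paths Character vector of BED file paths. The 4th column must be
#'   the identity fraction in \[0, 1\].
#' @param identity_threshold Minimum identity to mask (default 0.95).
#' @return An interval tibble (`chrom`, `start`, `end`) of merged
#'   qualifying records, with the threshold recorded in the
#'   `identity_threshold` attribute.
#' @export
read_exclusion_mask <- function(paths, identity_threshold = 0.95) {
  recs <- purrr::map(paths, function(p) {
    empty <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), identity = numeric())
    if (file.size(p) == 0) return(empty)
    x <- readr::read_tsv(p, col_names = FALSE, show_col_types = FALSE)
    if (nrow(x) == 0) return(empty)
    if (ncol(x) < 4) {
      rlang::abort(paste0("BED file ", p, " lacks the identity fraction (4th column)"))
    }
    tibble::tibble(chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
                   end = as.integer(x[[3]]), identity = as.numeric(x[[4]]))
  }) |>
    dplyr::bind_rows()
  mask <- merge_intervals(recs[recs$identity >= identity_threshold,
                               c("chrom", "start", "end")])
  attr(mask, "identity_threshold") <- identity_threshold
  mask
}

#' Read a labeled truth set of pathogenic and benign variants
#'
#' @param path TSV with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `label` (`pathogenic`/`benign`), the four delta scores `ag`, `al`,
#'   `dg`, `dl`, a `squirls_max` column, and optionally `cadd` (carried
#'   through for comparison only, never used as a model feature).
#' @return Tibble with 0-based `pos`.
#' @export
read_truth_set <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(x$label %in% c("pathogenic", "benign"))) {
    rlang::abort("truth-set labels must be 'pathogenic' or 'benign'")
  }
  dplyr::mutate(x, pos = as.integer(.data$pos) - 1L)
}

#' Write a truth set (inverse of [read_truth_set()])
#' @param truth Truth tibble with 0-based `pos`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_set <- function(truth, path) {
  readr::write_tsv(dplyr::mutate(truth, pos = .data$pos + 1L), path)
  invisible(path)
}

#' Write scored constraint regions as a BED-compatible TSV
#' @param regions Scored region tibble (see [normalize_constraint()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  out <- tibble::tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    region_id = regions$region_id,
    genes = purrr::map_chr(regions$gene_ids, paste, collapse = ","),
    raw_oe = regions$oe,
    constraint_score = regions$constraint_score,
    n_informative = regions$n_informative,
    coverage_fraction = regions$coverage_frac
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read scored constraint regions written by [write_regions_bed()]
#' @param path Path to the region TSV.
#' @return A region tibble with a `gene_ids` list column.
#' @export
read_regions_bed <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  x$gene_ids <- stringr::str_split(x$genes, ",")
  dplyr::rename(dplyr::select(x, -"genes"), oe = "raw_oe",
                coverage_frac = "coverage_fraction")
}
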