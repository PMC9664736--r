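#' Load protein-coding gene models from a GTF file
#'
#' Reads a GENCODE-style GTF, keeps protein-coding genes, and collapses each
#' gene's transcripts into a strand-separated union: the merged transcript
#' span defines the gene interval the constraint model tiles, and exon /
#' CDS intervals are merged across transcripts. Internally all coordinates
#' are 0-based half-open (GTF is 1-based closed; conversion happens here).
#'
#' @param gtf Path to a GTF file with `gene`, `transcript`, `exon` (and
#'   optionally `CDS`) features carrying a `gene_type` (or `gene_biotype`)
#'   attribute.
#' @param genome A [genome_config()]. Records on chromosomes absent from
#'   the configuration (including Y) are dropped.
#'
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (merged transcript span), `single_exon`, and list
#'   columns `exons` and `cds` of merged interval tibbles (`start`, `end`).
#'   Rows are ordered by (chrom, start). A gene whose features span two
#'   chromosomes is rejected.
#' @export
read_gene_models <- function(gtf, genome) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges_seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    gene_type = gene_type_attr(gr)
  )
  build_gene_models(df, genome)
}

GenomicRanges_seqnames <- function(gr) methods::slot(gr, "seqnames")

gene_type_attr <- function(gr) {
  md <- S4Vectors::mcols(gr)
  if ("gene_type" %in% colnames(md)) return(md$gene_type)
  if ("gene_biotype" %in% colnames(md)) return(md$gene_biotype)
  rlang::abort("GTF lacks a gene_type/gene_biotype attribute")
}

# Shared builder consumed by both the GTF reader and the simulator.
# `features` is a tibble(chrom, start, end, strand, type, gene_id, gene_type)
# in 0-based half-open coordinates.
build_gene_models <- function(features, genome) {
  features <- features[features$chrom %in% genome$chroms$chrom, ]
  pc <- features[features$gene_type == "protein_coding", ]
  if (nrow(pc) == 0) {
    rlang::abort("no protein-coding features found")
  }
  split_chrom <- pc |>
    dplyr::distinct(.data$gene_id, .data$chrom) |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(split_chrom) > 0) {
    rlang::abort(paste0(
      "gene(s) span more than one chromosome: ",
      paste(split_chrom$gene_id, collapse = ", ")
    ))
  }
  tx <- pc[pc$type == "transcript", ]
  ex <- pc[pc$type == "exon", ]
  cds <- pc[pc$type == "CDS", ]
  if (nrow(tx) == 0) tx <- ex  # GTFs without explicit transcript rows
  genes <- tx |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    )
  merge_per_gene <- function(feat) {
    feat |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::reframe({
        red <- IRanges::reduce(to_iranges(.data$start, .data$end))
        tibble::tibble(start = IRanges::start(red) - 1L, end = IRanges::end(red))
      }) |>
      tidyr::nest(.by = "gene_id", .key = "ivs")
  }
  ex_n <- merge_per_gene(ex)
  cds_n <- if (nrow(cds) > 0) merge_per_gene(cds) else
    tibble::tibble(gene_id = character(), ivs = list())
  empty_ivs <- tibble::tibble(start = integer(), end = integer())
  genes <- genes |>
    dplyr::left_join(dplyr::rename(ex_n, exons = "ivs"), by = "gene_id") |>
    dplyr::left_join(dplyr::rename(cds_n, cds = "ivs"), by = "gene_id") |>
    dplyr::mutate(
      exons = purrr::map(.data$exons, ~ if (is.null(.x)) empty_ivs else .x),
      cds = purrr::map(.data$cds, ~ if (is.null(.x)) empty_ivs else .x),
      single_exon = purrr::map_int(.data$exons, nrow) == 1L
    ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select(
      "gene_id", "chrom", "strand", "start", "end", "single_exon",
      "exons", "cds"
    )
  bad <- purrr::map2_lgl(genes$exons, seq_len(nrow(genes)), function(e, i) {
    nrow(e) > 0 && (min(e$start) < genes$start[i] || max(e$end) > genes$end[i])
  })
  if (any(bad)) {
    rlang::abort(paste0(
      "exons fall outside the merged transcript span for: ",
      paste(genes$gene_id[bad], collapse = ", ")
    ))
  }
  genes
}

#' Write gene models back to a GTF file
#'
#' Emits gene, transcript, exon and CDS features (one synthetic transcript
#' per gene holding the merged intervals), converting back to 1-based
#' closed GTF coordinates. Round-trips through [read_gene_models()].
#'
#' @param genes A gene-model tibble as returned by [read_gene_models()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(genes, path) {
  attr_str <- function(gid, tid = NULL) {
    s <- sprintf('gene_id "%s"; gene_type "protein_coding";', gid)
    if (!is.null(tid)) s <- paste0(s, sprintf(' transcript_id "%s";', tid))
    s
  }
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tid <- paste0(g$gene_id, ".t1")
    base <- function(type, s, e, at) {
      sprintf("%s\tspliceoe\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, s + 1L, e, g$strand, at)
    }
    lines <- c(
      lines,
      base("gene", g$start, g$end, attr_str(g$gene_id)),
      base("transcript", g$start, g$end, attr_str(g$gene_id, tid))
    )
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, base("exon", ex$start[j], ex$end[j],
                             attr_str(g$gene_id, tid)))
    }
    cd <- g$cds[[1]]
    for (j in seq_len(nrow(cd))) {
      lines <- c(lines, base("CDS", cd$start[j], cd$end[j],
                             attr_str(g$gene_id, tid)))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

# Merged gene spans as a plain interval tibble (chrom/start/end/gene_id).
gene_spans <- function(genes) {
  tibble::tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    gene_id = genes$gene_id
  )
}
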