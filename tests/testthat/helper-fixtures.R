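# A hand-built filtering fixture: one gene, 100 variants of which 17
# violate exactly one inclusion criterion each, leaving 83.
filter_fixture <- function() {
  set.seed(20240601)
  nt <- c("A", "C", "G", "T")
  reference <- list(chr1 = paste(sample(nt, 3000, replace = TRUE),
                                 collapse = ""))
  ref_at <- function(p) substr(reference$chr1, p + 1L, p + 1L)
  genes <- tibble::tibble(
    gene_id = "G1", chrom = "chr1", strand = "+",
    start = 1000L, end = 2000L, single_exon = FALSE,
    exons = list(tibble::tibble(start = c(1000L, 1600L),
                                end = c(1400L, 2000L))),
    cds = list(tibble::tibble(start = c(1000L, 1600L),
                              end = c(1400L, 2000L)))
  )
  # score records: genic positions except two planted unscored holes,
  # plus a stretch outside the gene so out-of-gene variants stay scored
  unscored_pos <- c(1450L, 1451L)
  score_pos <- c(setdiff(1000:1999, unscored_pos), 2100:2150)
  site_scores <- purrr::map(score_pos, function(p) {
    r <- ref_at(p)
    tibble::tibble(chrom = "chr1", pos = p, ref = r,
                   alt = setdiff(nt, r),
                   ag = 0.05, al = 0.02, dg = 0.01, dl = 0.0)
  }) |> dplyr::bind_rows()
  mask <- tibble::tibble(chrom = "chr1", start = 1500L, end = 1510L)
  coverage <- tibble::tibble(chrom = "chr1", pos = c(1000:1999, 2100:2150),
                             fraction_10x = 0.95)
  mk <- function(pos, ref = ref_at(pos), alt = NULL, ac = 3L,
                 filter = "PASS") {
    if (is.null(alt)) alt <- setdiff(nt, ref)[1]
    tibble::tibble(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                   ac = ac, filter = filter)
  }
  clean_pos <- setdiff(1000:1399, c(unscored_pos, 1500:1509))[1:83]
  clean <- dplyr::bind_rows(purrr::map(clean_pos, mk))
  bad <- dplyr::bind_rows(
    dplyr::mutate(mk(1601L), alt = "AT"),             # not an SNV
    dplyr::mutate(mk(1602L), ref = "AC"),             # not an SNV
    mk(1603L, filter = "LowQual"),                    # non-PASS
    mk(1604L, filter = "RF"),                         # non-PASS
    mk(1605L, ac = 0L),                               # AC = 0
    mk(1606L, ac = 0L),                               # AC = 0
    mk(1607L), mk(1608L),                             # low coverage (below)
    mk(1609L, ref = setdiff(nt, ref_at(1609L))[1]),   # ref mismatch
    mk(1610L, ref = setdiff(nt, ref_at(1610L))[1]),   # ref mismatch
    mk(2110L), mk(2120L),                             # outside the gene
    mk(1450L), mk(1451L),                             # unscored sites
    mk(1502L), mk(1505L),                             # masked
    mk(1615L)                                         # in the truth set
  )
  coverage$fraction_10x[coverage$pos %in% c(1607L, 1608L)] <- 0.3
  # keep the ref-mismatch rows scored for their (wrong) ref so that only
  # the reference check fails
  mismatch <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", pos = 1609L,
                   ref = setdiff(nt, ref_at(1609L))[1],
                   alt = setdiff(nt, setdiff(nt, ref_at(1609L))[1]),
                   ag = 0.01, al = 0, dg = 0, dl = 0),
    tibble::tibble(chrom = "chr1", pos = 1610L,
                   ref = setdiff(nt, ref_at(1610L))[1],
                   alt = setdiff(nt, setdiff(nt, ref_at(1610L))[1]),
                   ag = 0.01, al = 0, dg = 0, dl = 0)
  )
  site_scores <- dplyr::bind_rows(site_scores, mismatch)
  truth <- dplyr::bind_rows(mk(1615L))
  truth$label <- "pathogenic"
  variants <- dplyr::bind_rows(clean, bad)
  stopifnot(nrow(variants) == 100L)
  list(variants = variants, genes = genes, site_scores = site_scores,
       coverage = coverage, mask = mask, truth = truth,
       reference = reference, n_clean = 83L)
}

# Synthetic feature table with a planted decision rule:
# pathogenic iff constraint > 0.9 and spliceai > 0.5.
planted_examples <- function(n = 600L, seed = 9L) {
  withr::with_seed(seed, {
    x <- tibble::tibble(
      constraint = runif(n), spliceai = runif(n), squirls = runif(n),
      region_id = sprintf("r%04d", seq_len(n))
    )
    x$label <- ifelse(x$constraint > 0.9 & x$spliceai > 0.5,
                      "pathogenic", "benign")
    # guarantee a usable pathogenic class
    x$label[1:10] <- "pathogenic"
    x$constraint[1:10] <- runif(10, 0.92, 1)
    x$spliceai[1:10] <- runif(10, 0.6, 1)
    x
  })
}
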