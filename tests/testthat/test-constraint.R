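mk_genes <- function(span_end = 150L) {
  tibble::tibble(
    gene_id = "G1", chrom = "chr1", strand = "+",
    start = 0L, end = span_end, single_exon = FALSE,
    exons = list(tibble::tibble(start = 0L, end = span_end)),
    cds = list(tibble::tibble(start = 0L, end = span_end))
  )
}

uniform_table <- function(p = 0.01) {
  counts <- tidyr::expand_grid(ref = c("A", "C", "G", "T"), bin = 1:8)
  counts$chrom_class <- "autosome"
  counts$n_var <- round(p * 1000)
  counts$n_novar <- 1000L - counts$n_var
  substitution_table(counts)
}

test_that("windowed tiling covers gene spans and respects the minimum size", {
  regions <- enumerate_windows(mk_genes(150L), window_size = 50L)
  expect_equal(regions$start, c(0L, 50L, 100L))
  expect_equal(regions$end, c(50L, 100L, 150L))
  expect_error(enumerate_windows(mk_genes(), window_size = 10L),
               "informative-site cutoff")
  per_gene <- enumerate_windows(mk_genes(150L), mode = "per-gene")
  expect_equal(nrow(per_gene), 1L)
  expect_equal(per_gene$end, 150L)
})

test_that("per-gene mode emits one region per gene with merged-span bounds", {
  b <- small_bundle()
  regions <- enumerate_windows(b$genes, mode = "per-gene",
                               genome = b$genome)
  in_par <- b$genes$chrom == "chrX" &
    b$genes$end <= b$genome$par$end[1]
  expect_equal(nrow(regions), nrow(b$genes) - sum(in_par))
})

test_that("X windows overlapping a PAR interval are dropped", {
  b <- small_bundle()
  regions <- enumerate_windows(b$genes, window_size = 50L,
                               genome = b$genome)
  x_par <- dplyr::mutate(b$genome$par,
                         chrom = b$genome$chroms$chrom[
                           b$genome$chroms$chrom_class == "X"][1])
  overlaps <- regions$chrom == x_par$chrom &
    regions$start < x_par$end & regions$end > x_par$start
  expect_false(any(overlaps))
  # the first X gene lies wholly inside PAR1: none of its windows remain
  par_gene <- b$genes$gene_id[b$genes$chrom == "chrX"][1]
  expect_false(any(purrr::map_lgl(regions$gene_ids,
                                  ~ par_gene %in% .x)))
})

test_that("region tallies match the arithmetic definition", {
  # 50 scored sites, no variants, all in one cell with p = 0.01:
  # that cell's expectation is 0.5 and all observed counts are 0
  sites <- tibble::tibble(
    chrom = "chr1", pos = 0:49, ref = "A", max_sum = 0.05,
    has_variant = FALSE, sum_score = 0.05, bin = 1L, informative = TRUE
  )
  regions <- enumerate_windows(mk_genes(50L), window_size = 50L)
  tal <- tally_regions(regions, sites, uniform_table(0.01))
  expect_equal(tal$e_raw[[1]][1], 0.5, tolerance = 1e-12)
  expect_equal(sum(tal$o_raw[[1]]), 0)
  expect_lte(sum(tal$e_raw[[1]]), tal$end[1] - tal$start[1])
  expect_equal(tal$coverage_frac, 1)
  expect_equal(tal$n_informative, 50L)
})

test_that("tallies on simulated data equal an independent per-site loop", {
  b <- small_bundle()
  filtered <- filter_population_variants(
    b$variants, b$genes, b$site_scores, b$coverage,
    mask = b$mask, truth = b$truth, reference = b$reference
  )
  sites <- restrict_sites(summarize_sites(b$site_scores, filtered),
                          b$genes, b$genome, "autosome", b$mask)
  tab <- substitution_table(count_substitutions(sites))
  regions <- enumerate_windows(b$genes[b$genes$chrom == "chr1", ][1:3, ],
                               window_size = 50L)
  tal <- tally_regions(regions, sites, tab)
  for (i in sample(nrow(tal), 5)) {
    want <- oracle_tally(tal$chrom[i], tal$start[i], tal$end[i],
                         sites, tab, 8L)
    expect_equal(tal$o_raw[[i]], want$o, tolerance = 1e-12)
    expect_equal(tal$e_raw[[i]], want$e, tolerance = 1e-12)
  }
})

test_that("weight schemes evaluate per the published rules", {
  counts <- tidyr::expand_grid(ref = c("A", "C", "G", "T"), bin = 1:8)
  counts$chrom_class <- "autosome"
  counts$n_var <- 10L
  counts$n_novar <- 90L
  tab <- substitution_table(counts)  # proportion 1/32, p 0.1 everywhere
  expect_equal(weight_vector("unweighted", tab)$weight, rep(1, 32))
  expect_equal(weight_vector("inverse_proportion", tab)$weight,
               rep(32, 32))
  expect_equal(weight_vector("log", tab)$weight,
               rep(-10 * log10(1 / 32), 32))
  expect_equal(weight_vector("one_minus_proportion", tab)$weight,
               rep(1 - 1 / 32, 32))
  expect_equal(weight_vector("inverse_substitution_rate", tab)$weight,
               rep(10, 32))
  lin <- weight_vector("linear", tab)
  expect_equal(lin$weight[lin$bin == 1][1], 0.05)  # midpoint of [0, 0.1)
  expect_equal(lin$weight[lin$bin == 8][1], 3)     # midpoint of [2, 4]
})

test_that("zero-denominator cells get weight 0 and a flag", {
  counts <- tidyr::expand_grid(ref = c("A", "C", "G", "T"), bin = 1:8)
  counts$chrom_class <- "autosome"
  counts$n_var <- 10L
  counts$n_novar <- 90L
  counts$n_var[1] <- 0L
  counts$n_novar[1] <- 0L
  tab <- suppressWarnings(substitution_table(counts))
  w <- weight_vector("inverse_proportion", tab)
  expect_equal(w$weight[w$cell == 1], 0)
  expect_true(w$flagged[w$cell == 1])
})

test_that("weighted O/E is exactly zero when observed equals expected", {
  counts <- tidyr::expand_grid(ref = c("A", "C", "G", "T"), bin = 1:8)
  counts$chrom_class <- "autosome"
  counts$n_var <- 5L
  counts$n_novar <- 495L
  tab <- substitution_table(counts)
  for (s in c("unweighted", "linear", "log", "one_minus_proportion",
              "inverse_proportion", "inverse_substitution_rate")) {
    expect_identical(
      weighted_oe(numeric(32), numeric(32), weight_vector(s, tab)), 0)
  }
  # one bin with o = 0, e = 1 and unit weight contributes (1-2)/2
  o <- numeric(32); e <- numeric(32); e[5] <- 1
  expect_equal(weighted_oe(o, e, rep(1, 32)), -0.5)
})

test_that("weighted O/E equals a hand-coded loop on random tallies", {
  set.seed(77)
  w <- runif(32, 0.5, 40)
  for (rep in 1:20) {
    o <- rpois(32, 0.7)
    e <- runif(32, 0, 2)
    hand <- 0
    for (i in 1:32) {
      hand <- hand + w[i] * ((1 + o[i]) - (1 + e[i])) / (1 + e[i])
    }
    expect_equal(weighted_oe(o, e, w), hand, tolerance = 1e-12)
  }
})

test_that("adding one observed variant shifts O/E by exactly X[i]/E[i]", {
  set.seed(12)
  w <- runif(32, 1, 30)
  o <- rpois(32, 0.5)
  e <- runif(32, 0, 2)
  base <- weighted_oe(o, e, w)
  for (i in c(1L, 17L, 32L)) {
    o2 <- o
    o2[i] <- o2[i] + 1
    expect_equal(weighted_oe(o2, e, w) - base, w[i] / (1 + e[i]),
                 tolerance = 1e-12)
  }
})

test_that("window filter applies the informative-site and coverage cutoffs", {
  regions <- tibble::tibble(
    region_id = c("a", "b", "c"), chrom = "chr1",
    start = c(0L, 50L, 100L), end = c(50L, 100L, 150L),
    n_informative = c(7L, 6L, 20L),
    coverage_frac = c(0.9, 0.95, 0.79)
  )
  kept <- filter_windows(regions)
  expect_equal(kept$region_id, "a")
  expect_warning(
    filter_windows(regions, window_filter_config(lambda = 0.05)),
    "below the cutoff"
  )
})

test_that("single-exon adjustment shifts only single-exon regions, upward", {
  genes <- dplyr::bind_rows(
    mk_genes(150L),
    tibble::tibble(gene_id = "SE", chrom = "chr1", strand = "+",
                   start = 500L, end = 650L, single_exon = TRUE,
                   exons = list(tibble::tibble(start = 500L, end = 650L)),
                   cds = list(tibble::tibble(start = 500L, end = 650L)))
  )
  regions <- tibble::tibble(
    region_id = c("m1", "m2", "s1"), chrom = "chr1",
    start = c(0L, 50L, 500L), end = c(50L, 100L, 550L),
    gene_ids = list("G1", "G1", "SE"),
    oe = c(-2, 1, -1)
  )
  out <- adjust_single_exon(regions, genes, delta = 2)
  expect_equal(out$oe, c(-2, 1, 1))
  expect_equal(out$single_exon_adj, c(FALSE, FALSE, TRUE))
  # default delta anchors the single-exon mean at the multi-exon 80th
  # percentile and never shifts downward
  out2 <- adjust_single_exon(regions, genes)
  expect_gte(mean(out2$oe[out2$single_exon_adj]),
             mean(regions$oe[c(3)]))
  # no single-exon regions: identity
  out3 <- adjust_single_exon(regions[1:2, ], genes)
  expect_equal(out3$oe, regions$oe[1:2])
})

test_that("rank normalization maps O/E onto [0,1] against constraint", {
  regions <- tibble::tibble(
    region_id = c("a", "b", "c"), chrom = "chr1",
    start = c(0L, 50L, 100L), end = c(50L, 100L, 150L),
    oe = c(-3, 0, 5)
  )
  m <- normalize_constraint(regions)
  expect_equal(m$regions$constraint_score, c(1, 0.5, 0))
  expect_error(normalize_constraint(regions[1, ]), "at least two")
})

test_that("normalization equals a brute-force sort-and-rank, ties averaged", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    oe <- sample(c(rnorm(n - 2), rep(0.37, 2)))  # force a tie
    regions <- tibble::tibble(
      region_id = as.character(seq_len(n)), chrom = "chr1",
      start = seq_len(n) * 100L, end = seq_len(n) * 100L + 50L,
      oe = oe
    )
    m <- normalize_constraint(regions)
    expect_equal(m$regions$constraint_score, oracle_normalize(oe),
                 tolerance = 1e-12)
    tied <- which(oe == 0.37)
    expect_equal(m$regions$constraint_score[tied[1]],
                 m$regions$constraint_score[tied[2]])
    # anti-monotone in raw O/E
    expect_true(all(diff(m$regions$constraint_score[order(oe)]) <= 0))
  }
})

test_that("position lookup returns the covering score, max over overlaps", {
  regions <- tibble::tibble(
    region_id = c("r1", "r2", "r3"), chrom = "chr1",
    start = c(0L, 25L, 200L), end = c(50L, 75L, 250L),
    oe = c(-5, 2, 0)
  )
  m <- normalize_constraint(regions)
  sc <- m$regions$constraint_score
  expect_equal(score_position(m, "chr1", 10L), sc[1])
  expect_equal(score_position(m, "chr1", 30L), max(sc[1:2]))
  expect_true(is.na(score_position(m, "chr1", 100L)))
  expect_equal(region_at_position(m, "chr1", 30L), "r1")
})

test_that("the display transform is -10 log10(1 - s) with a cap at 1", {
  expect_equal(log_display_score(0), 0)
  expect_equal(log_display_score(0.9), 10)
  expect_equal(log_display_score(0.99), 20)
  expect_equal(log_display_score(1, cap = 45), 45)
  expect_error(log_display_score(1.2), "\\[0, 1\\]")
})
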