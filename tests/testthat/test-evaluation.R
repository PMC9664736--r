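toy_scores <- c(0.95, 0.9, 0.85, 0.8, 0.7, 0.6, 0.5, 0.4, 0.35, 0.2,
                0.1, 0.05)

test_that("PR curves hit the analytic endpoints", {
  perfect <- pr_curve(c(0.9, 0.8, 0.2, 0.1),
                      c("pathogenic", "pathogenic", "benign", "benign"))
  expect_true(any(perfect$precision == 1 & perfect$recall == 1))
  expect_equal(average_precision(perfect), 1)
  flat <- pr_curve(rep(0.5, 10), rep(c("pathogenic", "benign"), 5))
  expect_equal(nrow(flat), 1L)
  expect_equal(flat$precision, 0.5)
  expect_equal(flat$recall, 1)
  expect_equal(average_precision(flat), 0.5)
  expect_error(pr_curve(1:3 / 4, rep("benign", 3)), "both classes")
})

test_that("a 12-point toy curve matches brute-force confusion matrices", {
  labs <- rep(c("pathogenic", "benign"), 6)
  curve <- pr_curve(toy_scores, labs)
  want <- oracle_pr(toy_scores, labs)
  expect_equal(curve$threshold, want$threshold)
  expect_equal(curve$precision, want$precision, tolerance = 1e-12)
  expect_equal(curve$recall, want$recall, tolerance = 1e-12)
  expect_equal(average_precision(curve),
               oracle_average_precision(toy_scores, labs),
               tolerance = 1e-12)
  # ties between scores collapse to one threshold
  tied <- pr_curve(c(0.9, 0.9, 0.1, 0.1),
                   c("pathogenic", "benign", "pathogenic", "benign"))
  expect_equal(nrow(tied), 2L)
  expect_equal(tied$precision,
               oracle_pr(c(0.9, 0.9, 0.1, 0.1),
                         c("pathogenic", "benign", "pathogenic",
                           "benign"))$precision)
})

test_that("average precision is 1 exactly when classes separate strictly", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(6:15, 1)
    scores <- runif(n)
    labs <- sample(rep(c("pathogenic", "benign"), length.out = n))
    ap <- average_precision(pr_curve(scores, labs))
    expect_gte(ap, 0)
    expect_lte(ap, 1)
    strict <- min(scores[labs == "pathogenic"]) >
      max(scores[labs == "benign"])
    expect_equal(ap == 1, strict)
  }
})

test_that("the PR baseline is the pathogenic fraction", {
  expect_equal(pr_baseline(100, 300), 0.25)
  expect_equal(pr_baseline(0, 10), 0)
  expect_equal(pr_baseline(5, 5), 0.5)
  expect_error(pr_baseline(0, 0), "empty")
})

test_that("decile edges are lower-inclusive, last bin closed", {
  expect_equal(decile_index(0.1), 2L)
  expect_equal(decile_index(1.0), 10L)
  expect_equal(decile_index(0.0999999), 1L)
  expect_equal(decile_index(0), 1L)
  expect_error(decile_index(1.5), "\\[0, 1\\]")
  # partition: every score maps to exactly one bin
  set.seed(2)
  s <- c(runif(500), seq(0, 1, by = 0.1))
  idx <- decile_index(s)
  expect_true(all(idx >= 1 & idx <= 10))
  expect_true(all(s >= (idx - 1) / 10 - 1e-12))
  expect_true(all(s < idx / 10 + 1e-12 | idx == 10L))
})

test_that("odds ratios follow the printed 2x2 formulas", {
  # symmetric table: OR = 1 and the CI spans 1
  scores <- c(rep(0.05, 20), rep(0.95, 20))
  labels <- rep(c("pathogenic", "benign"), 20)
  et <- odds_ratio_enrichment(scores, labels)
  expect_equal(et$odds_ratio[et$decile == 1], 1)
  expect_lt(et$ci_lo[et$decile == 1], 1)
  expect_gt(et$ci_hi[et$decile == 1], 1)
  # hand-computed example: A=20, B=5, C=10, D=40
  sc <- c(rep(0.95, 25), rep(0.05, 50))
  lb <- c(rep("pathogenic", 20), rep("benign", 5),
          rep("pathogenic", 10), rep("benign", 40))
  et2 <- odds_ratio_enrichment(sc, lb)
  row <- et2[et2$decile == 10, ]
  expect_equal(row$odds_ratio, 16)
  expect_equal(row$se, sqrt(1 / 20 + 1 / 5 + 1 / 10 + 1 / 40),
               tolerance = 1e-12)
  expect_equal(row$ci_lo, exp(log(16) - 1.96 * row$se), tolerance = 1e-12)
  # marginals conserve class totals in every decile
  expect_true(all(abs((et2$A + et2$C) -
                        (30 + 2 * et2$corrected * 0.5)) < 1e-9))
})

test_that("enrichment agrees with an independent 2x2 oracle on random tables", {
  set.seed(99)
  for (rep in 1:200) {
    n <- 400
    scores <- runif(n)
    labels <- ifelse(runif(n) < 0.3 * scores + 0.05, "pathogenic",
                     "benign")
    if (length(unique(labels)) < 2) next
    et <- odds_ratio_enrichment(scores, labels)
    dec <- decile_index(scores)
    for (i in sample(1:10, 3)) {
      a <- sum(labels == "pathogenic" & dec == i)
      b <- sum(labels == "benign" & dec == i)
      cc <- sum(labels == "pathogenic") - a
      d <- sum(labels == "benign") - b
      want <- oracle_or(a, b, cc, d)
      row <- et[et$decile == i, ]
      expect_equal(row$odds_ratio, want$or, tolerance = 1e-12)
      expect_equal(row$se, want$se, tolerance = 1e-12)
      expect_equal(row$ci_lo, want$lo, tolerance = 1e-12)
      expect_equal(row$ci_hi, want$hi, tolerance = 1e-12)
    }
  }
})

test_that("subset rules implement the clinical strata and compose", {
  ex <- tibble::tibble(
    rel_pos = c("A-1", "D+2", "splice_region_intronic",
                "splice_region_exonic", "intronic", "deep_intronic",
                "exonic", "deep_exonic", "A-2", "D+1"),
    spliceai = c(0.9, 0.1, 0.3, 0.15, 0.05, 0.01, 0.5, 0.1, 0.25, 0.18)
  )
  no_canon <- subset_filter(ex, "drop_canonical")
  expect_false(any(no_canon$rel_pos %in% c("A-1", "A-2", "D+1", "D+2")))
  expect_true("splice_region_intronic" %in% no_canon$rel_pos)
  no_sr <- subset_filter(ex, "drop_splice_region")
  expect_true(all(no_sr$rel_pos %in% c("intronic", "deep_intronic",
                                       "exonic", "deep_exonic")))
  low <- subset_filter(ex, "low_spliceai")
  expect_true(all(low$spliceai < 0.2))
  composed <- subset_filter(ex, c("drop_splice_region", "low_spliceai"))
  manual <- ex[!ex$rel_pos %in% c("A-1", "A-2", "D+1", "D+2",
                                  "splice_region_intronic",
                                  "splice_region_exonic") &
                 ex$spliceai < 0.2, ]
  expect_equal(as.data.frame(composed), as.data.frame(manual))
  expect_error(subset_filter(ex, "nope"), "unknown subset rule")
})

test_that("evaluation reports summarize methods over subsets", {
  set.seed(8)
  ex <- tibble::tibble(
    label = rep(c("pathogenic", "benign"), c(30, 70)),
    rel_pos = sample(c("A-1", "deep_intronic", "exonic"), 100,
                     replace = TRUE),
    spliceai = runif(100),
    method_a = c(runif(30, 0.5, 1), runif(70, 0, 0.6))
  )
  rep_all <- evaluation_report(ex, list(a = "method_a"))
  expect_equal(rep_all$n_path, 30)
  expect_equal(rep_all$baseline, 0.3)
  rep_sub <- evaluation_report(ex, list(a = "method_a"),
                               subset = "drop_canonical")
  expect_lt(rep_sub$n_path + rep_sub$n_benign, 100)
})
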