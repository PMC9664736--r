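test_that("feature assembly takes the max delta score and drops unscorable variants", {
  b <- small_bundle()
  fit <- suppressWarnings(fit_splice_constraint(b))
  ex <- assemble_examples(b$truth, fit, genome = b$genome)
  expect_true(all(c("constraint", "spliceai", "squirls",
                    "region_id") %in% names(ex)))
  expect_equal(ex$spliceai, pmax(ex$ag, ex$al, ex$dg, ex$dl))
  expect_true(all(is.finite(ex$constraint)))
  # brute-force recount: autosomal truth variants with a covering region
  auto <- b$truth[!grepl("X$", b$truth$chrom), ]
  covered <- !is.na(score_position(fit$models$autosome, auto$chrom,
                                   auto$pos))
  expect_equal(nrow(ex), sum(covered))
})

test_that("a single variant row yields the expected max feature", {
  truth <- tibble::tibble(
    chrom = "chr1", pos = 5L, ref = "A", alt = "C", label = "pathogenic",
    ag = 0.1, al = 0.6, dg = 0.0, dl = 0.2, squirls_max = 0.5
  )
  expect_equal(pmax(truth$ag, truth$al, truth$dg, truth$dl), 0.6)
})

test_that("group split keeps regions intact and is seed-deterministic", {
  ex <- planted_examples(1000L)
  # two variants sharing a region are always co-assigned
  ex$region_id[2] <- ex$region_id[1]
  s1 <- group_split_examples(ex, seed = 5L)
  expect_equal(s1$split[1], s1$split[2])
  s2 <- group_split_examples(ex, seed = 5L)
  expect_identical(s1$split, s2$split)
  s3 <- group_split_examples(ex, seed = 6L)
  expect_false(identical(s1$split, s3$split))
  expect_error(
    group_split_examples(dplyr::mutate(ex, region_id = "one")),
    "one constraint region"
  )
})

test_that("the realized training share concentrates around 60%", {
  ex <- planted_examples(1000L)
  fracs <- vapply(1:200, function(s) {
    mean(group_split_examples(ex, seed = s)$split == "train")
  }, numeric(1))
  expect_true(all(fracs >= 0.5 & fracs <= 0.7))
})

test_that("stratified folds hit exact per-fold class counts on single-variant regions", {
  ex <- tibble::tibble(
    constraint = 0.5, spliceai = 0.5, squirls = 0.5,
    region_id = sprintf("r%03d", 1:500),
    label = rep(c("pathogenic", "benign"), c(100, 400))
  )
  out <- stratified_group_folds(ex, k = 5L, seed = 3L)
  tab <- table(out$fold, out$label)
  expect_equal(unname(tab[, "pathogenic"]), rep(20L, 5))
  expect_equal(unname(tab[, "benign"]), rep(80L, 5))
  # no region in two folds
  expect_equal(dplyr::n_distinct(paste(out$region_id, out$fold)),
               dplyr::n_distinct(out$region_id))
})

test_that("cross-validation folds are disjoint, exhaustive and above baseline", {
  ex <- planted_examples(500L)
  cv <- cross_validate_ensemble(ex, k = 5L, n_trees = 150L, seed = 2L)
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(sum(cv$folds$n_path + cv$folds$n_benign), nrow(ex))
  base <- pr_baseline(sum(ex$label == "pathogenic"),
                      sum(ex$label == "benign"))
  expect_true(all(cv$folds$average_precision > base))
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(nrow(glance(cv)), 1L)
})

test_that("training is reproducible and recovers a planted rule", {
  ex <- planted_examples(800L)
  split <- group_split_examples(ex, seed = 4L)
  tr <- split[split$split == "train", ]
  te <- split[split$split == "test", ]
  m1 <- train_ensemble(tr, n_trees = 1000L, seed = 7L)
  m2 <- train_ensemble(tr, n_trees = 1000L, seed = 7L)
  expect_equal(m1$forest$num.trees, 1000L)
  p1 <- predict(m1, te)
  p2 <- predict(m2, te)
  expect_identical(p1, p2)
  expect_identical(m1$fingerprint, m2$fingerprint)
  expect_true(all(p1 >= 0 & p1 <= 1))
  acc <- mean((p1 >= 0.5) == (te$label == "pathogenic"))
  expect_gt(acc, 0.95)
  # duplicate rows score identically
  pd <- predict(m1, te[c(1, 1), ])
  expect_equal(pd[1], pd[2])
  expect_error(predict(m1, te[, c("spliceai", "squirls")]),
               "missing feature")
  expect_error(train_ensemble(dplyr::mutate(tr, label = "benign")),
               "both classes")
})

test_that("shuffling the only informative feature collapses performance", {
  ex <- planted_examples(800L, seed = 21L)
  # make constraint the only informative feature
  ex$label <- ifelse(ex$constraint > 0.8, "pathogenic", "benign")
  split <- group_split_examples(ex, seed = 8L)
  tr <- split[split$split == "train", ]
  te <- split[split$split == "test", ]
  full <- train_ensemble(tr, n_trees = 300L, seed = 3L)
  ap_full <- average_precision(pr_curve(predict(full, te), te$label))
  tr_abl <- tr
  tr_abl$constraint <- withr::with_seed(99L, sample(tr$constraint))
  te_abl <- te
  te_abl$constraint <- withr::with_seed(98L, sample(te$constraint))
  abl <- train_ensemble(tr_abl, n_trees = 300L, seed = 3L)
  ap_abl <- average_precision(pr_curve(predict(abl, te_abl), te$label))
  base <- pr_baseline(sum(te$label == "pathogenic"),
                      sum(te$label == "benign"))
  expect_gt(ap_full, 0.95)
  expect_lt(ap_abl, base + 0.25)
})

test_that("models survive a save/load round trip and reject corrupt files", {
  ex <- planted_examples(300L)
  m <- train_ensemble(ex, n_trees = 100L, seed = 1L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(m, path)
  m2 <- load_ensemble(path)
  probe <- planted_examples(50L, seed = 33L)
  expect_identical(predict(m, probe), predict(m2, probe))
  expect_identical(m2$fingerprint, m$fingerprint)
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_ensemble(bad), "cannot read|not a spliceoe")
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something_else"), other)
  expect_error(load_ensemble(other), "not a spliceoe")
})
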