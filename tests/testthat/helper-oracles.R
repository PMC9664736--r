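# Independent oracle implementations used to cross-check the package.
# These deliberately use naive loops, not the vectorized code paths.

# Precision/recall by explicit confusion matrices at every distinct
# threshold (descending), predicting positive when score >= threshold.
oracle_pr <- function(scores, labels) {
  pos <- labels == "pathogenic"
  ths <- sort(unique(scores), decreasing = TRUE)
  out <- data.frame(threshold = ths, precision = NA_real_,
                    recall = NA_real_)
  for (i in seq_along(ths)) {
    called <- scores >= ths[i]
    tp <- sum(called & pos)
    out$precision[i] <- tp / sum(called)
    out$recall[i] <- tp / sum(pos)
  }
  out
}

oracle_average_precision <- function(scores, labels) {
  pr <- oracle_pr(scores, labels)
  r_prev <- 0
  ap <- 0
  for (i in seq_len(nrow(pr))) {
    ap <- ap + (pr$recall[i] - r_prev) * pr$precision[i]
    r_prev <- pr$recall[i]
  }
  ap
}

# 2x2 odds ratio with Haldane-Anscombe correction and log-scale CI.
oracle_or <- function(a, b, cc, d) {
  if (any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  or <- (a / b) / (cc / d)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(or = or, se = se,
       lo = exp(log(or) - 1.96 * se),
       hi = exp(log(or) + 1.96 * se))
}

# Naive descending sort-and-rank normalization with tie averaging.
oracle_normalize <- function(oe) {
  n <- length(oe)
  asc_rank <- numeric(n)
  for (i in seq_len(n)) {
    asc_rank[i] <- mean(which(sort(oe) == oe[i]))
  }
  (n - asc_rank) / (n - 1)
}

# Per-site loop over one region against a site summary and probability
# lookup; mirrors the tally definition literally.
oracle_tally <- function(chrom, start, end, sites, table, n_bins) {
  cell_of <- function(ref, bin) {
    (match(ref, c("A", "C", "G", "T")) - 1L) * n_bins + bin
  }
  p <- numeric(4L * n_bins)
  p[cell_of(table$ref, table$bin)] <- table$p
  o <- numeric(4L * n_bins)
  e <- numeric(4L * n_bins)
  for (pos in start:(end - 1L)) {
    row <- which(sites$chrom == chrom & sites$pos == pos)
    if (length(row) == 0) next
    cl <- cell_of(sites$ref[row], sites$bin[row])
    e[cl] <- e[cl] + p[cl]
    if (sites$has_variant[row]) o[cl] <- o[cl] + 1
  }
  list(o = o, e = e)
}

# Rank-based AUC of scores against binary labels.
rank_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  cmp <- outer(sp, sn, ">")
  eq <- outer(sp, sn, "==")
  mean(cmp) + 0.5 * mean(eq)
}

# Tiny deterministic bundle for quick unit tests.
small_bundle <- function(seed = 101L) {
  simulate_bundle(simulation_config(
    seed = seed, n_genes = 10L, n_genes_x = 3L,
    n_pathogenic = 15L, n_benign = 60L
  ))
}

# Per-site depletion classes recomputed from a bundle's own outputs:
# which scored sites are high-score (max summed score >= the motif
# threshold) and lie in planted constrained genes.
site_depletion_table <- function(b) {
  sites <- b$site_scores |>
    spliceoe::sum_delta_scores() |>
    dplyr::group_by(chrom, pos) |>
    dplyr::summarise(max_sum = max(sum_score), .groups = "drop")
  spans <- dplyr::arrange(
    tibble::tibble(chrom = b$genes$chrom, start = b$genes$start,
                   end = b$genes$end, gene_id = b$genes$gene_id),
    chrom, start)
  sites$gene_id <- NA_character_
  for (cc in unique(spans$chrom)) {
    sel <- sites$chrom == cc
    sp <- spans[spans$chrom == cc, ]
    idx <- findInterval(sites$pos[sel], sp$start)
    ok <- idx >= 1 & sites$pos[sel] < sp$end[pmax(idx, 1)]
    gid <- rep(NA_character_, sum(sel))
    gid[ok] <- sp$gene_id[idx[ok]]
    sites$gene_id[sel] <- gid
  }
  con <- b$gene_classes$gene_id[b$gene_classes$constrained]
  tibble::tibble(
    chrom = sites$chrom, pos = sites$pos,
    constrained = sites$gene_id %in% con,
    high = sites$max_sum >= b$config$motif_threshold
  )
}
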