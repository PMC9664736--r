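#' Assemble labeled feature vectors from a truth set
#'
#' Builds the three-feature vector the ensemble classifier trains on:
#' the regional constraint score, the max splice-prediction delta score
#' (the largest of AG/AL/DG/DL for the variant; switchable to the summed
#' score), and the max spliceosome-classifier score. Variants off the
#' autosomes, or missing any required annotation (including a constraint
#' score -- e.g. falling in a filtered-out window), are excluded. Each
#' example keeps the id of the constraint region it falls in, which later
#' drives group-aware splitting.
#'
#' @param truth Truth tibble from [read_truth_set()].
#' @param fit A `splice_constraint_fit` (or a single `constraint_model`).
#' @param genome Optional [genome_config()] used to identify autosomes;
#'   without it, chromosome names ending in `"X"` are treated as X.
#' @param spliceai_feature `"max"` (default) to use the max of the four
#'   delta scores as the splice-prediction feature, `"sum"` for the
#'   summed score.
#' @return Tibble of examples: truth columns plus `spliceai`, `squirls`,
#'   `constraint`, `region_id`, `label`.
#' @export
assemble_examples <- function(truth, fit, genome = NULL,
                              spliceai_feature = c("max", "sum")) {
  spliceai_feature <- match.arg(spliceai_feature)
  x <- truth
  if (!is.null(genome)) {
    cls <- chrom_class_of(genome, x$chrom)
    x <- x[cls == "autosome", , drop = FALSE]
  } else {
    x <- x[!grepl("X$", x$chrom), , drop = FALSE]
  }
  x$spliceai <- if (spliceai_feature == "max") {
    pmax(x$ag, x$al, x$dg, x$dl)
  } else {
    pmin(x$ag + x$al + x$dg + x$dl, 1)
  }
  x$squirls <- x$squirls_max
  x <- annotate_constraint(x, if (inherits(fit, "splice_constraint_fit"))
    fit$models else fit)
  x$region_id <- x$constraint_region
  x <- x[stats::complete.cases(x[, c("spliceai", "squirls", "constraint",
                                     "region_id")]), , drop = FALSE]
  if (length(unique(x$label)) < 2) {
    rlang::abort("need both pathogenic and benign examples after filtering")
  }
  x
}

#' Region-grouped train/test split
#'
#' Randomly assigns whole constraint regions (not individual variants) to
#' the training or test side, so variants sharing a region never straddle
#' the split; each region lands on the training side with probability
#' `train_frac`, making the expected training share of variants
#' `train_frac`.
#'
#' @param examples Examples from [assemble_examples()].
#' @param train_frac Expected training fraction (default 0.6).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return `examples` with a `split` column (`"train"`/`"test"`).
#' @export
group_split_examples <- function(examples, train_frac = 0.6, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  regions <- sort(unique(examples$region_id))
  if (length(regions) < 2) {
    rlang::abort("all examples fall in one constraint region; cannot split")
  }
  assign <- withr::with_seed(seed, {
    stats::rbinom(length(regions), 1L, train_frac) == 1L
  })
  names(assign) <- regions
  examples$split <- ifelse(assign[examples$region_id], "train", "test")
  examples
}

#' Stratified, region-grouped cross-validation folds
#'
#' Assigns constraint regions to `k` folds so that no region's variants
#' appear in two folds, while keeping the pathogenic and benign counts as
#' even as possible across folds (largest regions placed first, each into
#' the fold where it least disturbs the class balance).
#'
#' @param examples Examples carrying `region_id` and `label`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return `examples` with an integer `fold` column.
#' @export
stratified_group_folds <- function(examples, k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  reg <- examples |>
    dplyr::count(.data$region_id, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  for (cl in c("pathogenic", "benign")) {
    if (!cl %in% names(reg)) reg[[cl]] <- 0L
  }
  reg$size <- reg$pathogenic + reg$benign
  reg <- withr::with_seed(seed, reg[sample.int(nrow(reg)), , drop = FALSE])
  reg <- reg[order(-reg$size), , drop = FALSE]
  fold_path <- numeric(k)
  fold_ben <- numeric(k)
  fold_of <- integer(nrow(reg))
  for (i in seq_len(nrow(reg))) {
    # increase in squared class load if this region joins each fold;
    # a single-class region is steered purely by its own class
    cost <- (fold_path + reg$pathogenic[i])^2 - fold_path^2 +
      (fold_ben + reg$benign[i])^2 - fold_ben^2
    f <- which.min(cost)
    fold_of[i] <- f
    fold_path[f] <- fold_path[f] + reg$pathogenic[i]
    fold_ben[f] <- fold_ben[f] + reg$benign[i]
  }
  if (any(fold_path == 0) || any(fold_ben == 0)) {
    rlang::abort("stratification failed: a fold lacks one of the classes")
  }
  examples$fold <- fold_of[match(examples$region_id, reg$region_id)]
  examples
}

ensemble_features <- function() c("constraint", "spliceai", "squirls")

#' Train the random-forest ensemble
#'
#' Fits a probability forest (default 1000 trees) on the three-feature
#' vector with standard defaults otherwise: unlimited depth,
#' sqrt-features per split, bootstrap sampling. Training is fully
#' reproducible from the recorded seed, and a fingerprint of the training
#' data and seed is stored with the model.
#'
#' @param examples Examples from [assemble_examples()] (with `label`).
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer training seed.
#' @return A `splice_ensemble` object.
#' @export
train_ensemble <- function(examples, n_trees = 1000L, seed = 1L) {
  feats <- ensemble_features()
  if (length(unique(examples$label)) < 2) {
    rlang::abort("both classes are required to train the ensemble")
  }
  df <- examples[, feats]
  df$label <- factor(examples$label, levels = c("benign", "pathogenic"))
  forest <- ranger::ranger(
    dependent.variable.name = "label", data = df,
    num.trees = n_trees, probability = TRUE, importance = "impurity",
    seed = seed, num.threads = 1
  )
  structure(
    list(forest = forest, features = feats, n_trees = n_trees,
         seed = seed,
         fingerprint = rlang::hash(list(df, seed, n_trees)),
         version = 1L),
    class = "splice_ensemble"
  )
}

#' @export
print.splice_ensemble <- function(x, ...) {
  cat("<splice_ensemble>", x$n_trees, "trees | features:",
      paste(x$features, collapse = ", "), "| seed", x$seed, "\n")
  invisible(x)
}

#' Predict pathogenicity probabilities
#'
#' @param object A `splice_ensemble`.
#' @param newdata Tibble carrying the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector in \[0, 1\]: the forest vote fraction for the
#'   pathogenic class. A recommended preliminary decision cutoff is 0.5.
#' @export
predict.splice_ensemble <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing feature column(s): ",
                        paste(missing, collapse = ", ")))
  }
  pr <- stats::predict(object$forest, data = newdata[, object$features],
                       num.threads = 1)
  unname(pr$predictions[, "pathogenic"])
}

#' Cross-validate the ensemble on the training set
#'
#' Runs stratified, region-grouped k-fold cross-validation: each fold's
#' model is trained on the remaining folds and evaluated on the held-out
#' fold with a precision-recall curve; a pooled curve over all held-out
#' predictions summarizes the combined performance.
#'
#' @param examples Training examples.
#' @param k Number of folds (default 5).
#' @param n_trees Trees per fold model.
#' @param seed Integer seed (drives both fold assignment and training).
#' @return A `splice_cv` list: per-fold tibble (`fold`, `n_path`,
#'   `n_benign`, `average_precision`, `curve`) and the pooled curve and
#'   average precision.
#' @export
cross_validate_ensemble <- function(examples, k = 5L, n_trees = 1000L,
                                    seed = 1L) {
  examples <- stratified_group_folds(examples, k = k, seed = seed)
  folds <- sort(unique(examples$fold))
  per_fold <- purrr::map(folds, function(f) {
    tr <- examples[examples$fold != f, , drop = FALSE]
    va <- examples[examples$fold == f, , drop = FALSE]
    m <- train_ensemble(tr, n_trees = n_trees, seed = seed + f)
    p <- predict(m, va)
    curve <- pr_curve(p, va$label)
    tibble::tibble(
      fold = f,
      n_path = sum(va$label == "pathogenic"),
      n_benign = sum(va$label == "benign"),
      average_precision = average_precision(curve),
      curve = list(curve),
      scores = list(p),
      labels = list(va$label)
    )
  }) |>
    dplyr::bind_rows()
  pooled <- pr_curve(unlist(per_fold$scores), unlist(per_fold$labels))
  structure(
    list(folds = per_fold, pooled_curve = pooled,
         pooled_average_precision = average_precision(pooled),
         k = k, seed = seed, assignments = examples$fold),
    class = "splice_cv"
  )
}

#' @export
print.splice_cv <- function(x, ...) {
  cat("<splice_cv>", x$k, "folds | pooled average precision",
      round(x$pooled_average_precision, 4), "\n")
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.splice_cv <- function(x, ...) {
  dplyr::select(x$folds, "fold", "n_path", "n_benign",
                "average_precision")
}

#' @rdname tidiers
#' @export
glance.splice_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    mean_average_precision = mean(x$folds$average_precision),
    pooled_average_precision = x$pooled_average_precision
  )
}

#' @rdname tidiers
#' @export
tidy.splice_ensemble <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidiers
#' @export
glance.splice_ensemble <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    n_train = x$forest$num.samples,
    oob_brier = x$forest$prediction.error,
    seed = x$seed
  )
}

#' Save / load a trained ensemble
#'
#' The model file is a versioned serialized object with embedded
#' metadata; loading verifies the version and the object class, and a
#' reloaded model predicts identically to the original.
#'
#' @param ensemble A `splice_ensemble`.
#' @param path File path.
#' @return `save_ensemble`: `path` invisibly. `load_ensemble`: the
#'   restored `splice_ensemble`.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "splice_ensemble"))
  saveRDS(list(format = "spliceoe_ensemble", format_version = 1L,
               model = ensemble), path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    rlang::abort(paste0("cannot read model file: ", conditionMessage(e)))
  })
  if (!is.list(obj) || !identical(obj$format, "spliceoe_ensemble")) {
    rlang::abort("file is not a spliceoe ensemble model")
  }
  if (!identical(obj$format_version, 1L)) {
    rlang::abort(paste0("unsupported model format version: ",
                        obj$format_version))
  }
  obj$model
}
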