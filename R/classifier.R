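#' Assemble a modelling dataset from rho features and island labels
#'
#' Joins the feature table with the label table and keeps only islands with
#' a definite label. Uncovered islands (no attributed events) are dropped
#' too: an all-zero vector carries no fragmentation information.
#'
#' @param rho Rho tibble from [compute_rho()] / [featurize()].
#' @param labels Label tibble from [label_islands()].
#' @param sample_name Provenance tag stored with the dataset.
#' @param keep_uncovered Keep islands with N = 0 (default FALSE).
#' @return Tibble `island_id`, `chrom`, `start`, `end`, `label`, rho
#'   columns; attribute `sample_name`.
#' @export
make_dataset <- function(rho, labels, sample_name = "sample",
                         keep_uncovered = FALSE) {
  if (anyDuplicated(rho$island_id)) stop("duplicated island_id in feature table")
  out <- rho |>
    dplyr::inner_join(
      dplyr::select(labels, "island_id", "label"), by = "island_id"
    ) |>
    dplyr::filter(!is.na(.data$label))
  if (!keep_uncovered) out <- dplyr::filter(out, !.data$uncovered)
  out <- dplyr::select(out, "island_id", "chrom", "start", "end", "label",
                       dplyr::all_of(rho_cols()))
  attr(out, "sample_name") <- sample_name
  out
}

#' Balance a dataset by undersampling the majority class
#'
#' The minority class is kept whole; the majority class is downsampled
#' uniformly without replacement to the minority size. Deterministic given
#' the seed.
#'
#' @param dataset Labeled dataset tibble from [make_dataset()].
#' @param seed Integer seed.
#' @return Balanced dataset tibble.
#' @export
balance_by_undersampling <- function(dataset, seed) {
  tab <- table(factor(dataset$label, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present to balance")
  minority <- as.integer(names(tab)[which.min(tab)])
  majority <- 1L - minority
  n_min <- min(tab)
  maj_idx <- which(dataset$label == majority)
  keep <- with_seed(seed, sort(sample(maj_idx, n_min)))
  out <- dataset[sort(c(which(dataset$label == minority), keep)), , drop = FALSE]
  attr(out, "sample_name") <- attr(dataset, "sample_name")
  out
}

#' Train the random-forest methylation classifier
#'
#' Fits a two-class random forest of the form
#' y ~ (rho_AA, rho_AC, ..., rho_TT). The caller supplies a class-balanced
#' dataset (see [balance_by_undersampling()]), so the implied class priors
#' are 0.5/0.5. An optional grid search selects `num_trees`/`min_node` by
#' internal cross-validated macro accuracy on the training split only.
#'
#' @param dataset Balanced labeled dataset tibble.
#' @param num_trees Number of trees (default 500).
#' @param mtry Features per split (default floor(sqrt(16)) = 4).
#' @param min_node Minimum terminal node size (default 1).
#' @param seed Integer seed.
#' @param grid Optional named list, e.g.
#'   `list(num_trees = c(100, 500), min_node = c(1, 5))`; when supplied, all
#'   combinations are scored by `grid_k`-fold cross-validation on `dataset`
#'   and the best is refit on the whole training set.
#' @param grid_k Folds for the internal grid search (default 5).
#' @param r_hat Optional methylated fraction inferred from the unbalanced
#'   training labels; stored in the bundle for later top-r prediction.
#' @param sample_name Provenance tag.
#' @return An `fm_model` bundle.
#' @export
train_forest <- function(dataset, num_trees = 500, mtry = 4, min_node = 1,
                         seed = 1, grid = NULL, grid_k = 5, r_hat = NULL,
                         sample_name = attr(dataset, "sample_name") %||% "sample") {
  y <- factor(dataset$label, levels = c(0, 1))
  if (length(unique(dataset$label)) < 2)
    stop("training requires both classes")
  x <- as.matrix(dataset[, rho_cols()])
  if (!is.null(grid)) {
    combos <- expand.grid(
      num_trees = grid$num_trees %||% num_trees,
      min_node = grid$min_node %||% min_node
    )
    scores <- purrr::map_dbl(seq_len(nrow(combos)), function(i) {
      folds <- stratified_folds(dataset$label, grid_k, seed = seed + 1000L)
      accs <- purrr::map_dbl(seq_len(grid_k), function(f) {
        tr <- folds != f
        fit <- with_seed(seed + f, randomForest::randomForest(
          x[tr, , drop = FALSE], y[tr],
          ntree = combos$num_trees[i], mtry = mtry,
          nodesize = combos$min_node[i]
        ))
        p <- predict(fit, x[!tr, , drop = FALSE], type = "prob")[, "1"]
        macro_accuracy(dataset$label[!tr], as.integer(p > 0.5))
      })
      mean(accs, na.rm = TRUE)
    })
    best <- which.max(scores)
    num_trees <- combos$num_trees[best]
    min_node <- combos$min_node[best]
  }
  forest <- with_seed(seed, randomForest::randomForest(
    x, y, ntree = num_trees, mtry = mtry, nodesize = min_node
  ))
  structure(
    list(
      forest = forest,
      feature_order = rho_cols(),
      num_trees = num_trees, mtry = mtry, min_node = min_node,
      seed = seed,
      r_hat = r_hat,
      class_balance = "trained on balanced classes; implied priors 0.5/0.5",
      sample_name = sample_name,
      fragmeth_version = as.character(utils::packageVersion("fragmeth"))
    ),
    class = "fm_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fm_model <- function(x, ...) {
  cat("<fm_model> random forest, ", x$num_trees, " trees, mtry ", x$mtry,
      ", min node ", x$min_node, "\n", sep = "")
  cat("  trained on: ", x$sample_name, " (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$r_hat))
    cat("  inferred methylated fraction r = ", signif(x$r_hat, 4), "\n", sep = "")
  invisible(x)
}

#' Posterior probability of methylation per island
#'
#' The posterior is the fraction of trees in the ensemble voting for the
#' methylated class (the forest's vote share), in \[0,1\].
#'
#' @param model An `fm_model`.
#' @param rho Rho tibble (must contain the 16 canonical feature columns).
#' @return Tibble `island_id` (plus `chrom`/`start`/`end` when present),
#'   `posterior`.
#' @export
predict_posteriors <- function(model, rho) {
  stopifnot(inherits(model, "fm_model"))
  missing_cols <- setdiff(model$feature_order, names(rho))
  if (length(missing_cols))
    stop("feature table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  x <- as.matrix(rho[, model$feature_order])
  p <- predict(model$forest, x, type = "prob")[, "1"]
  keep <- intersect(c("island_id", "chrom", "start", "end"), names(rho))
  dplyr::bind_cols(rho[, keep], tibble(posterior = unname(p)))
}

#' Hard labels by posterior ranking: the top-r rule
#'
#' Islands are sorted by decreasing posterior (posterior ties broken by
#' genomic coordinate, then id, for determinism); the top round(r * K)
#' islands are labeled methylated and the remaining 1 - r fraction
#' unmethylated.
#'
#' @param posteriors Tibble from [predict_posteriors()].
#' @param r Expected methylated fraction, in \[0,1\].
#' @return The input with an added integer `pred_label` column.
#' @export
apply_top_r <- function(posteriors, r) {
  stopifnot(r >= 0, r <= 1)
  k <- nrow(posteriors)
  n_meth <- round(r * k)
  ord <- order(
    -posteriors$posterior,
    if ("chrom" %in% names(posteriors)) posteriors$chrom else rep(0L, k),
    if ("start" %in% names(posteriors)) posteriors$start else rep(0L, k),
    posteriors$island_id
  )
  pred <- integer(k)
  pred[ord[seq_len(n_meth)]] <- 1L
  dplyr::mutate(posteriors, pred_label = pred)
}

# mean of per-class accuracies; NA when a truth class is absent
macro_accuracy <- function(truth, pred) {
  accs <- purrr::map_dbl(c(0L, 1L), function(cl) {
    idx <- truth == cl
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] == cl)
  })
  mean(accs)
}

# average precision from posteriors (AP over the ranked positives)
average_precision <- function(truth, posterior) {
  ord <- order(-posterior)
  pos <- truth[ord] == 1L
  if (!any(pos)) return(NA_real_)
  prec <- cumsum(pos) / seq_along(pos)
  sum(prec[pos]) / sum(pos)
}

#' Evaluate predictions against ground-truth labels
#'
#' Computes the macro-averaged accuracy (the unweighted mean of the per-
#' class accuracies over the methylated and unmethylated classes), the ROC
#' curve and its AUC, the precision-recall curve and average precision, and
#' the confusion matrix.
#'
#' @param truth Tibble with `island_id` and integer `label`.
#' @param predictions Tibble with `island_id`, `posterior` and either a
#'   `pred_label` column or an `r` to derive one.
#' @param r Optional expected methylated fraction used to derive hard labels
#'   via [apply_top_r()] when `predictions` lacks `pred_label`.
#' @return An `fm_eval` object (also a list): `macro_accuracy`, `auc_roc`,
#'   `average_precision`, `confusion`, `roc`, `pr`, `n`.
#' @export
evaluate_predictions <- function(truth, predictions, r = NULL) {
  if (!"pred_label" %in% names(predictions)) {
    if (is.null(r)) stop("predictions lack pred_label; supply r for the top-r rule")
    predictions <- apply_top_r(predictions, r)
  }
  df <- dplyr::inner_join(
    dplyr::select(truth, "island_id", truth_label = "label"),
    predictions, by = "island_id"
  )
  df <- dplyr::filter(df, !is.na(.data$truth_label))
  if (length(unique(df$truth_label)) < 2)
    stop("macro accuracy undefined: a truth class is absent")
  roc_obj <- pROC::roc(df$truth_label, df$posterior, quiet = TRUE,
                       levels = c("0", "1"), direction = "<")
  roc_tbl <- tibble(
    threshold = roc_obj$thresholds,
    tpr = roc_obj$sensitivities,
    fpr = 1 - roc_obj$specificities
  )
  ord <- order(-df$posterior)
  pos <- df$truth_label[ord] == 1L
  pr_tbl <- tibble(
    recall = cumsum(pos) / sum(pos),
    precision = cumsum(pos) / seq_along(pos)
  )
  structure(
    list(
      macro_accuracy = macro_accuracy(df$truth_label, df$pred_label),
      auc_roc = as.numeric(pROC::auc(roc_obj)),
      average_precision = average_precision(df$truth_label, df$posterior),
      confusion = table(truth = factor(df$truth_label, levels = c(0, 1)),
                        predicted = factor(df$pred_label, levels = c(0, 1))),
      roc = roc_tbl,
      pr = pr_tbl,
      n = nrow(df)
    ),
    class = "fm_eval"
  )
}

#' @export
print.fm_eval <- function(x, ...) {
  cat("<fm_eval> ", x$n, " islands\n", sep = "")
  cat("  macro accuracy   ", signif(x$macro_accuracy, 4), "\n", sep = "")
  cat("  ROC AUC          ", signif(x$auc_roc, 4), "\n", sep = "")
  cat("  avg precision    ", signif(x$average_precision, 4), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

# stratified fold assignment; falls back to unstratified with a warning
# when a class has fewer members than folds
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  folds <- integer(n)
  tab <- table(labels)
  if (any(tab < k)) {
    warning("a class has fewer than ", k, " members; using unstratified folds")
    return(with_seed(seed, sample(rep_len(seq_len(k), n))))
  }
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the methylation classifier
#'
#' Islands are partitioned into k class-stratified folds. Within each fold
#' the training split is balanced by undersampling, a forest is trained,
#' and posteriors are computed for the held-out islands; hard labels use
#' the top-r rule with r inferred from the training split (or supplied).
#' Test folds keep their natural class distribution.
#'
#' @param dataset Labeled dataset tibble from [make_dataset()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param num_trees,mtry,min_node Forest hyperparameters.
#' @param r Optional fixed methylated fraction for the top-r rule; default
#'   is the labeled fraction of each training split.
#' @return An `fm_cv` object: `folds` (per-fold metric tibble), `posteriors`
#'   (pooled held-out posteriors), `summary` (mean metrics).
#' @export
cross_validate <- function(dataset, k = 10, seed = 1, num_trees = 500,
                           mtry = 4, min_node = 1, r = NULL) {
  stopifnot(k >= 2, nrow(dataset) >= k)
  fold_of <- stratified_folds(dataset$label, k, seed = seed)
  res <- purrr::map(seq_len(k), function(f) {
    train <- dataset[fold_of != f, , drop = FALSE]
    test <- dataset[fold_of == f, , drop = FALSE]
    r_f <- r %||% mean(train$label == 1L)
    balanced <- balance_by_undersampling(train, seed = seed + f)
    model <- train_forest(balanced, num_trees = num_trees, mtry = mtry,
                          min_node = min_node, seed = seed + 100L + f)
    post <- apply_top_r(predict_posteriors(model, test), r = r_f)
    ev <- tryCatch(
      evaluate_predictions(dplyr::select(test, "island_id", "label"), post),
      error = function(e) NULL
    )
    list(
      metrics = tibble(
        fold = f, n_test = nrow(test),
        macro_accuracy = if (is.null(ev)) NA_real_ else ev$macro_accuracy,
        auc_roc = if (is.null(ev)) NA_real_ else ev$auc_roc,
        average_precision = if (is.null(ev)) NA_real_ else ev$average_precision
      ),
      posteriors = dplyr::mutate(
        dplyr::inner_join(post, dplyr::select(test, "island_id", "label"),
                          by = "island_id"),
        fold = f
      )
    )
  })
  folds <- purrr::map_dfr(res, "metrics")
  structure(
    list(
      folds = folds,
      posteriors = purrr::map_dfr(res, "posteriors"),
      summary = dplyr::summarise(
        folds,
        macro_accuracy = mean(.data$macro_accuracy, na.rm = TRUE),
        auc_roc = mean(.data$auc_roc, na.rm = TRUE),
        average_precision = mean(.data$average_precision, na.rm = TRUE)
      )
    ),
    class = "fm_cv"
  )
}

#' @export
print.fm_cv <- function(x, ...) {
  cat("<fm_cv> ", nrow(x$folds), "-fold cross-validation\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Mean-decrease-in-impurity feature importance
#'
#' Gini impurity reductions at every split using a feature, weighted by the
#' samples reaching the node and averaged over trees (MDI), normalised to
#' sum to 1 over the 16 dinucleotide features.
#'
#' @param model An `fm_model`.
#' @return Named numeric vector in canonical feature order, summing to 1.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "fm_model"))
  imp <- model$forest$importance[, "MeanDecreaseGini"]
  imp <- imp[model$feature_order]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

#' Save / load a model bundle
#'
#' The bundle embeds the feature order, seed and training provenance, so a
#' reloaded model reproduces posteriors bit-identically.
#'
#' @param model An `fm_model`.
#' @param path File path.
#' @return `save_model`: `path`, invisibly. `load_model`: an `fm_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fm_model")) stop("not an fm_model bundle: ", path)
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted model: feature importances
#'
#' @param x An `fm_model`.
#' @param ... Unused.
#' @return Tibble `feature`, `dinucleotide`, `importance` (MDI, sums to 1).
#' @method tidy fm_model
#' @export
tidy.fm_model <- function(x, ...) {
  imp <- feature_importance(x)
  tibble(
    feature = names(imp),
    dinucleotide = sub("^rho_", "", names(imp)),
    importance = unname(imp)
  )
}

#' One-row model summary
#'
#' @param x An `fm_model`.
#' @param ... Unused.
#' @return One-row tibble with hyperparameters and OOB error.
#' @method glance fm_model
#' @export
glance.fm_model <- function(x, ...) {
  tibble(
    num_trees = x$num_trees, mtry = x$mtry, min_node = x$min_node,
    oob_error = tail(x$forest$err.rate[, "OOB"], 1),
    seed = x$seed, sample_name = x$sample_name
  )
}

#' Tidy an evaluation: metrics in long form
#'
#' @param x An `fm_eval`.
#' @param ... Unused.
#' @return Tibble `metric`, `value`.
#' @method tidy fm_eval
#' @export
tidy.fm_eval <- function(x, ...) {
  tibble(
    metric = c("macro_accuracy", "auc_roc", "average_precision"),
    value = c(x$macro_accuracy, x$auc_roc, x$average_precision)
  )
}

#' One-row evaluation summary
#'
#' @param x An `fm_eval`.
#' @param ... Unused.
#' @return One-row tibble of the headline metrics.
#' @method glance fm_eval
#' @export
glance.fm_eval <- function(x, ...) {
  tibble(macro_accuracy = x$macro_accuracy, auc_roc = x$auc_roc,
         average_precision = x$average_precision, n = x$n)
}
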