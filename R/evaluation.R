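# Evaluation: confusion matrices (rows = true class, columns = predicted),
# overall accuracy = 100 * trace / total, per-activity accuracy = class
# recall (diagonal / row sum), stratified holdout and k-fold CV.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of instances whose true class is `class_i`
#' and predicted class `class_j`, over the fixed activity order `A1..A5`
#' (or a supplied level set). Rows are true classes, columns predicted.
#'
#' @param true,predicted Equal-length label vectors.
#' @param levels Class order; defaults to [activity_levels()].
#'
#' @return Integer matrix of class `posture_confusion`.
#' @export
#' @examples
#' confusion_matrix(c("A1", "A1"), c("A1", "A2"))
confusion_matrix <- function(true, predicted, levels = activity_levels()) {
  stopifnot(length(true) == length(predicted), length(true) >= 1)
  bad <- setdiff(unique(c(as.character(true), as.character(predicted))), levels)
  if (length(bad) > 0) {
    abort(
      paste0("labels outside the class order: ", paste(bad, collapse = ", ")),
      class = "sitsense_bad_label"
    )
  }
  tf <- factor(as.character(true), levels = levels)
  pf <- factor(as.character(predicted), levels = levels)
  m <- unclass(table(tf, pf))
  dimnames(m) <- list(true = levels, predicted = levels)
  structure(m, class = c("posture_confusion", class(m)))
}

as_posture_confusion <- function(m, levels = rownames(m)) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  dimnames(m) <- list(true = levels, predicted = levels)
  structure(m, class = c("posture_confusion", class(m)))
}

#' Per-activity accuracy (class recall)
#'
#' `100 * counts[c, c] / rowsum(c)`, rounded half-up to `digits` decimals.
#' A class with an empty row has undefined recall and is reported as `NA`.
#'
#' @param cm A `posture_confusion` matrix.
#' @param class Activity id; if `NULL`, all classes.
#' @param digits Reporting precision (decimal places).
#'
#' @return Named numeric vector of percentages.
#' @export
per_activity_accuracy <- function(cm, class = NULL, digits = 2) {
  rs <- rowSums(cm)
  acc <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  acc <- round_half_up(acc, digits)
  names(acc) <- rownames(cm)
  if (!is.null(class)) {
    if (!class %in% rownames(cm)) {
      abort(paste0("unknown class: ", class), class = "sitsense_bad_label")
    }
    return(acc[[class]])
  }
  acc
}

#' Overall accuracy
#'
#' `100 * trace / total`, the multiclass reading of accuracy =
#' (TP + TN) / (TP + TN + FP + FN).
#'
#' @inheritParams per_activity_accuracy
#' @return Percentage in \[0, 100\].
#' @export
overall_accuracy <- function(cm, digits = 2) {
  round_half_up(100 * sum(diag(cm)) / sum(cm), digits)
}

#' Per-class TP/TN/FP/FN decomposition
#'
#' One-vs-rest counts per class, for transparency alongside the recall
#' definition of per-activity accuracy.
#'
#' @param cm A `posture_confusion` matrix.
#' @return Tibble with `class`, `tp`, `fp`, `fn`, `tn`.
#' @export
class_counts <- function(cm) {
  tot <- sum(cm)
  tibble(
    class = rownames(cm),
    tp = unname(diag(cm)),
    fp = unname(colSums(cm) - diag(cm)),
    fn = unname(rowSums(cm) - diag(cm)),
    tn = unname(tot - rowSums(cm) - colSums(cm) + diag(cm))
  )
}

#' @method tidy posture_confusion
#' @export
tidy.posture_confusion <- function(x, ...) {
  df <- as_tibble(as.table(x))
  names(df) <- c("true", "predicted", "n")
  df$n <- as.integer(df$n)
  df
}

#' @method glance posture_confusion
#' @export
glance.posture_confusion <- function(x, ...) {
  tibble(
    total = sum(x), correct = sum(diag(x)),
    overall_accuracy = overall_accuracy(x)
  )
}

#' @method autoplot posture_confusion
#' @export
autoplot.posture_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "grey20") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted class", y = "True class", fill = "Count")
}

#' Stratified train/test split
#'
#' Shuffles within each class (seeded) and assigns the first
#' `round(train_fraction * n_class)` rows to training, preserving class
#' proportions within one instance.
#'
#' @param fm Feature matrix tibble.
#' @param train_fraction Fraction in (0, 1); the published protocol used
#'   0.75 (a 3:1 split).
#' @param seed Seed for the shuffle.
#'
#' @return List with `train` and `test` tibbles (disjoint, exhaustive).
#' @export
stratified_split <- function(fm, train_fraction = 0.75, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- as.character(fm$label)
  if (any(table(y) < 2)) {
    abort("every class needs at least 2 instances",
      class = "sitsense_small_class"
    )
  }
  set.seed(stage_seed(seed, "split"))
  train_idx <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    ntr <- round(train_fraction * length(idx))
    ntr <- min(max(ntr, 1), length(idx) - 1)
    train_idx <- c(train_idx, idx[seq_len(ntr)])
  }
  list(
    train = fm[sort(train_idx), ],
    test = fm[sort(setdiff(seq_len(nrow(fm)), train_idx)), ]
  )
}

stratified_folds <- function(y, k, seed) {
  set.seed(stage_seed(seed, "folds"))
  fold <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Per-feature max-abs scaling fit on training rows, applied with clipping.
# Leakage-safe normalization for evaluation mode.
fit_feature_scale <- function(train, features) {
  vapply(features, function(f) {
    s <- max(abs(train[[f]]))
    if (s == 0) 1 else s
  }, numeric(1))
}

apply_feature_scale <- function(fm, scales) {
  for (f in names(scales)) {
    fm[[f]] <- pmin(pmax(fm[[f]] / scales[[f]], -1), 1)
  }
  fm
}

new_eval_report <- function(cm, split, classifier_id, seed, extra = list()) {
  structure(
    c(
      list(
        confusion = cm,
        overall_accuracy = overall_accuracy(cm),
        per_activity = per_activity_accuracy(cm),
        split = split, classifier = classifier_id, seed = seed
      ),
      extra
    ),
    class = "posture_eval"
  )
}

#' @export
print.posture_eval <- function(x, ...) {
  cat(
    "<posture_eval> ", x$classifier, " | ", x$split, " | overall ",
    format(x$overall_accuracy, nsmall = 2), "%\n",
    sep = ""
  )
  print(unclass(x$confusion))
  invisible(x)
}

#' @method tidy posture_eval
#' @export
tidy.posture_eval <- function(x, ...) {
  tibble(
    classifier = x$classifier,
    class = names(x$per_activity),
    accuracy = unname(x$per_activity)
  )
}

#' @method glance posture_eval
#' @export
glance.posture_eval <- function(x, ...) {
  tibble(
    classifier = x$classifier, split = x$split,
    overall_accuracy = x$overall_accuracy,
    total = sum(x$confusion), seed = x$seed
  )
}

#' Evaluate a classifier with a stratified holdout split
#'
#' Normalization scales (per-feature max-abs) and, optionally, CFS/PSO
#' feature selection are fit on the training part only.
#'
#' @param fm Feature matrix.
#' @param spec One entry of [classifier_roster()] (or a compatible list
#'   with `id` and `fit(fm, features)`).
#' @param features Feature names to use (`NULL` = all).
#' @param train_fraction Training fraction.
#' @param seed Seed.
#' @param rescale Refit per-feature max-abs scaling on the training part.
#'
#' @return A `posture_eval` report.
#' @export
holdout_eval <- function(fm, spec, features = NULL, train_fraction = 0.75,
                         seed = 1, rescale = TRUE) {
  feats <- features %||% feature_columns(fm)
  parts <- stratified_split(fm, train_fraction, seed)
  if (rescale) {
    scales <- fit_feature_scale(parts$train, feats)
    parts$train <- apply_feature_scale(parts$train, scales)
    parts$test <- apply_feature_scale(parts$test, scales)
  }
  model <- spec$fit(parts$train, feats)
  pred <- predict(model, parts$test)
  cm <- confusion_matrix(parts$test$label, pred$label,
    levels = sort(unique(as.character(fm$label)))
  )
  new_eval_report(
    cm, paste0("holdout ", train_fraction), spec$id, seed,
    extra = list(n_train = nrow(parts$train), n_test = nrow(parts$test))
  )
}

#' Stratified k-fold cross-validation
#'
#' Predicts every row exactly once and pools the fold confusion matrices.
#' Per-feature normalization (and feature selection, when `select = TRUE`)
#' is fit within the training folds only.
#'
#' @param fm Feature matrix.
#' @param spec Classifier spec (see [holdout_eval()]).
#' @param k Number of folds (>= 2); every class must have >= k instances.
#' @param features Feature names (`NULL` = all).
#' @param seed Seed.
#' @param select Re-run CFS/PSO selection inside each training fold.
#' @param select_params [pso_params()] for per-fold selection.
#' @param bins Discretization bins for per-fold selection.
#' @param rescale Refit per-feature max-abs scaling per fold.
#'
#' @return A `posture_eval` report with the pooled confusion matrix.
#' @export
kfold_cv <- function(fm, spec, k = 10, features = NULL, seed = 1,
                     select = FALSE, select_params = pso_params(),
                     bins = 10, rescale = TRUE) {
  stopifnot(k >= 2)
  y <- as.character(fm$label)
  if (any(table(y) < k)) {
    abort("every class needs at least k instances", class = "sitsense_small_class")
  }
  feats <- features %||% feature_columns(fm)
  fold <- stratified_folds(y, k, seed)
  true_all <- pred_all <- character(0)
  for (f in seq_len(k)) {
    train <- fm[fold != f, ]
    test <- fm[fold == f, ]
    use <- feats
    if (select) {
      tab <- build_correlation_table(train[c("label", feats)], bins = bins)
      sp <- select_params
      sp$seed <- stage_seed(seed, paste0("select-fold-", f))
      use <- pso_search(tab, sp)$names
    }
    if (rescale) {
      scales <- fit_feature_scale(train, use)
      train <- apply_feature_scale(train, scales)
      test <- apply_feature_scale(test, scales)
    }
    model <- spec$fit(train, use)
    pred <- predict(model, test)
    true_all <- c(true_all, as.character(test$label))
    pred_all <- c(pred_all, pred$label)
  }
  cm <- confusion_matrix(true_all, pred_all, levels = sort(unique(y)))
  new_eval_report(cm, paste0(k, "-fold CV"), spec$id, seed)
}

#' Write an evaluation report
#'
#' JSON (full report) plus an aligned-text table of per-activity and
#' overall accuracies; the confusion matrix additionally as CSV.
#'
#' @param report A `posture_eval`.
#' @param path_json,path_txt,path_csv Output paths (`NULL` to skip).
#' @return `path_json`, invisibly.
#' @export
write_eval_report <- function(report, path_json, path_txt = NULL,
                              path_csv = NULL) {
  jsonlite::write_json(
    list(
      classifier = report$classifier, split = report$split,
      seed = report$seed, overall_accuracy = report$overall_accuracy,
      per_activity = as.list(report$per_activity),
      confusion = unclass(report$confusion),
      class_counts = class_counts(report$confusion)
    ),
    path_json,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(path_csv)) {
    utils::write.csv(unclass(report$confusion), path_csv)
  }
  if (!is.null(path_txt)) {
    lines <- c(
      sprintf("Classifier: %s  (%s)", report$classifier, report$split),
      sprintf("Overall accuracy: %.2f%%", report$overall_accuracy),
      "",
      sprintf("%-6s %10s", "Class", "Recall(%)"),
      sprintf(
        "%-6s %10.2f", names(report$per_activity),
        report$per_activity
      )
    )
    writeLines(lines, path_txt)
  }
  invisible(path_json)
}
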