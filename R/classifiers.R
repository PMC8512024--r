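# The three recognition techniques: Gaussian naive Bayes, K-nearest
# neighbors (Euclidean or median-binarized Hamming), and one-against-all
# RBF-kernel SVM.  All take a feature matrix tibble (label + feature
# columns) and return a fitted object whose predict() method yields a
# tibble of labels and per-class scores.  Ties are always broken toward the
# lowest class id (and for KNN distance ties, the lowest training-row
# index), so predictions are invariant to training-row permutations.

split_xy <- function(fm, features = NULL) {
  feats <- features %||% feature_columns(fm)
  missing <- setdiff(feats, names(fm))
  if (length(missing) > 0) {
    abort(paste0("missing feature columns: ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(fm[feats])
  if (!all(is.finite(x))) {
    abort("non-finite feature values", class = "sitsense_nonfinite_feature")
  }
  list(x = x, y = as.character(fm$label), features = feats)
}

score_tibble <- function(scores, classes) {
  colnames(scores) <- classes
  # argmax with ties toward the lowest class id (classes sorted)
  lab <- classes[apply(scores, 1, which.max)]
  tibble(label = lab, as_tibble(scores))
}

#' Gaussian naive Bayes classifier
#'
#' Per class and feature, a Gaussian density with the class-conditional
#' mean and (population) variance floored at `var_floor`; empirical class
#' priors. Prediction maximizes log-prior plus summed log-densities, ties
#' broken toward the lowest class id.
#'
#' @param fm Training feature matrix (`label` + feature columns). Every
#'   class needs at least 2 rows.
#' @param features Feature names to use (default: all feature columns).
#' @param var_floor Variance floor guarding near-constant features.
#'
#' @return Object of class `posture_nb`.
#' @export
train_nb <- function(fm, features = NULL, var_floor = 1e-9) {
  d <- split_xy(fm, features)
  classes <- sort(unique(d$y))
  counts <- table(d$y)
  if (any(counts < 2)) {
    abort("every class needs at least 2 training rows",
      class = "sitsense_small_class"
    )
  }
  means <- vars <- matrix(0, length(classes), ncol(d$x),
    dimnames = list(classes, d$features)
  )
  for (cl in classes) {
    xc <- d$x[d$y == cl, , drop = FALSE]
    means[cl, ] <- colMeans(xc)
    vars[cl, ] <- pmax(apply(xc, 2, function(v) mean((v - mean(v))^2)), var_floor)
  }
  structure(
    list(
      classes = classes, priors = as.numeric(counts[classes] / sum(counts)),
      means = means, vars = vars, features = d$features,
      var_floor = var_floor
    ),
    class = "posture_nb"
  )
}

#' @export
predict.posture_nb <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$features])
  ll <- matrix(0, nrow(x), length(object$classes))
  for (i in seq_along(object$classes)) {
    mu <- object$means[i, ]
    s2 <- object$vars[i, ]
    # row-wise sum of log N(x | mu, s2)
    ll[, i] <- log(object$priors[i]) +
      rowSums(sweep(-sweep(x, 2, mu)^2, 2, 2 * s2, `/`)) -
      sum(0.5 * log(2 * pi * s2))
  }
  score_tibble(ll, object$classes)
}

#' K-nearest-neighbor classifier
#'
#' Majority vote among the K nearest training rows. `metric = "euclidean"`
#' uses raw distances; `metric = "hamming"` first binarizes every feature
#' at its training-set median (a value is 1 when above the median) and
#' counts disagreeing bits — the convention used here to apply a Hamming
#' metric to real-valued features. Distance ties are resolved toward the
#' lowest training-row index and vote ties toward the lowest class id.
#'
#' @param fm Training feature matrix.
#' @param k Number of neighbors (1..rows).
#' @param metric `"hamming"` (default, as published) or `"euclidean"`.
#' @param features Feature names to use.
#'
#' @return Object of class `posture_knn`.
#' @export
train_knn <- function(fm, k = 3, metric = c("hamming", "euclidean"),
                      features = NULL) {
  metric <- match.arg(metric)
  d <- split_xy(fm, features)
  if (k < 1 || k > nrow(d$x)) {
    abort("k must be in 1..nrow(training data)", class = "sitsense_bad_k")
  }
  medians <- NULL
  x <- d$x
  if (metric == "hamming") {
    medians <- apply(x, 2, median)
    x <- sweep(x, 2, medians, `>`) * 1
  }
  structure(
    list(
      x = x, y = d$y, classes = sort(unique(d$y)), k = as.integer(k),
      metric = metric, medians = medians, features = d$features
    ),
    class = "posture_knn"
  )
}

#' @export
predict.posture_knn <- function(object, newdata, ...) {
  q <- as.matrix(newdata[object$features])
  if (object$metric == "hamming") {
    q <- sweep(q, 2, object$medians, `>`) * 1
    # disagreement count via binary cross-products
    d2 <- q %*% t(1 - object$x) + (1 - q) %*% t(object$x)
  } else {
    d2 <- outer(rowSums(q^2), rep(1, nrow(object$x))) +
      outer(rep(1, nrow(q)), rowSums(object$x^2)) -
      2 * q %*% t(object$x)
    d2[d2 < 0] <- 0
  }
  classes <- object$classes
  votes <- matrix(0, nrow(q), length(classes))
  for (i in seq_len(nrow(q))) {
    # order() breaks distance ties by training-row index
    nn <- order(d2[i, ])[seq_len(object$k)]
    tab <- table(factor(object$y[nn], levels = classes))
    votes[i, ] <- as.numeric(tab) / object$k
  }
  score_tibble(votes, classes)
}

#' One-against-all RBF-kernel SVM
#'
#' One binary soft-margin RBF machine per class (class vs rest); the
#' predicted class maximizes the binary decision value. The
#' quadratic-programming core is delegated to a standard SVM solver; this
#' wrapper owns the one-against-all decomposition, the kernel-scale
#' convention and the score aggregation. The default kernel scale is
#' `sqrt(p)` for `p` features — the convention behind a "medium Gaussian"
#' kernel preset — giving `gamma = 1 / (2 p)`.
#'
#' @param fm Training feature matrix (>= 2 classes).
#' @param cost Soft-margin box constraint C.
#' @param kernel_scale RBF kernel scale sigma; `gamma = 1 / (2 sigma^2)`.
#'   Default `sqrt(p)`.
#' @param features Feature names to use.
#'
#' @return Object of class `posture_svm` with one machine per class.
#' @export
train_svm <- function(fm, cost = 1, kernel_scale = NULL, features = NULL) {
  d <- split_xy(fm, features)
  classes <- sort(unique(d$y))
  if (length(classes) < 2) {
    abort("SVM needs at least 2 classes", class = "sitsense_small_class")
  }
  kernel_scale <- kernel_scale %||% sqrt(ncol(d$x))
  gamma <- 1 / (2 * kernel_scale^2)
  machines <- lapply(classes, function(cl) {
    yy <- factor(ifelse(d$y == cl, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(
      x = d$x, y = yy, kernel = "radial", gamma = gamma, cost = cost,
      scale = FALSE
    )
  })
  names(machines) <- classes
  structure(
    list(
      classes = classes, machines = machines, features = d$features,
      cost = cost, kernel_scale = kernel_scale, gamma = gamma
    ),
    class = "posture_svm"
  )
}

#' @export
predict.posture_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$features])
  dec <- vapply(object$classes, function(cl) {
    pr <- predict(object$machines[[cl]], x, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # e1071 orients the decision value toward the first factor level ("pos")
    # but may flip depending on which label it saw first; normalize sign
    if (colnames(attr(pr, "decision.values")) == "neg/pos") -dv else dv
  }, numeric(nrow(x)))
  dec <- matrix(dec, nrow = nrow(x))
  score_tibble(dec, object$classes)
}

#' @method glance posture_nb
#' @export
glance.posture_nb <- function(x, ...) {
  tibble(
    kind = "nb", n_classes = length(x$classes),
    n_features = length(x$features)
  )
}

#' @method glance posture_knn
#' @export
glance.posture_knn <- function(x, ...) {
  tibble(
    kind = "knn", k = x$k, metric = x$metric,
    n_classes = length(x$classes), n_features = length(x$features),
    n_train = nrow(x$x)
  )
}

#' @method glance posture_svm
#' @export
glance.posture_svm <- function(x, ...) {
  tibble(
    kind = "svm", cost = x$cost, kernel_scale = x$kernel_scale,
    n_classes = length(x$classes), n_features = length(x$features),
    n_support = sum(vapply(x$machines, function(m) m$tot.nSV, numeric(1)))
  )
}

#' @method tidy posture_nb
#' @export
tidy.posture_nb <- function(x, ...) {
  means <- as_tibble(x$means, rownames = "class")
  means_long <- tidyr::pivot_longer(means, -"class",
    names_to = "feature", values_to = "mean"
  )
  vars <- as_tibble(x$vars, rownames = "class")
  vars_long <- tidyr::pivot_longer(vars, -"class",
    names_to = "feature", values_to = "variance"
  )
  left_join(means_long, vars_long, by = c("class", "feature"))
}

#' Classifier roster specification
#'
#' Compact descriptions of the models evaluated by [kfold_cv()] and
#' [run_pipeline()]: naive Bayes, KNN at K in {3, 5, 7, 11}, and SVM.
#'
#' @param knn_k Integer vector of K values.
#' @param knn_metric Distance metric for KNN. The roster defaults to
#'   Euclidean: on continuous window features, median binarization (the
#'   published Hamming convention, available via
#'   `knn_metric = "hamming"`) reduces every feature to one bit and
#'   discards the amplitude structure the synthetic postures differ by.
#' @param svm_cost,svm_kernel_scale SVM hyperparameters.
#' @return Named list of classifier specs (`id`, `fit` function).
#' @export
classifier_roster <- function(knn_k = c(3, 5, 7, 11),
                              knn_metric = "euclidean",
                              svm_cost = 1, svm_kernel_scale = NULL) {
  specs <- list(nb = list(
    id = "nb",
    fit = function(fm, features) train_nb(fm, features = features)
  ))
  for (k in knn_k) {
    kk <- k
    specs[[paste0("knn", kk)]] <- list(
      id = paste0("knn", kk),
      fit = local({
        kfix <- kk
        function(fm, features) {
          train_knn(fm, k = kfix, metric = knn_metric, features = features)
        }
      })
    )
  }
  specs$svm <- list(
    id = "svm",
    fit = function(fm, features) {
      train_svm(fm,
        cost = svm_cost, kernel_scale = svm_kernel_scale,
        features = features
      )
    }
  )
  specs
}
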