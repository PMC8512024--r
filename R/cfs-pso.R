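# Correlation-based feature selection (CFS).
#
# A candidate subset S of k features is scored by Hall's merit
#     merit(S) = k * mean(r_cf) / sqrt(k + k (k - 1) * mean(r_ff)),
# where r_cf are the feature-class correlations and r_ff the pairwise
# feature-feature correlations over S.  Correlation is measured by
# symmetrical uncertainty on discretized features (Pearson offered as a
# variant).  The merit surface is searched by a binary particle swarm;
# an exhaustive search provides the exact optimum for small banks.

#' Symmetrical uncertainty between two discrete variables
#'
#' `SU(A, B) = 2 I(A;B) / (H(A) + H(B))`, a normalized mutual information in
#' \[0, 1\]; 0 when either variable is constant (zero entropy).
#'
#' @param a,b Equal-length vectors treated as categorical.
#' @return SU in \[0, 1\].
#' @export
#' @examples
#' symmetrical_uncertainty(c(1, 1, 2, 2), c("x", "x", "y", "y")) # 1
symmetrical_uncertainty <- function(a, b) {
  if (length(a) != length(b)) {
    abort("a and b must have equal length", class = "sitsense_length_mismatch")
  }
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p)
  pb <- colSums(p)
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  ha <- ent(pa)
  hb <- ent(pb)
  if (ha == 0 || hb == 0) {
    return(0)
  }
  hab <- ent(as.vector(p))
  mi <- ha + hb - hab
  max(0, min(1, 2 * mi / (ha + hb)))
}

discretize_equal_width <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(rep(1L, length(x)))
  }
  cuts <- seq(rng[1], rng[2], length.out = bins + 1)
  findInterval(x, cuts, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Build the CFS correlation table
#'
#' Discretizes each feature into `bins` equal-width bins over its observed
#' range, then computes symmetrical uncertainty between every feature and
#' the class and between every feature pair. With `measure = "pearson"`,
#' absolute Pearson correlation replaces SU for feature pairs and the
#' correlation ratio (square root of the between-class variance fraction)
#' for feature-class association. Constant features get zero correlations:
#' they carry no information.
#'
#' @param fm Feature matrix tibble (`label` column + feature columns).
#' @param bins Number of discretization bins (>= 2).
#' @param measure `"su"` (default) or `"pearson"`.
#'
#' @return List of class `cfs_correlations`: `feature_class` (named vector),
#'   `feature_feature` (symmetric matrix, unit diagonal), `features`,
#'   `measure`, `bins`.
#' @export
build_correlation_table <- function(fm, bins = 10, measure = c("su", "pearson")) {
  measure <- match.arg(measure)
  stopifnot(nrow(fm) >= 1, bins >= 2)
  feats <- feature_columns(fm)
  stopifnot(length(feats) >= 1)
  y <- as.character(fm$label)
  x <- as.matrix(fm[feats])
  p <- length(feats)
  constant <- apply(x, 2, function(v) min(v) == max(v))

  if (measure == "su") {
    xd <- apply(x, 2, discretize_equal_width, bins = bins)
    fc <- vapply(
      seq_len(p),
      function(j) if (constant[j]) 0 else symmetrical_uncertainty(xd[, j], y),
      numeric(1)
    )
    ff <- diag(1, p)
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        v <- if (constant[i] || constant[j]) {
          0
        } else {
          symmetrical_uncertainty(xd[, i], xd[, j])
        }
        ff[i, j] <- ff[j, i] <- v
      }
    }
  } else {
    cls <- factor(y)
    fc <- vapply(seq_len(p), function(j) {
      if (constant[j]) {
        return(0)
      }
      # correlation ratio: sqrt of between-class variance share
      mu <- mean(x[, j])
      btw <- sum(tapply(x[, j], cls, function(v) length(v) * (mean(v) - mu)^2))
      tot <- sum((x[, j] - mu)^2)
      if (tot == 0) 0 else sqrt(btw / tot)
    }, numeric(1))
    ff <- abs(stats::cor(x))
    ff[!is.finite(ff)] <- 0
    diag(ff) <- 1
  }
  names(fc) <- feats
  dimnames(ff) <- list(feats, feats)
  structure(
    list(
      feature_class = fc, feature_feature = ff, features = feats,
      measure = measure, bins = bins
    ),
    class = "cfs_correlations"
  )
}

#' CFS merit of a feature subset
#'
#' `k * mean(r_cf) / sqrt(k + k (k - 1) * mean(r_ff))` over the masked
#' features; for `k = 1` this reduces to the feature's class correlation.
#'
#' @param mask Logical vector over the table's features (>= 1 selected).
#' @param table A [build_correlation_table()] result.
#' @return Merit (unitless).
#' @export
cfs_merit <- function(mask, table) {
  stopifnot(inherits(table, "cfs_correlations"))
  mask <- as.logical(mask)
  k <- sum(mask)
  if (k == 0) abort("empty feature subset", class = "sitsense_empty_subset")
  rcf <- mean(table$feature_class[mask])
  if (k == 1) {
    return(rcf)
  }
  ffsub <- table$feature_feature[mask, mask]
  rff <- mean(ffsub[upper.tri(ffsub)])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Binary PSO parameters
#'
#' Constriction-style defaults: swarm 20, 100 iterations, inertia 0.72,
#' cognitive = social = 1.49, velocity clamp 4, sigmoid transfer.
#'
#' @param swarm_size Particles (>= 2).
#' @param iterations Iterations (>= 1).
#' @param w Inertia weight.
#' @param c1,c2 Cognitive and social acceleration.
#' @param v_max Velocity clamp (absolute).
#' @param seed Seed for the search's RNG stream.
#' @return List of class `pso_params`.
#' @export
pso_params <- function(swarm_size = 20, iterations = 100, w = 0.72,
                       c1 = 1.49, c2 = 1.49, v_max = 4, seed = 1) {
  stopifnot(swarm_size >= 2, iterations >= 1, w > 0, c1 > 0, c2 > 0, v_max > 0)
  structure(
    list(
      swarm_size = swarm_size, iterations = iterations, w = w,
      c1 = c1, c2 = c2, v_max = v_max, seed = seed
    ),
    class = "pso_params"
  )
}

new_feature_subset <- function(mask, table, method, trace = NULL, params = NULL) {
  structure(
    list(
      mask = mask, names = table$features[mask],
      merit = cfs_merit(mask, table), method = method,
      class_corr = unname(table$feature_class[mask]),
      trace = trace, params = params
    ),
    class = "feature_subset"
  )
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(
    "<feature_subset> ", sum(x$mask), "/", length(x$mask),
    " features, merit ", format(x$merit, digits = 4),
    " (", x$method, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Binary particle-swarm search for the best-merit subset
#'
#' Real-valued velocities are updated with inertia, cognitive and social
#' terms, clamped to `[-v_max, v_max]`; each bit is then set with
#' probability `sigmoid(v)`. Fitness is the CFS merit; particles with an
#' empty mask get one random bit switched on. One particle is initialized
#' at the best single feature, so the returned merit is never below the
#' best single-feature class correlation. The global best only improves,
#' so the returned trace is monotone non-decreasing.
#'
#' After the swarm search, a deterministic backward-elimination pass drops
#' any feature whose removal does not lower the merit (`prune = TRUE`),
#' mirroring the parsimony tie-break of [brute_force_best_subset()]:
#' redundant features that ride along at equal merit are eliminated. The
#' pruning step never decreases the returned merit.
#'
#' @param table A [build_correlation_table()] result.
#' @param params A [pso_params()].
#' @param prune Drop equal-merit redundant features after the search.
#'
#' @return A `feature_subset`: `mask`, `names`, `merit`, `method = "pso"`,
#'   `trace` (best merit per iteration), `params`.
#' @export
pso_search <- function(table, params = pso_params(), prune = TRUE) {
  stopifnot(inherits(table, "cfs_correlations"))
  p <- length(table$features)
  if (p < 1) abort("no features to select from", class = "sitsense_empty_subset")
  set.seed(stage_seed(params$seed, "pso"))
  sigmoid <- function(v) 1 / (1 + exp(-v))

  x <- matrix(runif(params$swarm_size * p) < 0.5, params$swarm_size, p)
  # seed one particle with the single best feature
  best1 <- which.max(table$feature_class)
  x[1, ] <- FALSE
  x[1, best1] <- TRUE
  none <- rowSums(x) == 0
  if (any(none)) {
    for (i in which(none)) x[i, sample.int(p, 1)] <- TRUE
  }
  v <- matrix(runif(params$swarm_size * p, -params$v_max, params$v_max),
    params$swarm_size, p
  )
  fit <- apply(x, 1, cfs_merit, table = table)
  pbest <- x
  pbest_fit <- fit
  gi <- which.max(fit)
  gbest <- x[gi, ]
  gbest_fit <- fit[gi]
  trace <- numeric(params$iterations)

  for (it in seq_len(params$iterations)) {
    r1 <- matrix(runif(params$swarm_size * p), params$swarm_size, p)
    r2 <- matrix(runif(params$swarm_size * p), params$swarm_size, p)
    v <- params$w * v +
      params$c1 * r1 * (pbest - x) +
      params$c2 * r2 * (matrix(gbest, params$swarm_size, p, byrow = TRUE) - x)
    v <- pmin(pmax(v, -params$v_max), params$v_max)
    x <- matrix(runif(params$swarm_size * p), params$swarm_size, p) < sigmoid(v)
    none <- rowSums(x) == 0
    if (any(none)) {
      for (i in which(none)) x[i, sample.int(p, 1)] <- TRUE
    }
    fit <- apply(x, 1, cfs_merit, table = table)
    improved <- fit > pbest_fit
    pbest[improved, ] <- x[improved, ]
    pbest_fit[improved] <- fit[improved]
    if (max(fit) > gbest_fit) {
      gi <- which.max(fit)
      gbest <- x[gi, ]
      gbest_fit <- fit[gi]
    }
    trace[it] <- gbest_fit
  }
  if (prune) gbest <- prune_subset(gbest, table)
  new_feature_subset(gbest, table, "pso", trace = trace, params = params)
}

# Greedy backward elimination: repeatedly remove the feature whose removal
# yields the highest merit, as long as the merit does not drop (ties toward
# the lowest feature index).  Deterministic; merit is non-decreasing.
prune_subset <- function(mask, table) {
  cur <- cfs_merit(mask, table)
  repeat {
    idx <- which(mask)
    if (length(idx) <= 1) {
      return(mask)
    }
    cand <- vapply(idx, function(j) {
      m <- mask
      m[j] <- FALSE
      cfs_merit(m, table)
    }, numeric(1))
    best <- which.max(cand)
    if (cand[best] + 1e-12 < cur) {
      return(mask)
    }
    mask[idx[best]] <- FALSE
    cur <- cand[best]
  }
}

#' Exhaustive best-merit subset (validation oracle)
#'
#' Enumerates all non-empty subsets (feature count capped at 20) and
#' returns the exact merit maximum. Ties are broken toward smaller
#' subsets, then lexicographic mask order.
#'
#' @param table A [build_correlation_table()] result.
#' @return A `feature_subset` with `method = "brute_force"`.
#' @export
brute_force_best_subset <- function(table) {
  stopifnot(inherits(table, "cfs_correlations"))
  p <- length(table$features)
  if (p > 20) {
    abort("brute force capped at 20 features", class = "sitsense_too_many")
  }
  best_mask <- NULL
  best_merit <- -Inf
  best_k <- Inf
  for (code in seq_len(2^p - 1)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
    m <- cfs_merit(mask, table)
    k <- sum(mask)
    better <- m > best_merit + 1e-12 ||
      (abs(m - best_merit) <= 1e-12 && k < best_k)
    if (better) {
      best_mask <- mask
      best_merit <- m
      best_k <- k
    }
  }
  new_feature_subset(best_mask, table, "brute_force")
}

#' @method tidy feature_subset
#' @export
tidy.feature_subset <- function(x, ...) {
  tibble(
    feature = x$names,
    class_corr = x$class_corr
  )
}

#' @method glance feature_subset
#' @export
glance.feature_subset <- function(x, ...) {
  tibble(
    n_selected = sum(x$mask), n_features = length(x$mask),
    merit = x$merit, method = x$method
  )
}

#' Write a selection report as JSON
#'
#' Mask, names, merit, search trace, seed and parameters.
#'
#' @param subset A `feature_subset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(subset, path) {
  jsonlite::write_json(
    list(
      mask = subset$mask, names = subset$names, merit = subset$merit,
      method = subset$method, trace = subset$trace,
      params = subset$params[setdiff(names(subset$params), "")]
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @method autoplot feature_subset
#' @export
autoplot.feature_subset <- function(object, ...) {
  if (is.null(object$trace)) {
    abort("no search trace to plot (brute-force subset)")
  }
  df <- tibble(iteration = seq_along(object$trace), merit = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$merit)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      title = "Binary PSO search trace",
      x = "Iteration", y = "Best CFS merit"
    )
}
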