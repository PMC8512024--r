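# Symmetrical uncertainty, CFS merit, exhaustive search and binary PSO.

test_that("symmetrical uncertainty hits its dependence and independence limits", {
  a <- rep(c(1, 2), each = 10)
  expect_equal(symmetrical_uncertainty(a, a), 1)
  expect_equal(symmetrical_uncertainty(a, rev(a)), 1) # relabelled copy
  # exact product contingency table -> exactly 0
  b <- rep(rep(c("x", "y"), 10))
  expect_equal(symmetrical_uncertainty(a, b), 0)
  # constant variable has zero entropy
  expect_equal(symmetrical_uncertainty(rep(1, 20), a), 0)
  expect_error(symmetrical_uncertainty(1:3, 1:4), class = "sitsense_length_mismatch")
})

test_that("SU on a 2x2 joint table equals a direct entropy computation", {
  # joint counts [[2,1],[1,2]]
  a <- c(0, 0, 0, 1, 1, 1)
  b <- c(0, 0, 1, 0, 1, 1)
  p <- c(2, 1, 1, 2) / 6
  h <- function(q) -sum(q * log(q))
  ha <- h(c(0.5, 0.5))
  hb <- h(c(0.5, 0.5))
  mi <- ha + hb - h(p)
  expect_equal(symmetrical_uncertainty(a, b), 2 * mi / (ha + hb))
})

test_that("correlation table: class-identical, duplicated, noise and constant features", {
  set.seed(4)
  n <- 5000
  label <- sample(c("A1", "A2", "A3"), n, replace = TRUE)
  fm <- tibble::tibble(
    label = label,
    same = as.numeric(factor(label)), # codes the class exactly
    dup = as.numeric(factor(label)),
    noise = runif(n),
    const = 1
  )
  tab <- build_correlation_table(fm, bins = 10)
  expect_equal(unname(tab$feature_class[["same"]]), 1)
  expect_equal(tab$feature_feature["same", "dup"], 1)
  expect_lt(tab$feature_class[["noise"]], 0.05)
  expect_equal(unname(tab$feature_class[["const"]]), 0)
  expect_equal(unname(tab$feature_feature["const", "noise"]), 0)
  # structure invariants
  expect_equal(tab$feature_feature, t(tab$feature_feature))
  expect_equal(unname(diag(tab$feature_feature)), rep(1, 4))
  expect_true(all(tab$feature_feature >= 0 & tab$feature_feature <= 1))
})

test_that("merit closed forms and order invariance", {
  tab <- random_corr_table(5, seed = 1)
  tab$feature_class[] <- c(0.7, 0.5, 0.5, 0.2, 0.9)
  expect_equal(cfs_merit(c(TRUE, FALSE, FALSE, FALSE, FALSE), tab), 0.7)
  # k = 2, both r_cf = 0.5, r_ff = 1 -> 0.5 (full redundancy penalty)
  tab$feature_feature[2, 3] <- tab$feature_feature[3, 2] <- 1
  expect_equal(cfs_merit(c(FALSE, TRUE, TRUE, FALSE, FALSE), tab), 0.5)
  expect_error(cfs_merit(rep(FALSE, 5), tab), class = "sitsense_empty_subset")
  # merit is invariant to feature permutation
  set.seed(2)
  perm <- sample(5)
  tab2 <- tab
  tab2$feature_class <- tab$feature_class[perm]
  tab2$feature_feature <- tab$feature_feature[perm, perm]
  tab2$features <- tab$features[perm]
  mask <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(
    cfs_merit(mask[perm], tab2),
    cfs_merit(mask, tab)
  )
})

test_that("brute force equals an independent exhaustive enumeration", {
  for (s in 1:5) {
    tab <- random_corr_table(8, seed = 100 + s)
    bf <- brute_force_best_subset(tab)
    expect_equal(bf$merit, enumerate_best_merit(tab), tolerance = 1e-12)
  }
  expect_error(
    brute_force_best_subset(random_corr_table(21, 1)),
    class = "sitsense_too_many"
  )
})

test_that("brute force picks exactly one of two perfectly redundant relevant features", {
  tab <- random_corr_table(4, seed = 9)
  tab$feature_class[] <- c(0.8, 0.8, 0.1, 0.1)
  tab$feature_feature[] <- 0.05
  tab$feature_feature[1, 2] <- tab$feature_feature[2, 1] <- 1
  diag(tab$feature_feature) <- 1
  bf <- brute_force_best_subset(tab)
  expect_equal(sum(bf$mask[1:2]), 1)
})

test_that("duplicating an equally-relevant feature never raises the optimum merit", {
  # With equal class correlations among the relevant features, a perfect
  # duplicate only adds redundancy (a unit pair correlation) without
  # changing the subset-mean relevance, so the optimum cannot improve.
  # (For *unequal* relevances a duplicate of an above-average feature can
  # legitimately raise Hall's merit by re-weighting the mean.)
  for (s in 1:5) {
    set.seed(200 + s)
    p <- 6
    fc <- c(rep(0.8, 3), rep(0.02, 3))
    ff <- matrix(runif(p * p, 0, 0.2), p, p)
    ff <- (ff + t(ff)) / 2
    diag(ff) <- 1
    nm <- paste0("f", 1:p)
    tab <- structure(
      list(
        feature_class = stats::setNames(fc, nm), feature_feature = ff,
        features = nm, measure = "su", bins = 10
      ),
      class = "cfs_correlations"
    )
    bf <- brute_force_best_subset(tab)
    j <- which(bf$mask)[1]
    tab2 <- tab
    tab2$features <- c(tab$features, "dup")
    tab2$feature_class <- c(tab$feature_class, dup = unname(tab$feature_class[j]))
    ff2 <- matrix(0, p + 1, p + 1)
    ff2[1:p, 1:p] <- tab$feature_feature
    ff2[p + 1, ] <- c(tab$feature_feature[j, ], 1)
    ff2[, p + 1] <- c(tab$feature_feature[, j], 1)
    ff2[p + 1, j] <- ff2[j, p + 1] <- 1
    dimnames(ff2) <- list(tab2$features, tab2$features)
    tab2$feature_feature <- ff2
    bf2 <- brute_force_best_subset(tab2)
    expect_lte(bf2$merit, bf$merit + 1e-12)
    # and the duplicate pair is never both selected
    expect_lte(sum(bf2$mask[c(j, p + 1)]), 1)
  }
})

test_that("PSO handles the single-feature problem and zero class correlations", {
  tab <- random_corr_table(1, seed = 3)
  res <- pso_search(tab, pso_params(iterations = 5, seed = 1))
  expect_equal(res$names, "f1")
  expect_equal(res$merit, unname(tab$feature_class[1]))
  tab0 <- random_corr_table(6, seed = 4)
  tab0$feature_class[] <- 0
  res0 <- pso_search(tab0, pso_params(iterations = 10, seed = 1))
  expect_equal(res0$merit, 0)
})

test_that("PSO is seeded-deterministic with a monotone best-merit trace", {
  tab <- random_corr_table(10, seed = 5)
  r1 <- pso_search(tab, pso_params(seed = 7))
  r2 <- pso_search(tab, pso_params(seed = 7))
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace) >= 0))
  # never below the best single feature
  expect_gte(r1$merit, max(tab$feature_class))
})

test_that("PSO recovers the exhaustive optimum on planted-structure tables", {
  # 3 relevant features, 7 noise; relevant ones weakly inter-correlated
  hits <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    fc <- c(runif(3, 0.6, 0.9), runif(7, 0, 0.1))
    ff <- matrix(runif(100, 0, 0.2), 10, 10)
    ff <- (ff + t(ff)) / 2
    diag(ff) <- 1
    nm <- paste0("f", 1:10)
    tab <- structure(
      list(
        feature_class = stats::setNames(fc, nm), feature_feature = ff,
        features = nm, measure = "su", bins = 10
      ),
      class = "cfs_correlations"
    )
    bf <- brute_force_best_subset(tab)
    ps <- pso_search(tab, pso_params(seed = s))
    if (abs(ps$merit - bf$merit) < 1e-10) hits <- hits + 1
    # the planted relevant features are always part of the optimum
    expect_true(all(bf$mask[1:3]))
  }
  expect_gte(hits, 9) # >= 95% expected; allow one miss in ten
})

test_that("selection report JSON carries mask, merit, trace and params", {
  tab <- random_corr_table(6, seed = 6)
  res <- pso_search(tab, pso_params(iterations = 20, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_json(res, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$merit, res$merit)
  expect_equal(rep$names, res$names)
  expect_length(rep$trace, 20)
  expect_equal(rep$params$swarm_size, 20)
})
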