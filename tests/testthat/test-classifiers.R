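# Naive Bayes, KNN and OAA-SVM contracts, with library cross-checks.

test_that("naive Bayes separates distant Gaussian classes almost perfectly", {
  train <- gaussian_two_class(200, gap = 5, seed = 1)
  test <- gaussian_two_class(200, gap = 5, seed = 2)
  model <- train_nb(train)
  pred <- predict(model, test)
  acc <- mean(pred$label == test$label)
  expect_gt(acc, 0.99)
})

test_that("naive Bayes tie and degenerate contracts", {
  # single-class training always predicts that class
  train1 <- tibble::tibble(label = "A3", f1 = c(0, 1, 2), f2 = c(1, 1, 2))
  m1 <- train_nb(train1)
  expect_equal(predict(m1, tibble::tibble(f1 = 99, f2 = -99))$label, "A3")
  # symmetric two-class problem, equidistant query -> lowest class id
  train2 <- tibble::tibble(
    label = rep(c("A1", "A2"), each = 3),
    f1 = c(-2, -1, -3, 2, 1, 3)
  )
  m2 <- train_nb(train2)
  expect_equal(predict(m2, tibble::tibble(f1 = 0))$label, "A1")
  # a class with one row is rejected
  expect_error(
    train_nb(tibble::tibble(label = c("A1", "A1", "A2"), f1 = 1:3)),
    class = "sitsense_small_class"
  )
})

test_that("naive Bayes agrees with an established implementation away from boundaries", {
  train <- gaussian_two_class(100, gap = 6, seed = 3)
  test <- gaussian_two_class(100, gap = 6, seed = 4)
  mine <- predict(train_nb(train), test)$label
  ref <- e1071::naiveBayes(
    x = as.data.frame(train[c("f1", "f2")]),
    y = factor(train$label)
  )
  theirs <- as.character(predict(ref, as.data.frame(test[c("f1", "f2")])))
  expect_equal(mine, theirs)
})

test_that("KNN majority vote, exact-match and resubstitution contracts", {
  train <- tibble::tibble(
    label = c("A1", "A1", "A2", "A2", "A2"),
    f1 = c(0, 0.1, 5, 5.1, 5.2),
    f2 = c(0, 0.1, 5, 5.1, 5.2)
  )
  m1 <- train_knn(train, k = 1, metric = "euclidean")
  expect_equal(predict(m1, train[3, ])$label, "A2")
  m3 <- train_knn(train, k = 3, metric = "euclidean")
  # query near two A1s and one A2 -> A1
  expect_equal(predict(m3, tibble::tibble(f1 = 1, f2 = 1))$label, "A1")
  # K = 1 resubstitution on duplicate-free data is perfect
  set.seed(5)
  big <- tibble::tibble(
    label = rep(c("A1", "A2", "A3"), each = 20),
    f1 = rnorm(60), f2 = rnorm(60)
  )
  mk <- train_knn(big, k = 1, metric = "euclidean")
  expect_equal(predict(mk, big)$label, big$label)
  expect_error(train_knn(big, k = 61), class = "sitsense_bad_k")
})

test_that("Euclidean KNN matches class::knn on continuous data", {
  skip_if_not_installed("class")
  train <- gaussian_two_class(80, gap = 3, seed = 6)
  test <- gaussian_two_class(80, gap = 3, seed = 7)
  mine <- predict(train_knn(train, k = 5, metric = "euclidean"), test)$label
  theirs <- as.character(class::knn(
    train = as.matrix(train[c("f1", "f2")]),
    test = as.matrix(test[c("f1", "f2")]),
    cl = factor(train$label), k = 5
  ))
  expect_equal(mine, theirs)
})

test_that("Hamming KNN binarizes at the training medians", {
  train <- tibble::tibble(
    label = c("A1", "A1", "A1", "A2", "A2", "A2"),
    f1 = c(0, 1, 2, 10, 11, 12), # median 6: bits 0,0,0,1,1,1
    f2 = c(5, 5, 5, 5, 5, 5) # constant: all bits 0, no influence
  )
  m <- train_knn(train, k = 3, metric = "hamming")
  expect_equal(unname(m$medians["f1"]), 6)
  expect_equal(predict(m, tibble::tibble(f1 = 100, f2 = 0))$label, "A2")
  expect_equal(predict(m, tibble::tibble(f1 = -100, f2 = 0))$label, "A1")
  # distance is a bit-disagreement count: query above both medians is 0 bits
  # from every A2 row and 1 bit from every A1 row
  knn_sep <- train_knn(train, k = 5, metric = "hamming")
  votes <- predict(knn_sep, tibble::tibble(f1 = 100, f2 = 0))
  expect_equal(votes$A2, 3 / 5)
})

test_that("Gaussian-simulation accuracy exceeds 99% for KNN and SVM too", {
  train <- gaussian_two_class(200, gap = 5, seed = 8)
  test <- gaussian_two_class(200, gap = 5, seed = 9)
  pk <- predict(train_knn(train, k = 5, metric = "euclidean"), test)
  expect_gt(mean(pk$label == test$label), 0.99)
  ps <- predict(train_svm(train), test)
  expect_gt(mean(ps$label == test$label), 0.99)
})

test_that("OAA-SVM trains one machine per class and separates a toy problem", {
  toy <- tibble::tibble(
    label = c("A1", "A1", "A2", "A2"),
    f1 = c(0, 0, 1, 1), f2 = c(0, 0.1, 1, 0.9)
  )
  m <- train_svm(toy, cost = 10)
  expect_named(m$machines, c("A1", "A2"))
  expect_equal(predict(m, toy)$label, toy$label)
  # default kernel scale is sqrt(p); gamma = 1/(2 p)
  expect_equal(m$kernel_scale, sqrt(2))
  expect_equal(m$gamma, 1 / 4)
  # five-class problem -> five machines
  set.seed(10)
  five <- tibble::tibble(
    label = rep(activity_levels(), each = 10),
    f1 = rep(1:5, each = 10) + rnorm(50, 0, 0.05),
    f2 = rep(c(0, 2, 4, 6, 8), each = 10) + rnorm(50, 0, 0.05)
  )
  m5 <- train_svm(five)
  expect_length(m5$machines, 5)
  sc <- predict(m5, five)
  expect_true(all(activity_levels() %in% names(sc)))
  expect_error(train_svm(tibble::tibble(label = "A1", f1 = 1:4)),
    class = "sitsense_small_class"
  )
})

test_that("classifiers are invariant to training-row permutation", {
  set.seed(11)
  train <- tibble::tibble(
    label = rep(c("A1", "A2", "A3"), each = 30),
    f1 = rnorm(90, rep(c(0, 3, 6), each = 30)),
    f2 = rnorm(90, rep(c(0, -3, 3), each = 30))
  )
  test <- train[sample(90, 30), ]
  perm <- sample(90)
  shuffled <- train[perm, ]
  expect_equal(
    predict(train_nb(train), test)$label,
    predict(train_nb(shuffled), test)$label
  )
  expect_equal(
    predict(train_knn(train, 5, "euclidean"), test)$label,
    predict(train_knn(shuffled, 5, "euclidean"), test)$label
  )
  expect_equal(
    predict(train_svm(train), test)$label,
    predict(train_svm(shuffled), test)$label
  )
})

test_that("the classifier roster covers NB, KNN at 3/5/7/11 and SVM", {
  roster <- classifier_roster()
  expect_named(roster, c("nb", "knn3", "knn5", "knn7", "knn11", "svm"))
  train <- gaussian_two_class(30, gap = 6, seed = 12)
  for (spec in roster) {
    model <- spec$fit(train, c("f1", "f2"))
    expect_true(all(predict(model, train)$label %in% c("A1", "A2")))
  }
})
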