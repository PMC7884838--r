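make_toy_matrix <- function(n_per_class = 20, seed = 5) {
  # two k=1 composition archetypes, trivially separable
  cfg <- sim_config(seed = seed, n_positives = n_per_class,
                    n_negatives = n_per_class,
                    hairpin_length_range = c(80, 160))
  kmer_matrix(sim_hairpins(cfg), sim_coding(cfg))
}

test_that("stratified split partitions exactly and deterministically", {
  m <- make_toy_matrix(10)
  sp <- split_dataset(m, 0.7, seed = 1)
  expect_equal(sum(sp$train$labels == 1), 7)
  expect_equal(sum(sp$train$labels == 0), 7)
  expect_equal(sum(sp$test$labels == 1), 3)
  expect_setequal(c(sp$train$ids, sp$test$ids), m$ids)
  expect_length(intersect(sp$train$ids, sp$test$ids), 0)
  sp2 <- split_dataset(m, 0.7, seed = 1)
  expect_identical(sp$train$ids, sp2$train$ids)
  sp3 <- split_dataset(m, 0.7, seed = 2)
  expect_false(identical(sp$train$ids, sp3$train$ids))
})

test_that("single-class data cannot be stratified or trained", {
  m <- make_toy_matrix(10)
  pos_only <- list(x = m$x[m$labels == 1, ], labels = m$labels[m$labels == 1],
                   ids = m$ids[m$labels == 1], k = 4L,
                   skipped = m$skipped)
  class(pos_only) <- "kmer_matrix"
  expect_error(split_dataset(pos_only), "stratify")
  expect_error(mirna_classifier(m$x[m$labels == 1, ],
                                m$labels[m$labels == 1], "svm"),
               "both classes")
})

test_that("SVM separates linearly separable toy data perfectly", {
  set.seed(8)
  x <- rbind(matrix(rnorm(100, 3), 50), matrix(rnorm(100, -3), 50))
  colnames(x) <- c("f1", "f2")
  y <- rep(c(1, 0), each = 50)
  fit <- mirna_classifier(x, y, method = "svm", seed = 1)
  expect_equal(predict(fit, x, type = "class"), y)
})

test_that("1-nearest-neighbour reproduces training labels on the training set", {
  m <- make_toy_matrix(15)
  fit <- mirna_classifier(m, method = "knn", seed = 1, k_neighbours = 1)
  expect_equal(predict(fit, m$x, type = "class"), m$labels)
})

test_that("naive Bayes decisions flip under class-mean swap", {
  set.seed(9)
  x <- rbind(matrix(rnorm(200, 2), 50), matrix(rnorm(200, -2), 50))
  colnames(x) <- paste0("f", 1:4)
  y <- rep(c(1, 0), each = 50)
  nb1 <- mirna_classifier(x, y, method = "nb")
  nb2 <- mirna_classifier(x, 1 - y, method = "nb")
  p1 <- predict(nb1, x)
  p2 <- predict(nb2, x)
  expect_equal(p1 > 0.5, p2 < 0.5)
})

test_that("fits are reproducible for a fixed seed across all methods", {
  m <- make_toy_matrix(15)
  for (mt in c("svm", "rf", "xgboost", "knn", "nb")) {
    f1 <- mirna_classifier(m, method = mt, seed = 3)
    f2 <- mirna_classifier(m, method = mt, seed = 3)
    expect_equal(predict(f1, m$x), predict(f2, m$x), info = mt)
  }
})

test_that("probabilities lie in [0,1] and feature mismatch is caught", {
  m <- make_toy_matrix(10)
  fit <- mirna_classifier(m, method = "rf", seed = 1)
  p <- predict(fit, m$x)
  expect_true(all(p >= 0 & p <= 1))
  bad <- m$x[, rev(colnames(m$x))]
  expect_error(predict(fit, bad), "feature order")
})

test_that("metric formulas match direct substitution", {
  r <- confusion_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$accuracy, 0.7)
  expect_equal(r$f_measure, 2 * (0.75 * 0.6) / (0.75 + 0.6))
  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_equal(unlist(perfect[c("precision", "accuracy", "recall",
                                "f_measure")]),
               c(precision = 1, accuracy = 1, recall = 1, f_measure = 1))
  half <- confusion_metrics(5, 5, 5, 5)
  expect_equal(unlist(half[c("precision", "accuracy", "recall",
                             "f_measure")]),
               c(precision = .5, accuracy = .5, recall = .5, f_measure = .5))
})

test_that("zero denominators give NaN with a warning, never silent zero", {
  expect_warning(
    expect_warning(r <- confusion_metrics(0, 0, 5, 5), "precision undefined"),
    "F-measure undefined")
  expect_true(is.nan(r$precision))
  expect_true(is.nan(r$f_measure))
  expect_equal(r$accuracy, 0.5)
})

test_that("metrics are invariant to test-row order", {
  m <- make_toy_matrix(15)
  sp <- split_dataset(m, 0.7, seed = 2)
  fit <- mirna_classifier(sp$train, method = "nb", seed = 2)
  r1 <- evaluate(fit, sp$test)
  perm <- sample(length(sp$test$labels))
  shuffled <- list(x = sp$test$x[perm, ], labels = sp$test$labels[perm])
  r2 <- evaluate(fit, shuffled)
  expect_equal(r1$confusion, r2$confusion)
})

test_that("ROC endpoints, degenerate orderings and trapezoid AUC behave", {
  y <- c(1, 1, 0, 0, 1, 0)
  r <- roc_curve(as.numeric(y), y)
  expect_equal(auc(r), 1)
  expect_equal(auc(roc_curve(rep(0.5, 6), y)), 0.5)
  expect_equal(auc(roc_curve(1 - y, y)), 0)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_error(roc_curve(c(.1, .2), c(1, 1)), "both classes")
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  y <- rep(c(0, 1), 50)
  p <- runif(100) + 0.3 * y
  ours <- auc(roc_curve(p, y))
  theirs <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("model selection maximizes F with accuracy then fixed-order ties", {
  mk <- function(alg, f, acc) {
    r <- confusion_metrics(5, 1, 5, 1, algorithm = alg)
    r$f_measure <- f; r$accuracy <- acc
    r
  }
  expect_equal(select_best(list(mk("rf", .9, .9), mk("nb", .8, .95))), "rf")
  expect_equal(select_best(list(mk("rf", .9, .90), mk("nb", .9, .95))), "nb")
  expect_equal(select_best(list(mk("nb", .9, .9), mk("svm", .9, .9),
                                mk("knn", .9, .9))), "svm")
  expect_error(select_best(list()), "no metric")
})
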