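CLASSIFIER_METHODS <- c("svm", "rf", "xgboost", "knn", "nb")
# fixed tie-break order used by select_best()
CLASSIFIER_ORDER <- c("svm", "rf", "xgboost", "knn", "nb")

#' Oracle classifier from a probability function
#'
#' Wraps an arbitrary function of the feature matrix as a
#' `mirna_classifier`, so scanner behaviour can be exercised against a
#' model with known ground truth (e.g. probability 1 exactly on windows
#' of a planted signature).
#'
#' @param fun function taking the numeric feature matrix and returning
#'   one probability per row.
#' @param k featurizer word length the oracle expects (default 4).
#' @return an object of class `mirna_classifier` with method `"custom"`.
#' @export
oracle_classifier <- function(fun, k = 4L) {
  stopifnot(is.function(fun))
  structure(list(method = "custom", fit = fun, seed = NA_integer_,
                 k = as.integer(k),
                 feature_names = kmer_vocabulary(k),
                 hyperparams = list(), n_train = 0L,
                 class_counts = table(factor(c(0, 1)))),
            class = "mirna_classifier")
}

#' Stratified train/test split
#'
#' Splits a labeled feature matrix into training and testing parts,
#' stratified by label (the conventional 70/30 split by default). The
#' partition is exact — every row lands in exactly one part — and
#' deterministic for a fixed seed.
#'
#' @param m a [kmer_matrix()].
#' @param train_fraction fraction per class assigned to training
#'   (0 < f < 1; default 0.7).
#' @param seed RNG seed.
#' @return list with `train` and `test`, each a `kmer_matrix`.
#' @export
split_dataset <- function(m, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(m, "kmer_matrix"),
            train_fraction > 0, train_fraction < 1)
  if (any(table(factor(m$labels, levels = c(0, 1))) < 2))
    stop("each class needs at least 2 rows to stratify")
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(m$labels), m$labels), function(rows) {
      sample(rows, round(train_fraction * length(rows)))
    }), use.names = FALSE)
  })
  take <- function(rows) {
    out <- list(x = m$x[rows, , drop = FALSE], labels = m$labels[rows],
                ids = m$ids[rows], k = m$k,
                skipped = m$skipped[0, , drop = FALSE])
    class(out) <- "kmer_matrix"
    out
  }
  list(train = take(sort(idx)),
       test = take(sort(setdiff(seq_along(m$labels), idx))))
}

#' Fit a pre-miRNA classifier
#'
#' The modelling core of the package: fits one of five classifiers to a
#' k-mer feature matrix with binary labels (1 = pre-miRNA hairpin,
#' 0 = negative) and returns a classed model whose `predict()` method
#' yields per-row positive-class probabilities.
#'
#' Backends: `svm` — RBF-kernel support vector machine with Platt
#' probability calibration ([e1071::svm()]); `rf` — random forest
#' ([randomForest::randomForest()]); `xgboost` — gradient-boosted trees
#' ([xgboost::xgb.train()]); `knn` — k-nearest neighbours
#' ([class::knn()], lazy, distance vote); `nb` — Gaussian naive Bayes
#' ([e1071::naiveBayes()]). Hyperparameters can be overridden through
#' `...`; the defaults recorded in the fitted object are the study
#' settings.
#'
#' @param x a [kmer_matrix()], or a numeric feature matrix if `labels`
#'   is given.
#' @param labels binary labels (ignored when `x` is a `kmer_matrix`).
#' @param method one of `"svm"`, `"rf"`, `"xgboost"`, `"knn"`, `"nb"`.
#' @param seed RNG seed recorded in the model; fixed seed + data give
#'   identical predictions.
#' @param ... hyperparameter overrides for the backend
#'   (e.g. `cost`, `gamma` for svm; `ntree` for rf; `nrounds`,
#'   `max_depth`, `eta` for xgboost; `k_neighbours` for knn).
#' @return an object of class `mirna_classifier`.
#' @export
mirna_classifier <- function(x, labels = NULL,
                             method = c("svm", "rf", "xgboost", "knn", "nb"),
                             seed = 1L, ...) {
  method <- match.arg(method)
  if (inherits(x, "kmer_matrix")) {
    labels <- x$labels
    k <- x$k
    x <- x$x
  } else {
    k <- round(log(ncol(x), 4))
  }
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  if (length(unique(labels)) < 2)
    stop("training data must contain both classes")
  y <- factor(labels, levels = c(0, 1))
  hp <- list(...)
  fit <- with_seed(seed, switch(method,
    svm = e1071::svm(x, y, probability = TRUE,
                     kernel = hp$kernel %||% "radial",
                     cost = hp$cost %||% 1,
                     gamma = hp$gamma %||% (1 / ncol(x))),
    rf = randomForest::randomForest(x, y, ntree = hp$ntree %||% 300L),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    max_depth = hp$max_depth %||% 4,
                    eta = hp$eta %||% 0.3,
                    seed = seed),
      data = xgboost::xgb.DMatrix(x, label = as.integer(labels)),
      nrounds = hp$nrounds %||% 60L),
    knn = list(train_x = x, train_y = y,
               k_neighbours = hp$k_neighbours %||% 11L),
    nb = e1071::naiveBayes(x, y)))
  structure(list(method = method, fit = fit, seed = as.integer(seed),
                 k = k, feature_names = colnames(x),
                 hyperparams = hp,
                 n_train = nrow(x),
                 class_counts = table(y)),
            class = "mirna_classifier")
}

#' Predict positive-class probabilities
#'
#' @param object a [mirna_classifier()].
#' @param newdata numeric feature matrix (or `kmer_matrix`) with the same
#'   feature order used in training.
#' @param type `"prob"` (default) for positive-class probabilities or
#'   `"class"` for 0/1 calls at threshold 0.5.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`, or integer 0/1.
#' @export
predict.mirna_classifier <- function(object, newdata, type = c("prob", "class"),
                                     ...) {
  type <- match.arg(type)
  if (inherits(newdata, "kmer_matrix")) newdata <- newdata$x
  stopifnot(is.matrix(newdata))
  if (!is.null(object$feature_names) &&
      !identical(colnames(newdata), object$feature_names))
    stop("feature order of newdata does not match the trained model")
  p <- switch(object$method,
    svm = {
      pr <- predict(object$fit, newdata, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    rf = predict(object$fit, newdata, type = "prob")[, "1"],
    xgboost = predict(object$fit, xgboost::xgb.DMatrix(newdata)),
    knn = with_seed(object$seed, {
      kn <- class::knn(object$fit$train_x, newdata, object$fit$train_y,
                       k = object$fit$k_neighbours, prob = TRUE)
      ifelse(kn == "1", attr(kn, "prob"), 1 - attr(kn, "prob"))
    }),
    nb = predict(object$fit, newdata, type = "raw")[, "1"],
    custom = object$fit(newdata))
  p <- unname(p)
  if (type == "class") as.integer(p > 0.5) else p
}

#' @export
print.mirna_classifier <- function(x, ...) {
  cat(sprintf("mirna_classifier: %s (k = %d, %d features), %d training rows, seed %d\n",
              toupper(x$method), x$k, length(x$feature_names),
              x$n_train, x$seed))
  invisible(x)
}

#' @export
summary.mirna_classifier <- function(object, ...) {
  print(object)
  cat(sprintf("  class counts: neg %d / pos %d\n",
              object$class_counts[["0"]], object$class_counts[["1"]]))
  if (length(object$hyperparams))
    cat("  hyperparameter overrides:",
        paste(names(object$hyperparams), unlist(object$hyperparams),
              sep = "=", collapse = ", "), "\n")
  invisible(object)
}

#' Confusion-count performance metrics
#'
#' Precision, accuracy, recall (sensitivity) and F-measure from raw
#' confusion counts:
#' precision = TP/(TP+FP); accuracy = (TP+TN)/(TP+TN+FN+FP);
#' recall = TP/(TP+FN); F = 2 * precision * recall / (precision + recall).
#' A zero denominator yields `NaN` with a warning — never a silent 0.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @param algorithm optional tag recorded in the result.
#' @return object of class `classifier_metrics`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn, algorithm = NA_character_) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  accuracy <- (tp + tn) / (tp + tn + fn + fp)
  f_measure <- if (is.nan(precision) || is.nan(recall) ||
                   (precision + recall) == 0) {
    warning("F-measure undefined: zero denominator", call. = FALSE)
    NaN
  } else 2 * precision * recall / (precision + recall)
  structure(list(algorithm = algorithm,
                 precision = precision, accuracy = accuracy,
                 recall = recall, f_measure = f_measure,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "classifier_metrics")
}

#' Evaluate a fitted classifier on a test set
#'
#' Confusion counts are taken at probability threshold `threshold`
#' (default 0.5); metrics follow [confusion_metrics()].
#'
#' @param model a [mirna_classifier()].
#' @param test a [kmer_matrix()] (or list with `x` and `labels`).
#' @param threshold probability cut for calling the positive class.
#' @return object of class `classifier_metrics`.
#' @export
evaluate <- function(model, test, threshold = 0.5) {
  stopifnot(inherits(model, "mirna_classifier"), length(test$labels) > 0)
  p <- predict(model, test$x)
  call_pos <- p > threshold
  y <- test$labels == 1
  confusion_metrics(tp = sum(call_pos & y), fp = sum(call_pos & !y),
                    tn = sum(!call_pos & !y), fn = sum(!call_pos & y),
                    algorithm = model$method)
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("%s  precision %.4f  accuracy %.4f  recall %.4f  F %.4f\n",
              if (is.na(x$algorithm)) "metrics" else toupper(x$algorithm),
              x$precision, x$accuracy, x$recall, x$f_measure))
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$confusion[["tp"]], x$confusion[["fp"]],
              x$confusion[["tn"]], x$confusion[["fn"]]))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over all distinct predicted
#' probabilities; AUC by the trapezoidal rule.
#'
#' @param model a [mirna_classifier()], or a numeric vector of
#'   probabilities if `labels` is supplied directly.
#' @param test a [kmer_matrix()] test set (or binary labels when `model`
#'   is a probability vector).
#' @return object of class `roc_curve`: data.frame of (fpr, tpr) with an
#'   `auc` attribute.
#' @export
roc_curve <- function(model, test) {
  if (inherits(model, "mirna_classifier")) {
    p <- predict(model, test$x)
    y <- test$labels
  } else {
    p <- model
    y <- if (inherits(test, "kmer_matrix")) test$labels else test
  }
  stopifnot(length(p) == length(y))
  if (length(unique(y)) < 2)
    stop("ROC needs both classes in the test set")
  thr <- c(Inf, sort(unique(p), decreasing = TRUE), -Inf)
  pos <- sum(y == 1); neg <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(p >= t & y == 1) / pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(p >= t & y == 0) / neg, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(data.frame(fpr = fpr, tpr = tpr),
            auc = auc, class = c("roc_curve", "data.frame"))
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", attr(x, "auc")), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Area under a ROC curve
#' @param x a [roc_curve()].
#' @return the AUC.
#' @export
auc <- function(x) attr(x, "auc")

#' Select the best-performing algorithm
#'
#' Maximizes F-measure; ties broken by accuracy, then by the fixed order
#' SVM, RF, XGBoost, KNN, NB.
#'
#' @param reports list of [classifier_metrics()] objects.
#' @return the winning algorithm tag (character).
#' @export
select_best <- function(reports) {
  if (!length(reports)) stop("no metric reports supplied")
  f <- vapply(reports, function(r) r$f_measure, numeric(1))
  a <- vapply(reports, function(r) r$accuracy, numeric(1))
  tag <- vapply(reports, function(r) r$algorithm, character(1))
  ord <- match(tag, CLASSIFIER_ORDER)
  ord[is.na(ord)] <- length(CLASSIFIER_ORDER) + 1L
  best <- order(-f, -a, ord, seq_along(reports))[1]
  tag[best]
}

#' Benchmark the five classifiers
#'
#' Trains every requested algorithm on a stratified split of the feature
#' matrix, evaluates each on the held-out part and selects the best by
#' F-measure (ties: accuracy, then fixed order).
#'
#' @param m a [kmer_matrix()].
#' @param train_fraction training fraction of the split (default 0.7).
#' @param seed RNG seed for the split and every fit.
#' @param methods algorithms to run (default all five).
#' @return object of class `mirna_bench`: list with `models`, `metrics`,
#'   `rocs`, `best`, and the `split` used.
#' @export
bench_classifiers <- function(m, train_fraction = 0.7, seed = 1L,
                              methods = CLASSIFIER_METHODS) {
  sp <- split_dataset(m, train_fraction, seed = seed)
  models <- lapply(methods, function(mt)
    mirna_classifier(sp$train, method = mt, seed = seed))
  names(models) <- methods
  metrics <- lapply(models, evaluate, test = sp$test)
  rocs <- lapply(models, roc_curve, test = sp$test)
  structure(list(models = models, metrics = metrics, rocs = rocs,
                 best = select_best(metrics), split = sp, seed = seed),
            class = "mirna_bench")
}

#' @export
print.mirna_bench <- function(x, ...) {
  cat(sprintf("Classifier benchmark (%d train / %d test rows)\n",
              length(x$split$train$labels), length(x$split$test$labels)))
  for (mt in names(x$metrics)) {
    r <- x$metrics[[mt]]
    cat(sprintf("  %-8s precision %.4f  accuracy %.4f  recall %.4f  F %.4f  AUC %.4f\n",
                toupper(mt), r$precision, r$accuracy, r$recall, r$f_measure,
                auc(x$rocs[[mt]])))
  }
  cat(sprintf("  best: %s\n", toupper(x$best)))
  invisible(x)
}

#' Write benchmark metrics as TSV
#'
#' One row per algorithm with the four metrics, AUC and confusion counts.
#'
#' @param bench a [bench_classifiers()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bench_tsv <- function(bench, path) {
  rows <- do.call(rbind, lapply(names(bench$metrics), function(mt) {
    r <- bench$metrics[[mt]]
    data.frame(algorithm = mt, precision = r$precision,
               accuracy = r$accuracy, recall = r$recall,
               f_measure = r$f_measure, auc = auc(bench$rocs[[mt]]),
               tp = r$confusion[["tp"]], fp = r$confusion[["fp"]],
               tn = r$confusion[["tn"]], fn = r$confusion[["fn"]])
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
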