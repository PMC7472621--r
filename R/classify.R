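#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds so that every class is spread as
#' evenly as possible across folds (within-class shuffling is seeded). With at
#' least `k` samples per class this guarantees every class appears in every
#' training split.
#'
#' @param labels Vector or factor of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, same length as `labels`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  old <- local_seed(as.integer(seed))
  on.exit(restore_seed(old), add = TRUE)
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated SVM evaluation of a feature table
#'
#' Reproduces the evaluation protocol for individual identification: a support
#' vector machine with a linear, third-order polynomial or radial basis
#' function kernel, stratified five-fold cross-validation, per-fold test
#' accuracy, and macro-averaged precision, specificity and F1 together with a
#' pooled confusion matrix.
#'
#' The penalty parameter defaults to `C = 100` for the RBF kernel and `C = 1`
#' otherwise. The polynomial kernel uses degree 3 with libsvm's default
#' `gamma = 1/ncol` and `coef0 = 0`. Features are not rescaled before training
#' (histogram segments are already normalized); pass `scale = TRUE` to let the
#' SVM standardize columns.
#'
#' @param data Feature tibble from [extract_features()]: a `label` column plus
#'   numeric feature columns (a `filename` column is ignored).
#' @param kernel `"rbf"`, `"linear"` or `"poly3"`.
#' @param C Penalty parameter; default 100 for RBF, 1 otherwise.
#' @param k Number of folds (5 for the standard protocol).
#' @param seed Integer seed controlling the fold assignment.
#' @param average `"macro"` (default) or `"micro"` averaging for the
#'   multiclass precision/specificity/F1 scalars.
#' @param scale Passed to [e1071::svm()].
#' @return An object of class `wtld_eval` with fields `kernel`, `C`,
#'   `fold_accuracies`, `mean_accuracy`, `precision`, `specificity`, `f1`,
#'   `per_class` (tibble), `confusion_counts`, `confusion_pct` (rows = true
#'   class, percentages summing to 100), `seed`, `n`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(synth_config(n_classes = 3, images_per_class = 8))
#' fx <- extract_features(ds)
#' crossval_evaluate(fx, kernel = "linear", seed = 7)
#' }
#' @export
crossval_evaluate <- function(data, kernel = c("rbf", "linear", "poly3"),
                              C = NULL, k = 5L, seed = 1L,
                              average = c("macro", "micro"), scale = FALSE) {
  kernel <- match.arg(kernel)
  average <- match.arg(average)
  stopifnot(is.data.frame(data), "label" %in% names(data))
  C <- C %||% if (kernel == "rbf") 100 else 1
  y <- droplevels(as.factor(data$label))
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  small <- table(y) < k
  if (any(small))
    stop("class(es) with fewer than ", k, " samples: ",
         paste(names(which(small)), collapse = ", "), call. = FALSE)
  x <- as.matrix(data[setdiff(names(data), c("label", "filename"))])
  storage.mode(x) <- "double"
  folds <- stratified_folds(y, k, seed)
  svm_kernel <- c(rbf = "radial", linear = "linear", poly3 = "polynomial")[kernel]
  counts <- matrix(0L, nlevels(y), nlevels(y),
                   dimnames = list(true = levels(y), predicted = levels(y)))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = svm_kernel,
                      degree = 3L, cost = C, scale = scale)
    pred <- stats::predict(fit, x[!tr, , drop = FALSE])
    fold_acc[f] <- mean(pred == y[!tr])
    counts <- counts + table(factor(y[!tr], levels(y)),
                             factor(pred, levels(y)))
  }
  met <- metrics_from_confusion(counts, average = average)
  structure(
    list(kernel = kernel, C = C, fold_accuracies = fold_acc,
         mean_accuracy = mean(fold_acc),
         precision = met$precision, specificity = met$specificity,
         f1 = met$f1, per_class = met$per_class,
         confusion_counts = counts,
         confusion_pct = 100 * counts / rowSums(counts),
         seed = as.integer(seed), n = nrow(data), average = average),
    class = "wtld_eval")
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest accuracy, precision, recall, specificity and F1 per class from
#' a square count matrix (rows = true class, columns = predicted class), plus
#' macro or micro averages. A class that is never predicted has undefined
#' precision, reported as 0 with a warning; a class with no true samples is an
#' error.
#'
#' @param counts Square non-negative integer matrix.
#' @param average `"macro"` or `"micro"`.
#' @return List with `accuracy`, `precision`, `specificity`, `f1` (scalars)
#'   and `per_class` (tibble with one row per class).
#' @examples
#' metrics_from_confusion(matrix(c(40, 20, 10, 30), 2))
#' @export
metrics_from_confusion <- function(counts, average = c("macro", "micro")) {
  average <- match.arg(average)
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (any(rowSums(counts) == 0))
    stop("confusion matrix has a class with no true samples; metrics undefined",
         call. = FALSE)
  total <- sum(counts)
  tp <- diag(counts)
  fn <- rowSums(counts) - tp
  fp <- colSums(counts) - tp
  tn <- total - tp - fn - fp
  if (any(tp + fp == 0))
    warning("class(es) never predicted; precision reported as 0")
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  per_class <- tibble::tibble(
    class = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    n = as.integer(rowSums(counts)),
    precision = unname(precision), recall = unname(recall),
    specificity = unname(specificity), f1 = unname(f1))
  if (average == "macro") {
    list(accuracy = sum(tp) / total, precision = mean(precision),
         specificity = mean(specificity), f1 = mean(f1),
         per_class = per_class)
  } else {
    mp <- sum(tp) / sum(tp + fp)
    mr <- sum(tp) / sum(tp + fn)
    list(accuracy = sum(tp) / total, precision = mp,
         specificity = sum(tn) / sum(tn + fp),
         f1 = if (mp + mr == 0) 0 else 2 * mp * mr / (mp + mr),
         per_class = per_class)
  }
}

#' @export
print.wtld_eval <- function(x, ...) {
  cat(sprintf("<wtld_eval> %s kernel SVM (C = %g), %d-fold stratified CV, n = %d\n",
              x$kernel, x$C, length(x$fold_accuracies), x$n))
  cat(sprintf("  fold accuracies: %s\n",
              paste(sprintf("%.3f", x$fold_accuracies), collapse = " ")))
  cat(sprintf("  mean accuracy %.3f | precision %.3f | specificity %.3f | F1 %.3f (%s)\n",
              x$mean_accuracy, x$precision, x$specificity, x$f1, x$average))
  invisible(x)
}

#' Tidy per-class metrics of an evaluation
#'
#' @param x A `wtld_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per class: `class`, `n`, `precision`, `recall`,
#'   `specificity`, `f1`.
#' @method tidy wtld_eval
#' @export
tidy.wtld_eval <- function(x, ...) x$per_class

#' One-row summary of an evaluation
#'
#' @param x A `wtld_eval` object.
#' @param ... Unused.
#' @return One-row tibble: kernel, C, mean and sd of fold accuracies, macro
#'   precision/specificity/F1, n, seed.
#' @method glance wtld_eval
#' @export
glance.wtld_eval <- function(x, ...) {
  tibble::tibble(kernel = x$kernel, C = x$C,
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = stats::sd(x$fold_accuracies),
                 precision = x$precision, specificity = x$specificity,
                 f1 = x$f1, n = x$n, seed = x$seed)
}

#' Plot the pooled confusion matrix of an evaluation
#'
#' Heat map of row-normalized confusion percentages (rows = true class).
#'
#' @param object A `wtld_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wtld_eval
#' @export
autoplot.wtld_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion_pct))
  names(df) <- c("true", "predicted", "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$pct)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100), name = "%") +
    ggplot2::scale_y_discrete(limits = rev(levels(df$true))) +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("%s kernel SVM, mean accuracy %.3f",
                                  object$kernel, object$mean_accuracy)) +
    ggplot2::theme_minimal()
}

#' Serialize an evaluation report to JSON (plus a confusion-matrix CSV)
#'
#' @param eval A `wtld_eval` object.
#' @param path JSON output path; the pooled confusion percentages are also
#'   written to `paste0(path, "_confusion.csv")`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  stopifnot(inherits(eval, "wtld_eval"))
  rep <- list(kernel = eval$kernel, C = eval$C,
              fold_accuracies = eval$fold_accuracies,
              mean_accuracy = eval$mean_accuracy,
              precision = eval$precision, specificity = eval$specificity,
              f1 = eval$f1, average = eval$average,
              confusion_pct = unname(apply(eval$confusion_pct, 1, as.numeric,
                                           simplify = FALSE)),
              classes = rownames(eval$confusion_counts),
              seed = eval$seed, n = eval$n)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(eval$confusion_pct,
                   paste0(tools::file_path_sans_ext(path), "_confusion.csv"))
  invisible(path)
}
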