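shannon_entropy <- function(x) {
  p <- table(x)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

# supervised binary discretization: the midpoint split maximizing
# information gain against the class labels
best_split <- function(x, y) {
  ux <- sort(unique(x))
  if (length(ux) < 2) return(NULL)
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  h <- shannon_entropy(y)
  gains <- vapply(cuts, function(ct) {
    lo <- x <= ct
    p <- mean(lo)
    h - p * shannon_entropy(y[lo]) - (1 - p) * shannon_entropy(y[!lo])
  }, numeric(1))
  list(threshold = cuts[which.max(gains)], gain = max(gains))
}

#' Rank features by gain ratio
#'
#' Evaluates the relevance of each attribute against the class label by its
#' gain ratio: information gain divided by the split information (the
#' entropy of the attribute itself), which penalises many-valued attributes.
#' Numeric attributes are first discretized by a supervised binary split at
#' the midpoint maximizing information gain. A constant attribute, or one
#' carrying no information about the class, scores 0.
#'
#' @param features A data frame of feature columns plus the label; columns
#'   named in `exclude` are skipped.
#' @param label Name of the class column (must have at least two observed
#'   classes).
#' @param exclude Character vector of columns to skip (identifier columns).
#' @return Tibble of class `gain_ratio_ranking` with columns `feature`,
#'   `gain_ratio`, `threshold` (NA for categorical attributes), sorted in
#'   decreasing relevance.
#' @examples
#' cohort <- simulate_cohort(40, seed = 3)
#' feats <- extract_features(cohort$profiles, cohort$sessions)
#' gain_ratio_rank(feats)
#' @export
gain_ratio_rank <- function(features, label = "label", exclude = "user_id") {
  y <- features[[label]]
  if (length(unique(y)) < 2) {
    abort("gain ratio is undefined with a single class",
          class = "cogniscore_ranking_error")
  }
  h_class <- shannon_entropy(y)
  cols <- setdiff(names(features), c(label, exclude))
  out <- purrr::map_dfr(cols, function(col) {
    x <- features[[col]]
    threshold <- NA_real_
    if (is.numeric(x) && length(unique(x)) > 2) {
      sp <- best_split(x, y)
      if (is.null(sp)) {
        return(tibble(feature = col, gain_ratio = 0, threshold = NA_real_))
      }
      threshold <- sp$threshold
      x <- x <= sp$threshold
    }
    x <- as.factor(x)
    split_info <- shannon_entropy(x)
    if (split_info == 0) {
      return(tibble(feature = col, gain_ratio = 0, threshold = threshold))
    }
    cond <- sum(vapply(split(seq_along(y), x), function(idx) {
      length(idx) / length(y) * shannon_entropy(y[idx])
    }, numeric(1)))
    gain <- max(h_class - cond, 0)
    tibble(feature = col, gain_ratio = gain / split_info, threshold = threshold)
  })
  out <- arrange(out, desc(.data$gain_ratio))
  class(out) <- c("gain_ratio_ranking", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.gain_ratio_ranking <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$gain_ratio,
    y = stats::reorder(.data$feature, .data$gain_ratio)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "gain ratio", y = NULL) +
    ggplot2::theme_minimal()
}

#' Classifier backends for screening
#'
#' Thin adapters giving a common `fit(x, y)` / `predict(model, x)` contract
#' over established learners: `"dt"` (pruned decision tree, maximum depth 5,
#' 3 pruning cross-validation folds), `"rf"` (random forest, depth-limited),
#' `"svm"` (linear support vector machine), `"nb"` (naive Bayes) and
#' `"majority"` (majority-class baseline). Any list with `name`, `fit` and
#' `predict` elements is accepted wherever a backend is expected, so custom
#' learners plug in directly.
#'
#' @param name Backend name.
#' @param maxdepth Maximum tree depth for `"dt"`/`"rf"`.
#' @param prune_folds Internal cross-validation folds used for tree pruning.
#' @param ... Extra arguments stored for the learner call.
#' @return A list of class `classifier_backend`.
#' @export
classifier_backend <- function(name = c("dt", "rf", "svm", "nb", "majority"),
                               maxdepth = 5, prune_folds = 3, ...) {
  name <- match.arg(name)
  extra <- list(...)
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(paste0("backend '", name, "' needs package '", pkg, "'"),
            class = "cogniscore_settings_error")
    }
  }
  backend <- switch(name,
    dt = list(
      fit = function(x, y) {
        df <- data.frame(x, .y = y)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(
                       maxdepth = maxdepth, xval = prune_folds
                     ))
      },
      predict = function(model, x) {
        predict(model, newdata = data.frame(x), type = "class")
      }
    ),
    rf = list(
      fit = function(x, y) {
        need("randomForest")
        randomForest::randomForest(
          x = data.frame(x), y = y,
          ntree = extra$ntree %||% 200,
          maxnodes = 2^maxdepth
        )
      },
      predict = function(model, x) predict(model, newdata = data.frame(x))
    ),
    svm = list(
      fit = function(x, y) {
        need("e1071")
        df <- data.frame(x, .y = y)
        e1071::svm(.y ~ ., data = df, kernel = "linear")
      },
      predict = function(model, x) predict(model, newdata = data.frame(x))
    ),
    nb = list(
      fit = function(x, y) {
        need("e1071")
        e1071::naiveBayes(x = data.frame(x), y = y)
      },
      predict = function(model, x) predict(model, newdata = data.frame(x))
    ),
    majority = list(
      fit = function(x, y) names(which.max(table(y))),
      predict = function(model, x) rep(model, nrow(x))
    )
  )
  structure(c(list(name = name), backend), class = "classifier_backend")
}

as_backend <- function(x) {
  if (inherits(x, "classifier_backend")) return(x)
  if (is.character(x)) return(classifier_backend(x))
  if (is.list(x) && all(c("fit", "predict") %in% names(x))) {
    return(structure(
      c(list(name = x$name %||% "custom"), x[c("fit", "predict")]),
      class = "classifier_backend"
    ))
  }
  abort("backend must be a name or a list with fit/predict functions",
        class = "cogniscore_settings_error")
}

#' Grouped k-fold cross-validated screening evaluation
#'
#' Splits participants (not rows) into k folds, so no user's records can sit
#' in both the training and the evaluation side of a fold, then pools the
#' held-out predictions into a confusion matrix with overall accuracy and
#' per-class precision, recall and F-measure.
#'
#' @param features Feature table from [extract_features()] (or any data
#'   frame with a group column, feature columns and a factor label).
#' @param backend A [classifier_backend()], backend name, or fit/predict
#'   list.
#' @param k Number of folds; must not exceed the number of groups.
#' @param seed Integer seed for the fold assignment.
#' @param label,group Names of the label and grouping columns.
#' @return An `eval_report`: `confusion` matrix (truth in rows), `accuracy`
#'   (percent), `class_metrics` tibble, `folds` assignment, `k`, `backend`.
#' @examples
#' cohort <- simulate_cohort(60, seed = 5)
#' feats <- extract_features(cohort$profiles, cohort$sessions)
#' grouped_kfold_evaluate(feats, "dt", k = 5, seed = 5)
#' @export
grouped_kfold_evaluate <- function(features, backend = classifier_backend("dt"),
                                   k = 10, seed = 1,
                                   label = "label", group = "user_id") {
  backend <- as_backend(backend)
  y <- features[[label]]
  if (!is.factor(y)) y <- factor(y)
  groups <- unique(features[[group]])
  if (k > length(groups)) {
    abort(paste0("k = ", k, " exceeds the ", length(groups),
                 " available groups"),
          class = "cogniscore_fold_error")
  }
  fold_of <- with_local_seed(seed, {
    setNames(rep_len(seq_len(k), length(groups))[sample.int(length(groups))],
             groups)
  })
  x <- features[, setdiff(names(features), c(label, group)), drop = FALSE]
  row_fold <- fold_of[features[[group]]]
  truth <- factor(character(0), levels = levels(y))
  pred <- factor(character(0), levels = levels(y))
  for (f in seq_len(k)) {
    test <- row_fold == f
    model <- backend$fit(x[!test, , drop = FALSE], droplevels(y[!test]))
    p <- backend$predict(model, x[test, , drop = FALSE])
    truth <- c(truth, y[test])
    pred <- c(pred, factor(as.character(p), levels = levels(y)))
  }
  confusion <- table(truth = truth, predicted = pred)
  accuracy <- 100 * sum(diag(confusion)) / sum(confusion)
  class_metrics <- purrr::map_dfr(levels(y), function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else {
      0
    }
    tibble(class = cl, precision = 100 * precision, recall = 100 * recall,
           f_measure = 100 * f1, support = sum(confusion[cl, ]))
  })
  structure(
    list(confusion = confusion, accuracy = accuracy,
         class_metrics = class_metrics,
         folds = tibble(group = groups, fold = unname(fold_of[groups])),
         k = k, backend = backend$name, seed = seed,
         n = length(groups)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s backend, %d-fold grouped CV, n = %d>\n",
              x$backend, x$k, x$n))
  cat(sprintf("accuracy: %.2f%%\n", x$accuracy))
  print(x$class_metrics)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  x$class_metrics
}

#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, k = x$k, n = x$n, backend = x$backend)
}

#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  df <- as_tibble(as.data.frame(object$confusion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("%s, %d-fold grouped CV: accuracy %.1f%%",
                                  object$backend, object$k, object$accuracy)) +
    ggplot2::theme_minimal()
}
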