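# Thin internal wrapper around ranger probability forests so that one
# place owns hyperparameter translation, determinism (single thread,
# explicit seed) and lexicographic tie-breaking on predicted classes.

default_hyper <- function() {
  list(num_trees = 300L, max_depth = 0L, mtry = "sqrt",
       min_node_size = 1L, replace = TRUE, class_weights = NULL)
}

resolve_mtry <- function(mtry, p) {
  m <- if (is.character(mtry)) {
    switch(mtry,
           sqrt = sqrt(p),
           log2 = log2(p),
           stopf("unknown mtry spec '%s'", mtry))
  } else if (mtry <= 1) mtry * p else mtry
  max(1L, min(p, as.integer(floor(m))))
}

rf_fit <- function(X, y, hyper = list(), seed = 1L,
                   importance = "impurity") {
  hyper <- utils::modifyList(default_hyper(), hyper)
  y <- factor(as.character(y), levels = sort(unique(as.character(y))))
  cw <- if (identical(hyper$class_weights, "balanced")) {
    n <- table(y)
    as.numeric(length(y) / (nlevels(y) * n))
  } else NULL
  fit <- ranger::ranger(
    x = X, y = y, probability = TRUE,
    num.trees = hyper$num_trees,
    mtry = resolve_mtry(hyper$mtry, ncol(X)),
    min.node.size = hyper$min_node_size,
    max.depth = hyper$max_depth,
    replace = hyper$replace,
    sample.fraction = 1,
    class.weights = cw,
    importance = importance,
    seed = seed, num.threads = 1L,
    verbose = FALSE
  )
  list(fit = fit, classes = levels(y), features = colnames(X),
       hyper = hyper, seed = seed)
}

rf_prob <- function(model, X) {
  if (!identical(colnames(X), model$features)) {
    if (setequal(colnames(X), model$features)) {
      X <- X[, model$features, drop = FALSE]
    } else {
      missing <- setdiff(model$features, colnames(X))
      extra <- setdiff(colnames(X), model$features)
      stopf("feature mismatch: missing [%s], extra [%s]",
            paste(utils::head(missing, 5), collapse = ", "),
            paste(utils::head(extra, 5), collapse = ", "))
    }
  }
  p <- stats::predict(model$fit, data = X, num.threads = 1L,
                      verbose = FALSE)$predictions
  p[, sort(colnames(p)), drop = FALSE]
}

# argmax with lexicographic tie-break (columns are sorted, "first" wins)
rf_class <- function(prob) colnames(prob)[max.col(prob, ties.method = "first")]

rf_accuracy <- function(model, X, y) {
  mean(rf_class(rf_prob(model, X)) == as.character(y))
}

# Mean k-fold cross-validated accuracy of one hyperparameter setting.
rf_cv_accuracy <- function(X, y, hyper, folds, seed = 1L) {
  k <- attr(folds, "k") %||% max(folds)
  acc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    m <- rf_fit(X[tr, , drop = FALSE], y[tr], hyper,
                seed = child_seed(seed, f))
    rf_accuracy(m, X[!tr, , drop = FALSE], y[!tr])
  }, 0)
  list(per_fold = acc, mean = mean(acc), sd = stats::sd(acc))
}
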