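# Model-facing helpers shared with the feature-selection module: both
# accept either a fitted gv_classifier or the internal forest list.
as_rf <- function(model) {
  if (inherits(model, "gv_classifier")) model$forest else model
}
model_features <- function(model) as_rf(model)$features

GVTAX_MODEL_VERSION <- "1.0"

#' Default randomized-search hyperparameter grid
#'
#' Conventional random-forest ranges: forest size, tree depth
#' (0 = unbounded), features considered per split (`"sqrt"`, `"log2"`
#' or a fraction of features), minimum terminal node size, and whether
#' trees are grown on bootstrap resamples.
#'
#' @return Named list of candidate value vectors (a `gvtax_grid`).
#' @export
default_grid <- function() {
  structure(list(
    num_trees = c(100L, 200L, 300L, 500L, 1000L),
    max_depth = c(0L, 10L, 20L, 30L, 50L),
    mtry = list("sqrt", "log2", 0.1, 0.3, 0.5),
    min_node_size = c(1L, 2L, 5L, 10L),
    replace = c(TRUE, FALSE)
  ), class = "gvtax_grid")
}

#' A small grid for quick runs
#' @rdname default_grid
#' @export
small_grid <- function() {
  structure(list(
    num_trees = c(100L, 300L),
    max_depth = 0L,
    mtry = list("sqrt", 0.2),
    min_node_size = c(1L, 5L),
    replace = TRUE
  ), class = "gvtax_grid")
}

grid_size <- function(grid) prod(lengths(grid))

# One configuration drawn uniformly from a grid.
draw_config <- function(grid) {
  lapply(grid, function(v) {
    x <- v[[sample.int(length(v), 1L)]]
    if (is.list(x)) x[[1]] else x
  })
}

# Refined grid: +/- one step around the best value for numeric
# parameters with alternatives; other parameters fixed at the best.
refine_grid <- function(grid, best) {
  out <- lapply(names(grid), function(p) {
    v <- grid[[p]]
    vals <- if (is.list(v)) v else as.list(v)
    if (length(vals) > 1 && is.numeric(best[[p]]) &&
        all(vapply(vals, is.numeric, TRUE))) {
      i <- which(vapply(vals, identical, TRUE, best[[p]]))[1]
      vals[max(1L, i - 1L):min(length(vals), i + 1L)]
    } else {
      list(best[[p]])
    }
  })
  names(out) <- names(grid)
  structure(out, class = "gvtax_grid")
}

expand_configs <- function(grid) {
  idx <- expand.grid(lapply(grid, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(idx)), function(r) {
    cfg <- lapply(names(grid), function(p) {
      v <- grid[[p]]
      x <- if (is.list(v)) v[[idx[r, p]]] else v[[idx[r, p]]]
      x
    })
    names(cfg) <- names(grid)
    cfg
  })
}

config_key <- function(cfg) paste(vapply(cfg, format, ""), collapse = "|")

#' Hyperparameter tuning: randomized search then grid search
#'
#' Stage 1 draws `n_random_draws` configurations at random from the
#' grid and scores each by stratified k-fold cross-validated accuracy.
#' Stage 2 exhaustively searches a refined grid (one step either side
#' of the stage-1 optimum for numeric parameters) with the same folds
#' and returns the configuration with the highest mean CV accuracy.
#'
#' @param mat Feature matrix (genomes x features).
#' @param labels Class labels, one per row.
#' @param grid A `gvtax_grid` ([default_grid()] or [small_grid()]).
#' @param n_random_draws Stage-1 sample size, default 20.
#' @param cv_folds Folds, default 10 (reduced with a warning when the
#'   smallest class is smaller).
#' @param seed Integer seed; the selected configuration is
#'   deterministic.
#' @return List of class `gv_tune`: `best_hyper`, `cv_report`
#'   (per-fold accuracies of the winner), `search` (scored
#'   configurations from both stages).
#' @export
gv_tune <- function(mat, labels, grid = default_grid(),
                    n_random_draws = 20, cv_folds = 10, seed = 1L) {
  if (length(grid) == 0 || any(lengths(grid) == 0)) stopf("empty hyperparameter grid")
  folds <- make_folds(labels, cv_folds, seed = seed)

  score_configs <- function(configs, stage, seed_base) {
    res <- lapply(seq_along(configs), function(i) {
      cv <- rf_cv_accuracy(mat, labels, configs[[i]], folds,
                           seed = child_seed(seed_base, i))
      list(cfg = configs[[i]], mean = cv$mean, sd = cv$sd,
           per_fold = cv$per_fold, stage = stage)
    })
    res
  }

  n_total <- grid_size(grid)
  configs1 <- with_seed(seed, {
    if (n_total <= n_random_draws) {
      expand_configs(grid)
    } else {
      seen <- character(0)
      out <- list()
      while (length(out) < n_random_draws) {
        cfg <- draw_config(grid)
        k <- config_key(cfg)
        if (!(k %in% seen)) {
          seen <- c(seen, k)
          out[[length(out) + 1L]] <- cfg
        }
      }
      out
    }
  })
  stage1 <- score_configs(configs1, "random", child_seed(seed, 1000))
  best1 <- stage1[[which.max(vapply(stage1, `[[`, 0, "mean"))]]

  refined <- refine_grid(grid, best1$cfg)
  configs2 <- expand_configs(refined)
  stage2 <- score_configs(configs2, "grid", child_seed(seed, 2000))
  best2 <- stage2[[which.max(vapply(stage2, `[[`, 0, "mean"))]]

  search <- do.call(rbind, lapply(c(stage1, stage2), function(s) {
    data.frame(stage = s$stage, config = config_key(s$cfg),
               mean_cv_accuracy = s$mean, sd = s$sd,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    best_hyper = best2$cfg,
    cv_report = cv_report(best2$per_fold, seed, "kfold"),
    search = search
  ), class = "gv_tune")
}

cv_report <- function(per_fold, seed, scheme) {
  structure(list(per_fold = per_fold, mean = mean(per_fold),
                 sd = stats::sd(per_fold), seed = seed, scheme = scheme),
            class = "gv_cv_report")
}

#' @export
print.gv_cv_report <- function(x, ...) {
  cat(sprintf("<gv_cv_report> %s, %d folds: accuracy %.4f +/- %.4f\n",
              x$scheme, length(x$per_fold), x$mean, x$sd))
  invisible(x)
}

#' @export
print.gv_tune <- function(x, ...) {
  cat("<gv_tune> best configuration:\n")
  utils::str(x$best_hyper, give.attr = FALSE)
  print(x$cv_report)
  invisible(x)
}

#' Plain stratified k-fold cross-validation of one configuration
#'
#' Scores a single hyperparameter configuration by stratified k-fold
#' CV. Fold assignment and per-fold fit seeds match
#' [gv_nested_cv()]'s, so with a single-configuration grid the nested
#' estimate reduces exactly to this one.
#'
#' @inheritParams gv_tune
#' @param hyper Forest hyperparameters.
#' @return A `gv_cv_report` (scheme `"kfold"`).
#' @export
gv_kfold_cv <- function(mat, labels, hyper = list(), cv_folds = 10,
                        seed = 1L) {
  labels <- as.character(labels)
  folds <- make_folds(labels, cv_folds, seed = seed)
  k <- attr(folds, "k")
  acc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    m <- rf_fit(mat[tr, , drop = FALSE], labels[tr], hyper,
                seed = child_seed(seed, 100 + f))
    rf_accuracy(m, mat[!tr, , drop = FALSE], labels[!tr])
  }, 0)
  cv_report(acc, seed, "kfold")
}

#' Nested cross-validation
#'
#' Model selection (the randomized + grid search of [gv_tune()]) runs
#' inside each outer training fold; the selected model is then scored
#' on the outer test fold it has never seen. The outer-fold accuracies
#' estimate how well the whole training strategy generalizes.
#'
#' @inheritParams gv_tune
#' @param outer_folds,inner_folds Fold counts, default 10.
#' @return A `gv_cv_report` (scheme `"nested"`).
#' @export
gv_nested_cv <- function(mat, labels, grid = default_grid(),
                         outer_folds = 10, inner_folds = 10,
                         n_random_draws = 20, seed = 1L) {
  labels <- as.character(labels)
  outer <- make_folds(labels, outer_folds, seed = seed)
  k <- attr(outer, "k")
  acc <- vapply(seq_len(k), function(f) {
    tr <- outer != f
    Xtr <- mat[tr, , drop = FALSE]
    ytr <- labels[tr]
    best <- if (grid_size(grid) == 1) {
      lapply(grid, function(v) if (is.list(v)) v[[1]] else v[[1]])
    } else {
      tn <- gv_tune(Xtr, ytr, grid, n_random_draws = n_random_draws,
                    cv_folds = inner_folds, seed = child_seed(seed, f))
      tn$best_hyper
    }
    m <- rf_fit(Xtr, ytr, best, seed = child_seed(seed, 100 + f))
    rf_accuracy(m, mat[!tr, , drop = FALSE], labels[!tr])
  }, 0)
  cv_report(acc, seed, "nested")
}

#' Learning curve over training-set size
#'
#' For each fraction, every cross-validation training fold is
#' subsampled (stratified, at least one genome per class) to that
#' fraction, a model is fitted on the subsample and scored on the
#' fold's untouched test part.
#'
#' @inheritParams gv_tune
#' @param fractions Fractions of the training fold to use, default
#'   `seq(0.25, 1, by = 0.25)`.
#' @param hyper Forest hyperparameters used at every size (tuning at
#'   every size is supported by passing a `grid` instead).
#' @return `data.frame`: `fraction`, `n_sequences` (mean subsample
#'   size), `mean_accuracy`, `sd`.
#' @export
gv_learning_curve <- function(mat, labels, fractions = seq(0.25, 1, 0.25),
                              cv_folds = 10, seed = 1L, hyper = list(),
                              grid = NULL, n_random_draws = 10) {
  if (any(fractions <= 0 | fractions > 1)) stopf("fractions must be in (0, 1]")
  labels <- as.character(labels)
  folds <- make_folds(labels, cv_folds, seed = seed)
  k <- attr(folds, "k")
  rows <- lapply(seq_along(fractions), function(i) {
    fr <- fractions[i]
    res <- vapply(seq_len(k), function(f) {
      tr_idx <- which(folds != f)
      sub <- tr_idx[stratified_subsample(labels[tr_idx], fr,
                                         seed = child_seed(seed, i * 100 + f))]
      hy <- if (!is.null(grid) && grid_size(grid) > 1) {
        gv_tune(mat[sub, , drop = FALSE], labels[sub], grid,
                n_random_draws = n_random_draws, cv_folds = 3,
                seed = child_seed(seed, i * 1000 + f))$best_hyper
      } else hyper
      m <- rf_fit(mat[sub, , drop = FALSE], labels[sub], hy,
                  seed = child_seed(seed, i * 10000 + f))
      c(rf_accuracy(m, mat[folds == f, , drop = FALSE], labels[folds == f]),
        length(sub))
    }, c(0, 0))
    data.frame(fraction = fr, n_sequences = mean(res[2, ]),
               mean_accuracy = mean(res[1, ]), sd = stats::sd(res[1, ]))
  })
  do.call(rbind, rows)
}

#' Fit a final classifier
#'
#' Fits a random forest on all supplied genomes, restricted to the
#' given feature subset, and freezes the feature and class order into
#' the returned model.
#'
#' @inheritParams gv_tune
#' @param features Feature subset to train on (must be columns of
#'   `mat`); default all.
#' @param hyper Forest hyperparameters (e.g. `gv_tune()$best_hyper`).
#' @param level `"order"` or `"family"` (metadata only).
#' @param cv_accuracy Optional CV accuracy stored as metadata.
#' @return Object of class `gv_classifier`.
#' @export
gv_fit <- function(mat, labels, features = colnames(mat), hyper = list(),
                   level = c("order", "family"), seed = 1L,
                   cv_accuracy = NULL) {
  level <- match.arg(level)
  missing <- setdiff(features, colnames(mat))
  if (length(missing) > 0) {
    stopf("features not in matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  tab <- table(labels)
  if (any(tab == 1)) {
    warnf("class(es) with a single member: %s",
          paste(names(tab)[tab == 1], collapse = ", "))
  }
  forest <- rf_fit(mat[, features, drop = FALSE], labels, hyper,
                   seed = seed, importance = "impurity")
  structure(list(
    level = level,
    forest = forest,
    features = features,
    classes = forest$classes,
    hyper = forest$hyper,
    seed = seed,
    cv_accuracy = cv_accuracy,
    version = GVTAX_MODEL_VERSION,
    trained_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "gv_classifier")
}

#' @export
print.gv_classifier <- function(x, ...) {
  cat(sprintf("<gv_classifier> %s-level, %d classes, %d features, %d trees\n",
              x$level, length(x$classes), length(x$features),
              x$hyper$num_trees))
  if (!is.null(x$cv_accuracy)) {
    cat(sprintf("  CV accuracy: %.4f\n", x$cv_accuracy))
  }
  invisible(x)
}

#' @export
summary.gv_classifier <- function(object, ...) {
  print(object)
  cat("  classes:", paste(object$classes, collapse = ", "), "\n")
  cat("  hyperparameters:\n")
  utils::str(object$hyper, give.attr = FALSE)
  invisible(object)
}

#' Persist / restore a trained classifier
#'
#' Models are stored as a directory: the serialized forest plus a JSON
#' metadata file carrying the format version, frozen feature and class
#' order, hyperparameters and seed. Loading a model whose format
#' version does not match the package's is an error, never a silent
#' fallback.
#'
#' @param model A `gv_classifier`.
#' @param dir Model directory.
#' @export
save_gv_classifier <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- model[setdiff(names(model), "forest")]
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model$forest, file.path(dir, "forest.rds"))
  invisible(dir)
}

#' @rdname save_gv_classifier
#' @export
load_gv_classifier <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$version, GVTAX_MODEL_VERSION)) {
    stopf("model format version '%s' does not match supported version '%s'",
          meta$version, GVTAX_MODEL_VERSION)
  }
  model <- c(meta, list(forest = readRDS(file.path(dir, "forest.rds"))))
  meta_order <- c("level", "forest", "features", "classes", "hyper", "seed",
                  "cv_accuracy", "version", "trained_at")
  model <- model[intersect(meta_order, names(model))]
  model$hyper <- as.list(model$hyper)
  structure(model, class = "gv_classifier")
}
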