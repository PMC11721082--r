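#' Screen GVOG features by within-order prevalence
#'
#' Keeps a GVOG when its prevalence (fraction of genomes carrying it)
#' within a taxonomic order clears `min_prevalence`. Under
#' `mode = "any"` the maximum prevalence across orders must clear the
#' threshold (a GVOG well represented in at least one order is kept);
#' under `mode = "every"` the minimum must. GC content is always
#' retained.
#'
#' @param mat Feature matrix from [build_feature_matrix()].
#' @param orders Character vector of order labels, one per matrix row.
#' @param min_prevalence Prevalence threshold, default 0.25.
#' @param mode `"any"` (default) or `"every"`.
#' @return Character vector of retained feature names,
#'   `gc_content` first, GVOGs in their original column order.
#' @export
prevalence_screen <- function(mat, orders, min_prevalence = 0.25,
                              mode = c("any", "every")) {
  mode <- match.arg(mode)
  if (length(orders) != nrow(mat)) {
    stopf("orders has %d entries for %d genomes", length(orders), nrow(mat))
  }
  gvogs <- setdiff(colnames(mat), "gc_content")
  prev <- prevalence_table(mat, orders)
  stat <- if (mode == "any") apply(prev, 1, max) else apply(prev, 1, min)
  kept <- gvogs[stat[gvogs] >= min_prevalence]
  c("gc_content", kept)
}

#' Per-(GVOG, order) prevalence table
#'
#' @inheritParams prevalence_screen
#' @return Matrix of prevalence fractions, GVOGs x orders.
#' @export
prevalence_table <- function(mat, orders) {
  orders <- as.character(orders)
  gvogs <- setdiff(colnames(mat), "gc_content")
  lvls <- unique(orders)
  sizes <- table(orders)[lvls]
  if (any(sizes == 0)) stopf("order with zero genomes")
  prev <- vapply(lvls, function(o) {
    colMeans(mat[orders == o, gvogs, drop = FALSE])
  }, numeric(length(gvogs)))
  if (is.null(dim(prev))) prev <- matrix(prev, nrow = length(gvogs),
                                         dimnames = list(gvogs, lvls))
  prev
}

#' Cluster collinear features on Spearman rank correlation
#'
#' Binary GVOG profiles are strongly collinear (co-inherited gene
#' blocks), which splits permutation importance across correlated
#' copies. Clustering on the distance 1 - rho (Spearman) with Ward's
#' linkage and keeping one representative per cluster removes that
#' redundancy before importance is measured.
#'
#' @param mat Feature matrix (columns are features).
#' @param distance_threshold Tree cut height on 1 - rho; default 0.5.
#' @param ranking Optional named numeric vector; within a cluster the
#'   highest-ranked feature becomes the representative (default: first
#'   feature in column order).
#' @return List of class `feature_clusters`: `clusters` (named integer
#'   vector feature -> cluster), `representatives` (one feature per
#'   cluster), `threshold`, `linkage`.
#' @export
spearman_cluster <- function(mat, distance_threshold = 0.5, ranking = NULL) {
  if (ncol(mat) < 2) stopf("need >= 2 features to cluster, got %d", ncol(mat))
  rho <- suppressWarnings(stats::cor(mat, method = "spearman"))
  rho[is.na(rho)] <- 0   # constant columns correlate with nothing
  diag(rho) <- 1
  d <- stats::as.dist(1 - rho)
  if (distance_threshold <= 0) {
    cl <- stats::setNames(seq_len(ncol(mat)), colnames(mat))
  } else {
    hc <- stats::hclust(d, method = "ward.D2")
    cl <- stats::cutree(hc, h = distance_threshold)
  }
  reps <- vapply(split(names(cl), cl), function(members) {
    if (!is.null(ranking)) {
      r <- ranking[members]
      r[is.na(r)] <- -Inf
      members[order(-r, members)][1]
    } else members[1]
  }, "")
  structure(list(clusters = cl, representatives = unname(reps),
                 threshold = distance_threshold, linkage = "ward.D2"),
            class = "feature_clusters")
}

#' @export
print.feature_clusters <- function(x, ...) {
  cat(sprintf("<feature_clusters> %d features in %d clusters (1 - rho, %s, cut %.2f)\n",
              length(x$clusters), length(x$representatives), x$linkage,
              x$threshold))
  invisible(x)
}

#' Recursive feature elimination accuracy curve
#'
#' For each requested feature-set size, features are eliminated
#' iteratively (dropping the 10% of remaining features with the lowest
#' impurity importance per round) down to that size, and the surviving
#' subset is scored by stratified k-fold cross-validation.
#'
#' @param mat Feature matrix.
#' @param labels Class labels, one per row.
#' @param sizes Strictly increasing feature-set sizes to score.
#' @param cv_folds Folds for scoring, default 10.
#' @param seed Integer seed.
#' @param hyper Forest hyperparameters (named list, see details of
#'   [gv_tune()]).
#' @param step Fraction of remaining features dropped per elimination
#'   round, default 0.1.
#' @return `data.frame` with columns `n_features`, `mean_cv_accuracy`,
#'   `sd`.
#' @export
rfe_curve <- function(mat, labels, sizes, cv_folds = 10, seed = 1L,
                      hyper = list(), step = 0.1) {
  if (any(sizes < 1)) stopf("feature-set sizes must be >= 1")
  if (any(sizes > ncol(mat))) stopf("size exceeds %d features", ncol(mat))
  if (is.unsorted(sizes, strictly = TRUE)) stopf("sizes must be strictly increasing")

  # eliminate once down to the smallest size, recording survivors at
  # each requested size on the way
  surviving <- colnames(mat)
  subsets <- list()
  for (target in rev(sizes)) {
    while (length(surviving) > target) {
      m <- rf_fit(mat[, surviving, drop = FALSE], labels, hyper,
                  seed = child_seed(seed, length(surviving)))
      imp <- m$fit$variable.importance
      n_drop <- min(length(surviving) - target,
                    max(1L, floor(step * length(surviving))))
      surviving <- surviving[order(-imp[surviving])]
      surviving <- surviving[seq_len(length(surviving) - n_drop)]
    }
    subsets[[as.character(target)]] <- surviving
  }

  folds <- make_folds(labels, cv_folds, seed = seed)
  rows <- lapply(sizes, function(s) {
    sub <- subsets[[as.character(s)]]
    cv <- rf_cv_accuracy(mat[, sub, drop = FALSE], labels, hyper, folds,
                         seed = seed)
    data.frame(n_features = s, mean_cv_accuracy = cv$mean, sd = cv$sd)
  })
  do.call(rbind, rows)
}

#' Permutation importance on a held-out set
#'
#' Mean decrease in held-out accuracy when one feature column is
#' shuffled, repeated `n_repeats` times. When a
#' [spearman_cluster()] result is supplied, only cluster
#' representatives are permuted (correlated copies would otherwise
#' mask each other's importance).
#'
#' @param model Fitted forest (from [gv_fit()] or internal fit).
#' @param mat Held-out feature matrix.
#' @param labels Held-out labels.
#' @param n_repeats Shuffles per feature, default 10.
#' @param seed Integer seed.
#' @param clusters Optional `feature_clusters` object.
#' @return Object of class `importance_ranking`: `data.frame` with
#'   `feature`, `mean_importance`, `sd_importance`, ordered by
#'   decreasing mean; attribute `method = "permutation"`.
#' @export
permutation_importance <- function(model, mat, labels, n_repeats = 10,
                                   seed = 1L, clusters = NULL) {
  feats <- model_features(model)
  if (!setequal(colnames(mat), feats)) {
    stopf("feature mismatch between model and matrix")
  }
  mat <- mat[, feats, drop = FALSE]
  targets <- if (!is.null(clusters)) {
    intersect(feats, clusters$representatives)
  } else feats
  baseline <- rf_accuracy(as_rf(model), mat, labels)
  drops <- matrix(NA_real_, nrow = length(targets), ncol = n_repeats,
                  dimnames = list(targets, NULL))
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      perm <- sample.int(nrow(mat))
      for (f in targets) {
        shuffled <- mat
        shuffled[, f] <- mat[perm, f]
        drops[f, r] <- baseline - rf_accuracy(as_rf(model), shuffled, labels)
      }
    }
  })
  ranking(data.frame(
    feature = targets,
    mean_importance = rowMeans(drops),
    sd_importance = apply(drops, 1, stats::sd),
    stringsAsFactors = FALSE
  ), method = "permutation", baseline = baseline)
}

#' Impurity-based (MDI) feature importance
#'
#' Mean decrease in Gini impurity accumulated over the trees of the
#' forest, normalized to sum to 1 across features.
#'
#' @param model Fitted forest (trained with impurity importance).
#' @return An `importance_ranking` (method `"impurity"`). The
#'   per-tree spread is not exposed by the forest backend, so
#'   `sd_importance` is `NA`.
#' @export
impurity_importance <- function(model) {
  rf <- as_rf(model)
  imp <- rf$fit$variable.importance
  if (is.null(imp)) stopf("model was not fitted with impurity importance")
  imp <- imp / sum(imp)
  ranking(data.frame(
    feature = names(imp),
    mean_importance = unname(imp),
    sd_importance = NA_real_,
    stringsAsFactors = FALSE
  ), method = "impurity")
}

ranking <- function(df, method, baseline = NULL) {
  df <- df[order(-df$mean_importance, df$feature), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("importance_ranking", "data.frame"),
            method = method, baseline = baseline)
}

#' @export
print.importance_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<importance_ranking> method = %s, %d features\n",
              attr(x, "method"), nrow(x)))
  print.data.frame(utils::head(x, n), digits = 4)
  invisible(x)
}

#' Select the final feature subset from an importance ranking
#'
#' Top-`k` features by mean importance, ties broken lexicographically
#' by feature name. GC content is always part of the final feature set
#' (swapped in for the weakest selected feature when it would
#' otherwise drop out).
#'
#' @param ranking An `importance_ranking`.
#' @param k Number of features to keep.
#' @return Character vector of `k` feature names, ranking order.
#' @export
select_final_features <- function(ranking, k) {
  if (k < 1) stopf("k must be >= 1")
  if (k > nrow(ranking)) stopf("k = %d exceeds %d ranked features", k, nrow(ranking))
  ord <- order(-ranking$mean_importance, ranking$feature)
  sel <- ranking$feature[ord][seq_len(k)]
  if ("gc_content" %in% ranking$feature && !("gc_content" %in% sel)) {
    sel[k] <- "gc_content"
  }
  sel
}
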