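# A small deterministic matrix generator for selection tests: two
# informative blocks plus noise columns.
sel_data <- function(n_per_class = 40, n_noise = 30, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c("A", "B"), each = n_per_class)
  informative <- ifelse(y == "A", 1, 0)
  X <- cbind(
    gc_content = ifelse(y == "A", 0.3, 0.5) + rnorm(n, 0, 0.01),
    sig = informative,
    matrix(rbinom(n * n_noise, 1, 0.3), n,
           dimnames = list(NULL, sprintf("noise%02d", seq_len(n_noise))))
  )
  rownames(X) <- sprintf("g%03d", seq_len(n))
  list(X = X, y = y)
}

test_that("prevalence screening matches hand-enumerated prevalences in both modes", {
  # 2 orders of 4 genomes; v1 present in 1/4 of A and 0/4 of B
  mat <- cbind(gc_content = rep(0.4, 8),
               v1 = c(1, 0, 0, 0, 0, 0, 0, 0),
               v2 = rep(1, 8),
               v3 = c(0, 0, 0, 0, 1, 1, 0, 0))
  rownames(mat) <- sprintf("g%d", 1:8)
  orders <- rep(c("A", "B"), each = 4)

  expect_setequal(prevalence_screen(mat, orders, 0.25, "any"),
                  c("gc_content", "v1", "v2", "v3"))
  expect_setequal(prevalence_screen(mat, orders, 0.25, "every"),
                  c("gc_content", "v2"))
  # vacuous threshold keeps everything
  expect_length(prevalence_screen(mat, orders, 0, "every"), 4)

  prev <- prevalence_table(mat, orders)
  expect_equal(prev["v1", "A"], 0.25)
  expect_equal(prev["v3", "B"], 0.5)
})

test_that("prevalence screening is monotone in the threshold", {
  sub <- fix_mat[, 1:80]
  kept_prev <- NULL
  for (thr in c(0, 0.1, 0.25, 0.5, 0.9)) {
    kept <- prevalence_screen(sub, fix_orders, thr)
    if (!is.null(kept_prev)) expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }
})

test_that("spearman clustering groups identical columns and splits independent ones", {
  set.seed(7)
  a <- rbinom(200, 1, 0.5)
  b <- rbinom(200, 1, 0.5)  # independent of a: |rho| small
  mat <- cbind(f1 = a, f2 = a, f3 = b)
  cl <- spearman_cluster(mat, distance_threshold = 0.5)
  expect_equal(cl$clusters[["f1"]], cl$clusters[["f2"]])
  expect_false(cl$clusters[["f1"]] == cl$clusters[["f3"]])

  # threshold 0: every feature its own cluster
  cl0 <- spearman_cluster(mat, distance_threshold = 0)
  expect_length(unique(cl0$clusters), 3)

  expect_error(spearman_cluster(mat[, 1, drop = FALSE]), ">= 2 features")
})

test_that("spearman clustering is invariant to monotone transforms of a column", {
  set.seed(8)
  mat <- cbind(f1 = runif(100), f2 = runif(100), f3 = runif(100))
  mat2 <- mat
  mat2[, "f2"] <- exp(5 * mat2[, "f2"])  # strictly monotone transform
  c1 <- spearman_cluster(mat, 0.7)
  c2 <- spearman_cluster(mat2, 0.7)
  expect_identical(c1$clusters, c2$clusters)
})

test_that("constant columns cluster apart (rho defined as 0 against all)", {
  set.seed(9)
  mat <- cbind(f1 = rbinom(100, 1, 0.5), flat = rep(1, 100),
               f3 = rbinom(100, 1, 0.5))
  cl <- spearman_cluster(mat, 0.5)
  expect_false(cl$clusters[["flat"]] == cl$clusters[["f1"]])
})

test_that("the RFE curve scores the full model at size = total and holds its accuracy on the signal support", {
  d <- sel_data(n_per_class = 30, n_noise = 20, seed = 2)
  sizes <- c(5, ncol(d$X))
  curve <- rfe_curve(d$X, d$y, sizes, cv_folds = 5, seed = 3,
                     hyper = list(num_trees = 100))
  expect_equal(nrow(curve), 2)
  expect_equal(curve$n_features, sizes)
  # informative features (gc + sig) survive elimination to size 5, so
  # accuracy there stays within 2 points of the full model
  expect_lt(abs(curve$mean_cv_accuracy[1] - curve$mean_cv_accuracy[2]), 0.02 + 1e-9)
  expect_error(rfe_curve(d$X, d$y, c(0, 5)), ">= 1")
  expect_error(rfe_curve(d$X, d$y, c(5, 2)), "strictly increasing")
})

test_that("permutation importance finds the signal, zeroes constants, and collapses under collinearity", {
  d <- sel_data(n_per_class = 40, n_noise = 10, seed = 4)
  X <- cbind(d$X, flat = rep(1, nrow(d$X)))
  holdout <- sel_data(n_per_class = 40, n_noise = 10, seed = 5)
  Xh <- cbind(holdout$X, flat = rep(1, nrow(holdout$X)))
  m <- gvtax:::rf_fit(X, d$y, list(num_trees = 200), seed = 1)

  imp <- permutation_importance(m, Xh, holdout$y, n_repeats = 10, seed = 6)
  expect_s3_class(imp, "importance_ranking")
  # a constant column cannot matter
  expect_equal(imp$mean_importance[imp$feature == "flat"], 0)
  # the informative features outrank everything else
  expect_true(imp$feature[1] %in% c("sig", "gc_content"))

  expect_error(permutation_importance(m, Xh[, -2], holdout$y), "mismatch")
})

test_that("a duplicated feature's importance is masked by its copy and restored by clustering", {
  # one fully informative feature, duplicated, among 30 noise columns:
  # the model can route the signal through either copy, so permuting
  # one copy understates its true importance
  set.seed(24)
  n <- 80
  y <- rep(c("A", "B"), each = n / 2)
  sig <- as.numeric(y == "A")
  X <- cbind(sig = sig, sig_copy = sig,
             matrix(rbinom(n * 30, 1, 0.3), n,
                    dimnames = list(NULL, sprintf("noise%02d", 1:30))))
  Xh <- cbind(sig = sig, sig_copy = sig,
              matrix(rbinom(n * 30, 1, 0.3), n,
                     dimnames = list(NULL, sprintf("noise%02d", 1:30))))
  m <- gvtax:::rf_fit(X, y, list(num_trees = 200), seed = 2)
  imp <- permutation_importance(m, Xh, y, n_repeats = 10, seed = 7)
  both <- imp$mean_importance[imp$feature %in% c("sig", "sig_copy")]

  # clustering merges the copies; retraining on one representative per
  # cluster re-concentrates the signal in the surviving copy
  cl <- spearman_cluster(X, 0.5)
  expect_false(all(c("sig", "sig_copy") %in% cl$representatives))
  mrep <- gvtax:::rf_fit(X[, cl$representatives, drop = FALSE], y,
                         list(num_trees = 200), seed = 3)
  imp_cl <- permutation_importance(
    mrep, Xh[, cl$representatives, drop = FALSE], y,
    n_repeats = 10, seed = 8)
  rep_imp <- imp_cl$mean_importance[
    imp_cl$feature %in% c("sig", "sig_copy")]
  expect_length(rep_imp, 1)

  # masking: the weaker copy measures well under half of the restored
  # (unmasked) importance despite carrying the complete class signal,
  # and neither copy reaches the restored value
  expect_lt(min(both), 0.5 * rep_imp)
  expect_true(all(both < rep_imp))
  expect_gt(rep_imp, 0.3)
})

test_that("permutation importance of a label-independent feature converges to zero", {
  d <- sel_data(n_per_class = 40, n_noise = 5, seed = 9)
  holdout <- sel_data(n_per_class = 40, n_noise = 5, seed = 10)
  m <- gvtax:::rf_fit(d$X, d$y, list(num_trees = 200), seed = 3)
  imp <- permutation_importance(m, holdout$X, holdout$y,
                                n_repeats = 50, seed = 11)
  noise_imp <- imp$mean_importance[grepl("^noise", imp$feature)]
  expect_true(all(abs(noise_imp) < 0.03))
})

test_that("impurity importance normalizes to one and ranks a separating feature first", {
  d <- sel_data(n_per_class = 40, n_noise = 20, seed = 12)
  m <- gvtax:::rf_fit(d$X, d$y, list(num_trees = 300), seed = 4)
  imp <- impurity_importance(m)
  expect_equal(sum(imp$mean_importance), 1, tolerance = 1e-9)
  expect_true(imp$feature[1] %in% c("sig", "gc_content"))
  # the two separating features absorb most of the impurity decrease
  expect_gt(sum(imp$mean_importance[imp$feature %in% c("sig", "gc_content")]),
            0.5)
  # pure-noise features each stay below twice the uniform share in this
  # strongly-separated design
  noise_imp <- imp$mean_importance[grepl("^noise", imp$feature)]
  expect_true(all(noise_imp < 2 / ncol(d$X)))
})

test_that("final feature selection keeps top-k, breaks ties lexicographically, retains GC", {
  rk <- structure(
    data.frame(feature = c("a", "b", "c"),
               mean_importance = c(0.3, 0.3, 0.1),
               sd_importance = NA_real_),
    class = c("importance_ranking", "data.frame"), method = "impurity")
  expect_identical(select_final_features(rk, 2), c("a", "b"))
  expect_identical(select_final_features(rk, 3), c("a", "b", "c"))
  expect_error(select_final_features(rk, 0), ">= 1")
  expect_error(select_final_features(rk, 4), "exceeds")

  rk_gc <- structure(
    data.frame(feature = c("a", "b", "gc_content"),
               mean_importance = c(0.5, 0.4, 0.1),
               sd_importance = NA_real_),
    class = c("importance_ranking", "data.frame"), method = "impurity")
  expect_true("gc_content" %in% select_final_features(rk_gc, 2))
})
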