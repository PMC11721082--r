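#' Predict taxonomy for query genomes
#'
#' Applies a trained classifier to a feature matrix. The class
#' probability is the fraction of trees voting for the class; ties are
#' broken lexicographically. Predictions with a maximum probability
#' below `low_confidence_cutoff` are flagged: in practice incorrect
#' assignments concentrate in this low-probability regime, so the
#' probability is a useful confidence proxy.
#'
#' @param object A `gv_classifier`.
#' @param newdata Feature matrix; columns are matched to the model's
#'   frozen feature list by name (reordering is permitted; missing or
#'   extra features are an error).
#' @param low_confidence_cutoff Probability below which a call is
#'   flagged, default 0.5.
#' @param ... Unused.
#' @return A `gv_prediction`: `data.frame` with `genome_id`, `level`,
#'   `predicted_class`, `probability`, `low_confidence`; the full
#'   probability matrix (rows = genomes, columns = classes) is in
#'   `attr(, "prob")`.
#' @export
predict.gv_classifier <- function(object, newdata,
                                  low_confidence_cutoff = 0.5, ...) {
  prob <- rf_prob(object$forest, newdata)
  cls <- rf_class(prob)
  p <- prob[cbind(seq_len(nrow(prob)), match(cls, colnames(prob)))]
  out <- data.frame(
    genome_id = rownames(newdata) %||% as.character(seq_len(nrow(newdata))),
    level = object$level,
    predicted_class = cls,
    probability = p,
    low_confidence = p < low_confidence_cutoff,
    stringsAsFactors = FALSE
  )
  rownames(prob) <- out$genome_id
  structure(out, class = c("gv_prediction", "data.frame"), prob = prob)
}

#' @export
print.gv_prediction <- function(x, ...) {
  cat(sprintf("<gv_prediction> %d genomes at the %s level (%d low-confidence)\n",
              nrow(x), x$level[1] %||% "?", sum(x$low_confidence)))
  print.data.frame(utils::head(x, 10), digits = 3)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Aggregate rare families into order-level bins
#'
#' Families with fewer than `min_members` genomes are relabeled to
#' their order's aggregate bin (e.g. families of Imitervirales with
#' few representatives become `IM`), so the family-level classifier
#' only sees classes with enough support to learn.
#'
#' @param labels `data.frame` with columns `genome_id`, `order`,
#'   `family`.
#' @param min_members Families below this size are aggregated;
#'   default 30.
#' @param order_bins Named character vector mapping order name to bin
#'   label; orders not listed get the first two letters, uppercased.
#' @return `labels` with an added/overwritten `family_class` column.
#' @export
aggregate_rare_families <- function(labels, min_members = 30,
                                    order_bins = c(
                                      Algavirales = "AG",
                                      Asfuvirales = "AF",
                                      Imitervirales = "IM",
                                      Pandoravirales = "PV",
                                      Pimascovirales = "PM"
                                    )) {
  counts <- table(labels$family)
  bin_of <- function(ord) {
    ifelse(ord %in% names(order_bins), order_bins[ord],
           toupper(substr(ord, 1, 2)))
  }
  rare <- labels$family %in% names(counts)[counts < min_members]
  labels$family_class <- ifelse(rare, unname(bin_of(labels$order)),
                                labels$family)
  labels
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`; a zero
#' denominator yields 0 by convention.
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @return `data.frame` with columns `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stopf("counts must be non-negative")
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  data.frame(precision = precision, recall = recall, f1 = f1)
}

#' Evaluate predictions against true labels
#'
#' Builds the classification report: overall accuracy, per-class
#' precision/recall/F1 with support, support-weighted averages, and
#' the confusion matrix both raw and row-normalized (rows = truth,
#' columns = predicted; each row of the normalized matrix sums to 1
#' for classes with support).
#'
#' @param predictions A `gv_prediction`, or a character vector of
#'   predicted classes named by genome id.
#' @param truth Named character vector (genome id -> true class), or a
#'   `data.frame` with `genome_id` and a class column.
#' @param truth_col Class column used when `truth` is a `data.frame`.
#' @return Object of class `gv_evaluation` with fields `accuracy`,
#'   `n`, `per_class`, `weighted`, `confusion`, `confusion_normalized`.
#' @export
gv_evaluate <- function(predictions, truth, truth_col = "class") {
  pred <- if (inherits(predictions, "gv_prediction")) {
    stats::setNames(predictions$predicted_class, predictions$genome_id)
  } else predictions
  if (is.data.frame(truth)) {
    truth <- stats::setNames(as.character(truth[[truth_col]]),
                             truth$genome_id)
  }
  if (!is.null(names(pred))) {
    missing <- setdiff(names(pred), names(truth))
    if (length(missing) > 0) {
      stopf("predictions without a truth label: %s",
            paste(utils::head(missing, 5), collapse = ", "))
    }
    truth <- truth[names(pred)]
  }
  if (length(pred) != length(truth)) {
    stopf("%d predictions vs %d truth labels", length(pred), length(truth))
  }
  classes <- sort(unique(c(pred, truth)))
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("truth", "predicted")

  support <- rowSums(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- support - tp
  prf <- precision_recall_f1(tp, fp, fn)
  per_class <- data.frame(class = classes, prf, support = as.integer(support),
                          row.names = NULL, stringsAsFactors = FALSE)

  n <- sum(cm)
  w <- support / n
  weighted <- c(precision = sum(w * prf$precision),
                recall = sum(w * prf$recall),
                f1 = sum(w * prf$f1))

  norm <- cm / ifelse(support > 0, support, 1)
  structure(list(
    accuracy = sum(tp) / n,
    n = as.integer(n),
    per_class = per_class,
    weighted = weighted,
    confusion = cm,
    confusion_normalized = norm
  ), class = "gv_evaluation")
}

#' @export
print.gv_evaluation <- function(x, digits = 2, ...) {
  cat(sprintf("<gv_evaluation> n = %d, accuracy = %s\n", x$n,
              format(round(x$accuracy, digits))))
  tab <- x$per_class
  tab$precision <- round(tab$precision, digits)
  tab$recall <- round(tab$recall, digits)
  tab$f1 <- round(tab$f1, digits)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("weighted avg: precision %s, recall %s, F1 %s\n",
              format(round(x$weighted[["precision"]], digits)),
              format(round(x$weighted[["recall"]], digits)),
              format(round(x$weighted[["f1"]], digits))))
  invisible(x)
}

#' Misclassification rate of an evaluation, in percent
#'
#' @param evaluation A `gv_evaluation`.
#' @return `100 * (1 - accuracy)`.
#' @export
misclassification_pct <- function(evaluation) {
  100 * (1 - evaluation$accuracy)
}

#' Flag order/family prediction disagreements
#'
#' The order- and family-level models are trained independently; this
#' reports rows where the family call's order bin does not match the
#' order call, without enforcing consistency.
#'
#' @param order_pred,family_pred `gv_prediction` objects for the same
#'   genomes.
#' @param order_bins As in [aggregate_rare_families()].
#' @return Logical vector named by genome id, `TRUE` when the two
#'   levels disagree.
#' @export
level_disagreement <- function(order_pred, family_pred,
                               order_bins = c(
                                 Algavirales = "AG",
                                 Asfuvirales = "AF",
                                 Imitervirales = "IM",
                                 Pandoravirales = "PV",
                                 Pimascovirales = "PM"
                               )) {
  stopifnot(identical(order_pred$genome_id, family_pred$genome_id))
  ord_bin <- ifelse(order_pred$predicted_class %in% names(order_bins),
                    order_bins[order_pred$predicted_class],
                    toupper(substr(order_pred$predicted_class, 1, 2)))
  fam_bin <- sub("_.*$", "", family_pred$predicted_class)
  stats::setNames(fam_bin != unname(ord_bin), order_pred$genome_id)
}
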