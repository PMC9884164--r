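# CinC-2017-style scoring: 4x4 confusion counting and per-class
# recall / precision / F1, overall accuracy, macro F1 over N, A, O.

#' Confusion counts
#'
#' @param true_labels,pred_labels equal-length label vectors over
#'   `c("N","A","O","~")`.
#' @return 4x4 integer matrix, rows = reference class, columns = predicted
#'   class, in N, A, O, ~ order.
#' @export
af_confusion <- function(true_labels, pred_labels) {
  true_labels <- as.character(true_labels); pred_labels <- as.character(pred_labels)
  if (length(true_labels) != length(pred_labels)) stop("label lists differ in length")
  bad <- !c(true_labels, pred_labels) %in% AF_CLASSES
  if (any(bad)) stop("unknown label(s): ",
                     paste(unique(c(true_labels, pred_labels)[bad]), collapse = ", "))
  tt <- factor(true_labels, levels = AF_CLASSES)
  pp <- factor(pred_labels, levels = AF_CLASSES)
  m <- table(tt, pp)
  matrix(as.integer(m), 4, 4, dimnames = list(reference = AF_CLASSES,
                                              predicted = AF_CLASSES))
}

#' Score a confusion matrix
#'
#' Per-class recall, precision and F1 (F1 = 2 * diagonal / (reference total +
#' predicted total)), overall accuracy (trace over the reference total), the
#' macro F1 over the N, A and O classes only, and per-class one-vs-rest
#' TP/FP/TN/FN with the per-class binary accuracy. Reference totals default
#' to the row sums; they can be overridden to score a matrix against
#' externally stated class counts.
#'
#' @param counts 4x4 matrix from [af_confusion()].
#' @param reference_totals optional length-4 vector of reference class counts
#'   overriding the row sums.
#' @return list of class `af_metrics`: `per_class` data.frame (recall,
#'   precision, F1, TP, FP, FN, TN, binary_acc), `acc`, `macro_F1`,
#'   `reference_totals`, `predicted_totals`, `undefined` (classes absent from
#'   both reference and prediction).
#' @export
af_score <- function(counts, reference_totals = NULL) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(4, 4)))
  ref <- if (is.null(reference_totals)) rowSums(counts) else {
    stopifnot(length(reference_totals) == 4)
    as.numeric(reference_totals)
  }
  pred <- colSums(counts)
  dg <- diag(counts)
  undefined <- ref == 0 & pred == 0
  if (any(undefined[1:3])) {
    warning("class(es) ", paste(AF_CLASSES[1:3][undefined[1:3]], collapse = ", "),
            " absent from reference and prediction; macro F1 excludes them")
  }
  recall <- ifelse(ref > 0, dg / ref, NA_real_)
  precision <- ifelse(pred > 0, dg / pred, NA_real_)
  f1 <- ifelse(ref + pred > 0, 2 * dg / (ref + pred), NA_real_)
  total <- sum(ref)
  tp <- dg
  fp <- pred - dg
  fn <- ref - dg
  tn <- total - tp - fp - fn
  per_class <- data.frame(class = AF_CLASSES, recall = recall,
                          precision = precision, F1 = f1,
                          TP = tp, FP = fp, FN = fn, TN = tn,
                          binary_acc = (tp + tn) / total,
                          row.names = AF_CLASSES)
  macro_idx <- which(!undefined[1:3])
  structure(list(per_class = per_class,
                 acc = sum(dg) / total,
                 macro_F1 = mean(f1[macro_idx]),
                 reference_totals = ref, predicted_totals = pred,
                 undefined = AF_CLASSES[undefined]),
            class = "af_metrics")
}

#' @export
print.af_metrics <- function(x, ...) {
  cat("4-class scoring (macro F1 over N, A, O)\n")
  print(round(x$per_class[, c("recall", "precision", "F1")], 3))
  cat(sprintf("overall accuracy %.3f   macro F1 %.3f\n", x$acc, x$macro_F1))
  invisible(x)
}
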