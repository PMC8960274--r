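#' One-vs-rest AUROC (rank / Mann-Whitney form)
#'
#' The area under the ROC curve for one class against all others, computed as
#' the probability that a randomly chosen positive outranks a randomly chosen
#' negative on the positive-class score, with ties counted 1/2.
#'
#' @param true_classes label vector.
#' @param probs score vector for the positive class, or a probability matrix
#'   with one named column per class.
#' @param positive_class the class treated as positive.
#' @return AUROC in \[0, 1\].
#' @export
auroc_one_vs_rest <- function(true_classes, probs, positive_class) {
  scores <- if (is.matrix(probs)) {
    if (!positive_class %in% colnames(probs))
      stop("no probability column for class ", positive_class)
    probs[, positive_class]
  } else probs
  pos <- true_classes == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: both classes must be present after binarization")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision, recall and F1 at a fixed operating point
#'
#' One-vs-rest confusion metrics per class at a probability threshold
#' (default 50%): a sample is predicted positive for class c iff its
#' probability for c is at least the threshold, so a sample may count as
#' negative for every class. Macro values are unweighted means over classes.
#' Undefined ratios (no predicted positives, or no true positives) are scored
#' 0, the convention that penalizes degenerate classifiers.
#'
#' @param true_classes label vector.
#' @param probs probability matrix, one named column per class.
#' @param threshold operating point in (0, 1).
#' @return list with `per_class` (data frame: class, tp/fp/fn/tn, precision,
#'   recall, f1, sensitivity, specificity) and `macro` (precision, recall,
#'   f1).
#' @export
confusion_metrics <- function(true_classes, probs, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  classes <- colnames(probs)
  if (is.null(classes)) stop("probs must have named class columns")
  per <- lapply(classes, function(cl) {
    pos <- true_classes == cl
    hat <- probs[, cl] >= threshold
    tp <- sum(pos & hat); fp <- sum(!pos & hat)
    fn <- sum(pos & !hat); tn <- sum(!pos & !hat)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    specificity <- if (tn + fp > 0) tn / (tn + fp) else 0
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = precision, recall = recall, f1 = f1,
               sensitivity = recall, specificity = specificity,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_class = per,
       macro = list(precision = mean(per$precision),
                    recall = mean(per$recall),
                    f1 = mean(per$f1)))
}

#' Positive likelihood ratio
#'
#' LR+ = sensitivity / (1 - specificity): how many times more likely a
#' positive test result is in diseased than in non-diseased subjects.
#'
#' @param sensitivity,specificity probabilities in \[0, 1\].
#' @return LR+ (> 0); `Inf` with a warning when specificity is exactly 1.
#' @examples
#' positive_likelihood_ratio(0.5, 0.8)  # 2.5
#' positive_likelihood_ratio(0.8, 0.5)  # 1.6
#' @export
positive_likelihood_ratio <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0) || any(c(sensitivity, specificity) > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  if (specificity == 1) {
    warning("specificity = 1: positive likelihood ratio is infinite")
    return(Inf)
  }
  sensitivity / (1 - specificity)
}

#' McGee's post-test probability change
#'
#' McGee's log-linear approximation maps a likelihood ratio to an additive
#' change in (post-test) probability: \eqn{\Delta P \approx 0.19 \ln(LR)},
#' reported in percent and rounded to one decimal. It is exact to within a
#' few percent for pre-test probabilities between 10% and 90%.
#'
#' @param lr_positive positive likelihood ratio (> 0).
#' @return probability change in percent, one-decimal rounding.
#' @examples
#' mcgee_probability_change(2.5)  # 17.4
#' mcgee_probability_change(1.6)  # 8.9
#' @export
mcgee_probability_change <- function(lr_positive) {
  if (any(lr_positive <= 0)) stop("lr_positive must be > 0")
  round(100 * 0.19 * log(lr_positive), 1)
}

#' Evaluate cross-validated predictions
#'
#' Computes per-class one-vs-rest AUROC (pooled over all out-of-fold
#' predictions, plus mean and SD across folds), macro precision / recall / F1
#' at the 50% operating point, and — for each disease class — the positive
#' likelihood ratio at that operating point together with McGee's post-test
#' probability change.
#'
#' @param predictions a predictions table from [cross_validate]: columns
#'   `true_class`, `p_<class>` for every class, and optionally `fold`.
#' @param threshold operating point for the confusion metrics.
#' @param disease_classes classes for which LR+ / delta-P are reported;
#'   defaults to every class except `"control"` / `"HC"`.
#' @return object of class `csae_metrics`.
#' @export
evaluate_predictions <- function(predictions, threshold = 0.5,
                                 disease_classes = NULL) {
  pcols <- grep("^p_", names(predictions), value = TRUE)
  if (!length(pcols)) stop("predictions must carry p_<class> columns")
  classes <- sub("^p_", "", pcols)
  probs <- as.matrix(predictions[, pcols, drop = FALSE])
  colnames(probs) <- classes
  truth <- predictions$true_class
  if (is.null(disease_classes))
    disease_classes <- setdiff(classes, c("control", "HC"))

  auroc <- vapply(classes, function(cl) auroc_one_vs_rest(truth, probs, cl),
                  numeric(1))
  fold_tab <- NULL
  if (!is.null(predictions$fold)) {
    folds <- sort(unique(predictions$fold))
    fold_tab <- do.call(rbind, lapply(folds, function(f) {
      i <- predictions$fold == f
      vals <- vapply(classes, function(cl) {
        tryCatch(auroc_one_vs_rest(truth[i], probs[i, , drop = FALSE], cl),
                 error = function(e) NA_real_)
      }, numeric(1))
      data.frame(fold = f, class = classes, auroc = vals,
                 stringsAsFactors = FALSE)
    }))
  }
  conf <- confusion_metrics(truth, probs, threshold)
  lr <- sapply(disease_classes, function(cl) {
    row <- conf$per_class[conf$per_class$class == cl, ]
    suppressWarnings(positive_likelihood_ratio(row$sensitivity, row$specificity))
  })
  dp <- vapply(lr, function(v)
    if (is.finite(v) && v > 0) mcgee_probability_change(v) else NA_real_,
    numeric(1))

  structure(list(classes = classes,
                 auroc = auroc,
                 macro_auroc = mean(auroc),
                 auroc_by_fold = fold_tab,
                 per_class = conf$per_class,
                 macro = conf$macro,
                 lr_positive = lr,
                 delta_p = dp,
                 threshold = threshold,
                 n = nrow(predictions)),
            class = "csae_metrics")
}

#' @export
print.csae_metrics <- function(x, ...) {
  cat(sprintf("CSAE evaluation over %d out-of-fold predictions\n", x$n))
  for (cl in x$classes) {
    extra <- ""
    if (!is.null(x$auroc_by_fold)) {
      v <- x$auroc_by_fold$auroc[x$auroc_by_fold$class == cl]
      extra <- sprintf(" (fold mean %.1f%% ± %.2f)",
                       100 * mean(v, na.rm = TRUE), 100 * sd(v, na.rm = TRUE))
    }
    cat(sprintf("  AUROC %-16s %.1f%%%s\n", cl, 100 * x$auroc[cl], extra))
  }
  cat(sprintf("  macro AUROC %.1f%%; at %.0f%% threshold: precision %.1f%%, recall %.1f%%, F1 %.1f%%\n",
              100 * x$macro_auroc, 100 * x$threshold, 100 * x$macro$precision,
              100 * x$macro$recall, 100 * x$macro$f1))
  for (cl in names(x$lr_positive)) {
    cat(sprintf("  %s: LR+ %.2f -> post-test probability %+.1f%%\n",
                cl, x$lr_positive[[cl]], x$delta_p[[cl]]))
  }
  invisible(x)
}

#' Tidy serialization of a metrics report
#'
#' Flattens a [evaluate_predictions] report to a long (metric, class, fold,
#' value) table that round-trips through CSV.
#'
#' @param x a `csae_metrics` object.
#' @param row.names,optional,... standard [as.data.frame] arguments (unused).
#' @return data frame with columns `metric`, `class`, `fold`, `value`.
#' @export
as.data.frame.csae_metrics <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- list()
  add <- function(metric, class, fold, value)
    rows[[length(rows) + 1]] <<- data.frame(metric = metric, class = class,
                                            fold = fold, value = value,
                                            stringsAsFactors = FALSE)
  for (cl in x$classes) add("auroc", cl, NA_integer_, x$auroc[[cl]])
  add("macro_auroc", "all", NA_integer_, x$macro_auroc)
  if (!is.null(x$auroc_by_fold))
    for (i in seq_len(nrow(x$auroc_by_fold)))
      add("auroc", x$auroc_by_fold$class[i], x$auroc_by_fold$fold[i],
          x$auroc_by_fold$auroc[i])
  for (i in seq_len(nrow(x$per_class))) {
    cl <- x$per_class$class[i]
    for (mname in c("precision", "recall", "f1", "sensitivity", "specificity"))
      add(mname, cl, NA_integer_, x$per_class[[mname]][i])
  }
  for (mname in c("precision", "recall", "f1"))
    add(paste0("macro_", mname), "all", NA_integer_, x$macro[[mname]])
  for (cl in names(x$lr_positive)) {
    add("lr_positive", cl, NA_integer_, x$lr_positive[[cl]])
    add("delta_p", cl, NA_integer_, x$delta_p[[cl]])
  }
  do.call(rbind, rows)
}
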