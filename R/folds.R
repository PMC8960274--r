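#' Patient-level stratified k-fold splits
#'
#' Partitions *patients* (never scans) into k near-equal folds, stratified by
#' class label, so that no patient contributes scans to both the training and
#' the test side of any fold. The union of the k test sets covers every
#' patient exactly once.
#'
#' @param manifest a cohort manifest (needs `patient_id` and `class_label`
#'   columns; `class_label` must be constant within a patient). Rows labeled
#'   `"undifferentiated"` are excluded from the folds.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return list of `k` fold splits, each a list with `fold_index` (0-based),
#'   `train_patient_ids`, `test_patient_ids`.
#' @export
patient_level_folds <- function(manifest, k = 5L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  m <- manifest[manifest$class_label != "undifferentiated", , drop = FALSE]
  pat <- unique(data.frame(patient_id = m$patient_id,
                           class_label = m$class_label,
                           stringsAsFactors = FALSE))
  if (anyDuplicated(pat$patient_id))
    stop("class_label is not constant within a patient")
  if (nrow(pat) < k) stop("fewer distinct patients (", nrow(pat), ") than folds")
  counts <- table(pat$class_label)
  stratify <- all(counts >= k)
  if (!stratify)
    warning("a class has fewer patients than folds; falling back to an ",
            "unstratified patient-level split")
  assign_fold <- with_local_seed(seed, {
    fold_of <- integer(nrow(pat))
    names(fold_of) <- pat$patient_id
    if (stratify) {
      offset <- 0L
      for (cl in sort(unique(pat$class_label))) {
        ids <- sample(pat$patient_id[pat$class_label == cl])
        fold_of[ids] <- (seq_along(ids) + offset) %% k
        offset <- offset + length(ids)  # rotate start so fold sizes balance
      }
    } else {
      ids <- sample(pat$patient_id)
      fold_of[ids] <- (seq_along(ids) - 1L) %% k
    }
    fold_of
  })
  lapply(seq_len(k) - 1L, function(f) {
    test <- names(assign_fold)[assign_fold == f]
    list(fold_index = f,
         train_patient_ids = sort(setdiff(pat$patient_id, test)),
         test_patient_ids = sort(test))
  })
}

#' Inverse-frequency class weights
#'
#' Weights each class inversely proportional to its number of training scans,
#' rescaled to average 1, so that rarer classes contribute proportionally more
#' to the classification loss. Doubling all counts leaves the weights
#' unchanged.
#'
#' @param labels class labels of the *training* scans (factor or character),
#'   or a cohort manifest (its `class_label` column is used, excluding
#'   undifferentiated rows).
#' @param classes optional class set; defaults to the factor levels / sorted
#'   unique labels. Every class must be present.
#' @return named numeric weight vector with mean 1.
#' @examples
#' class_weights(rep(c("HC", "RA", "PsA"), c(173, 434, 261)))
#' @export
class_weights <- function(labels, classes = NULL) {
  if (is.data.frame(labels)) {
    labels <- labels$class_label[labels$class_label != "undifferentiated"]
  }
  if (is.factor(labels)) {
    if (is.null(classes)) classes <- levels(labels)
    labels <- as.character(labels)
  }
  if (is.null(classes)) classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  if (any(counts == 0))
    stop("class absent from the training labels: ",
         paste(classes[counts == 0], collapse = ", "))
  w <- (1 / counts) / mean(1 / counts)
  names(w) <- classes
  w
}

#' Train the CSAE on one cross-validation fold
#'
#' Fits normalization statistics and class weights on the fold's training
#' rows only, trains a [csae_fit] model, and returns out-of-fold predictions
#' for the fold's test scans.
#'
#' @param prep a [prepare_cohort] object.
#' @param fold one element of [patient_level_folds].
#' @param config a [csae_config].
#' @param representation `"mask"`, `"subregion"` or `"product"`.
#' @param epochs,batch_size,learning_rate,seed,verbose passed to [csae_fit];
#'   the fold index is folded into the seed.
#' @return list with `model` (the fitted `csae`), `stats` (the fold's
#'   normalization statistics, `NULL` for the mask representation),
#'   `fold_index`, and `predictions` (data frame: `scan_id`, `patient_id`,
#'   `true_class`, one probability column per class, `fold`).
#' @export
train_fold <- function(prep, fold, config,
                       representation = c("mask", "subregion", "product"),
                       epochs = 30L, batch_size = 4L, learning_rate = 1e-3,
                       seed = 1L, verbose = FALSE) {
  representation <- match.arg(representation)
  m <- prep$manifest
  labeled <- m$class_label != "undifferentiated"
  tr_rows <- which(labeled & m$patient_id %in% fold$train_patient_ids)
  te_rows <- which(labeled & m$patient_id %in% fold$test_patient_ids)
  if (!length(tr_rows) || !length(te_rows)) stop("fold has empty train or test set")

  train <- representation_matrix(prep, tr_rows, representation)
  test <- representation_matrix(prep, te_rows, representation, stats = train$stats)
  ytr <- factor(m$class_label[tr_rows], levels = phantom_class_levels(m))
  yte <- factor(m$class_label[te_rows], levels = levels(ytr))

  model <- csae_fit(train$x, ytr, config,
                    epochs = epochs, batch_size = batch_size,
                    learning_rate = learning_rate,
                    validation = list(x = test$x, y = yte),
                    seed = stage_seed(seed, paste0("fold", fold$fold_index)),
                    verbose = verbose)
  probs <- predict(model, test$x)
  pred <- data.frame(scan_id = m$scan_id[te_rows],
                     patient_id = m$patient_id[te_rows],
                     true_class = as.character(yte),
                     stringsAsFactors = FALSE)
  for (cl in colnames(probs)) pred[[paste0("p_", cl)]] <- probs[, cl]
  pred$fold <- fold$fold_index
  list(model = model, stats = train$stats, fold_index = fold$fold_index,
       predictions = pred)
}

phantom_class_levels <- function(manifest) {
  present <- unique(manifest$class_label[manifest$class_label != "undifferentiated"])
  known <- phantom_classes[phantom_classes %in% present]
  c(known, sort(setdiff(present, known)))
}

#' Patient-level k-fold cross-validation of the CSAE
#'
#' Runs [train_fold] over a [patient_level_folds] partition so that every
#' labeled scan receives exactly one out-of-fold prediction. Normalization
#' statistics and class weights are recomputed inside each fold from its
#' training rows only.
#'
#' @inheritParams train_fold
#' @param k number of folds.
#' @param keep_models keep the k fitted models (needed for attribution and
#'   triage downstream).
#' @return object of class `csae_cv`: list with `predictions` (one row per
#'   labeled scan), `folds`, `models` (if kept), `stats` per fold, `config`,
#'   `representation`.
#' @export
cross_validate <- function(prep, k = 5L, config,
                           representation = c("mask", "subregion", "product"),
                           epochs = 30L, batch_size = 4L, learning_rate = 1e-3,
                           seed = 1L, keep_models = TRUE, verbose = FALSE) {
  representation <- match.arg(representation)
  folds <- patient_level_folds(prep$manifest, k = k, seed = seed)
  out <- lapply(folds, function(f) {
    if (verbose) message("fold ", f$fold_index)
    train_fold(prep, f, config, representation,
               epochs = epochs, batch_size = batch_size,
               learning_rate = learning_rate, seed = seed, verbose = verbose)
  })
  pred <- do.call(rbind, lapply(out, `[[`, "predictions"))
  rownames(pred) <- NULL
  structure(list(predictions = pred, folds = folds,
                 models = if (keep_models) lapply(out, `[[`, "model"),
                 stats = lapply(out, `[[`, "stats"),
                 config = config, representation = representation,
                 k = k, seed = seed),
            class = "csae_cv")
}

#' @export
print.csae_cv <- function(x, ...) {
  cat(sprintf("<csae_cv> %d-fold patient-level CV, %s representation, %d scans\n",
              x$k, x$representation, nrow(x$predictions)))
  invisible(x)
}
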