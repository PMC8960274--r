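#' Certainty-thresholded class assignment
#'
#' Assigns the argmax class when its probability reaches the certainty
#' threshold and the sentinel `"disregarded"` otherwise. Probabilities
#' *smaller than* the threshold are disregarded, so a probability exactly
#' equal to the threshold is kept.
#'
#' @param probs probability vector on the simplex, or a matrix with one named
#'   column per class (one row per scan).
#' @param threshold certainty threshold, in (1/K, 1\] for K classes (default
#'   0.75).
#' @param classes class labels; defaults to `names(probs)` / column names.
#' @return for a vector, a single label or `"disregarded"`; for a matrix, a
#'   data frame with the probabilities, `max_prob` and `assigned`.
#' @examples
#' triage_assign(c(HC = 0.80, RA = 0.10, PsA = 0.10))          # "HC"
#' triage_assign(c(HC = 0.50, RA = 0.30, PsA = 0.20))          # "disregarded"
#' triage_assign(c(HC = 0.75, RA = 0.15, PsA = 0.10))          # boundary kept
#' @export
triage_assign <- function(probs, threshold = 0.75, classes = NULL) {
  if (is.matrix(probs) || is.data.frame(probs)) {
    probs <- as.matrix(probs)
    if (is.null(classes)) classes <- colnames(probs)
    res <- lapply(seq_len(nrow(probs)), function(i)
      triage_assign(probs[i, ], threshold, classes))
    out <- as.data.frame(probs)
    out$max_prob <- apply(probs, 1, max)
    out$assigned <- vapply(res, identity, character(1))
    return(out)
  }
  k <- length(probs)
  if (is.null(classes)) classes <- names(probs) %||% paste0("class", seq_len(k))
  if (any(probs < -1e-9) || abs(sum(probs) - 1) > 1e-6)
    stop("probs must lie on the probability simplex")
  if (threshold <= 1 / k || threshold > 1)
    stop("threshold must lie in (1/", k, ", 1] — below 1/K the rule is vacuous")
  i <- which.max(probs)
  if (probs[i] >= threshold) classes[i] else "disregarded"
}

#' Distribution of triage assignments
#'
#' Counts and percentages per class, computed with two denominators: over
#' *all* cases (the disregarded bucket is its own category, so percentages
#' sum to 100 including it) and over *retained* cases only. Headline
#' percentages are integer-rounded; exact fractions are kept alongside.
#'
#' @param assigned character vector of assignments (class labels and
#'   `"disregarded"`), e.g. the `assigned` column of [triage_assign].
#' @param classes class label set; defaults to the non-sentinel values seen.
#' @return object of class `triage_distribution`: list with `all` and
#'   `retained` data frames (`class`, `n`, `percent`, `percent_exact`),
#'   `n`, `n_retained`.
#' @export
assignment_distribution <- function(assigned, classes = NULL) {
  if (!length(assigned)) stop("no triage results")
  if (is.null(classes)) classes <- sort(setdiff(unique(assigned), "disregarded"))
  n <- length(assigned)
  tab <- function(labels, denom) {
    cnt <- vapply(labels, function(cl) sum(assigned == cl), numeric(1))
    pct <- if (denom > 0) 100 * cnt / denom else rep(NA_real_, length(cnt))
    data.frame(class = labels, n = cnt, percent = round(pct),
               percent_exact = pct, stringsAsFactors = FALSE, row.names = NULL)
  }
  retained <- assigned != "disregarded"
  structure(list(all = tab(c(classes, "disregarded"), n),
                 retained = tab(classes, sum(retained)),
                 n = n, n_retained = sum(retained)),
            class = "triage_distribution")
}

#' @export
print.triage_distribution <- function(x, ...) {
  cat(sprintf("triage of %d cases (%d retained at threshold)\n", x$n, x$n_retained))
  cat("  over all cases:      ",
      paste(sprintf("%s %d%% (N=%d)", x$all$class, x$all$percent, x$all$n),
            collapse = ", "), "\n")
  if (x$n_retained > 0)
    cat("  over retained cases: ",
        paste(sprintf("%s %d%% (N=%d)", x$retained$class, x$retained$percent,
                      x$retained$n), collapse = ", "), "\n")
  else cat("  over retained cases:  (none retained)\n")
  invisible(x)
}

#' Triage of undifferentiated scans, validated against hidden truth
#'
#' Applies certainty-thresholded triage to predicted probabilities of
#' undifferentiated scans and — because synthetic phantoms carry their hidden
#' truth in the `latent_class` sidecar — reports the fraction of retained
#' assignments that match it. This validates the triage concept itself, which
#' is unverifiable on real undifferentiated patients.
#'
#' @param predictions data frame with `p_<class>` probability columns and a
#'   `latent_class` column (see [generate_cohort]); typically the
#'   undifferentiated rows scored by [predict_cohort].
#' @param threshold certainty threshold.
#' @return list with `agreement` (fraction of retained assignments matching
#'   the latent class; `NA` if none retained), `n_retained`, `n`, `triage`
#'   (the per-scan assignment table) and `distribution`.
#' @export
triage_synthetic_validation <- function(predictions, threshold = 0.75) {
  if (is.null(predictions$latent_class))
    stop("predictions carry no latent_class sidecar column")
  pcols <- grep("^p_", names(predictions), value = TRUE)
  probs <- as.matrix(predictions[, pcols, drop = FALSE])
  colnames(probs) <- sub("^p_", "", pcols)
  tri <- triage_assign(probs, threshold)
  tri$scan_id <- predictions$scan_id
  tri$latent_class <- predictions$latent_class
  kept <- tri$assigned != "disregarded"
  agreement <- if (any(kept))
    mean(tri$assigned[kept] == tri$latent_class[kept]) else NA_real_
  list(agreement = agreement, n_retained = sum(kept), n = nrow(tri),
       triage = tri, distribution = assignment_distribution(tri$assigned,
                                                            colnames(probs)))
}

#' Score scans with the cross-validated model ensemble
#'
#' Applies every fold model to the given scans and averages the predicted
#' class probabilities — the natural way to apply "the trained network" to
#' new (e.g. undifferentiated) cases after cross-validated training. Each
#' fold's own normalization statistics are used for its model.
#'
#' @param cv a [cross_validate] result with kept models.
#' @param prep a [prepare_cohort] object.
#' @param rows which manifest rows to score (default: the undifferentiated
#'   ones).
#' @return data frame: `scan_id`, `patient_id`, `class_label`,
#'   `latent_class` (if present), `p_<class>` columns.
#' @export
predict_cohort <- function(cv, prep, rows = NULL) {
  if (is.null(cv$models)) stop("cross_validate was run with keep_models = FALSE")
  m <- prep$manifest
  if (is.null(rows)) rows <- which(m$class_label == "undifferentiated")
  if (!length(rows)) stop("no rows to score")
  acc <- 0
  for (i in seq_along(cv$models)) {
    rep_i <- representation_matrix(prep, rows, cv$representation,
                                   stats = cv$stats[[i]])
    acc <- acc + predict(cv$models[[i]], rep_i$x)
  }
  probs <- acc / length(cv$models)
  out <- data.frame(scan_id = m$scan_id[rows], patient_id = m$patient_id[rows],
                    class_label = m$class_label[rows],
                    stringsAsFactors = FALSE)
  if (!is.null(m$latent_class)) out$latent_class <- m$latent_class[rows]
  for (cl in colnames(probs)) out[[paste0("p_", cl)]] <- probs[, cl]
  out
}
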