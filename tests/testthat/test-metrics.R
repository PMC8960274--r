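test_that("one-vs-rest AUROC handles separation, ties and hand cases", {
  y <- rep(c("pos", "neg"), each = 4)
  expect_equal(auroc_one_vs_rest(y, c(rep(0.9, 4), rep(0.1, 4)), "pos"), 1.0)
  expect_equal(auroc_one_vs_rest(y, rep(0.5, 8), "pos"), 0.5)
  # 6-sample hand case with one tie, against the exhaustive pairwise oracle
  y6 <- c("pos", "pos", "pos", "neg", "neg", "neg")
  s6 <- c(0.9, 0.5, 0.3, 0.5, 0.2, 0.1)
  expect_equal(auroc_one_vs_rest(y6, s6, "pos"), ref_auroc(y6, s6, "pos"))
  expect_equal(auroc_one_vs_rest(y6, s6, "pos"), (3 + 0.5 + 2 + 2) / 9)
  expect_error(auroc_one_vs_rest(rep("pos", 5), runif(5), "pos"), "both classes")
})

test_that("rank AUROC equals the brute-force oracle on random batteries", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    y <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.125), n, replace = TRUE)  # discrete -> many ties
    expect_equal(auroc_one_vs_rest(y, s, "a"), ref_auroc(y, s, "a"),
                 tolerance = 1e-12)
    # invariance under strictly monotone transforms of the scores
    expect_equal(auroc_one_vs_rest(y, exp(3 * s) - 1, "a"),
                 auroc_one_vs_rest(y, s, "a"), tolerance = 1e-12)
  }
})

test_that("confusion metrics at the 50% operating point match arithmetic", {
  classes <- c("HC", "RA", "PsA")
  onehot <- function(i) { p <- rep(0.05, 3); p[i] <- 0.9; p }
  # perfect predictions
  y <- rep(classes, 3)
  probs <- t(vapply(rep(1:3, 3), onehot, numeric(3)))
  colnames(probs) <- classes
  cm <- confusion_metrics(y, probs, 0.5)
  expect_true(all(cm$per_class$precision == 1) && all(cm$per_class$recall == 1))
  expect_equal(cm$macro$f1, 1)

  # everything predicted RA: RA recall 1, others 0
  probs1 <- matrix(rep(onehot(2), 9), ncol = 3, byrow = TRUE,
                   dimnames = list(NULL, classes))
  cm1 <- confusion_metrics(y, probs1, 0.5)
  expect_equal(cm1$per_class$recall, c(0, 1, 0))

  # 9-sample hand-built table: truth (3,3,3); predictions HC->HC x2, HC->RA,
  # RA->RA x3, PsA->RA, PsA->PsA x2
  yh <- rep(classes, each = 3)
  ph <- rbind(onehot(1), onehot(1), onehot(2),
              onehot(2), onehot(2), onehot(2),
              onehot(2), onehot(3), onehot(3))
  colnames(ph) <- classes
  cmh <- confusion_metrics(yh, ph, 0.5)
  hc <- cmh$per_class[cmh$per_class$class == "HC", ]
  ra <- cmh$per_class[cmh$per_class$class == "RA", ]
  psa <- cmh$per_class[cmh$per_class$class == "PsA", ]
  expect_equal(hc$precision, 1); expect_equal(hc$recall, 2 / 3)
  expect_equal(ra$precision, 3 / 5); expect_equal(ra$recall, 1)
  expect_equal(psa$precision, 1); expect_equal(psa$recall, 2 / 3)
  expect_equal(cmh$macro$f1, mean(c(2 * (2 / 3) / (5 / 3),
                                    2 * (3 / 5) / (8 / 5),
                                    2 * (2 / 3) / (5 / 3))))
  # macro-F1 bounded by the per-class extremes
  expect_lte(cmh$macro$f1, max(cmh$per_class$f1))
  expect_gte(cmh$macro$f1, min(cmh$per_class$f1))
})

test_that("positive likelihood ratios and McGee's interpretation", {
  expect_equal(positive_likelihood_ratio(0.5, 0.8), 2.5)
  expect_equal(positive_likelihood_ratio(0.8, 0.5), 1.6)
  expect_equal(positive_likelihood_ratio(0.3, 0.7), 1.0)  # uninformative
  expect_warning(lr <- positive_likelihood_ratio(0.9, 1), "infinite")
  expect_identical(lr, Inf)
  expect_equal(mcgee_probability_change(2.5), 17.4)
  expect_equal(mcgee_probability_change(1.6), 8.9)
  expect_equal(mcgee_probability_change(1.0), 0.0)
  # monotone increasing in LR+ and zero at 1
  lrs <- c(0.5, 1, 1.5, 2.5, 4, 10)
  expect_true(all(diff(mcgee_probability_change(lrs)) > 0))
  expect_error(mcgee_probability_change(0), "> 0")
})

test_that("evaluate_predictions summarizes, nulls out, and round-trips", {
  classes <- c("control", "erosive", "proliferative")
  set.seed(4)
  n <- 100
  truth <- sample(classes, n, replace = TRUE)
  perfect <- t(vapply(match(truth, classes), function(i) {
    p <- rep(0.01, 3); p[i] <- 0.98; p
  }, numeric(3)))
  pred <- data.frame(scan_id = seq_len(n), true_class = truth,
                     fold = rep(0:4, each = 20))
  for (j in 1:3) pred[[paste0("p_", classes[j])]] <- perfect[, j]
  met <- evaluate_predictions(pred)
  expect_true(all(met$auroc == 1))
  expect_equal(met$macro$f1, 1)
  expect_true(all(is.finite(unlist(met$lr_positive)) |
                  unlist(met$lr_positive) == Inf))

  # label-shuffled null: macro AUROC near 0.5
  null <- pred
  null$true_class <- sample(truth)
  met0 <- evaluate_predictions(null)
  expect_lt(abs(met0$macro_auroc - 0.5), 0.12)

  # tidy table round-trips through CSV
  tab <- as.data.frame(met)
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read.csv(f)
  expect_equal(back$value, tab$value, tolerance = 1e-12)
  expect_identical(back$metric, tab$metric)
})
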