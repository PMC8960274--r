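test_that("patient-level folds partition patients without overlap", {
  m <- generate_cohort(10, rep(1 / 3, 3), 0.4, tiny_params(), seed = 3)
  folds <- suppressWarnings(patient_level_folds(m, k = 5, seed = 1))
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f$test_patient_ids, 2)                    # 10 patients / 5
    expect_length(intersect(f$train_patient_ids, f$test_patient_ids), 0)
  }
  # union of test sets covers every patient exactly once
  all_test <- unlist(lapply(folds, `[[`, "test_patient_ids"))
  expect_identical(sort(all_test), sort(unique(m$patient_id)))
  # all scans of a patient stay on one side of every fold
  pat_with_repeats <- names(which(table(m$patient_id) > 1))
  for (p in pat_with_repeats) for (f in folds) {
    expect_true(p %in% f$train_patient_ids || p %in% f$test_patient_ids)
  }
  expect_error(patient_level_folds(m, k = 11), "fewer distinct patients")
  expect_warning(patient_level_folds(m, k = 4, seed = 1), "fewer patients than folds")
})

test_that("class weights are inverse-frequency with mean one", {
  expect_equal(unname(class_weights(rep(c("a", "b", "c"), each = 100))),
               c(1, 1, 1))
  # hand-derived from scan counts 173 / 434 / 261: weights proportional to
  # (1/173, 1/434, 1/261) rescaled to average 1
  w <- class_weights(rep(c("HC", "RA", "PsA"), c(173, 434, 261)),
                     classes = c("HC", "RA", "PsA"))
  expect_equal(unname(w), c(1.4553, 0.5801, 0.9646), tolerance = 1e-3)
  expect_equal(mean(w), 1)
  # scale invariance: doubling all counts changes nothing
  w2 <- class_weights(rep(c("HC", "RA", "PsA"), 2 * c(173, 434, 261)),
                      classes = c("HC", "RA", "PsA"))
  expect_equal(w, w2)
  expect_error(class_weights(c("a", "a", "b"), classes = c("a", "b", "c")),
               "absent.*c")
})

make_fake_prep <- function(n_patients = 9, seed = 1, extent = c(8, 8, 4)) {
  # synthetic prepared cohort without disk I/O, for split/leakage tests;
  # classes are balanced across patients so every fold sees every class
  m <- generate_cohort(n_patients, rep(1 / 3, 3), 0.2, tiny_params(), seed = seed)
  pat <- unique(m$patient_id)
  cls <- rep(c("control", "erosive", "proliferative"), length.out = length(pat))
  m$class_label <- cls[match(m$patient_id, pat)]
  m$latent_class <- m$class_label
  V <- prod(extent)
  set.seed(seed + 1000)
  cls <- match(m$class_label, c("control", "erosive", "proliferative"))
  sub <- matrix(rnorm(V * nrow(m), mean = cls), V, nrow(m))
  msk <- matrix(rbinom(V * nrow(m), 1, 0.3 + 0.2 * (cls - 1) / 2), V, nrow(m))
  structure(list(sub = sub, mask = msk, lesion = matrix(0, V, nrow(m)),
                 extent = extent, manifest = m),
            class = "prepared_cohort")
}

test_that("fold training is leakage-free: test rows cannot move the stats", {
  prep <- make_fake_prep(12, seed = 5)
  folds <- patient_level_folds(prep$manifest, k = 3, seed = 2)
  f <- folds[[1]]
  tr <- which(prep$manifest$patient_id %in% f$train_patient_ids)
  st1 <- csae:::representation_matrix(prep, tr, "subregion")$stats
  # perturb every held-out scan wildly
  prep2 <- prep
  te <- which(prep$manifest$patient_id %in% f$test_patient_ids)
  prep2$sub[, te] <- prep2$sub[, te] * 100 + 50
  st2 <- csae:::representation_matrix(prep2, tr, "subregion")$stats
  expect_identical(st1, st2)
  cw1 <- class_weights(prep$manifest$class_label[tr])
  cw2 <- class_weights(prep2$manifest$class_label[tr])
  expect_identical(cw1, cw2)
})

test_that("train_fold bookkeeping and determinism hold on a small cohort", {
  prep <- make_fake_prep(9, seed = 7)
  folds <- patient_level_folds(prep$manifest, k = 3, seed = 1)
  cfg <- tiny_config(c(8, 8, 4), c(3L, 6L), dropout = 0.1)
  out <- train_fold(prep, folds[[1]], cfg, "subregion",
                    epochs = 2, batch_size = 2, seed = 11)
  h <- out$model$history
  # 2 epochs x (train + validation) x 3 loss series
  expect_identical(nrow(h), 2L)
  expect_true(all(is.finite(as.matrix(
    h[, c("train_reconstruction", "train_classification", "train_total",
          "val_reconstruction", "val_classification", "val_total")]))))
  out2 <- train_fold(prep, folds[[1]], cfg, "subregion",
                     epochs = 2, batch_size = 2, seed = 11)
  expect_identical(out$model$history$train_total, out2$model$history$train_total)
  expect_identical(out$predictions, out2$predictions)
  # training loss decreases over a longer run (fixed seed smoke test)
  out3 <- train_fold(prep, folds[[1]], cfg, "subregion",
                     epochs = 8, batch_size = 2, seed = 11)
  h3 <- out3$model$history
  expect_lt(h3$train_total[8], h3$train_total[1])
})

test_that("cross-validation scores every labeled scan exactly once", {
  prep <- make_fake_prep(9, seed = 3)
  cfg <- tiny_config(c(8, 8, 4), c(3L, 6L), dropout = 0.1)
  cv <- cross_validate(prep, k = 3, cfg, "mask", epochs = 2, batch_size = 2,
                       seed = 2)
  pred <- cv$predictions
  labeled <- prep$manifest$scan_id[prep$manifest$class_label != "undifferentiated"]
  expect_identical(sort(pred$scan_id), sort(labeled))
  # fold index matches the fold whose test set holds the scan's patient
  for (i in seq_len(nrow(pred))) {
    f <- cv$folds[[pred$fold[i] + 1]]
    expect_true(pred$patient_id[i] %in% f$test_patient_ids)
  }
  pcols <- grep("^p_", names(pred))
  expect_true(all(abs(rowSums(pred[, pcols]) - 1) < 1e-6))
})
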