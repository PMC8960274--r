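test_that("configuration invariants are enforced", {
  expect_error(csae_config(c(24, 24, 15), 3, c(8L, 16L, 32L)), "divisible")
  expect_error(csae_config(c(16, 16, 8), 3, c(8L, 16L)), "equal n_stages")
  expect_error(csae_config(c(16, 16, 8), 3, c(8L, 8L, 16L)), "increasing")
  expect_error(csae_config(c(16, 16, 8), 2, c(8L, 16L), lambda_weight = 1.2),
               "lambda")
  # four pooling-free... three pools halve each axis three times
  cfg <- csae_config(c(64, 64, 32), 4, c(8L, 16L, 32L, 64L))
  expect_equal(cfg$target_extent %/% 2^(cfg$n_stages - 1), c(8, 8, 4))
  # parameter count strictly increases with channel width
  cfg2 <- csae_config(c(64, 64, 32), 4, 2L * c(8L, 16L, 32L, 64L))
  expect_gt(csae_n_parameters(cfg2), csae_n_parameters(cfg))
})

test_that("the compiled forward pass matches an independent R implementation", {
  for (spec in list(list(extent = c(8, 8, 4), ch = c(3L, 5L)),
                    list(extent = c(8, 4, 8), ch = c(2L, 4L, 6L)),
                    list(extent = c(4, 4, 4), ch = 4L))) {
    cfg <- tiny_config(spec$extent, spec$ch)
    w <- csae:::init_csae_weights(cfg, seed = 31)
    set.seed(31)
    x <- rnorm(prod(cfg$target_extent))
    ref <- ref_forward(w, cfg, x)
    got <- csae:::cpp_csae_forward(matrix(x), w, unclass(cfg), TRUE)
    expect_equal(as.numeric(got$logits), ref$logits, tolerance = 1e-5)
    expect_equal(as.numeric(got$probs), ref$probs, tolerance = 1e-5)
    expect_equal(as.numeric(got$recon), ref$recon, tolerance = 1e-4)
    # reconstruction extent equals input extent (mirrored decoder contract)
    expect_identical(length(got$recon), length(x))
  }
})

test_that("evaluation-mode forward is deterministic and batch-independent", {
  cfg <- tiny_config(c(8, 8, 4), c(3L, 5L), dropout = 0.2)
  w <- csae:::init_csae_weights(cfg, seed = 5)
  set.seed(5)
  X <- matrix(rnorm(prod(cfg$target_extent) * 4), ncol = 4)
  a <- csae:::cpp_csae_forward(X, w, unclass(cfg), FALSE)
  b <- csae:::cpp_csae_forward(X, w, unclass(cfg), FALSE)
  expect_identical(a$probs, b$probs)
  expect_true(all(abs(rowSums(a$probs) - 1) < 1e-6))
  perm <- c(3, 1, 4, 2)
  p <- csae:::cpp_csae_forward(X[, perm], w, unclass(cfg), FALSE)
  expect_equal(p$probs, a$probs[perm, ], tolerance = 1e-12)
})

test_that("network gradients agree with finite differences of the R oracle", {
  cfg <- tiny_config(c(8, 8, 4), c(3L, 5L))
  w <- csae:::init_csae_weights(cfg, seed = 9)
  set.seed(42)
  x <- rnorm(prod(cfg$target_extent))
  lam <- 0.7; cw <- c(1.2, 0.8, 1.0); ycls <- 2L
  loss_ref <- function(w) {
    f <- ref_forward(w, cfg, x)
    (1 - lam) * mean((x - f$recon)^2) + lam * (-cw[ycls] * log(f$probs[ycls]))
  }
  lg <- csae:::cpp_csae_loss_grad(x, ycls, w, unclass(cfg), lam, cw)
  expect_equal(lg$total, loss_ref(w), tolerance = 1e-5)
  h <- 1e-5
  set.seed(1)
  for (i in seq_along(w$conv)) {
    idx <- sample(length(w$conv[[i]]$W), 2)
    for (j in idx) {
      wp <- w; wm <- w
      wp$conv[[i]]$W[j] <- wp$conv[[i]]$W[j] + h
      wm$conv[[i]]$W[j] <- wm$conv[[i]]$W[j] - h
      fd <- (loss_ref(wp) - loss_ref(wm)) / (2 * h)
      expect_equal(lg$grads$conv[[i]]$W[j], fd, tolerance = 2e-3)
    }
  }
})

test_that("combined loss reproduces hand-computed values", {
  # pure reconstruction: unit offset everywhere -> MSE 1
  l0 <- combined_loss(x = c(2, 3, 4), x_hat = c(3, 4, 5), y = c(1, 0, 0),
                      y_prob = c(0.2, 0.5, 0.3), lambda_weight = 0)
  expect_equal(l0$total, 1.0)
  # pure classification, perfect prediction -> 0
  l1 <- combined_loss(0, 0, y = c(0, 1, 0), y_prob = c(0, 1, 0),
                      lambda_weight = 1)
  expect_equal(l1$total, 0)
  # hand-computed mixed case
  lh <- combined_loss(x = c(0, 0), x_hat = c(1, 0), y = c(1, 0, 0),
                      y_prob = c(0.5, 0.25, 0.25), lambda_weight = 0.5)
  expect_equal(lh$reconstruction_term, 0.5)
  expect_equal(lh$classification_term, -log(0.5))
  expect_equal(lh$total, 0.5966, tolerance = 1e-4)
  expect_equal(lh$total,
               (1 - 0.5) * lh$reconstruction_term + 0.5 * lh$classification_term,
               tolerance = 1e-9)
  expect_error(combined_loss(0, 0, c(1, 0, 0), c(0.5, 0.25, 0.25), 1.5), "0, 1")
  expect_error(combined_loss(0, 0, c(1, 1, 0), c(0.5, 0.25, 0.25), 0.5), "one-hot")
  expect_message(combined_loss(0, 0, c(1, 0, 0), c(0, 0.5, 0.5), 1), "clamped")
})

test_that("combined-loss gradients pass a finite-difference check", {
  set.seed(13)
  x <- rnorm(20); xh <- rnorm(20)
  y <- c(0, 0, 1); yp <- c(0.2, 0.3, 0.5); cw <- c(1.3, 0.9, 0.8)
  g <- combined_loss_grad(x, xh, y, yp, 0.6, cw)
  h <- 1e-6
  for (i in c(1, 7, 20)) {
    xp <- xh; xm <- xh; xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    fd <- (combined_loss(x, xp, y, yp, 0.6, cw)$total -
           combined_loss(x, xm, y, yp, 0.6, cw)$total) / (2 * h)
    expect_equal(g$d_x_hat[i], fd, tolerance = 1e-4)
  }
  # gradient w.r.t. the true-class probability (raw partial)
  ypp <- yp; ypm <- yp
  ypp[3] <- yp[3] + h; ypm[3] <- yp[3] - h
  fd <- (-0.6 * cw[3] * log(ypp[3]) + 0.6 * cw[3] * log(ypm[3])) / (2 * h)
  expect_equal(g$d_y_prob[3], fd, tolerance = 1e-4)
  expect_identical(g$d_y_prob[1], 0)
})

test_that("training is reproducible and can overfit a fixed batch", {
  cfg <- tiny_config(c(16, 16, 8), c(4L, 8L), dropout = 0.1, lambda = 0.9)
  set.seed(77)
  n <- 8
  X <- matrix(rnorm(prod(cfg$target_extent) * n), ncol = n)
  y <- factor(rep(c("control", "erosive", "proliferative"), length.out = n))
  f1 <- csae_fit(X, y, cfg, epochs = 5, batch_size = 4, seed = 3)
  f2 <- csae_fit(X, y, cfg, epochs = 5, batch_size = 4, seed = 3)
  expect_identical(f1$history$train_total, f2$history$train_total)
  f3 <- csae_fit(X, y, cfg, epochs = 5, batch_size = 4, seed = 4)
  expect_false(identical(f1$history$train_total, f3$history$train_total))

  # training-capability smoke test: 200 full-batch steps drive the combined
  # loss below 10% of its starting value
  fo <- csae_fit(X, y, cfg, epochs = 200, batch_size = n, seed = 1)
  expect_lt(fo$history$train_total[200], 0.10 * fo$history$train_total[1])
})

test_that("the fitted model exposes the usual S3 surface", {
  cfg <- tiny_config(c(8, 8, 4), c(3L, 5L), dropout = 0)
  set.seed(2)
  X <- matrix(rnorm(prod(cfg$target_extent) * 6), ncol = 6)
  y <- factor(rep(c("a", "b", "c"), 2))
  fit <- csae_fit(X, y, cfg, epochs = 2, batch_size = 2, seed = 1)
  expect_s3_class(fit, "csae")
  expect_output(print(fit), "auto-encoder")
  expect_output(print(summary(fit)), "parameters")
  pr <- predict(fit, X)
  expect_identical(dim(pr), c(6L, 3L))
  expect_identical(colnames(pr), c("a", "b", "c"))
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  cl <- predict(fit, X, type = "class")
  expect_s3_class(cl, "factor")
  res <- residuals(fit, X)
  expect_identical(dim(res), dim(X))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
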