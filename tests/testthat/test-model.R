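test_that("hyperparameter validation enforces the architecture's constraints", {
  expect_error(tiny_hp(W = 4L), "odd")
  expect_error(tiny_hp(N_h = 7L), "even")
  expect_error(tiny_hp(T = 2L, W = 3L), "at least the window")
  expect_error(tiny_hp(N_y = 1L), "at least 2")
})

test_that("forward pass has the stated shapes and softmax contracts", {
  hp <- tiny_hp(T = 100L, N_y = 5L)
  m <- build_model(hp)
  x <- encode_reads(random_reads(3, 100, seed = 2), 100)
  pr <- predict_reads(m, x, return_hidden = TRUE)
  expect_equal(dim(pr$attention), c(3, 100))
  expect_equal(dim(pr$scores), c(3, 5))
  expect_equal(dim(pr$embedding), c(3, hp$N_h))
  expect_equal(dim(pr$hidden[[1]]), c(100, hp$N_h))
  expect_true(all(pr$attention >= 0))
  expect_equal(rowSums(pr$attention), rep(1, 3), tolerance = 1e-5)
  expect_equal(rowSums(pr$scores), rep(1, 3), tolerance = 1e-5)
})

test_that("embedding equals the attention-weighted sum of hidden states", {
  hp <- tiny_hp()
  m <- build_model(hp)
  x <- encode_reads(random_reads(5, hp$T, seed = 3), hp$T)
  pr <- predict_reads(m, x, return_hidden = TRUE)
  for (i in 1:5) {
    recomputed <- colSums(pr$attention[i, ] * pr$hidden[[i]])
    expect_lt(max(abs(recomputed - pr$embedding[i, ])), 1e-4)
  }
})

test_that("analytic gradients match central finite differences", {
  hp <- tiny_hp(T = 12L, N_c = 6L)
  m <- build_model(hp)
  set.seed(21)
  x <- encode_reads(random_reads(4, 12, seed = 21), 12)
  y <- c(1L, 2L, 3L, 1L)
  fw <- ampatt:::.forward; bw <- ampatt:::.backward
  loss_of <- function(params) {
    out <- fw(params, m$bn_state, hp, x, training = TRUE)
    ampatt:::.loss_accuracy(out$scores, y)[["loss"]]
  }
  out <- fw(m$params, m$bn_state, hp, x, training = TRUE, keep_cache = TRUE)
  g <- bw(m$params, hp, out$cache, y)
  eps <- 1e-5
  for (k in names(m$params)) {
    idx <- sample(length(m$params[[k]]), min(4L, length(m$params[[k]])))
    for (i in idx) {
      p1 <- m$params; p1[[k]][i] <- p1[[k]][i] + eps
      p2 <- m$params; p2[[k]][i] <- p2[[k]][i] - eps
      num <- (loss_of(p1) - loss_of(p2)) / (2 * eps)
      expect_equal(g[[k]][i], num, tolerance = 1e-4,
                   label = sprintf("d loss / d %s[%d]", k, i))
    }
  }
})

test_that("prediction is deterministic and batching-invariant", {
  hp <- tiny_hp()
  m <- build_model(hp)
  seqs <- random_reads(7, hp$T, seed = 6)
  x <- encode_reads(c(seqs, seqs[1]), hp$T)  # read 1 submitted twice
  pr_all <- predict_reads(m, x, batch_size = 8L)
  pr_one <- predict_reads(m, x, batch_size = 1L)
  expect_equal(pr_all$scores, pr_one$scores, tolerance = 1e-5)
  expect_equal(pr_all$attention, pr_one$attention, tolerance = 1e-5)
  expect_identical(pr_all$scores[1, ], pr_all$scores[8, ])
  expect_error(predict_reads(m, encode_reads(seqs, hp$T + 5L)), "match")
})

test_that("training contracts: class count, epochs = 0, loss naming", {
  hp <- tiny_hp(N_y = 2L)
  m <- build_model(hp)
  x <- encode_reads(random_reads(20, hp$T, seed = 8), hp$T)
  labels <- rep(c("a", "b"), 10)
  expect_error(train_model(m, x, rep("a", 20)), "2 classes")
  m0 <- train_model(m, x, labels, epochs = 0)
  expect_equal(nrow(m0$training_log), 0L)
  expect_identical(m0$params, m$params)
  m1 <- train_model(m, x, labels, epochs = 1)
  expect_identical(attr(m1$training_log, "loss_name"), "binary cross-entropy")
  hp3 <- tiny_hp(N_y = 3L)
  m3 <- train_model(build_model(hp3), x, rep(c("a", "b", "c"), length.out = 20),
                    epochs = 1)
  expect_identical(attr(m3$training_log, "loss_name"),
                   "categorical cross-entropy")
})

test_that("same seed and inputs reproduce the training loss sequence", {
  ds <- tiny_planted(60)
  hp <- tiny_hp(T = 30L, N_y = 2L, epochs = 2L, seed = 13L)
  x <- encode_reads(ds$reads$sequence, 30)
  m1 <- train_model(build_model(hp), x, ds$ground_truth$class)
  m2 <- train_model(build_model(hp), x, ds$ground_truth$class)
  expect_identical(m1$training_log$loss, m2$training_log$loss)
  expect_identical(m1$params, m2$params)
})

test_that("a separable planted problem is learned quickly", {
  ds <- tiny_planted(150)
  hp <- tiny_hp(T = 30L, N_y = 2L, N_c = 16L, N_h = 16L, epochs = 3L,
                batch_size = 32L, seed = 17L)
  x <- encode_reads(ds$reads$sequence, 30)
  m <- train_model(build_model(hp), x, ds$ground_truth$class)
  final <- m$training_log[nrow(m$training_log), ]
  expect_gt(final$accuracy, 0.95)
})

test_that("checkpoints round-trip through save_model / load_model", {
  hp <- tiny_hp()
  m <- build_model(hp, class_names = c("x", "y", "z"))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$class_names, m$class_names)
  x <- encode_reads(random_reads(2, hp$T, seed = 30), hp$T)
  expect_identical(predict_reads(m, x)$scores, predict_reads(m2, x)$scores)
})

test_that("bucketed prediction handles mixed lengths and preserves input order", {
  hp <- tiny_hp(T = 24L)
  m <- build_model(hp, class_names = c("x", "y", "z"))
  seqs <- c(random_reads(2, 17, seed = 40), random_reads(2, 24, seed = 41),
            random_reads(1, 9, seed = 42))
  buckets <- bucket_by_length(seqs, 12)
  pr <- predict_reads(m, buckets)
  expect_equal(dim(pr$scores), c(5, 3))
  expect_equal(rowSums(pr$scores), rep(1, 5), tolerance = 1e-5)
  # attention lengths follow each read's padded bucket length
  expect_equal(lengths(pr$attention), c(24, 24, 24, 24, 12))
  expect_equal(vapply(pr$attention, sum, 0), rep(1, 5), tolerance = 1e-5)
  # rows line up with the original input order: the 24-length bucket rows
  # must equal a direct array prediction of those same reads
  direct <- predict_reads(m, encode_reads(seqs[3:4], 24))
  expect_equal(pr$scores[3:4, ], direct$scores, tolerance = 1e-10)
})
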