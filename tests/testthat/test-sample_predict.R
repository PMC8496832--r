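test_that("the 1/N read caller votes for every class above chance", {
  # worked three-body-site example: 0.51 and 0.43 both exceed 1/3
  v <- majority_vote(rbind(c(0.51, 0.43, 0.06)), c("gut", "skin", "oral"))
  expect_identical(v$votes, c(1L, 1L, 0L))
  expect_equal(v$threshold, 1 / 3)
  expect_identical(v$predicted_label, "gut")
  # two-class threshold is 0.5
  v2 <- majority_vote(matrix(rep(c(0.9, 0.1), 10), ncol = 2, byrow = TRUE),
                      c("cd", "not_ibd"))
  expect_equal(v2$threshold, 0.5)
  expect_identical(v2$votes, c(10L, 0L))
  expect_identical(v2$predicted_label, "cd")
})

test_that("uniform scores fall back to a single argmax vote; ties break by name", {
  v <- majority_vote(rbind(rep(1 / 3, 3)), c("b_class", "a_class", "c_class"))
  expect_identical(sum(v$votes), 1L)
  # argmax fallback is position 1 ("b_class"); it wins the tally
  expect_identical(v$predicted_label, "b_class")
  # tied tallies resolve alphabetically
  v2 <- majority_vote(rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0)),
                      c("zeta", "alpha", "omega"))
  expect_identical(v2$votes, c(2L, 2L, 0L))
  expect_identical(v2$predicted_label, "alpha")
  expect_error(majority_vote(matrix(0, 0, 3), c("a", "b", "c")), "no reads")
})

test_that("vote conservation: each read casts between 1 and N votes", {
  set.seed(12)
  for (rep_i in 1:20) {
    N <- sample(2:5, 1)
    p <- stats::rgamma(N, 1); p <- p / sum(p)
    v <- majority_vote(rbind(p), paste0("c", seq_len(N)))
    expect_gte(sum(v$votes), 1L)
    expect_lte(sum(v$votes), N)
    # exactly one class strictly above 1/N -> exactly one vote
    if (sum(p > 1 / N) == 1L) expect_identical(sum(v$votes), 1L)
  }
})

test_that("average_embedding is the arithmetic mean and permutation-invariant", {
  expect_equal(average_embedding(rbind(c(0, 2), c(2, 0)))$vector, c(1, 1))
  e <- matrix(rnorm(12), 4)
  expect_equal(average_embedding(e)$vector, colMeans(e))
  expect_equal(average_embedding(e[c(3, 1, 4, 2), ])$vector,
               average_embedding(e)$vector)
  single <- rbind(c(0.3, -1, 2))
  expect_equal(average_embedding(single)$vector, drop(single))
  expect_error(average_embedding(matrix(0, 0, 3)), "no read")
})

test_that("pseudo-OTU clustering recovers well-separated blobs deterministically", {
  set.seed(31)
  centers <- rbind(c(0, 0), c(50, 0), c(0, 50))
  blob <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(80, sd = 0.5), ncol = 2), 2, centers[i, ], "+")))
  truth <- rep(1:3, each = 40)
  ctr <- pseudo_otu_fit(blob, k = 3, seed = 5)
  asg <- ampatt:::.assign_clusters(blob, ctr)
  # homogeneity 1.0: every cluster holds exactly one blob label
  expect_true(all(tapply(truth, asg, function(z) length(unique(z))) == 1))
  expect_identical(pseudo_otu_fit(blob, k = 3, seed = 5), ctr)
  # k = 1 is the global mean
  expect_equal(unname(drop(pseudo_otu_fit(blob, k = 1, seed = 5))),
               colMeans(blob), tolerance = 1e-8)
  expect_error(pseudo_otu_fit(blob[1:2, ], k = 3), "lower k")
})

test_that("nearest-centroid assignment agrees with exhaustive search", {
  set.seed(32)
  x <- matrix(rnorm(100 * 5), 100)
  ctr <- matrix(rnorm(10 * 5), 10)
  fast <- ampatt:::.assign_clusters(x, ctr)
  brute <- apply(x, 1, function(row)
    which.min(colSums((t(ctr) - row)^2)))
  expect_identical(fast, unname(brute))
})

test_that("pseudo-OTU tables count, normalize and retain empty clusters", {
  ctr <- rbind(c(0, 0), c(10, 0), c(20, 0))
  emb <- list(s1 = matrix(c(10.1, 9.9, 10.2, 9.8, 0, 0, 0, 0), ncol = 2),
              s2 = rbind(c(0.1, 0)))
  tab <- pseudo_otu_table(emb, ctr)
  expect_identical(unname(tab$counts["s1", ]), c(0L, 4L, 0L))
  expect_equal(unname(tab$relabund["s1", ]), c(0, 1, 0))
  expect_equal(rowSums(tab$relabund), c(s1 = 1, s2 = 1))
  expect_identical(ncol(tab$counts), 3L)  # empty cluster 3 kept as a column
  # zero-read sample: zero counts, NA relabund, flagged
  expect_warning(tab2 <- pseudo_otu_table(c(emb, list(s3 = NULL)), ctr), "s3")
  expect_identical(unname(tab2$counts["s3", ]), c(0L, 0L, 0L))
  expect_true(all(is.na(tab2$relabund["s3", ])))
  expect_identical(tab2$empty_samples, "s3")
})

test_that("random forest sample classifier separates blobs and is seeded", {
  set.seed(33)
  feat <- rbind(matrix(rnorm(60, 0), ncol = 3), matrix(rnorm(60, 4), ncol = 3))
  labs <- rep(c("a", "b"), each = 20)
  rf <- fit_sample_classifier(feat, labs, seed = 3)
  expect_gte(mean(predict_samples(rf, feat) == labs), 0.95)
  rf2 <- fit_sample_classifier(feat, labs, seed = 3)
  expect_identical(predict_samples(rf2, feat), predict_samples(rf, feat))
  expect_error(predict_samples(rf, feat[, 1:2]), "dimension")
  expect_error(fit_sample_classifier(feat, rep("a", 40)), "2 classes")
})

test_that("k-mer tables count overlapping windows in lexicographic order", {
  tab <- kmer_table(list(s1 = "AAAA"), k = 3)
  expect_equal(unname(tab[1, "AAA"]), 1)
  expect_equal(sum(tab), 1)
  expect_identical(colnames(tab)[1:5], c("AAA", "AAC", "AAG", "AAT", "ACA"))
  # window-count identity: a read of length L gives L - k + 1 counts
  set.seed(34)
  reads <- random_reads(5, 30, seed = 34)
  tabs <- kmer_table(list(s = reads), k = 4)
  expect_equal(rowSums(tabs), c(s = 1))  # row-normalized
  # independent dictionary counting oracle
  brute <- new.env()
  for (r in reads) for (i in 1:(nchar(r) - 3)) {
    km <- substr(r, i, i + 3)
    assign(km, (if (exists(km, brute)) get(km, brute) else 0) + 1, brute)
  }
  total <- sum(unlist(as.list(brute)))
  expect_equal(total, 5 * (30 - 4 + 1))
  for (km in ls(brute))
    expect_equal(unname(tabs[1, km]), get(km, brute) / total)
  # all-short sample: zero row with a warning
  expect_warning(z <- kmer_table(list(s = "ACG"), k = 9), "zero row")
  expect_equal(sum(z), 0)
})
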