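test_that("entropy profile hits the closed-form anchor cases", {
  # uniform 4-way column: 2 bits; constant column: 0 bits
  ep <- entropy_profile(c("AA", "CA", "GA", "TA"))
  expect_equal(ep$H, c(2, 0))
  # two equal bases: 1 bit
  ep2 <- entropy_profile(c("A", "A", "C", "C"))
  expect_equal(ep2$H, 1)
  expect_equal(rowSums(ep$freqs), c(1, 1))
  expect_error(entropy_profile(c("AC", "ACG")), "same length")
})

test_that("entropy matches a brute-force evaluator on random columns", {
  set.seed(41)
  seqs <- random_reads(50, 40, seed = 41)
  ep <- entropy_profile(seqs)
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (l in seq_len(40)) {
    p <- table(factor(chars[, l], levels = c("A", "C", "G", "T"))) / 50
    h <- 0
    for (b in c("A", "C", "G", "T")) if (p[[b]] > 0) h <- h - p[[b]] * log2(p[[b]])
    expect_equal(ep$H[l], h, tolerance = 1e-12)
  }
  expect_true(all(ep$H >= 0 & ep$H <= 2))
})

test_that("positions with non-ACGT characters renormalize over observed bases", {
  ep <- entropy_profile(c("AN", "A-", "AC", "AC"))
  expect_equal(ep$n_reads, c(4, 2))
  expect_equal(unname(ep$freqs[2, "C"]), 1)  # only the two C's count
  expect_equal(ep$H[2], 0)
})

test_that("class logo heights satisfy the stacking identity sum_b S = H", {
  set.seed(42)
  seqs <- random_reads(60, 25, seed = 42)
  labels <- sample(c("gut", "skin", "oral"), 60, replace = TRUE)
  lg <- class_logo(seqs, labels)
  for (ci in seq_along(lg$classes))
    expect_equal(unname(rowSums(lg$S[ci, , ])), lg$H$H, tolerance = 1e-12)
  # single class: S equals pooled f * H elementwise
  lg1 <- class_logo(seqs, rep("only", 60))
  ep <- entropy_profile(seqs)
  f <- ep$freqs; f[is.na(f)] <- 0
  expect_equal(lg1$S[1, , ], unname(f * ep$H), ignore_attr = TRUE)
  # conserved pooled position zeroes every class's letters
  lgc <- class_logo(c("AA", "AC"), c("x", "y"))
  expect_equal(sum(lgc$S[, 1, ]), 0)
  expect_error(class_logo(seqs, labels, classes = c("gut", "missing")),
               "missing")
})

test_that("mean attention averages per class and keeps unit row sums", {
  u <- c(0.5, 0.3, 0.2); v <- c(0.1, 0.1, 0.8)
  ms <- mean_attention(rbind(u, v, u), c("a", "a", "b"), "true_label",
                       window = 1)
  expect_equal(unname(ms$A["a", ]), (u + v) / 2)
  expect_equal(unname(ms$A["b", ]), u)
  expect_equal(unname(rowSums(ms$A)), c(1, 1), tolerance = 1e-5)
  set.seed(43)
  att <- matrix(stats::rgamma(20 * 15, 1), 20)
  att <- att / rowSums(att)
  ms2 <- mean_attention(att, sample(c("x", "y"), 20, replace = TRUE),
                        grouping = "predicted_label")
  expect_equal(unname(rowSums(ms2$A)), rep(1, 2), tolerance = 1e-5)
})

test_that("moving-average smoothing truncates at edges and preserves interior mass", {
  expect_equal(smooth_attention(rep(0.2, 5), 3), rep(0.2, 5))
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  sm <- smooth_attention(v, 9)
  expect_equal(sm[5], mean(v[1:9]))  # full window at interior position
  expect_equal(sm[1], mean(v[1:5]))  # truncated at the left edge
  expect_error(smooth_attention(v, 4), "odd")
  expect_error(smooth_attention(v, 11), "exceed")
  # brute-force double-loop oracle on random vectors
  set.seed(44)
  for (w in c(3, 5, 9)) {
    x <- stats::runif(30)
    naive <- vapply(seq_along(x), function(i) {
      lo <- max(1, i - (w - 1) / 2); hi <- min(30, i + (w - 1) / 2)
      mean(x[lo:hi])
    }, 0)
    expect_equal(smooth_attention(x, w), naive, tolerance = 1e-12)
  }
  # mass preservation away from the edges
  x2 <- numeric(40); x2[10:30] <- stats::runif(21)
  expect_equal(sum(smooth_attention(x2, 9)), sum(x2), tolerance = 1e-10)
})

test_that("attention aligns onto MSA columns and round-trips through gaps", {
  al <- c(s1 = "AC-G", s2 = "A-CG")
  att <- list(s1 = c(0.2, 0.3, 0.5), s2 = c(0.1, 0.6, 0.3))
  aa <- align_attention(al, att)
  expect_equal(unname(aa$per_sequence["s1", ]), c(0.2, 0.3, NA, 0.5))
  expect_equal(unname(aa$per_sequence["s2", ]), c(0.1, NA, 0.6, 0.3))
  # column means ignore gap entries rather than zero-filling them
  expect_equal(unname(aa$column_mean), c(0.15, 0.3, 0.6, 0.4))
  # gapless alignment is the identity
  aa2 <- align_attention(c(a = "ACGT"), list(a = c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(unname(aa2$per_sequence[1, ]), c(0.1, 0.2, 0.3, 0.4))
  expect_error(align_attention(al, list(s1 = c(0.5, 0.5))), "s1")
})

test_that("alignment round-trip recovers inputs bit-exactly for random gaps", {
  set.seed(45)
  for (i in 1:50) {
    L <- sample(5:30, 1)
    n_res <- sample(2:L, 1)
    res_cols <- sort(sample(L, n_res))
    chars <- rep("-", L); chars[res_cols] <- sample(c("A", "C", "G", "T"),
                                                   n_res, replace = TRUE)
    att <- stats::runif(n_res); att <- att / sum(att)
    aa <- align_attention(setNames(paste(chars, collapse = ""), "s"),
                          list(s = att))
    recovered <- aa$per_sequence[1, !is.na(aa$per_sequence[1, ])]
    expect_identical(unname(recovered), att)
  }
})

test_that("region attention sums partition the attention budget", {
  att <- rbind(cls1 = rep(0.01, 100))
  regions <- data.frame(name = c("V1", "V2", "V3"),
                        start = c(1, 41, 71), end = c(40, 70, 100))
  rt <- region_attention(att, regions)
  expect_equal(unname(rt[1, ]), c(0.40, 0.30, 0.30), tolerance = 1e-5)
  expect_equal(sum(rt), 1, tolerance = 1e-5)
  # one region spanning everything captures the total
  rt2 <- region_attention(att, data.frame(name = "all", start = 1, end = 100))
  expect_equal(unname(rt2[1, 1]), sum(att))
  expect_error(region_attention(att, data.frame(name = c("a", "b"),
                                                start = c(1, 40),
                                                end = c(50, 90))), "overlap")
  expect_error(region_attention(att, data.frame(name = "a", start = 1,
                                                end = 101)), "within")
})

test_that("logo rendering runs on a null device with and without attention", {
  seqs <- c("ACGTAC", "ACGAAC", "ACCTAC", "TCGTAC")
  lg <- class_logo(seqs, c("a", "a", "b", "b"))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot_logo(lg, class = "a"))
  expect_silent(plot_logo(lg, class = "b", attention = rep(1 / 6, 6)))
  expect_error(plot_logo(lg, class = "zz"), "not in the logo")
})

test_that("region tables read from TSV use 1-based inclusive coordinates", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tstart\tend", "V2\t11\t20", "V1\t1\t10"), p)
  rg <- read_regions(p)
  expect_identical(rg$name, c("V1", "V2"))  # sorted by start
  att <- rep(1 / 20, 20)
  rt <- region_attention(att, p)
  expect_equal(unname(rt[1, ]), c(0.5, 0.5))
})
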