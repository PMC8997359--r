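# Contact-matrix data model, I/O, digestion, balancing and transforms.

test_that("construction folds the lower triangle and validates input", {
  bins <- bin_genome(c(chr1 = 5000), 1000)
  m <- contact_matrix(bins, data.frame(i = c(1, 2, 3), j = c(2, 1, 3),
                                       count = c(5, 3, 7)))
  expect_equal(nrow(m$pixels), 2)
  expect_equal(m$pixels$count[m$pixels$i == 1 & m$pixels$j == 2], 8)
  expect_equal(m$total_count, 15)
  expect_error(contact_matrix(bins, data.frame(i = 1, j = 10, count = 1)),
               "out of range")
  expect_error(contact_matrix(bins, data.frame(i = 1, j = 2, count = -1)),
               "negative")
})

test_that("matrix text round-trip is lossless, empty files allowed", {
  bins <- bin_genome(c(chr1 = 8000, chr2 = 4000), 2000)
  m <- contact_matrix(bins, data.frame(i = c(1, 2, 5), j = c(3, 2, 6),
                                       count = c(4, 9, 2)))
  pf <- tempfile(); bf <- tempfile()
  write_matrix(m, pf, bf)
  m2 <- read_matrix(pf, bf)
  expect_equal(m2$pixels, m$pixels)
  expect_equal(m2$bins, m$bins)
  writeLines(character(0), pf)
  m0 <- read_matrix(pf, bf)
  expect_equal(m0$total_count, 0)
  writeLines("0\t10\t5", pf)
  expect_error(read_matrix(pf, bf), "out of range")
})

test_that("genome digestion applies cut, merge and split rules", {
  seqs <- Biostrings::DNAStringSet(c(
    plain = paste0(strrep("A", 300), "GATC", strrep("T", 296),
                   "GATC", strrep("A", 396)),
    shortfrag = paste0(strrep("A", 100), "GATC", strrep("C", 76),
                       "GATC", strrep("T", 820)),
    cutless = strrep("ACGT", 625)))
  expect_warning(bt <- digest_genome(seqs, "GATC", min_gap = 150,
                                     max_gap = 1000), "absent")
  plain <- bt[bt$chrom == "plain", ]
  expect_equal(plain$start, c(0, 300, 600))
  expect_equal(plain$end, c(300, 600, 1000))
  # fragment [100,180) is itself shorter than min_gap after the first cut:
  # [0,100) absorbs forward into [0,180)
  sf <- bt[bt$chrom == "shortfrag", ]
  expect_equal(sf$start[1], 0)
  expect_equal(sf$end[1], 180)
  expect_true(all(sf$end - sf$start >= 150))
  cl <- bt[bt$chrom == "cutless", ]
  expect_equal(nrow(cl), 3)
  expect_true(all(cl$end - cl$start <= 1000))
  expect_equal(cl$end[3], 2500)
})

test_that("balancing recovers a planted bias vector and masks empty bins", {
  set.seed(42)
  n <- 60
  # doubly-balanced target: constant matrix obeys equal marginals
  t_mat <- matrix(50, n, n)
  v <- exp(stats::rnorm(n, 0, 0.4))
  biased <- t_mat / outer(v, v)
  m <- dense_to_cm(biased)
  mb <- balance(m, tol = 1e-4)
  w <- mb$weights
  ratio <- w / v
  expect_lt(stats::sd(ratio) / mean(ratio), 0.01)
  # corrected marginal CV honours the contract, by direct summation
  M <- biased * outer(w, w)
  rs <- rowSums(M)
  expect_lt(stats::sd(rs) / mean(rs), 1e-3)
  # a zero row is masked
  Z <- matrix(10, 10, 10); Z[4, ] <- 0; Z[, 4] <- 0
  mz <- balance(dense_to_cm(Z))
  expect_true(is.na(mz$weights[4]))
  expect_false(anyNA(mz$weights[-4]))
})

test_that("already-balanced input yields constant weights", {
  m <- dense_to_cm(matrix(20, 40, 40))
  mb <- balance(m, tol = 1e-6)
  expect_lt(diff(range(mb$weights)) / mean(mb$weights), 1e-6)
})

test_that("down-sampling is binomial, seeded and identity at fraction 1", {
  M <- decay_matrix(80, scale = 400)
  m <- dense_to_cm(round(M))
  expect_identical(downsample(m, 1, seed = 1), m)
  d1 <- downsample(m, 0.8, seed = 7)
  d2 <- downsample(m, 0.8, seed = 7)
  expect_identical(d1$pixels, d2$pixels)
  tot <- m$total_count
  expect_lt(abs(d1$total_count - 0.8 * tot), 3 * sqrt(tot * 0.8 * 0.2))
  expect_error(downsample(m, 0, seed = 1), "fraction")
  # retained fraction is distributionally correct across seeds
  fr <- vapply(1:200, function(s) downsample(m, 0.8, s)$total_count / tot,
               numeric(1))
  expect_lt(abs(mean(fr) - 0.8), 3 * sqrt(0.8 * 0.2 / (tot * 200)))
})

test_that("observed/expected flattens decay and finds planted enrichment", {
  M <- decay_matrix(100, scale = 200)
  oe <- observed_expected(dense_to_cm(M))
  expect_true(all(abs(oe$matrix$pixels$count - 1) < 1e-9))
  # idempotence in ratio space: O/E of a flat matrix is 1 again
  oe2 <- observed_expected(oe$matrix)
  expect_true(all(abs(oe2$matrix$pixels$count - 1) < 1e-9))
  # planted 2x block, small against the chromosome so the block itself
  # barely moves the expected profile
  Mb <- decay_matrix(400, scale = 200)
  Mb[101:110, 101:110] <- Mb[101:110, 101:110] * 2
  Mb <- (Mb + t(Mb)) / 2
  oeb <- observed_expected(dense_to_cm(Mb))
  R <- tadremodel:::cm_dense(oeb$matrix, "chrT", corrected = FALSE)
  inblock <- R[101:110, 101:110][upper.tri(R[101:110, 101:110])]
  expect_lt(abs(mean(inblock) - 2) / 2, 0.05)
})

test_that("per-bin-pair log2 fold change is zero on self and exact on counts", {
  M <- round(decay_matrix(50, scale = 300))
  m <- dense_to_cm(M, resolution = 5000)
  fc_self <- bin_log2fc(m, m, resolution = 5000)
  expect_true(all(fc_self$log2fc == 0))
  # doubling all counts cancels through size factors (up to pseudocount)
  m2 <- m; m2$pixels$count <- m2$pixels$count * 2
  m2$total_count <- sum(m2$pixels$count)
  fc_dbl <- bin_log2fc(m, m2, resolution = 5000)
  expect_lt(max(abs(fc_dbl$log2fc)), 0.2)
  # single-pair arithmetic with pseudocount 1 and equal totals
  A <- matrix(0, 4, 4); A[1, 2] <- 31; A[3, 4] <- 9
  B <- matrix(0, 4, 4); B[1, 2] <- 7;  B[3, 4] <- 33
  fa <- dense_to_cm(A, 5000); fb <- dense_to_cm(B, 5000)
  fc <- bin_log2fc(fa, fb, resolution = 5000)
  expect_equal(fc$log2fc[fc$i == 1 & fc$j == 2], 2)
})

test_that("stored matrices answer symmetric queries identically", {
  M <- round(decay_matrix(30, scale = 100))
  m <- dense_to_cm(M)
  D <- tadremodel:::cm_dense(m, "chrT", corrected = FALSE)
  expect_identical(D, t(D))
})
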