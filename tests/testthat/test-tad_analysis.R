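# Insulation scoring, border calling and cross-condition classification.

test_that("insulation score matches the brute-force diamond oracle", {
  set.seed(3)
  for (n in c(60, 120)) {
    M <- decay_matrix(n, scale = 150) * exp(stats::rnorm(n * n, 0, 0.3))
    M <- (M + t(M)) / 2
    m <- dense_to_cm(round(M) + 1, resolution = 1000)
    wb <- c(5, 8)
    tr <- insulation_score(m, window_sizes = wb * 1000, smooth_bins = 1)
    D <- tadremodel:::cm_dense(m, "chrT", corrected = FALSE)
    orc <- oracle_insulation(D, wb)
    ok <- !is.na(orc)
    expect_equal(tr$score[ok], orc[ok], tolerance = 1e-10)
    expect_true(all(is.na(tr$score[!ok])))
  }
})

test_that("translation-invariant decay gives a flat interior score", {
  m <- dense_to_cm(decay_matrix(100, scale = 500), resolution = 1000)
  tr <- insulation_score(m, window_sizes = c(5000, 10000), smooth_bins = 1)
  s <- tr$score[!is.na(tr$score)]
  expect_lt(stats::sd(s), 1e-6)
})

test_that("two identical windows average to either track", {
  m <- dense_to_cm(round(decay_matrix(60, scale = 200)), resolution = 1000)
  a <- insulation_score(m, window_sizes = c(6000), smooth_bins = 1)
  b <- insulation_score(m, window_sizes = c(6000, 6000), smooth_bins = 1)
  expect_equal(a$score, b$score)
})

test_that("a planted border is the global score minimum", {
  n <- 120
  M <- decay_matrix(n, scale = 300)
  M[1:60, 61:120] <- M[1:60, 61:120] / 3
  M[61:120, 1:60] <- t(M[1:60, 61:120])
  m <- dense_to_cm(M, resolution = 1000)
  tr <- insulation_score(m, window_sizes = c(10000), smooth_bins = 1)
  expect_lte(abs(which.min(tr$score) - 60.5), 1)
})

test_that("border calling applies delta thresholds and the min-TAD rule", {
  spec <- planted_border_spec(seed = 901)
  sim <- simulate_matrix(spec)
  mb <- balance(sim$matrix)
  tr <- insulation_score(mb)
  bd <- call_borders(tr, mb)
  expect_true(all(bd$delta >= 0.04))
  expect_true(all(bd$strength[bd$delta >= 0.08] == "strong"))
  expect_true(all(bd$strength[bd$delta < 0.08] == "weak"))
  # minimum spacing enforced
  for (ch in unique(bd$chrom))
    expect_true(all(diff(sort(bd$pos[bd$chrom == ch])) >= 5000))
  # flat track yields nothing
  flat <- dense_to_cm(decay_matrix(80, scale = 300), resolution = 1000)
  trf <- insulation_score(flat, smooth_bins = 1)
  expect_equal(nrow(call_borders(trf, flat)), 0)
  # raising the strong threshold never increases the strong count
  n_at <- function(ds) sum(call_borders(tr, mb,
                                        delta_strong = ds)$strength == "strong")
  expect_true(n_at(0.08) >= n_at(0.3))
  expect_true(n_at(0.3) >= n_at(1))
})

test_that("robustness filter matches by position and strength class", {
  full <- data.frame(chrom = "chr1", pos = c(10000, 50000, 90000),
                     delta = c(0.1, 0.2, 0.09),
                     strength = c("strong", "strong", "weak"))
  down <- data.frame(chrom = "chr1", pos = c(10500, 50200),
                     delta = c(0.1, 0.05),
                     strength = c("strong", "weak"))
  rb <- robust_borders(full, down, match_tol = 2000)
  # strong matched by strong survives; strong matched only by weak does not;
  # weak with no partner does not
  expect_equal(rb$pos, 10000)
  expect_identical(robust_borders(full, full, match_tol = 0)$pos, full$pos)
  # boundary: partner exactly at match_tol survives, at match_tol+1 not
  d2 <- data.frame(chrom = "chr1", pos = 12001, delta = 0.1,
                   strength = "strong")
  expect_equal(nrow(robust_borders(full[1, ], d2, match_tol = 2001)), 1)
  expect_equal(nrow(robust_borders(full[1, ], d2, match_tol = 2000)), 0)
})

test_that("border classification implements the status precedence", {
  wt <- data.frame(chrom = "chr1", pos = c(1e5, 2e5, 3e5, 4e5),
                   delta = 0.2, strength = "strong")
  kd <- data.frame(chrom = "chr1",
                   pos = c(1e5,          # same -> maintained
                           2e5 + 1500,   # within fuzzy tol -> fuzzy
                           4e5 + 300),   # within same_tol but weak
                   delta = c(0.2, 0.2, 0.05),
                   strength = c("strong", "strong", "weak"))
  cls <- classify_borders(wt, kd, fuzzy_tol = 2000, same_tol = 600)
  got <- cls$status[match(wt$pos, cls$wt_pos)]
  expect_equal(got, c("maintained", "fuzzy", "lost", "weakened"))
  expect_equal(cls$shift[cls$wt_pos == 2e5], 1500)
  # identical strong lists: all maintained, none lost or new
  cls2 <- classify_borders(wt, wt)
  expect_true(all(cls2$status == "maintained"))
  # an unmatched kd strong border far away is new
  kd3 <- rbind(kd, data.frame(chrom = "chr1", pos = 9e5, delta = 0.3,
                              strength = "strong"))
  cls3 <- classify_borders(wt, kd3)
  expect_equal(sum(cls3$status == "new"), 1)
  expect_equal(cls3$kd_pos[cls3$status == "new"], 9e5)
  # classification partitions the WT strong set
  expect_equal(sum(!is.na(cls3$wt_pos)), nrow(wt))
  expect_error(classify_borders(rbind(wt, wt[1, ]), kd), "overlapping")
})

test_that("status intersection keeps only concordant borders", {
  a <- data.frame(chrom = "chr1", wt_pos = c(1e5, 2e5, 3e5, NA),
                  kd_pos = c(1e5, NA, 3e5 + 1500, 8e5),
                  status = c("maintained", "lost", "fuzzy", "new"))
  b <- data.frame(chrom = "chr1", wt_pos = c(1e5, 2e5, 3e5, NA),
                  kd_pos = c(1e5, NA, 3e5, 8e5 + 1000),
                  status = c("maintained", "lost", "maintained", "new"))
  it <- intersect_status(a, b, match_tol = 2000)
  expect_equal(it$maintained$wt_pos, 1e5)
  expect_equal(it$lost$wt_pos, 2e5)
  expect_equal(nrow(it$new), 1)
  expect_equal(it$discordant$wt_pos, 3e5)
  # self-intersection returns own sets
  ii <- intersect_status(a, a)
  expect_equal(ii$maintained$wt_pos, 1e5)
  expect_equal(nrow(ii$new), 1)
  expect_equal(nrow(ii$discordant), 0)
  # disjoint new borders do not intersect
  b2 <- b; b2$kd_pos[4] <- 5e5
  expect_equal(nrow(intersect_status(a, b2)$new), 0)
})

test_that("direct-binding annotation unions proteins over the vicinity", {
  borders <- data.frame(chrom = "chr1", pos = c(10000, 50000))
  peaks <- list(
    beaf = data.frame(chrom = "chr1", start = 9000, end = 9500),
    cp190 = data.frame(chrom = "chr1", start = 9900, end = 10100))
  ann <- annotate_direct(borders, peaks, vicinity = 5000)
  expect_true(ann$direct[1])
  expect_equal(ann$bound_proteins[1], "beaf,cp190")
  expect_false(ann$direct[2])
  # peak just beyond vicinity/2 does not count
  p2 <- list(x = data.frame(chrom = "chr1", start = 12501, end = 13000))
  expect_false(annotate_direct(borders[1, ], p2, vicinity = 5000)$direct)
  expect_error(annotate_direct(borders, list(data.frame())), "names")
})

test_that("proportion test equals the exhaustive hypergeometric oracle", {
  cases <- list(c(10, 10, 0, 10), c(5, 10, 5, 10), c(1, 2, 1, 2),
                c(7, 9, 2, 8), c(0, 6, 6, 6), c(3, 10, 9, 10))
  for (cs in cases) {
    expect_equal(proportion_test(cs[1], cs[2], cs[3], cs[4]),
                 oracle_fisher(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9)
  }
  expect_equal(proportion_test(5, 10, 5, 10), 1)
  expect_equal(proportion_test(1, 2, 1, 2), 1)
  expect_error(proportion_test(5, 3, 1, 2), "k <= n")
})
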