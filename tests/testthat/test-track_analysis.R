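# Occupancy heat maps, clustering rules, pausing index, PWM scanning and
# the rank-based group test.

flat_track <- function(value, chrom = "chr1", len = 1e5, bin = 100) {
  starts <- seq(0, len - bin, by = bin)
  data.frame(chrom = chrom, start = starts, end = starts + bin, value = value)
}

test_that("heat-map dialects winsorise and normalise as specified", {
  borders <- data.frame(chrom = "chr1", pos = c(30000, 60000))
  # constant positive track: every cell 1 under chip
  hm <- border_heatmap(flat_track(5), borders, dialect = "chip")
  expect_true(all(hm$matrix == 1))
  # an extreme outlier is clipped to the 95% positive quantile
  tr <- flat_track(5)
  tr$value[300] <- 1e5
  hm2 <- border_heatmap(tr, borders, dialect = "chip")
  expect_true(all(hm2$matrix <= 1))
  expect_true(all(hm2$matrix >= 0))
  # nascent: symmetric values span [-1, 1]
  set.seed(1)
  tr3 <- flat_track(0)
  tr3$value <- stats::rnorm(nrow(tr3))
  hm3 <- border_heatmap(tr3, borders, dialect = "nascent")
  expect_gte(min(hm3$matrix), -1)
  expect_lte(max(hm3$matrix), 1)
  expect_lt(min(hm3$matrix), 0)
  # dnase clips negatives at zero
  hm4 <- border_heatmap(tr3, borders, dialect = "dnase")
  expect_gte(min(hm4$matrix), 0)
  # dialect application is idempotent on its own output scale
  expect_true(all(border_heatmap(flat_track(1), borders,
                                 dialect = "chip")$matrix == 1))
  # rows ordered by decreasing reference signal
  ref <- flat_track(0)
  ref$value[ref$start >= 55000 & ref$start < 65000] <- 10
  hm5 <- border_heatmap(flat_track(5), borders, dialect = "chip",
                        reference = ref)
  expect_equal(hm5$row_order, c(2, 1))
})

test_that("occupancy clustering follows the quartile/cut-off rules", {
  # 5-bin windows: the quartiles are exactly the 2nd, 3rd and 4th sorted
  # values. Five pin datasets with window sum 100 fix the cut-off (the
  # median of positive sums) at 100.
  mk <- function(vals) matrix(vals, nrow = 1)
  mats <- c(
    list(allneg = mk(c(-1, -2, -3, -4, -5)),      # Q2, Q3 < 0
         extralow = mk(c(-3, -2, -1, 4, 5)),      # Q2 < 0 <= Q3
         zeros = mk(rep(0, 5)),                   # zeros fall to low
         low = mk(c(1, 2, 3, 4, 5)),              # all quartiles <= cutoff
         medium = mk(c(1, 2, 3, 200, 300)),       # Q3 above cutoff
         high = mk(c(2, 50, 300, 400, 500)),      # Q2 above cutoff, Q1 not
         extrahigh = mk(c(200, 300, 400, 500, 600))),  # Q1 above cutoff
    stats::setNames(replicate(5, mk(c(100, 0, 0, 0, 0)), simplify = FALSE),
                    paste0("pin", 1:5)))
  cc <- cluster_occupancy(mats)
  expect_equal(attr(cc, "cutoff"), 100)
  got <- stats::setNames(cc$class, cc$dataset)
  expect_equal(unname(got[c("allneg", "extralow", "zeros", "low", "medium",
                            "high", "extrahigh")]),
               c("no", "extra_low", "low", "low", "medium", "high",
                 "extra_high"))
  expect_true(all(got[paste0("pin", 1:5)] == "low"))
  # classes are exhaustive and exclusive: one class per (border, dataset)
  expect_true(all(cc$class %in% c("no", "extra_low", "low", "medium",
                                  "high", "extra_high")))
  expect_equal(nrow(cc), length(mats))
})

test_that("pausing index is the promoter/body ratio, scale invariant", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      start = c(10000, 40000), end = c(20000, 50000),
                      strand = c("+", "-"))
  # uniform signal: index 1
  pi1 <- pausing_index(flat_track(4), genes)
  expect_equal(unname(pi1), c(1, 1))
  # promoter mean 10, body mean 2 -> 5
  tr <- flat_track(2)
  tr$value[tr$start >= 9800 & tr$start < 10100] <- 10
  pi2 <- pausing_index(tr, genes)
  expect_equal(unname(pi2["gp"]), 5, tolerance = 0.1)
  # scale invariance
  tr10 <- tr; tr10$value <- tr$value * 10
  expect_equal(pausing_index(tr10, genes), pi2, tolerance = 1e-12)
  # zero body signal is discarded
  tr0 <- flat_track(0)
  tr0$value[tr0$start >= 9800 & tr0$start < 10050] <- 3
  expect_true(is.na(pausing_index(tr0, genes)["gm"]))
})

test_that("PWM site counts equal the per-window brute force", {
  pwm <- random_pwm(6, seed = 4)
  for (s in 1:10) {
    seqs <- random_dna(300, seed = 100 + s)
    expect_equal(count_pwm_sites(seqs, pwm, threshold_fraction = 0.85),
                 oracle_pwm_count(seqs, pwm, 0.85))
  }
  # monotone in threshold
  s1 <- random_dna(1000, seed = 3)
  expect_gte(count_pwm_sites(s1, pwm, threshold_fraction = 0.85),
             count_pwm_sites(s1, pwm, threshold_fraction = 0.95))
  # consensus at threshold 1 is found (plus reverse complement if present)
  cons <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
  padded <- paste0("CCCCCC", cons, "CCCCCC")
  expect_gte(count_pwm_sites(padded, pwm, threshold_fraction = 1), 1)
  # ambiguous bases void only their windows
  withN <- paste0("NNNNNN", cons, "NNNNNN")
  expect_gte(count_pwm_sites(withN, pwm, threshold_fraction = 1), 1)
})

test_that("group test matches exact enumeration and handles ties", {
  expect_equal(group_signal_test(1:5, 6:10), oracle_mwu(1:5, 6:10),
               tolerance = 1e-9)
  expect_equal(group_signal_test(1:5, 6:10), 2 / 252, tolerance = 1e-9)
  set.seed(8)
  for (rep in 1:5) {
    a <- stats::rnorm(sample(3:8, 1)); b <- stats::rnorm(sample(3:8, 1))
    expect_equal(group_signal_test(a, b), oracle_mwu(a, b),
                 tolerance = 1e-9)
  }
  # identical small samples: p = 1 by enumeration symmetry
  expect_equal(group_signal_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(group_signal_test(rep(2, 4), rep(2, 6)), 1)
  # large groups: normal approximation close to a resampling estimate
  set.seed(9)
  a <- stats::rnorm(1000); b <- stats::rnorm(1000, 0.1)
  p <- group_signal_test(a, b)
  expect_true(p > 0 && p < 1)
})
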