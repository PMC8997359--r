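# Synthetic-data generators: determinism, planted structure, ground truth.

test_that("generators are deterministic and round-trip through text I/O", {
  spec <- planted_border_spec(seed = 5, glen = 1e6, depth = 2e5,
                              n_borders = 4)
  a <- simulate_matrix(spec)
  b <- simulate_matrix(spec)
  expect_identical(a$matrix$pixels, b$matrix$pixels)
  expect_identical(a$truth$gc, b$truth$gc)
  pf <- tempfile(); bf <- tempfile()
  write_matrix(a$matrix, pf, bf)
  rt <- read_matrix(pf, bf)
  expect_equal(rt$pixels, a$matrix$pixels)
  expect_equal(rt$bins, a$matrix$bins)
})

test_that("distance-decay exponent is recovered by log-log regression", {
  spec <- synthetic_spec(c(chr1 = 3e6), resolution = 5000,
                         decay_exponent = 1, depth = 2e6, seed = 21)
  sim <- simulate_matrix(spec)
  oe <- observed_expected(sim$matrix)
  prof <- oe$expected
  sel <- prof$offset >= 1 & prof$offset <= 100 & prof$expected > 0
  fit <- stats::lm(log(expected) ~ log(1 + offset), data = prof[sel, ])
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.1)
})

test_that("planted borders reduce cross-border contacts by the stated depth", {
  spec <- synthetic_spec(c(chr1 = 1e6), resolution = 5000, depth = 3e6,
                         seed = 9,
                         borders = data.frame(chrom = "chr1", pos = 5e5,
                                              depth = 3))
  sim <- simulate_matrix(spec)
  M <- tadremodel:::cm_dense(sim$matrix, "chr1", corrected = FALSE)
  n <- nrow(M); b <- 100
  # matched-distance cross/within ratios, averaged over offsets
  ratios <- vapply(10:40, function(d) {
    i_cross <- (b - d + 1):b
    i_within <- setdiff(seq_len(n - d), (b - d):(b + 1))
    mean(M[cbind(i_cross, i_cross + d)]) /
      mean(M[cbind(i_within, i_within + d)])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1 / 3), 0.1 / 3)
})

test_that("condition pairs record intended statuses and share noise", {
  spec <- planted_border_spec(seed = 31, glen = 2e6, depth = 5e5,
                              n_borders = 6, resolution = 5000)
  bb <- spec$borders
  edits <- rbind(
    data.frame(type = "delete", chrom = "chr1", pos = bb$pos[1], value = NA),
    data.frame(type = "shift", chrom = "chr1", pos = bb$pos[2],
               value = 1500),
    data.frame(type = "shift", chrom = "chr1", pos = bb$pos[3],
               value = 50000),
    data.frame(type = "weaken", chrom = "chr1", pos = bb$pos[4],
               value = 1.5))
  pair <- simulate_condition_pair(spec, edits)
  st <- stats::setNames(pair$truth$status[!is.na(pair$truth$wt_pos)],
                        pair$truth$wt_pos[!is.na(pair$truth$wt_pos)])
  expect_equal(unname(st[as.character(bb$pos[1:4])]),
               c("lost", "fuzzy", "lost", "weakened"))
  expect_true(all(st[as.character(bb$pos[5:6])] == "maintained"))
  expect_equal(sum(pair$truth$status == "new"), 1)
  # empty edit list: identical matrices, all maintained
  p0 <- simulate_condition_pair(spec, NULL)
  expect_identical(p0$wt$matrix$pixels, p0$kd$matrix$pixels)
  expect_true(all(p0$truth$status == "maintained"))
  # unedited pixels share their noise between conditions
  wt_px <- pair$wt$matrix$pixels
  kd_px <- pair$kd$matrix$pixels
  key_w <- paste(wt_px$i, wt_px$j); key_k <- paste(kd_px$i, kd_px$j)
  far <- wt_px$i > 350 & wt_px$j > 350   # beyond the last edited border
  shared <- intersect(key_w[far], key_k)
  expect_gt(length(shared), 100)
  expect_identical(wt_px$count[match(shared, key_w)],
                   kd_px$count[match(shared, key_k)])
  expect_error(simulate_condition_pair(spec,
    data.frame(type = "delete", chrom = "chr1", pos = 123, value = NA)),
    "unknown border")
})

test_that("simulated tracks put recoverable bumps at chosen borders", {
  borders <- data.frame(chrom = "chr1",
                        pos = seq(50000, 450000, by = 50000))
  has <- rep(c(TRUE, FALSE), length.out = nrow(borders))
  tk <- simulate_tracks(borders, c(chr1 = 5e5), snr = 5, seed = 4,
                        has_bump = has)
  ann <- annotate_direct(borders, list(prot = tk$peaks), vicinity = 5000)
  expect_true(all(ann$direct[has]))
  # recovery through the signal itself: bump borders carry higher signal
  hm <- border_heatmap(tk$track, borders, dialect = "chip")
  sums <- rowSums(hm$raw)
  expect_gt(min(sums[has]), max(sums[!has]))
  # determinism
  tk2 <- simulate_tracks(borders, c(chr1 = 5e5), snr = 5, seed = 4,
                         has_bump = has)
  expect_identical(tk$track, tk2$track)
  # divergent dialect produces both signs around bumps
  dv <- simulate_tracks(borders, c(chr1 = 5e5), snr = 8, seed = 4,
                        has_bump = has, divergent = TRUE)
  expect_lt(min(dv$track$value), -3)
  expect_gt(max(dv$track$value), 3)
})

test_that("expression generator ties DEGs to reorganised TADs", {
  truth <- data.frame(chrom = "chr1",
                      wt_pos = seq(1e5, 2e6, by = 1e5),
                      kd_pos = seq(1e5, 2e6, by = 1e5),
                      status = rep(c("maintained", "lost"), each = 10))
  truth$kd_pos[truth$status == "lost"] <- NA
  ex <- simulate_expression(truth, c(chr1 = 2.1e6), genes_per_tad = 10,
                            deg_odds = 5, seed = 3)
  expect_equal(nrow(ex$genes), nrow(ex$deg))
  # genes never span borders
  for (k in seq_len(nrow(ex$genes)))
    expect_false(any(truth$wt_pos > ex$genes$start[k] &
                     truth$wt_pos < ex$genes$end[k]))
  # DEG status consistent with the thresholds
  st <- deg_status(ex$deg)
  expect_identical(st$status, ex$deg$status)
  # enrichment in reorganised TADs at odds 5
  tab <- table(ex$genes$tad_reorganised, ex$deg$status != "not-DE")
  frac_reorg <- tab["TRUE", "TRUE"] / sum(tab["TRUE", ])
  frac_cons <- tab["FALSE", "TRUE"] / sum(tab["FALSE", ])
  expect_gt(frac_reorg, frac_cons)
  # odds 1: no systematic difference (chi-square not tiny)
  ex0 <- simulate_expression(truth, c(chr1 = 2.1e6), genes_per_tad = 10,
                             deg_odds = 1, seed = 3)
  tab0 <- table(ex0$genes$tad_reorganised, ex0$deg$status != "not-DE")
  if (all(dim(tab0) == c(2, 2)))
    expect_gt(suppressWarnings(stats::chisq.test(tab0)$p.value), 0.001)
  # zero DEGs possible
  exz <- simulate_expression(truth, c(chr1 = 2.1e6), genes_per_tad = 2,
                             deg_odds = 1, base_rate = 0, seed = 5)
  expect_true(all(exz$deg$status == "not-DE"))
})
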