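# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (double loops, exhaustive enumeration) and
# never share code with the implementation they check.

# dense symmetric matrix -> contact_matrix on uniform bins
dense_to_cm <- function(M, resolution = 1000, chrom = "chrT") {
  n <- nrow(M)
  bins <- bin_genome(stats::setNames(n * resolution, chrom), resolution)
  ij <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  contact_matrix(bins, data.frame(i = ij[, 1], j = ij[, 2], count = M[ij]))
}

# translation-invariant decay matrix with optional planted blocks
decay_matrix <- function(n, alpha = 1, scale = 100) {
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  scale * (1 + D)^(-alpha)
}

# brute-force multi-window insulation score: double loop over bins/windows,
# z-scored per window, averaged
oracle_insulation <- function(M, window_bins) {
  n <- nrow(M)
  zs <- sapply(window_bins, function(w) {
    raw <- rep(NA_real_, n)
    if (n >= 2 * w + 1) {
      for (b in (w + 1):(n - w)) {
        vals <- c()
        for (i in (b - w):(b - 1)) for (j in (b + 1):(b + w))
          vals <- c(vals, M[i, j])
        raw[b] <- mean(vals, na.rm = TRUE)
      }
    }
    (raw - mean(raw, na.rm = TRUE)) / stats::sd(raw, na.rm = TRUE)
  })
  out <- rowMeans(zs)
  wmax <- max(window_bins)
  out[seq_len(n) <= wmax | seq_len(n) > n - wmax] <- NA
  out
}

# exhaustive two-sided Fisher exact p for a 2x2 table with fixed margins:
# sum of probabilities of all tables no more probable than the observed
oracle_fisher <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  lo <- max(0, m - n2); hi <- min(m, n1)
  probs <- vapply(lo:hi, function(k)
    stats::dhyper(k, n1, n2, m), numeric(1))
  p_obs <- stats::dhyper(k1, n1, n2, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mwu <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  idx <- utils::combn(length(pooled), n1)
  u_null <- apply(idx, 2, function(ii) {
    aa <- pooled[ii]; bb <- pooled[-ii]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  p <- 2 * min(mean(u_null <= u_obs + 1e-9), mean(u_null >= u_obs - 1e-9))
  min(1, p)
}

# brute-force PWM site count: score every window on both strands
oracle_pwm_count <- function(seq, pwm, threshold_fraction) {
  score1 <- function(s) {
    L <- ncol(pwm)
    n <- nchar(s)
    cnt <- 0
    max_s <- sum(apply(pwm, 2, max)); min_s <- sum(apply(pwm, 2, min))
    thr <- min_s + threshold_fraction * (max_s - min_s)
    for (o in seq_len(n - L + 1)) {
      win <- substr(s, o, o + L - 1)
      chars <- strsplit(win, "")[[1]]
      if (any(!chars %in% c("A", "C", "G", "T"))) next
      sc <- sum(vapply(seq_len(L), function(l) pwm[chars[l], l], numeric(1)))
      if (sc >= thr - 1e-9) cnt <- cnt + 1
    }
    cnt
  }
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  score1(toupper(seq)) + score1(rc(toupper(seq)))
}

# rank-based exhaustive Mann-Whitney oracle for untied samples: enumerates
# every group assignment of the pooled values
oracle_mwu_fast <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  u_null <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
}

random_pwm <- function(L, seed = 1) {
  set.seed(seed)
  M <- matrix(stats::rnorm(4 * L), 4, L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  M
}

random_dna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# standard border layout used by the recovery tests
planted_border_spec <- function(seed, n_borders = 15, glen = 5e6,
                                resolution = 5000, depth = 1e6,
                                border_depth = 3) {
  pos <- round(seq(0.06 * glen, 0.94 * glen,
                   length.out = n_borders) / resolution) * resolution
  synthetic_spec(stats::setNames(glen, "chr1"), resolution = resolution,
                 borders = data.frame(chrom = "chr1", pos = pos,
                                      depth = border_depth),
                 depth = depth, seed = seed)
}
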