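# Focal-enrichment chromatin loop calling (donut-filter style), loop
# comparison across conditions, aggregate peak analysis and annotation.
#
# A pixel is a loop peak when its count exceeds four local expectations
# (donut, horizontal strip, vertical strip, lower-left quadrant) with
# Poisson significance at the requested FDR and fold-enrichment thresholds;
# nearby peaks are merged and represented by the most significant pixel.

# sum of a submatrix via a 2D summed-area table
sat_build <- function(M) {
  M[is.na(M)] <- 0
  apply(apply(M, 2, cumsum), 1, cumsum)  # transposed cumulative; see sat_sum
}
sat_sum <- function(S, r1, r2, c1, c2) {
  # S is t(cumsum over rows then cols): S[c, r] = sum(M[1:r, 1:c])
  g <- function(r, c) if (r < 1 || c < 1) 0 else S[c, r]
  g(r2, c2) - g(r1 - 1, c2) - g(r2, c1 - 1) + g(r1 - 1, c1 - 1)
}

#' Call chromatin loops by local focal enrichment
#'
#' @param m a balanced `contact_matrix` on uniform bins of width
#'   `resolution` (aggregate first if necessary).
#' @param resolution bin width in bp.
#' @param fdr BH-adjusted significance threshold applied to every filter.
#' @param window local-neighbourhood half-width in bins.
#' @param peak_width excluded peak half-width in bins.
#' @param merge_dist peaks closer than this (bp, Chebyshev distance on the
#'   two coordinates) are merged, keeping the most significant pixel.
#' @param thresholds list of fold-enrichment factors: `donut` and
#'   `lowerleft` (default 1.75), `hv` for the horizontal/vertical strips
#'   (1.5), `singleton` (2) applied to single-pixel clusters, and `cluster`
#'   (0.02), the best adjusted p a merged cluster must reach to be retained.
#' @param max_dist maximum anchor separation considered (bp).
#' @return data.frame of loops: `chrom`, `start1`, `end1`, `start2`, `end2`,
#'   `observed`, `expected_donut`, `expected_horizontal`,
#'   `expected_vertical`, `expected_lowerleft`, `fdr`, `size`.
#' @export
call_loops <- function(m, resolution = 2000, fdr = 0.05, window = 10,
                       peak_width = 5, merge_dist = 20000,
                       thresholds = list(cluster = 0.02, hv = 1.5,
                                         donut = 1.75, singleton = 2),
                       max_dist = 500000) {
  if (bin_width_median(m$bins) != resolution)
    stop("matrix not at the requested resolution; aggregate first")
  if (is.null(m$weights)) stop("matrix must be balanced")
  blocks <- chrom_blocks(m$bins)
  oe <- observed_expected(m)
  loops <- list()
  for (ch in names(blocks)) {
    idx <- blocks[[ch]]
    n <- length(idx)
    if (n < 4 * window) next
    M <- cm_dense(m, ch, corrected = TRUE)
    raw <- cm_dense(m, ch, corrected = FALSE)
    w <- m$weights[idx]
    expd <- oe$expected$expected[oe$expected$chrom == ch]
    # candidate pixels: raw count > 0, donut fully above the diagonal
    px <- which(upper.tri(M) & raw > 0, arr.ind = TRUE)
    d <- px[, 2] - px[, 1]
    keep <- d > 2 * window & d <= max_dist / resolution &
      px[, 1] - window >= 1 & px[, 2] + window <= n &
      !is.na(M[px])
    px <- px[keep, , drop = FALSE]
    if (!nrow(px)) next
    W <- window; P <- peak_width
    S <- sat_build(M)
    Edense <- matrix(expd[abs(outer(seq_len(n), seq_len(n), "-")) + 1L], n, n)
    Edense[is.na(Edense)] <- 0
    SE <- sat_build(Edense)
    # vectorised rectangle sums over all candidate pixels at once; the
    # local expectation is the O/E ratio of the neighbourhood mapped back
    # to the pixel's own decay level
    sat_at <- function(SS, r, c) {
      v <- numeric(length(r))
      ok <- r >= 1 & c >= 1
      v[ok] <- SS[cbind(c[ok], r[ok])]
      v
    }
    boxsum <- function(SS, r1, r2, c1, c2) {
      r1 <- pmax(r1, 1); c1 <- pmax(c1, 1)
      r2 <- pmin(r2, n); c2 <- pmin(c2, n)
      empty <- r1 > r2 | c1 > c2
      v <- sat_at(SS, r2, c2) - sat_at(SS, r1 - 1, c2) -
        sat_at(SS, r2, c1 - 1) + sat_at(SS, r1 - 1, c1 - 1)
      v[empty] <- 0
      v
    }
    i <- px[, 1]; j <- px[, 2]
    eat <- expd[j - i + 1L]
    both <- function(r1, r2, c1, c2)
      cbind(boxsum(S, r1, r2, c1, c2), boxsum(SE, r1, r2, c1, c2))
    # donut: big box minus inner box minus the cross arms
    dn <- both(i - W, i + W, j - W, j + W) - both(i - P, i + P, j - P, j + P) -
      (both(i, i, j - W, j + W) - both(i, i, j - P, j + P)) -
      (both(i - W, i + W, j, j) - both(i - P, i + P, j, j))
    hz <- both(i - 1, i + 1, j - W, j + W) - both(i - 1, i + 1, j - P, j + P)
    vt <- both(i - W, i + W, j - 1, j + 1) - both(i - P, i + P, j - 1, j + 1)
    ll <- both(i + 1, i + W, j - W, j - 1) - both(i + 1, i + P, j - P, j - 1)
    ratio <- function(b) ifelse(b[, 2] > 0, b[, 1] / b[, 2] * eat, NA_real_)
    filters <- cbind(donut = ratio(dn), horizontal = ratio(hz),
                     vertical = ratio(vt), lowerleft = ratio(ll))
    obs_corr <- M[px]
    obs_raw <- raw[px]
    wprod <- w[px[, 1]] * w[px[, 2]]
    pvals <- matrix(NA_real_, nrow(px), 4)
    for (f in 1:4) {
      lambda_raw <- filters[, f] / wprod
      ok <- is.finite(lambda_raw) & lambda_raw > 0
      pvals[ok, f] <- stats::ppois(obs_raw[ok] - 1, lambda_raw[ok],
                                   lower.tail = FALSE)
      pvals[!ok, f] <- 1
    }
    padj <- apply(pvals, 2, stats::p.adjust, method = "BH")
    if (is.null(dim(padj))) padj <- matrix(padj, ncol = 4)
    enr_ok <- obs_corr >= thresholds$donut * filters[, 1] &
      obs_corr >= thresholds$hv * filters[, 2] &
      obs_corr >= thresholds$hv * filters[, 3] &
      obs_corr >= thresholds$donut * filters[, 4]
    sig <- which(apply(padj, 1, max) <= fdr & enr_ok &
                 apply(is.finite(filters), 1, all))
    if (!length(sig)) next
    # cluster significant pixels within merge_dist (Chebyshev, bp)
    mb <- ceiling(merge_dist / resolution)
    pi <- px[sig, 1]; pj <- px[sig, 2]
    fdr_min <- apply(padj[sig, , drop = FALSE], 1, min)
    cl <- seq_along(sig)
    repeat {
      changed <- FALSE
      for (a in seq_along(sig)) for (b in seq_along(sig)) {
        if (cl[a] != cl[b] &&
            max(abs(pi[a] - pi[b]), abs(pj[a] - pj[b])) <= mb) {
          cl[cl == cl[b]] <- cl[a]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (g in unique(cl)) {
      mem <- which(cl == g)
      if (min(fdr_min[mem]) > thresholds$cluster) next
      best <- mem[which.min(fdr_min[mem])]
      if (length(mem) == 1) {
        k <- sig[best]
        if (!(obs_corr[k] >= thresholds$singleton *
              max(filters[k, 1], filters[k, 4]))) next
      }
      k <- sig[best]
      bi <- idx[px[k, 1]]; bj <- idx[px[k, 2]]
      loops[[length(loops) + 1L]] <- data.frame(
        chrom = ch,
        start1 = m$bins$start[bi], end1 = m$bins$end[bi],
        start2 = m$bins$start[bj], end2 = m$bins$end[bj],
        observed = obs_corr[k],
        expected_donut = filters[k, 1],
        expected_horizontal = filters[k, 2],
        expected_vertical = filters[k, 3],
        expected_lowerleft = filters[k, 4],
        fdr = fdr_min[best],
        size = (m$bins$start[bj] + m$bins$end[bj]) / 2 -
               (m$bins$start[bi] + m$bins$end[bi]) / 2,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(loops)) do.call(rbind, loops) else
    data.frame(chrom = character(), start1 = integer(), end1 = integer(),
               start2 = integer(), end2 = integer(), observed = numeric(),
               expected_donut = numeric(), expected_horizontal = numeric(),
               expected_vertical = numeric(), expected_lowerleft = numeric(),
               fdr = numeric(), size = numeric())
  rownames(res) <- NULL
  res
}

loop_mid <- function(loops) {
  cbind((loops$start1 + loops$end1) / 2, (loops$start2 + loops$end2) / 2)
}

#' Compare loops between WT and a knockdown
#'
#' A WT anchor is matched when a knockdown loop anchor midpoint lies within
#' `anchor_tol`; both anchors matched (by the same kd loop) -> maintained,
#' exactly one -> partial, none -> lost. Each knockdown loop is consumed at
#' most once, greedily by total anchor distance.
#' @export
compare_loops <- function(wt, kd, anchor_tol = 2000) {
  status <- rep("lost", nrow(wt))
  kd_index <- rep(NA_integer_, nrow(wt))
  if (nrow(wt) && nrow(kd)) {
    wm <- loop_mid(wt); km <- loop_mid(kd)
    pairs <- list()
    for (a in seq_len(nrow(wt))) for (b in seq_len(nrow(kd))) {
      if (wt$chrom[a] != kd$chrom[b]) next
      d1 <- abs(wm[a, 1] - km[b, 1]); d2 <- abs(wm[a, 2] - km[b, 2])
      n_match <- (d1 <= anchor_tol) + (d2 <= anchor_tol)
      if (n_match > 0)
        pairs[[length(pairs) + 1L]] <-
          c(a = a, b = b, n = n_match, d = d1 + d2)
    }
    if (length(pairs)) {
      pr <- do.call(rbind, pairs)
      pr <- pr[order(-pr[, "n"], pr[, "d"]), , drop = FALSE]
      used_b <- logical(nrow(kd))
      for (r in seq_len(nrow(pr))) {
        a <- pr[r, "a"]; b <- pr[r, "b"]
        if (status[a] != "lost" || used_b[b]) next
        status[a] <- if (pr[r, "n"] == 2) "maintained" else "partial"
        kd_index[a] <- b
        used_b[b] <- TRUE
      }
    }
  }
  data.frame(wt[, c("chrom", "start1", "end1", "start2", "end2")],
             status = status, kd_index = kd_index,
             stringsAsFactors = FALSE)
}

#' Aggregate peak analysis
#'
#' Averages the observed/expected submatrices centred at the loop pixels.
#' The centre score is the centre value divided by the mean of the
#' lower-left corner block.
#'
#' @param halfwidth window half-width in bins (full window `2*halfwidth+1`).
#' @param corner_size corner block edge length (default `max(3,
#'   floor(halfwidth/3))`).
#' @return list with `matrix` (the averaged window) and `score`.
#' @export
apa <- function(m, loops, resolution = 2000, halfwidth = 15,
                corner_size = NULL) {
  if (is.null(corner_size)) corner_size <- max(3, floor(halfwidth / 3))
  oe <- observed_expected(m)
  blocks <- chrom_blocks(m$bins)
  acc <- matrix(0, 2 * halfwidth + 1, 2 * halfwidth + 1)
  nused <- 0
  for (ch in unique(loops$chrom)) {
    idx <- blocks[[ch]]
    n <- length(idx)
    R <- cm_dense(oe$matrix, ch, corrected = FALSE)
    ll <- loops[loops$chrom == ch, , drop = FALSE]
    mids <- loop_mid(ll)
    bi <- floor(mids[, 1] / resolution) + 1L
    bj <- floor(mids[, 2] / resolution) + 1L
    for (k in seq_len(nrow(ll))) {
      if (bj[k] - bi[k] < 2 * halfwidth) next
      if (bi[k] - halfwidth < 1 || bj[k] + halfwidth > n) next
      sub <- R[(bi[k] - halfwidth):(bi[k] + halfwidth),
               (bj[k] - halfwidth):(bj[k] + halfwidth)]
      sub[is.na(sub)] <- 0
      acc <- acc + sub
      nused <- nused + 1
    }
  }
  if (nused == 0) stop("no loop is far enough from the diagonal for APA")
  A <- acc / nused
  ctr <- halfwidth + 1
  nwin <- 2 * halfwidth + 1
  corner <- A[(nwin - corner_size + 1):nwin, 1:corner_size]
  list(matrix = A, score = A[ctr, ctr] / mean(corner), n = nused)
}

anchor_granges <- function(loops, which = 1) {
  s <- loops[[paste0("start", which)]]
  e <- loops[[paste0("end", which)]]
  GenomicRanges::GRanges(loops$chrom, IRanges::IRanges(s + 1L, e))
}

gene_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start + 1L, genes$end),
                         strand = genes$strand)
}

classify_anchor <- function(anchors, genes, enhancers) {
  if (is.null(genes$strand) || any(!genes$strand %in% c("+", "-")))
    stop("gene set must carry strand (+/-)")
  gg <- gene_granges(genes)
  prom <- GenomicRanges::promoters(gg, upstream = 1000, downstream = 0)
  enh <- GenomicRanges::GRanges(enhancers$chrom,
                                IRanges::IRanges(enhancers$start + 1L,
                                                 enhancers$end))
  cls <- rep("O", length(anchors))
  cls[IRanges::overlapsAny(anchors, gg, ignore.strand = TRUE)] <- "G"
  cls[IRanges::overlapsAny(anchors, enh)] <- "E"
  cls[IRanges::overlapsAny(anchors, prom, ignore.strand = TRUE)] <- "P"
  cls
}

#' Annotate loop anchors as promoter / enhancer / gene / other
#'
#' Precedence P > E > G > O per anchor; promoters are the strand-aware 1-kb
#' windows upstream of each TSS. The pair label is reported unordered
#' (`P-E`, not `E-P`).
#' @export
annotate_loops <- function(loops, genes, enhancers) {
  a1 <- classify_anchor(anchor_granges(loops, 1), genes, enhancers)
  a2 <- classify_anchor(anchor_granges(loops, 2), genes, enhancers)
  lv <- c("P", "E", "G", "O")
  pair <- vapply(seq_along(a1), function(k) {
    p <- sort(factor(c(a1[k], a2[k]), levels = lv))
    paste(p, collapse = "-")
  }, character(1))
  data.frame(loops, end1_class = a1, end2_class = a2, pair_class = pair,
             stringsAsFactors = FALSE)
}

#' Differential expression at maintained versus lost loop anchors
#'
#' Considers genes whose promoter (1-kb strand-aware upstream window)
#' overlaps an anchor of a maintained or lost WT loop; each gene counted
#' once. Reports DEG counts, fractions and a two-sided Fisher exact p.
#' @export
deg_at_loops <- function(comparisons, genes, deg) {
  gg <- gene_granges(genes)
  prom <- GenomicRanges::promoters(gg, upstream = 1000, downstream = 0)
  missing <- setdiff(deg$gene_id, genes$gene_id)
  if (length(missing)) {
    warning(length(missing), " DEG-table genes absent from annotation; skipped")
    deg <- deg[deg$gene_id %in% genes$gene_id, , drop = FALSE]
  }
  genes_at <- function(status) {
    sel <- comparisons$status == status
    if (!any(sel)) return(character(0))
    ll <- comparisons[sel, , drop = FALSE]
    anc <- c(anchor_granges(ll, 1), anchor_granges(ll, 2))
    hit <- IRanges::overlapsAny(prom, anc, ignore.strand = TRUE)
    unique(genes$gene_id[hit])
  }
  summarise <- function(ids) {
    st <- deg$status[match(ids, deg$gene_id)]
    k <- sum(st %in% c("up", "down"), na.rm = TRUE)
    c(n = length(ids), deg = k)
  }
  mm <- summarise(genes_at("maintained"))
  ll <- summarise(genes_at("lost"))
  p <- if (mm["n"] > 0 && ll["n"] > 0)
    proportion_test(mm["deg"], mm["n"], ll["deg"], ll["n"]) else NA_real_
  list(maintained = c(mm, fraction = unname(ifelse(mm["n"] > 0,
                                                   mm["deg"] / mm["n"], 0))),
       lost = c(ll, fraction = unname(ifelse(ll["n"] > 0,
                                             ll["deg"] / ll["n"], 0))),
       pvalue = p)
}
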