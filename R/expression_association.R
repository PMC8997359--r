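# TAD-relative gene-region classification across conditions, permutation
# tests for DEG enrichment in reorganised TADs, housekeeping-gene calling.

#' Classify genome segments by the fate of their TAD's borders
#'
#' The genome is split at the union of WT and knockdown border positions;
#' each segment inherits a class from the displacement of the two borders of
#' the WT TAD containing it (displacement = distance to the nearest
#' knockdown border). Counting borders displaced by more than `fuzzy_tol`:
#' two -> `kd_specific`, one -> `conserved_one`, none with both
#' displacements at most `same_tol` -> `conserved_two`, otherwise `fuzzy`
#' (both borders jittered but within `fuzzy_tol`). Segments outside any WT
#' TAD (before the first or after the last WT border) are `unassigned` and
#' excluded from downstream tests.
#'
#' @param wt_borders,kd_borders border tables with `chrom` and `pos`.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @return data.frame `chrom`, `start`, `end`, `class`.
#' @export
classify_tad_regions <- function(wt_borders, kd_borders, chrom_lengths,
                                 fuzzy_tol = 2000, same_tol = 600) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    wp <- sort(wt_borders$pos[wt_borders$chrom == ch])
    kp <- sort(kd_borders$pos[kd_borders$chrom == ch])
    cuts <- sort(unique(c(0, wp, kp, chrom_lengths[[ch]])))
    segs <- data.frame(chrom = ch, start = cuts[-length(cuts)],
                       end = cuts[-1], class = "unassigned",
                       stringsAsFactors = FALSE)
    if (length(wp) >= 2) {
      disp <- vapply(wp, function(p)
        if (length(kp)) min(abs(kp - p)) else Inf, numeric(1))
      mid <- (segs$start + segs$end) / 2
      tad <- findInterval(mid, wp)   # 0 = before first border
      inside <- tad >= 1 & tad < length(wp)
      for (s in which(inside)) {
        d1 <- disp[tad[s]]; d2 <- disp[tad[s] + 1]
        nbig <- (d1 > fuzzy_tol) + (d2 > fuzzy_tol)
        segs$class[s] <-
          if (nbig == 2) "kd_specific"
          else if (nbig == 1) "conserved_one"
          else if (d1 <= same_tol && d2 <= same_tol) "conserved_two"
          else "fuzzy"
      }
    }
    out[[ch]] <- segs
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# merged, sorted target list per chromosome for fast overlap counting
merge_intervals <- function(df) {
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    s <- d$start[1]; e <- d$end[1]
    ms <- numeric(0); me <- numeric(0)
    if (nrow(d) > 1) for (k in 2:nrow(d)) {
      if (d$start[k] <= e) e <- max(e, d$end[k])
      else { ms <- c(ms, s); me <- c(me, e); s <- d$start[k]; e <- d$end[k] }
    }
    out[[ch]] <- list(start = c(ms, s), end = c(me, e))
  }
  out
}

# count how many query regions overlap >= 1 merged target interval;
# starts/ends are parallel vectors per chromosome (vectorised over queries)
count_overlaps_merged <- function(qs, qe, tstart, tend) {
  if (!length(tstart)) return(0L)
  idx <- findInterval(qs, tstart)
  hit <- (idx >= 1 & qs < tend[pmax(idx, 1)]) |
         (idx < length(tstart) & tstart[idx + 1] < qe)
  sum(hit)
}

#' Region-overlap permutation test
#'
#' Observed statistic: the number of query regions overlapping at least one
#' target region. Null: each query region's start is redrawn uniformly
#' within its chromosome's universe segments, preserving width, chromosome
#' and region count (a regioneR-style randomisation). The p-value is
#' `(1 + #{null >= observed}) / (1 + n_perm)` (upper tail, enrichment); a
#' standardised `z` is reported alongside.
#'
#' @param deg_regions,target_regions,universe data.frames with `chrom`,
#'   `start`, `end`.
#' @param n_perm number of permutations.
#' @param seed RNG seed (required for reproducibility).
#' @param alternative `"enrichment"` (default) or `"depletion"`.
#' @return list `observed`, `null_draws`, `pvalue`, `z`.
#' @export
permutation_overlap_test <- function(deg_regions, target_regions, universe,
                                     n_perm = 1000, seed,
                                     alternative = c("enrichment",
                                                     "depletion")) {
  alternative <- match.arg(alternative)
  set.seed(seed)
  targets <- merge_intervals(target_regions)
  uni <- merge_intervals(universe)
  chroms <- unique(deg_regions$chrom)
  obs <- 0L
  nulls <- integer(n_perm)
  for (ch in chroms) {
    q <- deg_regions[deg_regions$chrom == ch, , drop = FALSE]
    tg <- targets[[ch]]
    if (is.null(tg)) tg <- list(start = numeric(0), end = numeric(0))
    obs <- obs + count_overlaps_merged(q$start, q$end, tg$start, tg$end)
    u <- uni[[ch]]
    if (is.null(u)) stop("universe has no segments on chromosome ", ch)
    widths <- q$end - q$start
    seglen <- u$end - u$start
    if (any(widths > max(seglen)))
      stop("region wider than its chromosome's universe segments")
    nw <- length(widths)
    if (length(seglen) == 1) {
      # single-segment universe: draw every permuted start in one call
      room <- seglen - widths            # recycled per permutation
      S <- matrix(u$start[1] + stats::runif(n_perm * nw) * rep(room, n_perm),
                  nrow = nw)
      E <- S + widths
      for (p in seq_len(n_perm)) {
        nulls[p] <- nulls[p] +
          count_overlaps_merged(S[, p], E[, p], tg$start, tg$end)
      }
    } else {
      # multi-segment universe: segment chosen per region with probability
      # proportional to its feasible start span
      for (p in seq_len(n_perm)) {
        starts <- vapply(widths, function(w) {
          room <- pmax(0, seglen - w)
          seg <- sample.int(length(seglen), 1, prob = room + 1e-9)
          u$start[seg] + stats::runif(1) * room[seg]
        }, numeric(1))
        nulls[p] <- nulls[p] +
          count_overlaps_merged(starts, starts + widths, tg$start, tg$end)
      }
    }
  }
  mu <- mean(nulls); sdv <- stats::sd(nulls)
  p <- if (alternative == "enrichment")
    (1 + sum(nulls >= obs)) / (1 + n_perm)
  else
    (1 + sum(nulls <= obs)) / (1 + n_perm)
  list(observed = obs, null_draws = nulls, pvalue = p,
       z = if (isTRUE(sdv > 0)) (obs - mu) / sdv else 0)
}

#' Housekeeping genes: top expression band in every sample
#'
#' A gene is housekeeping iff its expression lies in the top `percentile`%
#' of genes in every sample (i.e. at or above each sample's
#' `(100 - percentile)`-th percentile).
#'
#' @param expr numeric matrix, genes x samples, with rownames.
#' @param percentile width of the top band, in percent.
#' @return character vector of gene identifiers.
#' @export
call_housekeeping <- function(expr, percentile = 40) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2, !is.null(rownames(expr)))
  incomplete <- apply(expr, 1, function(x) any(is.na(x)))
  if (any(incomplete)) {
    warning(sum(incomplete), " genes with missing values excluded")
    expr <- expr[!incomplete, , drop = FALSE]
  }
  keep <- rep(TRUE, nrow(expr))
  for (s in seq_len(ncol(expr))) {
    thr <- stats::quantile(expr[, s], 1 - percentile / 100, names = FALSE)
    keep <- keep & expr[, s] >= thr
  }
  rownames(expr)[keep]
}

#' Differentially expressed genes spanning a TAD border
#'
#' Returns the DE genes whose body interval strictly contains a border
#' position.
#'
#' @param deg DEG table with `gene_id` and `status`.
#' @param genes gene table with `gene_id`, `chrom`, `start`, `end`.
#' @param borders border table with `chrom`, `pos`.
#' @export
deg_border_span_check <- function(deg, genes, borders) {
  de_ids <- deg$gene_id[deg$status %in% c("up", "down")]
  g <- genes[genes$gene_id %in% de_ids, , drop = FALSE]
  if (!nrow(g)) return(g)
  spans <- vapply(seq_len(nrow(g)), function(k) {
    bp <- borders$pos[borders$chrom == g$chrom[k]]
    any(bp > g$start[k] & bp < g$end[k])
  }, logical(1))
  out <- g[spans, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-apply DEG status thresholds to a DEG table
#'
#' Status rule: `up` iff `padj <= p_thresh` and `log2fc >= fc_thresh`;
#' `down` symmetric; otherwise `not-DE`. Used to make input tables
#' consistent with the stated thresholds.
#' @export
deg_status <- function(deg, p_thresh = 0.05, fc_thresh = 2) {
  deg$status <- ifelse(deg$padj <= p_thresh & deg$log2fc >= fc_thresh, "up",
                ifelse(deg$padj <= p_thresh & deg$log2fc <= -fc_thresh,
                       "down", "not-DE"))
  deg
}
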