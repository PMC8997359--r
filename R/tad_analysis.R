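# Insulation (TAD-separation) scoring and cross-condition border analysis.
#
# The insulation statistic: for each bin b and window of w bins, the mean
# corrected count in the w x w diamond spanning the w bins upstream versus
# the w bins downstream of b. Per-window tracks are z-scored per chromosome
# and averaged across windows; borders are local minima of the averaged
# score passing a separation (delta) threshold and a rank-sum test of the
# inter-domain diamond against the flanking intra-domain triangles.

window_bins <- function(bins, window_bp) {
  max(2L, as.integer(round(window_bp / bin_width_median(bins))))
}

#' Multi-scale insulation (TAD-separation) score
#'
#' @param m a balanced `contact_matrix`.
#' @param window_sizes windows in bp (converted to bins via the median bin
#'   width, minimum 2 bins).
#' @param smooth_bins width (bins) of a running-mean smoothing of the final
#'   averaged score; odd, 1 disables. Suppresses single-bin noise minima on
#'   fine bin tables, analogous to averaging over a dense window schedule.
#' @return data.frame `chrom`, `start`, `end`, `bin` (global index), `score`;
#'   `NA` where the largest window does not fit.
#' @export
insulation_score <- function(m, window_sizes = c(10000, 20000, 30000),
                             smooth_bins = 5) {
  stopifnot(inherits(m, "contact_matrix"),
            smooth_bins >= 1, smooth_bins %% 2 == 1)
  blocks <- chrom_blocks(m$bins)
  ws <- vapply(window_sizes, function(w) window_bins(m$bins, w), integer(1))
  out <- lapply(names(blocks), function(ch) {
    idx <- blocks[[ch]]
    n <- length(idx)
    M <- cm_dense(m, ch, corrected = TRUE)
    zs <- matrix(NA_real_, n, length(ws))
    for (k in seq_along(ws)) {
      w <- ws[k]
      raw <- rep(NA_real_, n)
      if (n >= 2 * w + 1) {
        for (b in (w + 1):(n - w))
          raw[b] <- mean(M[(b - w):(b - 1), (b + 1):(b + w)], na.rm = TRUE)
      }
      mu <- mean(raw, na.rm = TRUE)
      sdv <- stats::sd(raw, na.rm = TRUE)
      zs[, k] <- if (is.finite(sdv) && sdv > 0) (raw - mu) / sdv
                 else raw - mu
    }
    # a masked neighbour can void the smallest diamond; other windows still
    # inform the score, so average over the windows that are defined
    score <- rowMeans(zs, na.rm = TRUE)
    wmax <- max(ws)
    defined <- seq_len(n) > wmax & seq_len(n) <= n - wmax
    score[!defined] <- NA_real_
    score[is.nan(score)] <- NA_real_
    raw_score <- score
    if (smooth_bins > 1) score <- running_mean(score, smooth_bins)
    data.frame(chrom = ch, start = m$bins$start[idx], end = m$bins$end[idx],
               bin = idx, score = score, score_raw = raw_score,
               stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, out)
  attr(track, "window_sizes") <- window_sizes
  attr(track, "window_bins") <- ws
  track
}

# NA-aware centred running mean; positions that are NA stay NA
running_mean <- function(x, k) {
  h <- (k - 1) / 2
  n <- length(x)
  out <- rep(NA_real_, n)
  for (b in which(!is.na(x))) {
    w <- x[max(1, b - h):min(n, b + h)]
    out[b] <- mean(w, na.rm = TRUE)
  }
  out
}

# indices of local minima / maxima; NA gaps (masked bins, track edges) are
# skipped by comparing each defined bin with its nearest defined neighbours
local_extrema <- function(s, minima = TRUE) {
  ok <- which(!is.na(s))
  if (length(ok) < 3) return(integer(0))
  v <- s[ok]
  res <- integer(0)
  for (k in 2:(length(v) - 1)) {
    hit <- if (minima) (v[k] < v[k - 1] && v[k] <= v[k + 1])
           else (v[k] > v[k - 1] && v[k] >= v[k + 1])
    if (hit) res <- c(res, ok[k])
  }
  res
}

#' Call TAD borders from an insulation track
#'
#' Candidate borders are local minima of the score. `delta` is the mean of
#' the two flanking local maxima minus the minimum; candidates below
#' `delta_weak` are dropped. Significance: one-sided rank-sum test of the
#' inter-domain diamond values against the two flanking intra-domain
#' triangles (largest window), computed on observed/expected values so the
#' distance decay does not bias the comparison, BH-adjusted across
#' candidates. Borders closer
#' than `min_tad` are resolved by keeping the larger delta. Strength is
#' `"strong"` iff `delta >= delta_strong`, else `"weak"`.
#'
#' @param track output of [insulation_score()].
#' @param m the matrix the track was computed from.
#' @param delta_weak,delta_strong separation thresholds on the z-scored
#'   insulation difference.
#' @param pvalue BH-adjusted significance threshold.
#' @param min_tad minimum TAD width (bp) between adjacent borders.
#' @return data.frame `chrom`, `start`, `end`, `pos` (border bin midpoint),
#'   `delta`, `pvalue`, `strength`.
#' @export
call_borders <- function(track, m, delta_weak = 0.04, delta_strong = 0.08,
                         pvalue = 0.01, min_tad = 5000) {
  wbins <- attr(track, "window_bins")
  w <- max(wbins)
  oe <- observed_expected(m)
  cand <- list()
  for (ch in unique(track$chrom)) {
    tt <- track[track$chrom == ch, ]
    s <- tt$score
    mins <- local_extrema(s, minima = TRUE)
    if (!length(mins)) next
    maxs <- local_extrema(s, minima = FALSE)
    M <- cm_dense(oe$matrix, ch, corrected = FALSE)
    n <- nrow(tt)
    for (b in mins) {
      lmax <- maxs[maxs < b]
      rmax <- maxs[maxs > b]
      lv <- if (length(lmax)) s[max(lmax)] else max(s[seq_len(b - 1)], na.rm = TRUE)
      rv <- if (length(rmax)) s[min(rmax)] else max(s[(b + 1):n], na.rm = TRUE)
      delta <- mean(c(lv, rv)) - s[b]
      if (!is.finite(delta) || delta < delta_weak) next
      p <- NA_real_
      if (b - w >= 1 && b + w <= n) {
        dia <- as.vector(M[(b - w):(b - 1), (b + 1):(b + w)])
        up <- M[(b - w):(b - 1), (b - w):(b - 1)]
        dn <- M[(b + 1):(b + w), (b + 1):(b + w)]
        tri <- c(up[upper.tri(up)], dn[upper.tri(dn)])
        dia <- dia[!is.na(dia)]; tri <- tri[!is.na(tri)]
        if (length(dia) && length(tri))
          p <- suppressWarnings(
            stats::wilcox.test(dia, tri, alternative = "less")$p.value)
      }
      # sub-bin position: least-squares parabola through the minimum and up
      # to two defined neighbours on each side (clamped to one bin)
      pos <- (tt$start[b] + tt$end[b]) / 2
      nb <- (max(1, b - 2):min(n, b + 2))
      nb <- nb[!is.na(s[nb])]
      if (length(nb) >= 3) {
        x <- nb - b
        fit <- stats::lm.fit(cbind(1, x, x^2), s[nb])
        beta <- fit$coefficients
        if (is.finite(beta[3]) && beta[3] > 0) {
          frac <- max(-1, min(1, -beta[2] / (2 * beta[3])))
          pos <- pos + frac * (tt$end[b] - tt$start[b])
        }
      }
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = ch, start = tt$start[b], end = tt$end[b],
        pos = pos, delta = delta, pvalue = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), pos = numeric(), delta = numeric(),
                      pvalue = numeric(), strength = character()))
  bd <- do.call(rbind, cand)
  bd$pvalue <- stats::p.adjust(bd$pvalue, method = "BH")
  bd <- bd[!is.na(bd$pvalue) & bd$pvalue <= pvalue, , drop = FALSE]
  # enforce minimum border spacing, keeping the larger delta
  res <- list()
  for (ch in unique(bd$chrom)) {
    bb <- bd[bd$chrom == ch, ]
    bb <- bb[order(bb$pos), ]
    repeat {
      if (nrow(bb) < 2) break
      gaps <- diff(bb$pos)
      tooclose <- which(gaps < min_tad)
      if (!length(tooclose)) break
      g <- tooclose[1]
      drop <- if (bb$delta[g] >= bb$delta[g + 1]) g + 1 else g
      bb <- bb[-drop, , drop = FALSE]
    }
    res[[ch]] <- bb
  }
  bd <- do.call(rbind, res)
  bd$strength <- ifelse(bd$delta >= delta_strong, "strong", "weak")
  rownames(bd) <- NULL
  bd
}

# nearest-neighbour match of query positions against subject positions,
# ties broken to the leftmost subject; returns subject index or NA
nearest_within <- function(q, s, tol) {
  if (!length(s)) return(rep(NA_integer_, length(q)))
  ord <- order(s)
  s_sorted <- s[ord]
  vapply(q, function(x) {
    d <- abs(s_sorted - x)
    k <- which(d == min(d))[1]         # leftmost among ties (sorted order)
    if (d[k] <= tol) ord[k] else NA_integer_
  }, integer(1))
}

#' Robust borders: recovered in full and down-sampled data
#'
#' Returns the full-data borders having a down-sampled border of the same
#' strength class within `match_tol` bp (nearest neighbour, ties leftmost).
#' @export
robust_borders <- function(full, downsampled, match_tol = 2000) {
  if (!nrow(full)) return(full)
  keep <- logical(nrow(full))
  for (ch in unique(full$chrom)) {
    fi <- which(full$chrom == ch)
    for (cls in c("strong", "weak")) {
      qi <- fi[full$strength[fi] == cls]
      si <- which(downsampled$chrom == ch & downsampled$strength == cls)
      if (!length(qi)) next
      hit <- nearest_within(full$pos[qi], downsampled$pos[si], match_tol)
      keep[qi] <- !is.na(hit)
    }
  }
  out <- full[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify WT borders against a knockdown condition
#'
#' For each WT strong border, in order of precedence: a knockdown strong
#' border within `same_tol` -> maintained; a knockdown weak border within
#' `same_tol` -> weakened; any knockdown border within `fuzzy_tol` -> fuzzy
#' (shift recorded); otherwise lost. Each knockdown border is consumed by at
#' most one WT border (greedy nearest distance). Knockdown strong borders
#' with no WT strong border within `fuzzy_tol` are reported as new.
#'
#' @param wt,kd border tables from [call_borders()] (WT restricted to robust
#'   strong borders upstream for the maintained/lost ledger).
#' @param fuzzy_tol displacement tolerance for fuzzy borders (bp).
#' @param same_tol positional identity tolerance (bp); default one median
#'   bin width, minimum 600 bp.
#' @return data.frame `chrom`, `wt_pos`, `kd_pos`, `status`, `shift`.
#' @export
classify_borders <- function(wt, kd, fuzzy_tol = 2000, same_tol = NULL) {
  for (tab in list(wt, kd))
    for (ch in unique(tab$chrom)) {
      p <- sort(tab$pos[tab$chrom == ch])
      if (anyDuplicated(p)) stop("overlapping borders in one input list")
    }
  if (is.null(same_tol)) same_tol <- 600
  wt_s <- wt[wt$strength == "strong", , drop = FALSE]
  out <- list()
  for (ch in unique(c(wt_s$chrom, kd$chrom))) {
    ww <- wt_s[wt_s$chrom == ch, , drop = FALSE]
    kk <- kd[kd$chrom == ch, , drop = FALSE]
    consumed <- rep(FALSE, nrow(kk))
    if (nrow(ww)) {
      # greedy by distance: visit WT borders by their nearest-match distance
      dmat <- if (nrow(kk))
        abs(outer(ww$pos, kk$pos, "-")) else
        matrix(numeric(0), nrow(ww), 0)
      assigned <- rep(NA_integer_, nrow(ww))
      ord <- order(apply(dmat, 1, function(r) if (length(r)) min(r) else Inf))
      for (wi in ord) {
        status <- "lost"; kpos <- NA_real_; shift <- NA_real_
        if (nrow(kk)) {
          d <- dmat[wi, ]
          d[consumed] <- Inf
          pick <- function(sel) {
            cand <- which(sel)
            if (!length(cand)) return(NA_integer_)
            cand[order(d[cand], kk$pos[cand])][1]
          }
          ki <- pick(d <= same_tol & kk$strength == "strong")
          if (!is.na(ki)) status <- "maintained"
          if (is.na(ki)) {
            ki <- pick(d <= same_tol & kk$strength == "weak")
            if (!is.na(ki)) status <- "weakened"
          }
          if (is.na(ki)) {
            ki <- pick(d <= fuzzy_tol)
            if (!is.na(ki)) status <- "fuzzy"
          }
          if (!is.na(ki)) {
            consumed[ki] <- TRUE
            kpos <- kk$pos[ki]
            if (status == "fuzzy") shift <- kpos - ww$pos[wi]
          }
        }
        assigned[wi] <- 1L
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, wt_pos = ww$pos[wi], kd_pos = kpos,
          status = status, shift = shift, stringsAsFactors = FALSE)
      }
    }
    # new borders: kd strong with no WT strong within fuzzy_tol
    ks <- which(kk$strength == "strong")
    for (ki in ks) {
      if (nrow(ww) && any(abs(ww$pos - kk$pos[ki]) <= fuzzy_tol)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, wt_pos = NA_real_, kd_pos = kk$pos[ki],
        status = "new", shift = NA_real_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), wt_pos = numeric(),
                      kd_pos = numeric(), status = character(),
                      shift = numeric())
  # report WT borders in genomic order, new borders after
  res <- res[order(res$chrom, is.na(res$wt_pos),
                   ifelse(is.na(res$wt_pos), res$kd_pos, res$wt_pos)), ]
  rownames(res) <- NULL
  res
}

#' Intersect border classifications from two knockdowns
#'
#' @param a,b outputs of [classify_borders()] against the same WT.
#' @param match_tol tolerance for matching new borders between conditions.
#' @return list with `maintained`, `lost` (WT positions classified the same
#'   way in both), `new` (positions of a's new borders with a matching new
#'   border in b), and `discordant` (WT positions whose status differs).
#' @export
intersect_status <- function(a, b, match_tol = 2000) {
  akey <- paste(a$chrom, a$wt_pos)
  bkey <- paste(b$chrom, b$wt_pos)
  common <- function(status) {
    sel <- !is.na(a$wt_pos) & a$status == status &
      akey %in% bkey[!is.na(b$wt_pos) & b$status == status]
    a[sel, c("chrom", "wt_pos"), drop = FALSE]
  }
  ka <- a[!is.na(a$wt_pos), , drop = FALSE]
  kb <- b[!is.na(b$wt_pos), , drop = FALSE]
  m <- match(paste(ka$chrom, ka$wt_pos), paste(kb$chrom, kb$wt_pos))
  disc <- ka[!is.na(m) & ka$status != kb$status[m], c("chrom", "wt_pos")]
  an <- a[a$status == "new", , drop = FALSE]
  bn <- b[b$status == "new", , drop = FALSE]
  newsel <- logical(nrow(an))
  for (ch in unique(an$chrom)) {
    ai <- which(an$chrom == ch)
    bp <- bn$kd_pos[bn$chrom == ch]
    if (length(bp))
      newsel[ai] <- !is.na(nearest_within(an$kd_pos[ai], bp, match_tol))
  }
  list(maintained = common("maintained"), lost = common("lost"),
       new = an[newsel, c("chrom", "kd_pos"), drop = FALSE],
       discordant = disc)
}

#' Annotate borders with direct architectural-protein binding
#'
#' A border is "direct" iff at least one ChIP peak of any supplied protein
#' overlaps the window border centre +/- `vicinity / 2`.
#'
#' @param borders border table with `chrom` and `pos`.
#' @param peaks named list of BED-like data.frames (`chrom`, `start`, `end`),
#'   one per protein; the names are the protein labels.
#' @param vicinity window width (bp) centred on the border.
#' @return the border table with `bound_proteins` (comma-separated) and
#'   `direct` columns.
#' @export
annotate_direct <- function(borders, peaks, vicinity = 5000) {
  stopifnot(is.list(peaks), !is.null(names(peaks)), all(nzchar(names(peaks))))
  half <- vicinity / 2
  win <- GenomicRanges::GRanges(
    borders$chrom,
    IRanges::IRanges(start = pmax(0, round(borders$pos - half)) + 1L,
                     end = round(borders$pos + half)))
  found <- matrix(FALSE, nrow(borders), length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[[k]]
    gr <- GenomicRanges::GRanges(p$chrom,
                                 IRanges::IRanges(p$start + 1L, p$end))
    found[, k] <- IRanges::overlapsAny(win, gr)
  }
  borders$bound_proteins <- apply(found, 1, function(r)
    paste(names(peaks)[r], collapse = ","))
  borders$direct <- rowSums(found) > 0
  borders
}

#' Two-sided Fisher exact test on two proportions
#'
#' @param k1,n1 successes and total in group 1; `k2`,`n2` likewise.
#' @export
proportion_test <- function(k1, n1, k2, n2) {
  if (any(c(k1, n1, k2, n2) < 0) || k1 > n1 || k2 > n2)
    stop("need 0 <= k <= n in both groups")
  stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2,
                            byrow = TRUE))$p.value
}
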