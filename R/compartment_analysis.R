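# A/B compartments: leading eigenvector of the per-chromosome Pearson
# correlation of the observed/expected map, sign-oriented by GC content;
# saddle plots and compartmentalisation strength.

# per-chromosome O/E Pearson correlation matrix with masked bins dropped;
# returns list(cor, keep) where keep indexes the chromosome's bins
chrom_cor <- function(m, oe, ch, min_bins = 20) {
  blocks <- chrom_blocks(m$bins)
  idx <- blocks[[ch]]
  n <- length(idx)
  R <- cm_dense(oe$matrix, ch, corrected = FALSE)
  marg <- cm_marginals(m)[idx]
  unmasked <- if (is.null(m$weights)) rep(TRUE, n) else !is.na(m$weights[idx])
  keep <- which(marg > 0 & unmasked)
  if (length(keep) < min_bins) return(NULL)
  Rk <- R[keep, keep]
  Rk[is.na(Rk)] <- 0
  C <- suppressWarnings(stats::cor(Rk))
  C[is.na(C)] <- 0
  list(cor = C, keep = keep, idx = idx)
}

#' A/B compartment eigenvector
#'
#' Per chromosome: the leading eigenvector of the Pearson-correlation matrix
#' of the observed/expected map, oriented so that it correlates positively
#' with GC content; positive bins are labelled A, negative B. Chromosomes in
#' `exclude` (default `"4"` and `"Y"`) and chromosomes with fewer than 20
#' unmasked bins are masked.
#'
#' @param m a `contact_matrix` at the compartment resolution (aggregate
#'   first if necessary).
#' @param gc per-bin GC fraction aligned to `m$bins`.
#' @param exclude chromosome names to mask.
#' @return data.frame `chrom`, `start`, `end`, `e1`, `gc`, `label`
#'   (`"A"`/`"B"`/`NA`).
#' @export
compartment_eigenvector <- function(m, gc, exclude = c("4", "Y")) {
  stopifnot(length(gc) == nrow(m$bins))
  oe <- observed_expected(m)
  out <- data.frame(m$bins, e1 = NA_real_, gc = gc, label = NA_character_,
                    stringsAsFactors = FALSE)
  for (ch in unique(m$bins$chrom)) {
    if (ch %in% exclude) next
    cc <- chrom_cor(m, oe, ch)
    if (is.null(cc)) {
      warning("chromosome ", ch, " has too few unmasked bins; masked")
      next
    }
    ev <- eigen(cc$cor, symmetric = TRUE)
    e1 <- ev$vectors[, 1]
    bins_global <- cc$idx[cc$keep]
    gck <- gc[bins_global]
    r <- suppressWarnings(stats::cor(gck, e1))
    if (!is.na(r) && r < 0) e1 <- -e1
    out$e1[bins_global] <- e1
    out$label[bins_global] <- ifelse(e1 > 0, "A", ifelse(e1 < 0, "B", NA))
  }
  out
}

#' Compartment switches between two conditions
#'
#' @param a,b compartment tracks from [compartment_eigenvector()] on the
#'   same bin table.
#' @return list with per-bin `switch` labels (`A->A`, `A->B`, `B->A`,
#'   `B->B`, `masked`) and the genome-wide `fraction` of switched bins
#'   among bins unmasked in both tracks.
#' @export
detect_switches <- function(a, b) {
  if (!identical(a[c("chrom", "start", "end")], b[c("chrom", "start", "end")]))
    stop("bin tables disagree")
  lab <- ifelse(is.na(a$label) | is.na(b$label), "masked",
                paste0(a$label, "->", b$label))
  unmasked <- lab != "masked"
  switched <- lab %in% c("A->B", "B->A")
  list(switch = lab,
       fraction = if (any(unmasked)) sum(switched) / sum(unmasked) else NA)
}

#' Saddle plot and compartmentalisation strength
#'
#' Bins are ranked by eigenvector value (after trimming to the
#' `[trim[1], trim[2]]` quantile interval) into `n_bins` percentile groups;
#' the grid cell (p, q) is the mean intra-chromosomal observed/expected
#' value between bins of groups p and q. Strength is the mean of the two
#' homotypic corner blocks over the mean of the two heterotypic corners
#' (corner edge `n_bins/3`), computed on the nonnormalised grid, so that an
#' uncompartmentalised map gives strength 1. Any display normalisation (for
#' cross-condition comparability) is left to render time and never applied
#' to the statistic.
#'
#' @return list with `matrix` (the `n_bins x n_bins` grid, group 1 = lowest
#'   eigenvector, i.e. strongest B) and `strength`.
#' @export
saddle <- function(m, track, n_bins = 30, trim = c(0.025, 0.975)) {
  oe <- observed_expected(m)
  e1 <- track$e1
  ok <- which(!is.na(e1))
  qs <- stats::quantile(e1[ok], trim, names = FALSE)
  ok <- ok[e1[ok] >= qs[1] & e1[ok] <= qs[2]]
  if (length(ok) < n_bins) stop("fewer unmasked bins than saddle groups")
  grp_all <- rep(NA_integer_, nrow(track))
  grp_all[ok] <- as.integer(cut(rank(e1[ok], ties.method = "first"),
                                breaks = n_bins, labels = FALSE))
  sums <- matrix(0, n_bins, n_bins)
  cnts <- matrix(0, n_bins, n_bins)
  blocks <- chrom_blocks(m$bins)
  for (ch in unique(track$chrom)) {
    idx <- blocks[[ch]]
    g <- grp_all[idx]
    sel <- which(!is.na(g))
    if (length(sel) < 2) next
    R <- cm_dense(oe$matrix, ch, corrected = FALSE)
    C <- R[sel, sel, drop = FALSE]
    gg <- g[sel]
    for (p in unique(gg)) for (q in unique(gg)) {
      block <- C[gg == p, gg == q, drop = FALSE]
      if (p == q) {
        v <- block[upper.tri(block)]
      } else {
        v <- as.vector(block)
      }
      v <- v[!is.na(v)]
      if (!length(v)) next
      sums[p, q] <- sums[p, q] + sum(v)
      cnts[p, q] <- cnts[p, q] + length(v)
    }
  }
  grid <- ifelse(cnts > 0, sums / cnts, NA)
  k <- max(1L, floor(n_bins / 3))
  bb <- mean(grid[1:k, 1:k], na.rm = TRUE)
  aa <- mean(grid[(n_bins - k + 1):n_bins, (n_bins - k + 1):n_bins],
             na.rm = TRUE)
  ab <- mean(grid[1:k, (n_bins - k + 1):n_bins], na.rm = TRUE)
  ba <- mean(grid[(n_bins - k + 1):n_bins, 1:k], na.rm = TRUE)
  list(matrix = grid, strength = mean(c(aa, bb)) / mean(c(ab, ba)))
}
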