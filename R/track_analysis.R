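# Border-centred signal heat maps with assay-specific winsorization
# dialects, rule-based occupancy clustering, Pol II pausing index and PWM
# site counting.

# coverage-weighted mean of a bedGraph-style track over [start, end);
# uncovered positions contribute 0
track_mean <- function(track, chrom, start, end) {
  tt <- track[track$chrom == chrom & track$end > start & track$start < end, ,
              drop = FALSE]
  if (!nrow(tt)) return(0)
  ov <- pmin(tt$end, end) - pmax(tt$start, start)
  sum(tt$value * ov) / (end - start)
}

# per-column means of a track across a fixed window around a centre
window_profile <- function(track, chrom, center, window, ncol) {
  colw <- window / ncol
  starts <- center - window / 2 + (seq_len(ncol) - 1) * colw
  vapply(starts, function(s) track_mean(track, chrom, s, s + colw),
         numeric(1))
}

#' Border-centred signal heat map
#'
#' Signal is extracted in `window` bp around each border centre and binned
#' into `ncol` columns, then winsorised and normalised per dialect:
#' \describe{
#'   \item{chip}{clip at the 5\% quantile of negative values and the 95\%
#'     quantile of positive values; positives scaled to (0, 1]; negatives
#'     displayed as 0.}
#'   \item{dnase}{negative cut-off 0; positive cut-off the 75\% quantile.}
#'   \item{nascent}{as chip, but negatives are additionally scaled to
#'     [-1, 0).}
#' }
#' Rows are ordered by decreasing mean raw signal of `reference` (e.g. a
#' BEAF-32 track) over the same window when supplied.
#'
#' @param track data.frame `chrom`, `start`, `end`, `value`.
#' @param borders border table with `chrom`, `pos`.
#' @param window window width in bp.
#' @param dialect one of `"chip"`, `"dnase"`, `"nascent"`.
#' @param ncol number of heat-map columns.
#' @param reference optional track used only for row ordering.
#' @return list: `matrix` (borders x columns, normalised), `raw` (the
#'   pre-normalisation matrix), `row_order`, `borders`.
#' @export
border_heatmap <- function(track, borders, window = 5000,
                           dialect = c("chip", "dnase", "nascent"),
                           ncol = 50, reference = NULL) {
  dialect <- match.arg(dialect)
  raw <- t(vapply(seq_len(nrow(borders)), function(k)
    window_profile(track, borders$chrom[k], borders$pos[k], window, ncol),
    numeric(ncol)))
  if (all(raw == 0)) warning("track is empty over every border window")
  v <- as.vector(raw)
  pos <- v[v > 0]; neg <- v[v < 0]
  hi <- if (length(pos))
    stats::quantile(pos, if (dialect == "dnase") 0.75 else 0.95,
                    names = FALSE) else 1
  lo <- if (dialect == "dnase" || !length(neg)) 0
        else stats::quantile(neg, 0.05, names = FALSE)
  M <- pmin(raw, hi)
  M <- pmax(M, lo)
  norm <- M
  norm[M > 0] <- M[M > 0] / hi
  if (dialect == "nascent" && lo < 0) {
    norm[M < 0] <- M[M < 0] / abs(lo)
  } else {
    norm[M < 0] <- 0
  }
  row_order <- seq_len(nrow(borders))
  if (!is.null(reference)) {
    refsum <- vapply(seq_len(nrow(borders)), function(k)
      track_mean(reference, borders$chrom[k],
                 borders$pos[k] - window / 2, borders$pos[k] + window / 2),
      numeric(1))
    row_order <- order(refsum, decreasing = TRUE)
  }
  list(matrix = norm[row_order, , drop = FALSE], raw = raw,
       row_order = row_order, borders = borders[row_order, , drop = FALSE])
}

#' Rule-based occupancy clustering of borders
#'
#' For each (border, dataset), the quartiles Q1 <= Q2 <= Q3 of the raw
#' per-column signal in the window are compared with a cut-off defined as
#' the median of the positive window sums pooled across all datasets
#' (recomputed per input collection). Classes: `no` (Q2 and Q3 negative),
#' `extra_low` (Q2 negative, Q3 not), `low` (quartiles within [0, cutoff]),
#' `medium` (Q3 above cutoff), `high` (Q2 above cutoff), `extra_high`
#' (Q1 at or above cutoff). Zeros fall through to `low`; values exactly at
#' the cut-off go to the lower class.
#'
#' @param raw_matrices named list of raw border-window matrices (the `raw`
#'   element of [border_heatmap()] output), one per dataset, same row order.
#' @return data.frame `border`, `dataset`, `window_sum`, `class`, with the
#'   cut-off as attribute `cutoff`.
#' @export
cluster_occupancy <- function(raw_matrices) {
  stopifnot(is.list(raw_matrices), !is.null(names(raw_matrices)))
  sums <- unlist(lapply(raw_matrices, rowSums))
  possums <- sums[sums > 0]
  cutoff <- if (length(possums)) stats::median(possums) else 0
  out <- list()
  for (ds in names(raw_matrices)) {
    M <- raw_matrices[[ds]]
    for (b in seq_len(nrow(M))) {
      x <- M[b, ]
      x <- x[is.finite(x)]
      if (!length(x)) {
        warning("window with no data at border ", b, " dataset ", ds)
        cls <- "no"
      } else {
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
        cls <- if (q[2] < 0 && q[3] < 0) "no"
          else if (q[2] < 0) "extra_low"
          else if (q[1] > cutoff) "extra_high"
          else if (q[2] > cutoff) "high"
          else if (q[3] > cutoff) "medium"
          else "low"
      }
      out[[length(out) + 1L]] <- data.frame(
        border = b, dataset = ds, window_sum = sum(M[b, ]), class = cls,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "cutoff") <- cutoff
  res
}

#' Pol II pausing index
#'
#' Ratio of the mean Pol II signal over the promoter (200 bp upstream to
#' 50 bp downstream of the TSS) to the mean over the gene body (50 bp
#' upstream of the TSS to the gene end), both strand-aware. Indices of 0 or
#' below, or with an undefined body mean, are discarded (`NA`).
#'
#' @param polII signal track (`chrom`, `start`, `end`, `value`).
#' @param genes gene table with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return named numeric vector of pausing indices (NA where discarded).
#' @export
pausing_index <- function(polII, genes) {
  idx <- vapply(seq_len(nrow(genes)), function(k) {
    plus <- genes$strand[k] == "+"
    tss <- if (plus) genes$start[k] else genes$end[k]
    if (plus) {
      prom <- c(tss - 200, tss + 50)
      body <- c(tss - 50, genes$end[k])
    } else {
      prom <- c(tss - 50, tss + 200)
      body <- c(genes$start[k], tss + 50)
    }
    if (body[2] <= body[1]) {
      warning("zero-length body for gene ", genes$gene_id[k])
      return(NA_real_)
    }
    pm <- track_mean(polII, genes$chrom[k], prom[1], prom[2])
    bm <- track_mean(polII, genes$chrom[k], body[1], body[2])
    if (bm <= 0) return(NA_real_)
    r <- pm / bm
    if (r <= 0) NA_real_ else r
  }, numeric(1))
  names(idx) <- genes$gene_id
  idx
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# per-offset PWM scores along one strand of an encoded sequence; windows
# containing N (code NA) give NA
pwm_scan_strand <- function(code, pwm) {
  L <- ncol(pwm)
  n <- length(code) - L + 1
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (l in seq_len(L)) {
    v <- pwm[, l][code[seq_len(n) + l - 1L]]
    sc <- sc + v
  }
  sc
}

#' Count PWM sites above a relative-score threshold
#'
#' Scans both strands of `seq` (restricted to `region` +/- `flank` when a
#' region is given). A site counts iff its additive score is at least
#' `min_score + threshold_fraction * (max_score - min_score)`. Overlapping
#' sites each count; windows containing an ambiguous base are skipped.
#'
#' @param seq DNA sequence (character or `DNAString`).
#' @param pwm 4 x L numeric score matrix with rownames `A`, `C`, `G`, `T`.
#' @param region optional `c(start, end)` (0-based, half-open) within `seq`.
#' @param flank bp added on both sides of `region`.
#' @param threshold_fraction relative score threshold in [0, 1].
#' @export
count_pwm_sites <- function(seq, pwm, region = NULL, flank = 2000,
                            threshold_fraction = 0.85) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4,
            threshold_fraction >= 0, threshold_fraction <= 1)
  if (!identical(rownames(pwm), c("A", "C", "G", "T")))
    stop("pwm rownames must be A, C, G, T")
  s <- toupper(as.character(seq))
  if (!is.null(region)) {
    lo <- max(0, region[1] - flank)
    hi <- min(nchar(s), region[2] + flank)
    s <- substr(s, lo + 1, hi)
  }
  max_score <- sum(apply(pwm, 2, max))
  min_score <- sum(apply(pwm, 2, min))
  thr <- min_score + threshold_fraction * (max_score - min_score)
  count_strand <- function(str) {
    code <- DNA_CODE[strsplit(str, "")[[1]]]
    sc <- pwm_scan_strand(code, pwm)
    sum(!is.na(sc) & sc >= thr - 1e-9)
  }
  count_strand(s) + count_strand(revcomp_chr(s))
}

#' Mann-Whitney U test between two groups of border signals
#'
#' Exact when both groups are small and untied; normal approximation with
#' tie correction otherwise. All-tied inputs give p = 1.
#' @export
group_signal_test <- function(a_values, b_values) {
  stopifnot(length(a_values) >= 1, length(b_values) >= 1)
  if (length(unique(c(a_values, b_values))) == 1) return(1)
  ties <- anyDuplicated(c(a_values, b_values)) > 0
  exact <- !ties && length(a_values) <= 50 && length(b_values) <= 50
  suppressWarnings(
    stats::wilcox.test(a_values, b_values, alternative = "two.sided",
                       exact = exact, correct = !exact)$p.value)
}
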