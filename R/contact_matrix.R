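# Binned Hi-C contact matrices: construction, I/O, balancing and transforms.
#
# A contact matrix is stored as a bin table (BED-like, 0-based half-open,
# sorted and tiling each chromosome) plus an upper-triangle pixel list
# (1-based bin indices internally; 0-based in the text format). Symmetry is
# implied: only pixels with i <= j are kept.

#' Construct a contact matrix
#'
#' @param bins data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), sorted and non-overlapping within each chromosome.
#' @param pixels data.frame with columns `i`, `j`, `count` (1-based bin
#'   indices). Lower-triangle records are folded into the upper triangle by
#'   summation; duplicate pixels are summed.
#' @param weights optional per-bin balancing factors; `NA` marks masked bins.
#' @param balanced logical; whether `weights` satisfy the equal-marginal
#'   contract.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, pixels, weights = NULL, balanced = FALSE) {
  stopifnot(is.data.frame(bins), all(c("chrom", "start", "end") %in% names(bins)))
  bins <- data.frame(chrom = as.character(bins$chrom),
                     start = as.integer(bins$start),
                     end = as.integer(bins$end),
                     stringsAsFactors = FALSE)
  if (any(bins$start < 0) || any(bins$start >= bins$end))
    stop("invalid bin table: need 0 <= start < end")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE))
      stop("bins not sorted within chromosome ", ch)
    if (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)]))
      stop("bins not adjacent within chromosome ", ch)
  }
  n <- nrow(bins)
  if (nrow(pixels)) {
    pixels <- data.frame(i = as.integer(pixels$i), j = as.integer(pixels$j),
                         count = as.numeric(pixels$count))
    if (any(pixels$i < 1L) || any(pixels$j < 1L) ||
        any(pixels$i > n) || any(pixels$j > n))
      stop("pixel bin index out of range (1..", n, ")")
    if (any(pixels$count < 0)) stop("negative pixel count")
    flip <- pixels$i > pixels$j
    if (any(flip)) {
      tmp <- pixels$i[flip]
      pixels$i[flip] <- pixels$j[flip]
      pixels$j[flip] <- tmp
    }
    key <- paste(pixels$i, pixels$j)
    if (anyDuplicated(key)) {
      agg <- rowsum(pixels$count, key, reorder = FALSE)
      ij <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
      pixels <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                           count = as.numeric(agg[, 1]))
    }
    pixels <- pixels[order(pixels$i, pixels$j), , drop = FALSE]
    rownames(pixels) <- NULL
  } else {
    pixels <- data.frame(i = integer(), j = integer(), count = numeric())
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == n)
    if (any(!is.na(weights) & weights <= 0)) stop("weights must be positive or NA")
  }
  structure(list(bins = bins, pixels = pixels, weights = weights,
                 balanced = balanced, total_count = sum(pixels$count)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", nrow(x$bins), "bins,", nrow(x$pixels), "pixels, total",
      format(x$total_count, big.mark = ","),
      if (x$balanced) "(balanced)\n" else "(raw)\n")
  invisible(x)
}

#' Uniform bin table for a genome
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param resolution bin width in bp; the last bin of each chromosome may be
#'   shorter.
#' @export
bin_genome <- function(chrom_lengths, resolution) {
  stopifnot(resolution >= 1, length(chrom_lengths) >= 1,
            !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = as.integer(resolution))
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + as.integer(resolution), as.integer(len)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

bin_width_median <- function(bins) stats::median(bins$end - bins$start)

# per-chromosome index ranges of a bin table
chrom_blocks <- function(bins) {
  idx <- seq_len(nrow(bins))
  split(idx, factor(bins$chrom, levels = unique(bins$chrom)))
}

#' Read a contact matrix from pixel + bin-table text files
#'
#' The pixel file is whitespace-delimited `bin_i bin_j count` with 0-based
#' bin indices; the bin table is BED-like (`chrom start end [bin_id]`).
#' Lower-triangle records are folded into the upper triangle by summation.
#'
#' @param path pixel file.
#' @param bin_table_path bin table file.
#' @export
read_matrix <- function(path, bin_table_path) {
  bins <- utils::read.table(bin_table_path, header = FALSE,
                            stringsAsFactors = FALSE)
  names(bins)[1:3] <- c("chrom", "start", "end")
  px <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) {
      if (length(readLines(path, warn = FALSE)) == 0)
        return(data.frame(V1 = integer(), V2 = integer(), V3 = numeric()))
      stop(e)
    })
  if (nrow(px)) {
    if (ncol(px) < 3) stop("pixel file needs 3 columns (bin_i bin_j count)")
    bad <- which(px[[1]] < 0 | px[[2]] < 0 |
                 px[[1]] >= nrow(bins) | px[[2]] >= nrow(bins))
    if (length(bad))
      stop("pixel file line ", bad[1], ": bin index out of range")
    bad <- which(px[[3]] < 0)
    if (length(bad))
      stop("pixel file line ", bad[1], ": negative count")
  }
  contact_matrix(bins,
                 data.frame(i = px[[1]] + 1L, j = px[[2]] + 1L,
                            count = px[[3]]))
}

#' Write a contact matrix as pixel + bin-table text files
#'
#' Inverse of [read_matrix()]; indices written 0-based.
#' @export
write_matrix <- function(m, path, bin_table_path) {
  stopifnot(inherits(m, "contact_matrix"))
  utils::write.table(
    data.frame(m$bins$chrom, m$bins$start, m$bins$end,
               seq_len(nrow(m$bins)) - 1L),
    bin_table_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(m$pixels$i - 1L, m$pixels$j - 1L, m$pixels$count),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Digest a genome into restriction-fragment bins
#'
#' Cut sites are placed at every occurrence of `motif`. Fragments shorter
#' than `min_gap` are absorbed into the following fragment (left to right; a
#' trailing short fragment merges backward); fragments longer than `max_gap`
#' are split into equal pieces each at most `max_gap` bp.
#'
#' @param fasta path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param motif non-degenerate recognition sequence, e.g. `"GATC"` for DpnII.
#' @param min_gap,max_gap fragment length bounds in bp.
#' @return a bin table (`chrom`, `start`, `end`).
#' @export
digest_genome <- function(fasta, motif = "GATC", min_gap = 150, max_gap = 1000) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  if (!grepl("^[ACGT]+$", motif))
    stop("motif must be a non-degenerate DNA string")
  out <- lapply(seq_along(seqs), function(k) {
    ch <- names(seqs)[k]
    len <- Biostrings::width(seqs)[k]
    hits <- Biostrings::matchPattern(motif, seqs[[k]])
    cuts <- BiocGenerics::start(hits) - 1L   # 0-based cut coordinates
    cuts <- cuts[cuts > 0 & cuts < len]
    if (!length(cuts))
      warning("motif ", motif, " absent from chromosome ", ch)
    bounds <- c(0L, cuts, len)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    # absorb short fragments forward
    ms <- integer(0); me <- integer(0)
    cur_s <- starts[1]; cur_e <- ends[1]
    for (f in seq_along(starts)[-1]) {
      if (cur_e - cur_s < min_gap) {
        cur_e <- ends[f]
      } else {
        ms <- c(ms, cur_s); me <- c(me, cur_e)
        cur_s <- starts[f]; cur_e <- ends[f]
      }
    }
    if (cur_e - cur_s < min_gap && length(ms)) {
      # trailing short fragment merges backward
      me[length(me)] <- cur_e
    } else {
      ms <- c(ms, cur_s); me <- c(me, cur_e)
    }
    # split overlong fragments into equal pieces
    ss <- integer(0); ee <- integer(0)
    for (f in seq_along(ms)) {
      w <- me[f] - ms[f]
      if (w > max_gap) {
        npc <- ceiling(w / max_gap)
        cuts2 <- ms[f] + as.integer(round(w * seq_len(npc - 1) / npc))
        b2 <- c(ms[f], cuts2, me[f])
        ss <- c(ss, b2[-length(b2)]); ee <- c(ee, b2[-1])
      } else {
        ss <- c(ss, ms[f]); ee <- c(ee, me[f])
      }
    }
    data.frame(chrom = ch, start = ss, end = ee, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# raw (or corrected) marginals from the upper-triangle pixel list; the
# diagonal contributes once.
cm_marginals <- function(m, corrected = FALSE) {
  n <- nrow(m$bins)
  cnt <- m$pixels$count
  if (corrected && !is.null(m$weights)) {
    w <- ifelse(is.na(m$weights), 0, m$weights)
    cnt <- cnt * w[m$pixels$i] * w[m$pixels$j]
  }
  marg <- numeric(n)
  a1 <- rowsum(cnt, m$pixels$i, reorder = FALSE)
  marg[as.integer(rownames(a1))] <- a1[, 1]
  off <- m$pixels$i != m$pixels$j
  if (any(off)) {
    a2 <- rowsum(cnt[off], m$pixels$j[off], reorder = FALSE)
    idx <- as.integer(rownames(a2))
    marg[idx] <- marg[idx] + a2[, 1]
  }
  marg
}

#' Iteratively balance a contact matrix (ICE)
#'
#' Computes per-bin weights `b_i` such that the corrected counts
#' `c_ij * b_i * b_j` have near-equal marginals over unmasked bins. Bins with
#' zero raw marginal, or a marginal below the 2nd percentile of the nonzero
#' marginals, are masked (`NA` weight) before iteration.
#'
#' @param m a `contact_matrix`.
#' @param max_iter maximum number of iterations.
#' @param tol target coefficient of variation of the corrected marginals.
#' @param mask_percentile marginal-percentile below which bins are masked in
#'   addition to zero-marginal bins. Zero by default: a percentile cut (for
#'   sparse or artefact-laden real libraries) also removes genuinely
#'   depleted bins such as strong TAD borders, which are the signal here.
#' @return the matrix with `weights` filled in and `balanced = TRUE`.
#' @export
balance <- function(m, max_iter = 500, tol = 5e-3, mask_percentile = 0) {
  stopifnot(inherits(m, "contact_matrix"), nrow(m$pixels) >= 1)
  n <- nrow(m$bins)
  raw_marg <- cm_marginals(m)
  masked <- raw_marg == 0
  if (mask_percentile > 0) {
    lo <- stats::quantile(raw_marg[raw_marg > 0], mask_percentile,
                          names = FALSE)
    masked <- masked | raw_marg < lo
  }
  b <- ifelse(masked, NA_real_, 1)
  i <- m$pixels$i; j <- m$pixels$j; cnt <- m$pixels$count
  keep <- !masked[i] & !masked[j]
  i <- i[keep]; j <- j[keep]; cnt <- cnt[keep]
  off <- i != j
  # marginals are equalised within each chromosome: with no
  # inter-chromosomal pixels the components are disconnected and would
  # otherwise converge to different constants
  chrom_of <- rep(seq_along(chrom_blocks(m$bins)),
                  vapply(chrom_blocks(m$bins), length, integer(1)))
  cv <- Inf
  for (it in seq_len(max_iter)) {
    cc <- cnt * b[i] * b[j]
    marg <- numeric(n)
    a1 <- rowsum(cc, i, reorder = FALSE)
    marg[as.integer(rownames(a1))] <- a1[, 1]
    if (any(off)) {
      a2 <- rowsum(cc[off], j[off], reorder = FALSE)
      idx <- as.integer(rownames(a2))
      marg[idx] <- marg[idx] + a2[, 1]
    }
    cvs <- vapply(unique(chrom_of), function(ch) {
      v <- marg[chrom_of == ch & !masked]
      if (length(v) < 2 || mean(v) == 0) return(0)
      stats::sd(v) / mean(v)
    }, numeric(1))
    cv <- max(cvs)
    if (is.finite(cv) && cv <= tol) break
    mu_chrom <- vapply(unique(chrom_of), function(ch) {
      v <- marg[chrom_of == ch & !masked]
      if (length(v)) mean(v) else 1
    }, numeric(1))
    mu <- mu_chrom[chrom_of]
    adj <- ifelse(masked | marg == 0 | mu == 0, 1, marg / mu)
    b <- b / adj
  }
  if (!is.finite(cv) || cv > tol)
    stop(sprintf("balancing did not converge in %d iterations (CV = %.3g)",
                 max_iter, cv))
  out <- m
  out$weights <- b
  out$balanced <- TRUE
  out
}

#' Binomially down-sample a contact matrix
#'
#' Each pixel count is replaced by a Binomial(count, fraction) draw,
#' emulating retaining a random subset of reads.
#'
#' @param fraction retained fraction in (0, 1].
#' @param seed RNG seed (required; down-sampling is only meaningful
#'   reproducibly).
#' @export
downsample <- function(m, fraction, seed) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(m)
  out <- m
  set.seed(seed)
  out$pixels$count <- stats::rbinom(nrow(m$pixels),
                                    size = as.integer(round(m$pixels$count)),
                                    prob = fraction)
  out$pixels <- out$pixels[out$pixels$count > 0, , drop = FALSE]
  rownames(out$pixels) <- NULL
  out$total_count <- sum(out$pixels$count)
  out$weights <- NULL
  out$balanced <- FALSE
  out
}

# Dense corrected (or raw) matrix for one chromosome; masked bins are rows
# and columns of NA when corrected.
cm_dense <- function(m, chrom = NULL, corrected = TRUE) {
  blocks <- chrom_blocks(m$bins)
  if (is.null(chrom)) chrom <- names(blocks)[1]
  idx <- blocks[[chrom]]
  if (is.null(idx)) stop("unknown chromosome ", chrom)
  n <- length(idx)
  off <- idx[1] - 1L
  sel <- m$pixels$i >= idx[1] & m$pixels$i <= idx[n] &
         m$pixels$j >= idx[1] & m$pixels$j <= idx[n]
  px <- m$pixels[sel, , drop = FALSE]
  M <- matrix(0, n, n)
  ii <- px$i - off; jj <- px$j - off
  cnt <- px$count
  if (corrected && !is.null(m$weights)) {
    w <- m$weights[idx]
    cnt <- cnt * w[ii] * w[jj]
  }
  M[cbind(ii, jj)] <- cnt
  M[cbind(jj, ii)] <- cnt
  if (corrected && !is.null(m$weights)) {
    bad <- is.na(m$weights[idx])
    M[bad, ] <- NA_real_
    M[, bad] <- NA_real_
  }
  M
}

#' Expected contact decay and observed/expected transform
#'
#' The expected count at diagonal offset `d` is the mean corrected count over
#' all intra-chromosomal bin pairs at that offset (zeros included). Returns
#' the ratio matrix (same pixel structure, values = observed/expected) and
#' the per-chromosome expected profile. Inter-chromosomal pixels are
#' excluded.
#'
#' @param m a `contact_matrix`, balanced or raw (recorded in the result).
#' @return list with elements `matrix` (a `contact_matrix` whose counts are
#'   O/E ratios), `expected` (data.frame `chrom`, `offset`, `expected`) and
#'   `corrected` (logical flag).
#' @export
observed_expected <- function(m) {
  blocks <- chrom_blocks(m$bins)
  corrected <- m$balanced && !is.null(m$weights)
  ratios <- numeric(nrow(m$pixels))
  keepvec <- logical(nrow(m$pixels))
  prof <- list()
  for (ch in names(blocks)) {
    idx <- blocks[[ch]]
    rng <- range(idx)
    sel <- which(m$pixels$i >= rng[1] & m$pixels$i <= rng[2] &
                 m$pixels$j >= rng[1] & m$pixels$j <= rng[2])
    if (!length(idx)) next
    n <- length(idx)
    px <- m$pixels[sel, , drop = FALSE]
    cnt <- px$count
    if (corrected) {
      w <- m$weights
      cnt <- cnt * w[px$i] * w[px$j]
    }
    d <- px$j - px$i
    ok <- !is.na(cnt)
    # number of pairs at each offset, excluding masked bins
    unmask <- if (corrected) !is.na(m$weights[idx]) else rep(TRUE, n)
    npairs <- vapply(0:(n - 1), function(dd) {
      a <- which(unmask[seq_len(n - dd)] & unmask[seq_len(n - dd) + dd])
      length(a)
    }, numeric(1))
    sums <- numeric(n)
    agg <- rowsum(cnt[ok], d[ok], reorder = FALSE)
    sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    expd <- ifelse(npairs > 0, sums / npairs, NA_real_)
    prof[[ch]] <- data.frame(chrom = ch, offset = 0:(n - 1), expected = expd,
                             stringsAsFactors = FALSE)
    e_at <- expd[d + 1L]
    r <- ifelse(!is.na(cnt) & !is.na(e_at) & e_at > 0, cnt / e_at, NA_real_)
    ratios[sel] <- r
    keepvec[sel] <- !is.na(r)
  }
  out <- m
  out$pixels <- data.frame(i = m$pixels$i[keepvec], j = m$pixels$j[keepvec],
                           count = ratios[keepvec])
  out$weights <- NULL
  out$total_count <- sum(out$pixels$count)
  list(matrix = out, expected = do.call(rbind, prof), corrected = corrected)
}

#' Aggregate a contact matrix to a uniform resolution
#'
#' Counts are summed into uniform bins of the requested width.
#' @export
aggregate_matrix <- function(m, resolution) {
  lens <- vapply(chrom_blocks(m$bins),
                 function(idx) max(m$bins$end[idx]), numeric(1))
  newbins <- bin_genome(lens, resolution)
  # map old bins to new by midpoint
  mid <- (m$bins$start + m$bins$end) / 2
  map <- integer(nrow(m$bins))
  for (ch in unique(m$bins$chrom)) {
    old <- which(m$bins$chrom == ch)
    new <- which(newbins$chrom == ch)
    map[old] <- new[pmin(length(new), floor(mid[old] / resolution) + 1L)]
  }
  contact_matrix(newbins,
                 data.frame(i = map[m$pixels$i], j = map[m$pixels$j],
                            count = m$pixels$count))
}

#' Per-bin-pair log2 fold change between two conditions
#'
#' Counts are aggregated to `resolution`, library-size normalised by total
#' count, and compared as
#' `log2((a + pseudocount)/s_a) - log2((b + pseudocount)/s_b)`.
#' A simplified, size-factor-normalised alternative to a full dispersion
#' model; adequate for visual comparison of maps.
#'
#' @return data.frame `i`, `j`, `log2fc` on the aggregated bin table, plus
#'   attribute `bins`.
#' @export
bin_log2fc <- function(a, b, resolution = 5000, pseudocount = 1) {
  aa <- aggregate_matrix(a, resolution)
  bb <- aggregate_matrix(b, resolution)
  if (!identical(aa$bins, bb$bins))
    stop("bin tables disagree after aggregation")
  key_a <- paste(aa$pixels$i, aa$pixels$j)
  key_b <- paste(bb$pixels$i, bb$pixels$j)
  keys <- union(key_a, key_b)
  ca <- numeric(length(keys)); cb <- numeric(length(keys))
  ca[match(key_a, keys)] <- aa$pixels$count
  cb[match(key_b, keys)] <- bb$pixels$count
  sa <- aa$total_count; sb <- bb$total_count
  ij <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    log2fc = log2((ca + pseudocount) / sa) -
                             log2((cb + pseudocount) / sb))
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  attr(out, "bins") <- aa$bins
  out
}
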