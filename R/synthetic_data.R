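# Synthetic Hi-C data with planted ground truth: power-law distance decay,
# TAD blocks with tunable border insulation, focal loop peaks, checkerboard
# compartments with a GC covariate, ChIP-like tracks and DEG tables.
#
# Every generator is deterministic under a fixed seed and returns its
# ground truth alongside the data.

#' Specification of a synthetic Hi-C experiment
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param resolution uniform bin width (bp).
#' @param decay_exponent alpha in contact probability ~ (1 + d)^-alpha
#'   (d in bins).
#' @param borders data.frame `chrom`, `pos`, `depth`: planted TAD borders;
#'   `depth` is the fold reduction of cross-border contacts (> 1).
#' @param loops data.frame `chrom`, `pos1`, `pos2`, `enrichment`: focal
#'   peaks as 2D Gaussian bumps (sigma = 1 bin) of the given fold
#'   enrichment (> 1).
#' @param compartments `NULL`, or list with `block_size` (bp per A/B
#'   block), `factor` (within- over between-compartment contact ratio,
#'   >= 1) and optionally `gc_noise` (sd of the GC covariate, default
#'   0.02).
#' @param depth expected total contact count over the genome.
#' @param seed RNG seed.
#' @export
synthetic_spec <- function(chrom_lengths, resolution = 5000,
                           decay_exponent = 1, borders = NULL, loops = NULL,
                           compartments = NULL, depth = 1e6, seed = 1) {
  stopifnot(depth > 0, decay_exponent > 0, !is.null(names(chrom_lengths)))
  if (!is.null(borders)) {
    stopifnot(all(c("chrom", "pos", "depth") %in% names(borders)),
              all(borders$depth > 1))
    borders <- borders[order(borders$chrom, borders$pos), , drop = FALSE]
    rownames(borders) <- NULL
  }
  if (!is.null(loops))
    stopifnot(all(c("chrom", "pos1", "pos2", "enrichment") %in% names(loops)),
              all(loops$enrichment > 1))
  if (!is.null(compartments)) {
    stopifnot(is.list(compartments),
              compartments$factor >= 1, compartments$block_size > 0)
    if (is.null(compartments$gc_noise)) compartments$gc_noise <- 0.02
  }
  structure(list(chrom_lengths = chrom_lengths, resolution = resolution,
                 decay_exponent = decay_exponent, borders = borders,
                 loops = loops, compartments = compartments, depth = depth,
                 seed = seed),
            class = "synthetic_spec")
}

compartment_labels <- function(len, resolution, block_size) {
  n <- ceiling(len / resolution)
  mid <- (seq_len(n) - 0.5) * resolution
  ifelse(floor(mid / block_size) %% 2 == 0, "A", "B")
}

# expected intensity matrix for one chromosome (unscaled)
chrom_lambda <- function(spec, ch) {
  res <- spec$resolution
  n <- ceiling(spec$chrom_lengths[[ch]] / res)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- (1 + D)^(-spec$decay_exponent)
  if (!is.null(spec$borders)) {
    bb <- spec$borders[spec$borders$chrom == ch, , drop = FALSE]
    if (nrow(bb)) {
      # a cross-border contact is attenuated by the strongest border it
      # crosses (insulation is local; distant contacts are not damped by
      # every intervening border, which would erase long-range structure)
      supp <- matrix(1, n, n)
      for (k in seq_len(nrow(bb))) {
        at <- min(n, floor(bb$pos[k] / res) + 1L)  # first bin after border
        if (at > 1) {
          left <- 1:(at - 1); right <- at:n
          supp[left, right] <- pmax(supp[left, right], bb$depth[k])
          supp[right, left] <- t(supp[left, right])
        }
      }
      lam <- lam / supp
    }
  }
  lab <- NULL
  if (!is.null(spec$compartments)) {
    lab <- compartment_labels(spec$chrom_lengths[[ch]], res,
                              spec$compartments$block_size)
    same <- outer(lab, lab, "==")
    lam <- lam * ifelse(same, spec$compartments$factor, 1)
  }
  if (!is.null(spec$loops)) {
    ll <- spec$loops[spec$loops$chrom == ch, , drop = FALSE]
    if (nrow(ll)) {
      ii <- matrix(seq_len(n), n, n)
      jj <- t(ii)
      for (k in seq_len(nrow(ll))) {
        b1 <- floor(ll$pos1[k] / res) + 1
        b2 <- floor(ll$pos2[k] / res) + 1
        bump <- exp(-((ii - b1)^2 + (jj - b2)^2) / 2) +
                exp(-((ii - b2)^2 + (jj - b1)^2) / 2)
        lam <- lam * (1 + (ll$enrichment[k] - 1) * pmin(bump, 1))
      }
    }
  }
  list(lambda = lam, labels = lab, n = n)
}

#' Simulate a contact matrix with planted structure
#'
#' Expected intensity is the depth-scaled product of power-law decay, TAD
#' block factors, compartment checkerboard factor and loop Gaussian bumps;
#' counts are Poisson draws. Returns the matrix together with its ground
#' truth (planted borders, loops, compartment labels, GC covariate).
#'
#' @param spec a [synthetic_spec()].
#' @param scale optional intensity scale; by default chosen so the expected
#'   total equals `spec$depth`. [simulate_condition_pair()] passes the WT
#'   scale to the edited condition so unedited pixels keep identical
#'   intensities.
#' @return list `matrix` (a `contact_matrix`) and `truth` (list with
#'   `borders`, `loops`, `compartments`, `gc`, `scale`, `spec`).
#' @export
simulate_matrix <- function(spec, scale = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  res <- spec$resolution
  bins <- bin_genome(spec$chrom_lengths, res)
  lambdas <- list(); labels <- list()
  total_unscaled <- 0
  for (ch in names(spec$chrom_lengths)) {
    cl <- chrom_lambda(spec, ch)
    lambdas[[ch]] <- cl$lambda
    labels[[ch]] <- cl$labels
    ut <- cl$lambda[upper.tri(cl$lambda, diag = TRUE)]
    total_unscaled <- total_unscaled + sum(ut)
  }
  if (is.null(scale)) scale <- spec$depth / total_unscaled
  px <- list()
  offset <- 0L
  gc <- numeric(0)
  for (ch in names(spec$chrom_lengths)) {
    lam <- lambdas[[ch]] * scale
    n <- nrow(lam)
    ut <- which(upper.tri(lam, diag = TRUE), arr.ind = TRUE)
    # Poisson by inversion: one uniform per pixel, so condition pairs built
    # from an edited layout share the noise of every unedited pixel
    cnt <- stats::qpois(stats::runif(nrow(ut)), lam[ut])
    keep <- cnt > 0
    px[[ch]] <- data.frame(i = ut[keep, 1] + offset,
                           j = ut[keep, 2] + offset, count = cnt[keep])
    lab <- labels[[ch]]
    gnoise <- if (!is.null(spec$compartments)) spec$compartments$gc_noise
              else 0.02
    gch <- 0.4 + (if (is.null(lab)) 0 else 0.1 * (lab == "A")) +
      stats::rnorm(n, 0, gnoise)
    gc <- c(gc, pmin(pmax(gch, 0.05), 0.95))
    offset <- offset + n
  }
  m <- contact_matrix(bins, do.call(rbind, px))
  comp <- if (!is.null(spec$compartments))
    data.frame(bins, label = unlist(labels), stringsAsFactors = FALSE)
  else NULL
  truth <- list(borders = spec$borders, loops = spec$loops,
                compartments = comp, gc = gc, scale = scale, spec = spec)
  list(matrix = m, truth = truth)
}

#' Simulate a WT / knockdown condition pair with scripted border edits
#'
#' The knockdown matrix is regenerated from an edited layout using the same
#' seed stream, so unedited structure is shared. Edits reference planted
#' borders by chromosome and position:
#' \describe{
#'   \item{delete}{remove the border (intended status `lost`).}
#'   \item{shift}{move by `value` bp (`fuzzy` if within `fuzzy_tol`, else
#'     `lost` plus a `new` border at the shifted position).}
#'   \item{weaken}{set depth to `value` (`weakened`).}
#'   \item{add}{plant a new border of depth `value` at `pos` (`new`).}
#' }
#'
#' @param spec a [synthetic_spec()] (the WT layout).
#' @param edits data.frame `type`, `chrom`, `pos`, `value`.
#' @param fuzzy_tol displacement bound separating fuzzy from lost+new.
#' @return list `wt`, `kd` (each as [simulate_matrix()] output) and
#'   `truth`: data.frame `chrom`, `wt_pos`, `kd_pos`, `status`.
#' @export
simulate_condition_pair <- function(spec, edits = NULL, fuzzy_tol = 2000) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bb <- spec$borders
  if (is.null(bb)) bb <- data.frame(chrom = character(), pos = numeric(),
                                    depth = numeric())
  status <- data.frame(chrom = bb$chrom, wt_pos = bb$pos, kd_pos = bb$pos,
                       status = rep("maintained", nrow(bb)),
                       stringsAsFactors = FALSE)
  kd_borders <- bb
  kd_loops <- spec$loops
  if (!is.null(edits) && nrow(edits)) {
    for (k in seq_len(nrow(edits))) {
      e <- edits[k, ]
      if (e$type == "add") {
        kd_borders <- rbind(kd_borders,
                            data.frame(chrom = e$chrom, pos = e$pos,
                                       depth = e$value))
        status <- rbind(status,
                        data.frame(chrom = e$chrom, wt_pos = NA,
                                   kd_pos = e$pos, status = "new"))
        next
      }
      if (e$type == "delete_loop") {
        hit <- which(kd_loops$chrom == e$chrom & kd_loops$pos1 == e$pos)
        if (!length(hit)) stop("edit references unknown loop at ", e$pos)
        kd_loops <- kd_loops[-hit[1], , drop = FALSE]
        next
      }
      hit <- which(kd_borders$chrom == e$chrom & kd_borders$pos == e$pos)
      if (!length(hit))
        stop("edit references unknown border at ", e$chrom, ":", e$pos)
      hit <- hit[1]
      si <- which(status$chrom == e$chrom & !is.na(status$wt_pos) &
                  status$wt_pos == e$pos)[1]
      if (e$type == "delete") {
        kd_borders <- kd_borders[-hit, , drop = FALSE]
        status$kd_pos[si] <- NA
        status$status[si] <- "lost"
      } else if (e$type == "shift") {
        newpos <- kd_borders$pos[hit] + e$value
        kd_borders$pos[hit] <- newpos
        status$kd_pos[si] <- newpos
        if (abs(e$value) <= fuzzy_tol) {
          status$status[si] <- "fuzzy"
        } else {
          status$status[si] <- "lost"
          status$kd_pos[si] <- NA
          status <- rbind(status,
                          data.frame(chrom = e$chrom, wt_pos = NA,
                                     kd_pos = newpos, status = "new"))
        }
      } else if (e$type == "weaken") {
        kd_borders$depth[hit] <- e$value
        status$status[si] <- "weakened"
      } else stop("unknown edit type ", e$type)
    }
  }
  kd_spec <- spec
  kd_spec$borders <- if (nrow(kd_borders))
    kd_borders[order(kd_borders$chrom, kd_borders$pos), , drop = FALSE]
  else NULL
  kd_spec$loops <- kd_loops
  wt <- simulate_matrix(spec)
  kd <- simulate_matrix(kd_spec, scale = wt$truth$scale)
  rownames(status) <- NULL
  list(wt = wt, kd = kd, truth = status)
}

#' Simulate ChIP-like signal tracks and peak sets at borders
#'
#' Gaussian bumps of amplitude `snr * noise_sd` at the selected borders over
#' Gaussian noise, binned as a bedGraph track; the peak set records the bump
#' footprints. With `divergent = TRUE`, opposite-sign bumps flank each
#' border (a nascent-transcription-like pattern).
#'
#' @param borders data.frame `chrom`, `pos`.
#' @param chrom_lengths named vector (bp).
#' @param snr bump amplitude in noise-sd units.
#' @param seed RNG seed.
#' @param has_bump logical per border (default all).
#' @param bin track bin width (bp); `bump_sd` the bump width (bp).
#' @return list `track` (`chrom`, `start`, `end`, `value`) and `peaks`
#'   (`chrom`, `start`, `end`) plus `has_bump`.
#' @export
simulate_tracks <- function(borders, chrom_lengths, snr = 5, seed = 1,
                            has_bump = NULL, bin = 100, bump_sd = 500,
                            noise_sd = 1, divergent = FALSE) {
  stopifnot(snr > 0)
  set.seed(seed)
  if (is.null(has_bump)) has_bump <- rep(TRUE, nrow(borders))
  track <- list(); peaks <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = bin)
    mids <- starts + bin / 2
    val <- stats::rnorm(length(starts), 0, noise_sd)
    bsel <- which(borders$chrom == ch & has_bump)
    for (b in bsel) {
      p <- borders$pos[b]
      amp <- snr * noise_sd
      if (divergent) {
        val <- val - amp * exp(-(mids - (p - bump_sd))^2 / (2 * bump_sd^2)) +
                     amp * exp(-(mids - (p + bump_sd))^2 / (2 * bump_sd^2))
      } else {
        val <- val + amp * exp(-(mids - p)^2 / (2 * bump_sd^2))
      }
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = ch, start = max(0, p - 2 * bump_sd),
        end = min(len, p + 2 * bump_sd))
    }
    track[[ch]] <- data.frame(chrom = ch, start = starts,
                              end = pmin(starts + bin, len), value = val,
                              stringsAsFactors = FALSE)
  }
  list(track = do.call(rbind, track),
       peaks = if (length(peaks)) do.call(rbind, peaks) else
         data.frame(chrom = character(), start = numeric(), end = numeric()),
       has_bump = has_bump)
}

#' Simulate gene annotation and a DEG table tied to TAD reorganisation
#'
#' Genes are placed uniformly inside WT TADs (never spanning borders). DEG
#' status is drawn with odds `deg_odds` for genes inside reorganised TADs
#' (a TAD is reorganised when either flanking border's intended status is
#' not `maintained`). Fold changes and adjusted p-values are drawn
#' consistently with the thresholds.
#'
#' @param truth the `truth` table of [simulate_condition_pair()].
#' @param chrom_lengths named vector (bp).
#' @param genes_per_tad genes placed in each TAD.
#' @param deg_odds DEG odds multiplier in reorganised TADs (>= 1).
#' @param base_rate DEG probability in conserved TADs.
#' @param thresholds `c(padj, log2fc)` used when writing the table.
#' @param seed RNG seed.
#' @return list `genes` (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tad_reorganised`), `deg` (`gene_id`, `log2fc`, `padj`, `status`).
#' @export
simulate_expression <- function(truth, chrom_lengths, genes_per_tad = 3,
                                deg_odds = 5, base_rate = 0.1,
                                thresholds = c(padj = 0.05, log2fc = 2),
                                seed = 1) {
  stopifnot(deg_odds >= 1)
  set.seed(seed)
  p0 <- base_rate
  p1 <- p0 * deg_odds / (1 - p0 + p0 * deg_odds)
  genes <- list()
  gid <- 0L
  for (ch in names(chrom_lengths)) {
    wp <- sort(truth$wt_pos[truth$chrom == ch & !is.na(truth$wt_pos)])
    if (length(wp) < 2) next
    st <- truth$status[truth$chrom == ch & !is.na(truth$wt_pos)][order(
      truth$wt_pos[truth$chrom == ch & !is.na(truth$wt_pos)])]
    for (t in seq_len(length(wp) - 1)) {
      lo <- wp[t]; hi <- wp[t + 1]
      reorg <- st[t] != "maintained" || st[t + 1] != "maintained"
      for (g in seq_len(genes_per_tad)) {
        w <- stats::runif(1, 500, 2000)
        if (hi - lo <= w + 200) {
          warning("TAD too small for requested genes; placing fewer")
          break
        }
        s <- stats::runif(1, lo + 100, hi - w - 100)
        gid <- gid + 1L
        genes[[gid]] <- data.frame(
          gene_id = sprintf("gene%04d", gid), chrom = ch,
          start = round(s), end = round(s + w),
          strand = sample(c("+", "-"), 1), tad_reorganised = reorg,
          stringsAsFactors = FALSE)
      }
    }
  }
  genes <- do.call(rbind, genes)
  is_deg <- stats::runif(nrow(genes)) <
    ifelse(genes$tad_reorganised, p1, p0)
  sign <- sample(c(-1, 1), nrow(genes), replace = TRUE)
  log2fc <- ifelse(is_deg,
                   sign * (thresholds[["log2fc"]] + stats::rexp(nrow(genes))),
                   stats::rnorm(nrow(genes), 0, thresholds[["log2fc"]] / 4))
  padj <- ifelse(is_deg,
                 stats::runif(nrow(genes), 0, thresholds[["padj"]]),
                 stats::runif(nrow(genes), thresholds[["padj"]], 1))
  deg <- deg_status(data.frame(gene_id = genes$gene_id, log2fc = log2fc,
                               padj = padj, stringsAsFactors = FALSE),
                    p_thresh = thresholds[["padj"]],
                    fc_thresh = thresholds[["log2fc"]])
  list(genes = genes, deg = deg)
}
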