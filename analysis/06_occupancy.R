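#!/usr/bin/env Rscript
# Step 6: border-centred occupancy. Heat maps of the simulated ChIP track
# in 5-kb windows around the WT robust borders (chip winsorisation
# dialect, rows ordered by the track's own 5-kb summary), rule-based
# occupancy clustering, Pol II-style pausing indices on the simulated
# genes, and PWM site counts within 2 kb of borders with versus without a
# planted binding bump. Writes results/occupancy/.

suppressMessages(library(tadremodel))
dat <- "results/data"; out <- "results/occupancy"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

track <- read_bedgraph(file.path(dat, "chip_beaf.bedgraph"))
chip_truth <- utils::read.table(file.path(dat, "chip_truth.tsv"),
                                header = TRUE)
borders <- data.frame(chrom = chip_truth$chrom, pos = chip_truth$pos)

hm <- border_heatmap(track, borders, window = 5000, dialect = "chip",
                     reference = track)
utils::write.table(hm$matrix, file.path(out, "heatmap_chip.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)
cc <- cluster_occupancy(list(beaf = hm$raw))
utils::write.table(cc, file.path(out, "occupancy_classes.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("occupancy classes (cut-off ",
        signif(attr(cc, "cutoff"), 4), "): ",
        paste(names(table(cc$class)), table(cc$class), collapse = ", "))
# planted bumps should carry more signal than bump-free borders
p_mwu <- group_signal_test(cc$window_sum[chip_truth$has_bump],
                           cc$window_sum[!chip_truth$has_bump])
message(sprintf(
  "window-sum contrast, bump vs bump-free borders: %.1f vs %.1f (MWU p %.3g)",
  mean(cc$window_sum[chip_truth$has_bump]),
  mean(cc$window_sum[!chip_truth$has_bump]), p_mwu))

genes <- utils::read.table("results/expression/genes.tsv", header = TRUE)
pol <- simulate_tracks(data.frame(chrom = genes$chrom,
                                  pos = ifelse(genes$strand == "+",
                                               genes$start, genes$end)),
                       c(chr1 = max(genes$end) + 10000), snr = 4,
                       seed = 7, bump_sd = 200)
pidx <- pausing_index(pol$track, genes)
utils::write.table(data.frame(gene_id = names(pidx), pausing_index = pidx),
                   file.path(out, "pausing_index.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("pausing index: median %.2f over %d genes",
                stats::median(pidx, na.rm = TRUE), sum(!is.na(pidx))))

# PWM sites near borders: embed a motif at bump borders of a random genome
set.seed(11)
pwm <- matrix(stats::rnorm(4 * 8, 0, 2), 4, 8,
              dimnames = list(c("A", "C", "G", "T"), NULL))
consensus <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
glen <- 4e6
chrseq <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                collapse = "")
for (p in chip_truth$pos[chip_truth$has_bump])
  substr(chrseq, p, p + nchar(consensus) - 1) <- consensus
counts <- vapply(seq_len(nrow(chip_truth)), function(k)
  count_pwm_sites(chrseq, pwm,
                  region = c(chip_truth$pos[k], chip_truth$pos[k] + 1),
                  flank = 2000, threshold_fraction = 0.85),
  numeric(1))
utils::write.table(data.frame(chip_truth, pwm_sites = counts),
                   file.path(out, "pwm_sites.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("PWM sites at bump vs bump-free borders: ",
        mean(counts[chip_truth$has_bump]), " vs ",
        mean(counts[!chip_truth$has_bump]))
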