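#!/usr/bin/env Rscript
# Step 1: build the synthetic study. One 4-Mb chromosome with 12 planted
# TAD borders (insulation depth 3), 4 chromatin loops (5x enrichment),
# 200-kb A/B checkerboard compartments, and two scripted knockdowns (border
# deletions, a 1.5-kb fuzzy shift, a 10-kb relocation, a weakening, one
# loop deletion each). Writes the matrices as pixel/bin text plus ChIP-like
# tracks, peaks, gene models and DEG tables under results/data/.

suppressMessages(library(tadremodel))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- yaml::read_yaml(system.file("extdata", "demo_config.yaml",
                                   package = "tadremodel"))
genome <- unlist(cfg$genome)
borders <- do.call(rbind, lapply(cfg$borders, as.data.frame))
loops <- do.call(rbind, lapply(cfg$loops, as.data.frame))

spec <- synthetic_spec(genome, resolution = cfg$resolution,
                       borders = borders, loops = loops,
                       compartments = cfg$compartments, depth = cfg$depth,
                       seed = cfg$seeds$simulate)

conds <- list(wt = NULL)
for (kd in names(cfg$knockdowns))
  conds[[kd]] <- do.call(rbind, lapply(cfg$knockdowns[[kd]], as.data.frame))

for (cond in names(conds)) {
  if (cond == "wt") {
    sim <- simulate_matrix(spec)
    truth <- data.frame(chrom = borders$chrom, wt_pos = borders$pos,
                        kd_pos = borders$pos, status = "maintained")
  } else {
    pair <- simulate_condition_pair(spec, conds[[cond]])
    sim <- pair$kd
    truth <- pair$truth
  }
  write_matrix(sim$matrix, file.path(out, paste0(cond, ".pixels.tsv")),
               file.path(out, paste0(cond, ".bins.bed")))
  utils::write.table(truth, file.path(out, paste0(cond, ".truth.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %s pixels, %d planted borders", cond,
                  format(nrow(sim$matrix$pixels), big.mark = ","),
                  sum(!is.na(truth$kd_pos))))
  if (cond == "wt") {
    saveRDS(sim, file.path(out, "wt.sim.rds"))
  } else {
    saveRDS(pair, file.path(out, paste0(cond, ".pair.rds")))
  }
}

# architectural-protein ChIP emulation: bumps at 9 of the 12 borders
has_bump <- rep(c(TRUE, TRUE, TRUE, FALSE), 3)
tk <- simulate_tracks(borders, genome, snr = 5,
                      seed = cfg$seeds$simulate + 1, has_bump = has_bump)
write_bedgraph(tk$track, file.path(out, "chip_beaf.bedgraph"))
write_bed(tk$peaks, file.path(out, "chip_beaf_peaks.bed"))
utils::write.table(data.frame(borders, has_bump),
                   file.path(out, "chip_truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("ChIP track: %d bins, %d peaks", nrow(tk$track),
                nrow(tk$peaks)))
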