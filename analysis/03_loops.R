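#!/usr/bin/env Rscript
# Step 3: chromatin loops. Donut-filter calling at 2-kb bins (FDR 0.05,
# window 10, peak width 5, 20-kb merge), WT-versus-knockdown anchor
# comparison (maintained / partial / lost), aggregate peak analysis over
# the WT loops, and promoter/enhancer/gene/other anchor annotation with
# DEG fractions at maintained versus lost loops. Writes results/loops/.

suppressMessages(library(tadremodel))
dat <- "results/data"; out <- "results/loops"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- yaml::read_yaml(system.file("extdata", "demo_config.yaml",
                                   package = "tadremodel"))

mats <- list()
for (cond in c("wt", names(cfg$knockdowns)))
  mats[[cond]] <- balance(read_matrix(
    file.path(dat, paste0(cond, ".pixels.tsv")),
    file.path(dat, paste0(cond, ".bins.bed"))))

called <- lapply(mats, call_loops)
for (cond in names(called)) {
  write_bedpe(called[[cond]], file.path(out, paste0("loops_", cond,
                                                    ".bedpe")))
  message(cond, ": ", nrow(called[[cond]]), " loops")
}

for (kd in names(cfg$knockdowns)) {
  cmp <- compare_loops(called$wt, called[[kd]])
  utils::write.table(cmp, file.path(out, paste0("comparison_", kd, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(kd, " loop status: ",
          paste(names(table(cmp$status)), table(cmp$status),
                collapse = ", "))
}

ap <- apa(mats$wt, called$wt)
utils::write.table(ap$matrix, file.path(out, "apa_wt.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)
message(sprintf("WT APA centre score %.2f over %d loops", ap$score, ap$n))

# functional annotation: the simulated gene models, densified with genes
# whose promoters sit at the WT loop anchors (loops in this system connect
# promoters and regulatory elements), plus synthetic intergenic enhancers
pair <- readRDS(file.path(dat, paste0(names(cfg$knockdowns)[1],
                                      ".pair.rds")))
ex <- simulate_expression(pair$truth, unlist(cfg$genome),
                          genes_per_tad = 8, deg_odds = 5,
                          seed = cfg$seeds$expression)
anchor_tss <- unique(called$wt$end1 + 500)
anchor_genes <- data.frame(
  gene_id = sprintf("anch%02d", seq_along(anchor_tss)), chrom = "chr1",
  start = anchor_tss, end = anchor_tss + 3000, strand = "+")
genes <- rbind(ex$genes[, names(anchor_genes)], anchor_genes)
set.seed(cfg$seeds$expression)
anchor_deg <- deg_status(data.frame(
  gene_id = anchor_genes$gene_id,
  log2fc = stats::rnorm(nrow(anchor_genes), 0, 2.2),
  padj = stats::runif(nrow(anchor_genes))))
deg <- rbind(ex$deg, anchor_deg)
enh_mid <- (genes$end[-nrow(genes)] + genes$start[-1]) / 2
enhancers <- data.frame(chrom = "chr1", start = round(enh_mid[c(TRUE,
                                                                FALSE)]),
                        end = round(enh_mid[c(TRUE, FALSE)]) + 1000)
ann <- annotate_loops(called$wt, genes, enhancers)
utils::write.table(ann, file.path(out, "annotation_wt.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("anchor classes: ", paste(names(table(ann$pair_class)),
                                  table(ann$pair_class), collapse = ", "))

cmp1 <- compare_loops(called$wt, called[[names(cfg$knockdowns)[1]]])
dg <- deg_at_loops(cmp1, genes, deg)
utils::write.table(
  data.frame(group = c("maintained", "lost"),
             n = c(dg$maintained["n"], dg$lost["n"]),
             deg = c(dg$maintained["deg"], dg$lost["deg"]),
             fraction = c(dg$maintained["fraction"], dg$lost["fraction"]),
             fisher_p = dg$pvalue),
  file.path(out, "deg_at_loops.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
message(sprintf("DEG at anchors: maintained %s/%s, lost %s/%s (p = %s)",
                dg$maintained["deg"], dg$maintained["n"], dg$lost["deg"],
                dg$lost["n"], format(dg$pvalue, digits = 3)))
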