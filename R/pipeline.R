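# Configuration-driven orchestration of the full WT-versus-knockdown
# comparison on synthetic or file-based inputs, plus the plain-text
# writers for the standard interchange formats.

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `name`
#'   and `score` columns.
#' @export
write_bed <- function(df, path, name = NULL, score = NULL) {
  out <- df[, c("chrom", "start", "end")]
  if (!is.null(name)) out$name <- name
  if (!is.null(score)) out$score <- score
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a signal track as bedGraph
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#' @export
read_bedgraph <- function(path) {
  tt <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(tt)[1:4] <- c("chrom", "start", "end", "value")
  tt
}

#' Write loops as BEDPE
#' @export
write_bedpe <- function(loops, path) {
  out <- data.frame(loops$chrom, loops$start1, loops$end1,
                    loops$chrom, loops$start2, loops$end2,
                    name = sprintf("loop%d", seq_len(nrow(loops))),
                    fdr = if ("fdr" %in% names(loops)) loops$fdr else ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotation from GFF3 or BED-like TSV
#'
#' GFF3 is read through rtracklayer and reduced to `gene` features;
#' coordinates are returned 0-based half-open.
#' @export
read_genes <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr))
    data.frame(gene_id = ids,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               strand = as.character(BiocGenerics::strand(gr)),
               stringsAsFactors = FALSE)
  } else {
    g <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(g)))
    g
  }
}

pipeline_defaults <- function() {
  list(resolution = 2000, depth = 2e6, decay_exponent = 1,
       delta_weak = 0.04, delta_strong = 0.08, border_pvalue = 0.01,
       min_tad = 5000, downsample_fraction = 0.8, fuzzy_tol = 2000,
       same_tol = 600, match_tol = 2000,
       insulation_windows = c(10000, 20000, 30000),
       loop_resolution = 2000, loop_fdr = 0.05, loop_window = 10,
       loop_peak_width = 5, loop_merge_dist = 20000, anchor_tol = 2000,
       compartment_resolution = 10000, saddle_bins = 30,
       saddle_trim = c(0.025, 0.975), n_perm = 1000,
       deg_padj = 0.05, deg_log2fc = 2,
       genes_per_tad = 3, deg_odds = 5)
}

required_seeds <- c("simulate", "downsample", "expression", "permutation")

validate_config <- function(config) {
  known <- c("genome", "borders", "loops", "compartments", "seeds",
             "knockdowns", names(pipeline_defaults()))
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$genome)) stop("config key 'genome' is missing")
  missing_seeds <- setdiff(required_seeds, names(config$seeds))
  if (length(missing_seeds))
    stop("config must give a seed for every stochastic stage; missing: ",
         paste(missing_seeds, collapse = ", "))
  prm <- pipeline_defaults()
  for (k in names(prm)) if (!is.null(config[[k]])) prm[[k]] <- config[[k]]
  config$params <- prm
  config
}

df_or_null <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, function(r) as.data.frame(r,
                                                     stringsAsFactors = FALSE)))
}

#' Run the full WT-versus-knockdown comparison pipeline
#'
#' Reads a configuration (a list, or a YAML file path), simulates the WT
#' condition and each configured knockdown from the planted layout, and
#' runs border calling with down-sampling robustness, border
#' classification, loop calling and comparison, compartment and saddle
#' analysis, and the DEG-association permutation test. Every stage's seed
#' comes from the configuration; rerunning with the same configuration
#' reproduces the summary exactly. Failure of one knockdown comparison is
#' reported but does not abort the others.
#'
#' @param config list or YAML path. Required keys: `genome` (named
#'   chromosome lengths), `seeds` (named: simulate, downsample, expression,
#'   permutation), `borders` (planted border list), `knockdowns` (named
#'   list of edit tables). Optional: `loops`, `compartments`, and any
#'   analysis parameter (see `pipeline_defaults`).
#' @param out_dir output directory; created if needed.
#' @return the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  prm <- config$params
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- unlist(config$genome)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  borders <- df_or_null(config$borders)
  loops <- df_or_null(config$loops)
  edits_all <- lapply(config$knockdowns, df_or_null)

  spec <- synthetic_spec(genome, resolution = prm$resolution,
                         decay_exponent = prm$decay_exponent,
                         borders = borders, loops = loops,
                         compartments = config$compartments,
                         depth = prm$depth, seed = config$seeds$simulate)

  call_condition <- function(m) {
    mb <- balance(m)
    tr <- insulation_score(mb, prm$insulation_windows)
    full <- call_borders(tr, mb, prm$delta_weak, prm$delta_strong,
                         prm$border_pvalue, prm$min_tad)
    md <- balance(downsample(m, prm$downsample_fraction,
                             config$seeds$downsample))
    trd <- insulation_score(md, prm$insulation_windows)
    down <- call_borders(trd, md, prm$delta_weak, prm$delta_strong,
                         prm$border_pvalue, prm$min_tad)
    list(matrix = mb, track = tr,
         robust = robust_borders(full, down, prm$match_tol), full = full)
  }

  message("[pipeline] WT condition (config ", cfg_hash, ")")
  wt_sim <- simulate_matrix(spec)
  wt <- call_condition(wt_sim$matrix)
  write_bed(wt$robust, file.path(out_dir, "borders_wt.bed"),
            name = wt$robust$strength,
            score = round(wt$robust$delta * 1000))
  write_bedgraph(data.frame(wt$track[c("chrom", "start", "end")],
                            value = wt$track$score),
                 file.path(out_dir, "insulation_wt.bedgraph"))

  wt_loops <- NULL
  if (!is.null(loops)) {
    wt_loops <- call_loops(wt$matrix, resolution = prm$loop_resolution,
                           fdr = prm$loop_fdr, window = prm$loop_window,
                           peak_width = prm$loop_peak_width,
                           merge_dist = prm$loop_merge_dist)
    write_bedpe(wt_loops, file.path(out_dir, "loops_wt.bedpe"))
  }

  comp_wt <- NULL; strength_wt <- NULL; gc10 <- NULL; m10_wt <- NULL
  if (!is.null(config$compartments)) {
    m10_wt <- balance(aggregate_matrix(wt_sim$matrix,
                                       prm$compartment_resolution))
    nb <- nrow(m10_wt$bins)
    agg_gc <- vapply(seq_len(nb), function(b) {
      sel <- wt_sim$matrix$bins$chrom == m10_wt$bins$chrom[b] &
        wt_sim$matrix$bins$start >= m10_wt$bins$start[b] &
        wt_sim$matrix$bins$start < m10_wt$bins$end[b]
      mean(wt_sim$truth$gc[sel])
    }, numeric(1))
    gc10 <- agg_gc
    comp_wt <- compartment_eigenvector(m10_wt, gc10, exclude = character(0))
    strength_wt <- saddle(m10_wt, comp_wt, prm$saddle_bins,
                          prm$saddle_trim)$strength
  }

  summary <- list(config_hash = cfg_hash, conditions = list())
  comparisons <- list()
  for (kdname in names(edits_all)) {
    res <- tryCatch({
      message("[pipeline] knockdown ", kdname)
      pair <- simulate_condition_pair(spec, edits_all[[kdname]],
                                      prm$fuzzy_tol)
      kd <- call_condition(pair$kd$matrix)
      cls <- classify_borders(wt$robust, kd$robust, prm$fuzzy_tol,
                              prm$same_tol)
      utils::write.table(cls, file.path(out_dir,
                                        paste0("borders_", kdname, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      counts <- table(factor(cls$status,
                             levels = c("maintained", "weakened", "fuzzy",
                                        "lost", "new")))
      out <- list(border_status = as.list(counts), truth = pair$truth,
                  classification = cls)
      if (!is.null(wt_loops)) {
        kd_loops <- call_loops(kd$matrix, resolution = prm$loop_resolution,
                               fdr = prm$loop_fdr, window = prm$loop_window,
                               peak_width = prm$loop_peak_width,
                               merge_dist = prm$loop_merge_dist)
        lc <- compare_loops(wt_loops, kd_loops, prm$anchor_tol)
        utils::write.table(lc, file.path(out_dir,
                                         paste0("loops_", kdname, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out$loop_status <- as.list(table(factor(lc$status,
          levels = c("maintained", "partial", "lost"))))
      }
      if (!is.null(comp_wt)) {
        m10_kd <- balance(aggregate_matrix(pair$kd$matrix,
                                           prm$compartment_resolution))
        comp_kd <- compartment_eigenvector(m10_kd, gc10,
                                           exclude = character(0))
        sw <- detect_switches(comp_wt, comp_kd)
        out$switch_fraction <- sw$fraction
        out$strength_kd <- saddle(m10_kd, comp_kd, prm$saddle_bins,
                                  prm$saddle_trim)$strength
      }
      expr <- simulate_expression(pair$truth, genome,
                                  genes_per_tad = prm$genes_per_tad,
                                  deg_odds = prm$deg_odds,
                                  thresholds = c(padj = prm$deg_padj,
                                                 log2fc = prm$deg_log2fc),
                                  seed = config$seeds$expression)
      regions <- classify_tad_regions(
        data.frame(chrom = cls$chrom, pos = cls$wt_pos)[!is.na(cls$wt_pos), ],
        data.frame(chrom = cls$chrom, pos = cls$kd_pos)[!is.na(cls$kd_pos), ],
        genome, prm$fuzzy_tol, prm$same_tol)
      de <- expr$deg$status %in% c("up", "down")
      deg_regions <- expr$genes[de, c("chrom", "start", "end")]
      targets <- regions[regions$class %in% c("kd_specific", "conserved_one"),
                         c("chrom", "start", "end")]
      # universe = the border-delimited span genes can occupy, per chromosome
      universe <- do.call(rbind, lapply(names(genome), function(ch) {
        wp <- cls$wt_pos[cls$chrom == ch & !is.na(cls$wt_pos)]
        if (length(wp) >= 2)
          data.frame(chrom = ch, start = min(wp), end = max(wp))
        else data.frame(chrom = ch, start = 0, end = as.numeric(genome[[ch]]))
      }))
      pt <- if (nrow(deg_regions) && nrow(targets))
        permutation_overlap_test(deg_regions, targets, universe,
                                 n_perm = prm$n_perm,
                                 seed = config$seeds$permutation)
      else list(pvalue = NA, observed = NA, z = NA)
      out$deg_association <- list(observed = pt$observed, p = pt$pvalue,
                                  z = pt$z, n_deg = sum(de))
      out
    }, error = function(e) {
      warning("comparison ", kdname, " failed: ", conditionMessage(e))
      list(error = conditionMessage(e))
    })
    comparisons[[kdname]] <- res
  }
  summary$wt <- list(
    n_robust_borders = nrow(wt$robust),
    n_strong = sum(wt$robust$strength == "strong"),
    n_weak = sum(wt$robust$strength == "weak"),
    n_loops = if (!is.null(wt_loops)) nrow(wt_loops) else NA,
    saddle_strength = strength_wt)
  summary$comparisons <- lapply(comparisons, function(x)
    x[setdiff(names(x), c("truth", "classification"))])
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(c(summary, list(detail = comparisons)))
}
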