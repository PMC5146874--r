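# Orchestration of the stages into file-to-file runs. Each run_* function
# reads the standard formats, calls the corresponding module, and writes TSV
# outputs whose comment headers record the parameters and seed, so identical
# configurations reproduce identical files. The thin command-line wrapper in
# exec/ckreg dispatches subcommands onto these functions.

#' Read a run configuration file
#'
#' Flat YAML of `key: value` pairs (paths, `window`, `n_resamples`, `seed`,
#' `fdr_threshold`, `nd_policy`, `out_dir`); command-line flags override
#' configuration values.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping of key: value pairs")
  cfg
}

#' Read promoters back from a promoter FASTA
#'
#' Inverse of [write_promoter_fasta()] (headers `gene_id|window|truncated`).
#'
#' @param fasta_path promoter FASTA path.
#' @return a `promoter_set`.
#' @export
read_promoter_fasta <- function(fasta_path) {
  dss <- Biostrings::readDNAStringSet(fasta_path)
  parts <- strsplit(names(dss), "|", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("promoter FASTA headers must be gene_id|window|truncated")
  }
  window <- unique(vapply(parts, function(p) as.integer(p[[2L]]), integer(1L)))
  if (length(window) != 1L) stop("mixed window widths in promoter FASTA")
  seqs <- unname(as.character(dss))
  df <- data.frame(gene_id = vapply(parts, `[[`, character(1L), 1L),
                   sequence = toupper(seqs), length = nchar(seqs),
                   truncated = vapply(parts, `[[`, character(1L), 3L) == "true",
                   stringsAsFactors = FALSE)
  structure(list(window = window, promoters = df), class = "promoter_set")
}

#' Generate a complete synthetic input bundle
#'
#' Writes a toy genome with planted motifs, its annotation and truth table,
#' the motif list, up-/down-regulated DE tables over the focal genes, a
#' simulated nCounter panel, and a paired fold-change table into `out_dir`.
#' The `"paper-like"` preset emulates the target study design at desk scale:
#' 300 genes, 1 kb windows, background presence rate 0.22, a 50-gene
#' up-regulated focal set at elevated presence and a 50-gene down-regulated
#' set at depleted presence, 3 + 3 nCounter lanes with noise sigma 0.1, and
#' fold-change pairs at correlation 0.93.
#'
#' @param out_dir output directory (created if needed).
#' @param preset currently `"paper-like"`.
#' @param seed master seed; all outputs are pure functions of it.
#' @return named list of written file paths, invisibly.
#' @export
run_simulate <- function(out_dir, preset = "paper-like", seed = 1) {
  preset <- match.arg(preset, "paper-like")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 6L)
  n_genes <- 300L
  window <- 1000L
  ms <- motif_set(c("AAGATTTT", "AAGATCTT"), name = "typeB_RR_extended")
  toy <- make_toy_genome(n_genes = n_genes, n_contigs = 3L, window = window,
                         seed = seeds[1])
  up_ids <- toy$genes$gene_id[1:50]
  down_ids <- toy$genes$gene_id[51:100]
  planted <- plant_motifs(toy$genome, toy$genes, ms, p0 = 0.22, p1 = 0.65,
                          focal_set = up_ids, seed = seeds[2], window = window)
  # down-regulated genes get a depleted presence rate (re-planted at 0.05)
  down_rows <- match(down_ids, planted$truth$gene_id)
  planted2 <- plant_motifs(planted$genome, toy$genes[down_rows, ], ms,
                           p0 = 0.05, p1 = 0.05, focal_set = character(0),
                           seed = seeds[3], window = window)
  planted$genome <- planted2$genome
  planted$truth$has_hit[down_rows] <- planted2$truth$has_hit
  planted$truth$focal <- planted$truth$gene_id %in% c(up_ids, down_ids)
  paths <- list(
    genome = file.path(out_dir, "genome.fasta"),
    annotation = file.path(out_dir, "genes.gff3"),
    motifs = file.path(out_dir, "motifs.txt"),
    truth = file.path(out_dir, "truth.tsv"),
    de_up = file.path(out_dir, "de_up.tsv"),
    de_down = file.path(out_dir, "de_down.tsv"),
    nano_counts = file.path(out_dir, "nano_counts.tsv"),
    nano_probes = file.path(out_dir, "nano_probes.tsv"),
    nano_lanes = file.path(out_dir, "nano_lanes.tsv"),
    nano_truth = file.path(out_dir, "nano_truth.tsv"),
    paired_fc = file.path(out_dir, "paired_log2fc.tsv")
  )
  dss <- planted$genome
  Biostrings::writeXStringSet(dss, paths$genome)
  write_gene_annotation(toy$genes, paths$annotation)
  write_motif_file(ms, paths$motifs)
  write_tsv_manifest(planted$truth, paths$truth,
                     list(preset = preset, seed = seed))
  de_up <- simulate_de_table(length(up_ids), frac_up = 1, gene_ids = up_ids,
                             seed = seeds[4])
  de_down <- simulate_de_table(length(down_ids), frac_up = 0,
                               gene_ids = down_ids, seed = seeds[4] + 1L)
  write_de_table(de_up, paths$de_up)
  write_de_table(de_down, paths$de_down)
  sim <- simulate_nanostring_panel(seed = seeds[5])
  write_nanostring_panel(sim$panel, paths$nano_counts, paths$nano_probes,
                         paths$nano_lanes)
  write_tsv_manifest(data.frame(probe = names(sim$truth$log2fc),
                                true_log2fc = sim$truth$log2fc,
                                stringsAsFactors = FALSE),
                     paths$nano_truth, list(seed = seed, sigma = sim$truth$sigma))
  paired <- simulate_paired_foldchanges(500L, rho = 0.93, seed = seeds[6])
  write_tsv_manifest(paired, paths$paired_fc, list(rho = 0.93, seed = seed))
  invisible(paths)
}

#' Extract promoters from files to files
#'
#' @param genome_fasta genome FASTA path.
#' @param annotation_file GFF3/BED annotation path.
#' @param out_fasta output promoter FASTA.
#' @param out_manifest optional output TSV manifest.
#' @param window window width (default 1000).
#' @param feature_type annotation feature type (default `"gene"`).
#' @return `out_fasta`, invisibly.
#' @export
run_extract_promoters <- function(genome_fasta, annotation_file, out_fasta,
                                  out_manifest = NULL, window = 1000,
                                  feature_type = "gene") {
  genes <- read_gene_annotation(annotation_file, feature_type)
  prom <- extract_promoters(genome_fasta, genes, window)
  write_promoter_fasta(prom, out_fasta, out_manifest)
  invisible(out_fasta)
}

#' Scan promoters from files to a hit table file
#'
#' @param promoter_fasta promoter FASTA from [run_extract_promoters()].
#' @param motif_file motif list path.
#' @param out_tsv output hit-table TSV.
#' @param both_strands scan both orientations (default TRUE).
#' @return `out_tsv`, invisibly.
#' @export
run_scan <- function(promoter_fasta, motif_file, out_tsv, both_strands = TRUE) {
  prom <- read_promoter_fasta(promoter_fasta)
  ms <- read_motif_file(motif_file)
  hits <- scan_promoters(prom, ms, both_strands)
  write_hit_table(hits, out_tsv,
                  list(motifs = ms$name, k = ms$k,
                       n_kmers = length(ms$kmers),
                       both_strands = both_strands))
  invisible(out_tsv)
}

#' Resampling enrichment from files to files
#'
#' The universe is every gene in the hit table; each DE table contributes an
#' up- (`log2fc > 0`) and a down-regulated (`log2fc < 0`) gene set.
#'
#' @param hits_tsv hit-table TSV from [run_scan()].
#' @param de_tsvs named character vector of DE-table paths.
#' @param out_tsv output enrichment summary TSV.
#' @param histogram_dir optional directory for per-set null histograms.
#' @param n_resamples resamples per set (default 1000).
#' @param seed master seed.
#' @param fdr_threshold DE ingestion cutoff (default 1e-4).
#' @return the enrichment report, invisibly.
#' @export
run_enrich <- function(hits_tsv, de_tsvs, out_tsv, histogram_dir = NULL,
                       n_resamples = 1000, seed = 1, fdr_threshold = 1e-4) {
  hits <- read_tsv_manifest(hits_tsv)
  hits$has_hit <- as.logical(hits$has_hit)
  universe <- gene_universe(hits)
  if (is.null(names(de_tsvs))) {
    names(de_tsvs) <- sub("\\.tsv$", "", basename(de_tsvs))
  }
  gene_sets <- list()
  for (lbl in names(de_tsvs)) {
    de <- read_de_table(de_tsvs[[lbl]], fdr_threshold, tissue_label = lbl)
    up <- de$gene_id[de$log2fc > 0]
    down <- de$gene_id[de$log2fc < 0]
    if (length(up)) gene_sets[[paste0(lbl, "_up")]] <- up
    if (length(down)) gene_sets[[paste0(lbl, "_down")]] <- down
  }
  if (!length(gene_sets)) stop("no non-empty DE gene sets")
  report <- enrichment_report(universe, gene_sets, N = n_resamples, seed = seed)
  write_enrichment_report(report, out_tsv,
                          list(seed = seed, n_resamples = n_resamples,
                               M = universe$M, K = universe$K))
  if (!is.null(histogram_dir)) {
    dir.create(histogram_dir, recursive = TRUE, showWarnings = FALSE)
    for (lbl in names(report$histograms)) {
      write_tsv_manifest(report$histograms[[lbl]],
                         file.path(histogram_dir, paste0(lbl, "_null_hist.tsv")),
                         list(set_label = lbl, seed = seed))
    }
  }
  invisible(report)
}

#' nCounter normalization from files to files
#'
#' @param counts_tsv,probe_tsv,lane_tsv panel TSVs
#'   (see [read_nanostring_panel()]).
#' @param out_values normalized-values TSV.
#' @param out_qc QC TSV (`B`, `s_pos`, `s_ref`, standard-curve slope/R^2).
#' @param out_fc per-probe log2 fold-change TSV with `nd` codes.
#' @return the `normalized_panel`, invisibly.
#' @export
run_nano_norm <- function(counts_tsv, probe_tsv, lane_tsv, out_values,
                          out_qc = NULL, out_fc = NULL) {
  panel <- read_nanostring_panel(counts_tsv, probe_tsv, lane_tsv)
  norm <- normalize_nanostring(panel)
  write_normalized_panel(norm, out_values, out_qc)
  if (!is.null(out_fc)) {
    fc <- nanostring_log2fc(norm)
    out <- fc
    out$log2fc <- ifelse(fc$status == "ok",
                         format(round(fc$log2fc, 6), trim = TRUE),
                         ifelse(fc$status == "ND", "ND", "nd"))
    write_tsv_manifest(out, out_fc)
  }
  invisible(norm)
}

#' Cross-platform concordance from a paired table file
#'
#' @param paired_tsv TSV `gene_id`, `log2fc_a`, `log2fc_b` (blank/`nd`/`NA`
#'   entries are treated as not detected).
#' @param out_tsv output report TSV.
#' @param nd_policy `"exclude"` or `"zero"`.
#' @return the `concordance_report`, invisibly.
#' @export
run_concord <- function(paired_tsv, out_tsv, nd_policy = "exclude") {
  df <- read_tsv_manifest(paired_tsv)
  df$log2fc_a <- suppressWarnings(as.numeric(df$log2fc_a))
  df$log2fc_b <- suppressWarnings(as.numeric(df$log2fc_b))
  rep <- platform_concordance(df, nd_policy)
  write_tsv_manifest(
    data.frame(n_pairs = rep$n_pairs, pearson_r = rep$pearson_r,
               r_squared = rep$r_squared, slope = rep$slope,
               intercept = rep$intercept,
               sign_concordance = rep$sign_concordance,
               excluded_nd = rep$excluded_nd),
    out_tsv, list(nd_policy = nd_policy))
  invisible(rep)
}

#' Gene-set overlap from DE table files
#'
#' @param de_a_tsv,de_b_tsv DE-table TSVs.
#' @param out_tsv output report TSV.
#' @param fdr_threshold ingestion cutoff (default 1e-4).
#' @param universe_size optional universe size for the overlap p-value.
#' @return the `overlap_report`, invisibly.
#' @export
run_overlap <- function(de_a_tsv, de_b_tsv, out_tsv, fdr_threshold = 1e-4,
                        universe_size = NULL) {
  a <- read_de_table(de_a_tsv, fdr_threshold, "A")
  b <- read_de_table(de_b_tsv, fdr_threshold, "B")
  rep <- set_overlap(a, b, universe_size)
  write_tsv_manifest(
    data.frame(n_a = rep$n_a, n_b = rep$n_b, n_intersect = rep$n_intersect,
               n_same_direction = rep$n_same_direction,
               n_opposite = rep$n_opposite, n_undirected = rep$n_undirected,
               p_overlap = rep$p_overlap),
    out_tsv, list(fdr_threshold = fdr_threshold))
  invisible(rep)
}

#' Expression summaries from count files
#'
#' @param counts_tsv gene x sample counts TSV (first column `gene_id`).
#' @param lengths_tsv TSV `gene_id`, `length_bp`.
#' @param libsize_tsv TSV `sample`, `library_size`.
#' @param out_rpkm RPKM matrix TSV.
#' @param out_summary per-sample summary TSV (expressed-gene count,
#'   top-decile read share).
#' @param min_total expressed-gene threshold (default 20).
#' @param quantile top-share quantile (default 0.10).
#' @return the RPKM matrix, invisibly.
#' @export
run_summarize <- function(counts_tsv, lengths_tsv, libsize_tsv, out_rpkm,
                          out_summary = NULL, min_total = 20, quantile = 0.10) {
  counts <- read_tsv_manifest(counts_tsv)
  lens <- read_tsv_manifest(lengths_tsv)
  libs <- read_tsv_manifest(libsize_tsv)
  m <- as.matrix(counts[, -1L, drop = FALSE])
  rownames(m) <- counts$gene_id
  mat <- expression_matrix(m, lens$length_bp[match(rownames(m), lens$gene_id)],
                           libs$library_size[match(colnames(m), libs$sample)])
  rp <- rpkm(mat)
  write_tsv_manifest(data.frame(gene_id = rownames(rp), rp,
                                check.names = FALSE, stringsAsFactors = FALSE),
                     out_rpkm, list(min_total = min_total))
  if (!is.null(out_summary)) {
    expressed <- expressed_flag(mat, min_total)
    shares <- vapply(colnames(m), function(s) top_share(mat, s, quantile),
                     numeric(1L))
    write_tsv_manifest(
      data.frame(sample = colnames(m), library_size = mat$library_size,
                 n_expressed = sum(expressed), top_share = shares,
                 stringsAsFactors = FALSE),
      out_summary, list(min_total = min_total, quantile = quantile))
  }
  invisible(rp)
}
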