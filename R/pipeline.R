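#' Detect syntenic clusters from in-memory objects
#'
#' Core of the pipeline: builds the scaffold-pair dendrogram forest and the
#' permutation null model, runs the dynamic cut, and returns the reported
#' clusters.
#'
#' @param annotation_beta,annotation_gamma Translated [genome_annotation()]s.
#' @param hitset A [hit_set()].
#' @param config A [synteny_config()].
#' @return The [dynamic_cut()] result (clusters, final correction factor,
#'   test ledger), with the forest and null model attached.
#' @examples
#' fx <- synth_generate(synth_spec(
#'   seed = 7, blocks = list(list(beta_scaffold = 1, beta_genes = 3:8,
#'                                gamma_scaffold = 1, gamma_genes = 3:8)),
#'   n_noise = 50))
#' res <- detect_synteny(fx$beta, fx$gamma, fx$hits, synteny_config(seed = 7))
#' res$clusters[, c("scaffold_beta", "start_beta", "end_beta", "n_hits", "p_corrected")]
#' @export
detect_synteny <- function(annotation_beta, annotation_gamma, hitset,
                           config = synteny_config()) {
  forest <- build_forest(hitset)
  null <- build_null_model(hitset, config$seed)
  res <- dynamic_cut(forest, annotation_beta, annotation_gamma, hitset,
                     null, config)
  res$forest <- forest
  res$null <- null
  res
}

#' Write the reported-cluster table and per-organism BED files
#'
#' The TSV holds one row per cluster with spans on both organisms, hit and
#' gene counts, score, conservation ratio, and raw/corrected p-values; the
#' BED files hold the cluster spans per organism (BED is 0-based half-open,
#' converted on output).
#'
#' @param clusters Cluster table from [detect_synteny()].
#' @param path Output TSV path.
#' @param bed_beta,bed_gamma Optional BED output paths.
#' @return The TSV path, invisibly.
#' @export
write_cluster_table <- function(clusters, path, bed_beta = NULL, bed_gamma = NULL) {
  cols <- c("cluster_id", "scaffold_beta", "start_beta", "end_beta",
            "scaffold_gamma", "start_gamma", "end_gamma", "n_hits",
            "n_genes_beta", "n_genes_gamma", "score", "conservation_ratio",
            "p_raw", "correction_factor", "p_corrected", "method")
  df <- if (nrow(clusters)) clusters[, cols] else
    stats::setNames(data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
  for (nm in c("score", "conservation_ratio", "p_raw", "p_corrected")) {
    df[[nm]] <- sprintf("%.10g", as.numeric(df[[nm]]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed <- function(p, scaf, start, end, ids) {
    if (is.null(p)) return()
    writeLines(sprintf("%s\t%d\t%d\tcluster_%d", scaf, as.integer(start) - 1L,
                       as.integer(end), ids), p)
  }
  if (nrow(clusters)) {
    write_bed(bed_beta, clusters$scaffold_beta, clusters$start_beta,
              clusters$end_beta, clusters$cluster_id)
    write_bed(bed_gamma, clusters$scaffold_gamma, clusters$start_gamma,
              clusters$end_gamma, clusters$cluster_id)
  } else {
    if (!is.null(bed_beta)) writeLines(character(0), bed_beta)
    if (!is.null(bed_gamma)) writeLines(character(0), bed_gamma)
  }
  invisible(path)
}

#' Run the full pipeline from files
#'
#' Loads both genomes, translates exons, obtains the bi-directional hit set
#' (from supplied tabular alignment files, a cached hit-table checkpoint, or
#' by running an external aligner), detects significant clusters, and writes
#' the output tables. A `hits.tsv` checkpoint is written to `outdir`;
#' re-running with it present skips alignment and merging entirely.
#'
#' @param beta_fasta,beta_gff3,gamma_fasta,gamma_gff3 Input genome files.
#' @param outdir Output directory.
#' @param config A [synteny_config()].
#' @param tab_beta_to_gamma,tab_gamma_to_beta Optional precomputed 12-column
#'   alignment tables. If absent and no checkpoint exists, an external
#'   `blastp` is attempted via [run_external_aligner()].
#' @param organism_beta,organism_gamma Labels.
#' @return (Invisibly) list with the cluster table (`clusters`), the
#'   [hit_set()], both annotations, the final correction factor, and a
#'   `manifest` of written files.
#' @export
run_synteny <- function(beta_fasta, beta_gff3, gamma_fasta, gamma_gff3,
                        outdir, config = synteny_config(),
                        tab_beta_to_gamma = NULL, tab_gamma_to_beta = NULL,
                        organism_beta = "beta", organism_gamma = "gamma") {
  for (f in c(beta_fasta, beta_gff3, gamma_fasta, gamma_gff3)) {
    if (!file.exists(f)) stopf("input stage: missing file '%s'", f)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  message("[genome] loading annotations")
  beta <- translate_exons(load_annotation(beta_fasta, beta_gff3, organism_beta))
  gamma <- translate_exons(load_annotation(gamma_fasta, gamma_gff3, organism_gamma))

  checkpoint <- file.path(outdir, "hits.tsv")
  if (file.exists(checkpoint)) {
    message("[hits] reusing checkpoint ", checkpoint)
    hitset <- read_hit_table(checkpoint, organism_beta, organism_gamma)
  } else {
    if (is.null(tab_beta_to_gamma) || is.null(tab_gamma_to_beta)) {
      message("[align] running external aligner")
      fa_b <- file.path(outdir, "beta_exons.faa")
      fa_g <- file.path(outdir, "gamma_exons.faa")
      write_exon_fasta(beta, fa_b)
      write_exon_fasta(gamma, fa_g)
      tabs <- run_external_aligner(fa_b, fa_g, file.path(outdir, "align"))
      tab_beta_to_gamma <- tabs$beta_to_gamma
      tab_gamma_to_beta <- tabs$gamma_to_beta
    }
    message("[hits] merging bi-directional hits")
    fwd <- parse_blast_tabular(tab_beta_to_gamma, beta, gamma)
    rev <- parse_blast_tabular(tab_gamma_to_beta, gamma, beta)
    hitset <- make_bidirectional(fwd, rev, beta, gamma)
    write_hit_table(hitset, checkpoint)
  }

  message(sprintf("[cluster] %d hits; building forest and cutting", nrow(hitset$hits)))
  res <- detect_synteny(beta, gamma, hitset, config)
  paths <- c(clusters = file.path(outdir, "clusters.tsv"),
             bed_beta = file.path(outdir, "clusters_beta.bed"),
             bed_gamma = file.path(outdir, "clusters_gamma.bed"),
             hits = checkpoint)
  write_cluster_table(res$clusters, paths["clusters"],
                      paths["bed_beta"], paths["bed_gamma"])
  message(sprintf("[done] %d cluster(s), correction factor %d",
                  nrow(res$clusters), res$correction_factor))
  invisible(list(clusters = res$clusters, hitset = hitset,
                 beta = beta, gamma = gamma,
                 correction_factor = res$correction_factor,
                 ledger = res$ledger, manifest = paths))
}
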