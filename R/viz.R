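# Circos-ready visualization bundles. Rendering is out of process: these
# functions emit the text data files Circos consumes; a `circos` binary (if
# any) is invoked by the user, never required here.

viz_colors <- list(gene_fwd = "blue", gene_rev = "orange",
                   exon = "green", cluster = "red")

# K in [0,1] -> link alpha in [0.15, 1] (monotone, linear)
quality_alpha <- function(k) 0.15 + 0.85 * pmin(1, pmax(0, k))

viz_bundle <- function(karyotype, genes, links, exons = NULL, conf = NULL) {
  structure(list(karyotype = karyotype, genes = genes, exons = exons,
                 links = links, conf = conf),
            class = "viz_bundle")
}

#' @export
print.viz_bundle <- function(x, ...) {
  cat(sprintf("<viz_bundle> %d karyotype entr%s, %d gene tile(s), %d link(s)%s\n",
              nrow(x$karyotype), if (nrow(x$karyotype) == 1) "y" else "ies",
              nrow(x$genes), nrow(x$links),
              if (!is.null(x$exons)) sprintf(", %d exon tile(s)", nrow(x$exons)) else ""))
  invisible(x)
}

karyotype_entry <- function(id, label, start, end, color = "grey") {
  data.frame(chr = id, label = label, start = start, end = end,
             color = color, stringsAsFactors = FALSE)
}

gene_tiles <- function(annotation, scaffold, lo = 1, hi = Inf) {
  g <- annotation$genes
  g <- g[g$scaffold == scaffold & g$start >= lo & g$end <= hi, , drop = FALSE]
  data.frame(chr = rep(scaffold, nrow(g)), start = g$start, end = g$end,
             color = ifelse(g$strand == "-", viz_colors$gene_rev,
                            viz_colors$gene_fwd),
             stringsAsFactors = FALSE)
}

#' Chromosome-level visualization of reported clusters
#'
#' The karyotype shows the focus (query) scaffold first, followed by every
#' partner scaffold carrying at least one reported cluster; gene tiles are
#' coloured by strand (blue forward, orange reverse); one ribbon connects
#' each cluster's span on the focus scaffold to its span on the partner.
#'
#' @param clusters Cluster table from [dynamic_cut()] / [detect_synteny()].
#' @param annotation_beta,annotation_gamma Annotations.
#' @param focus_scaffold A scaffold of organism beta to center the view on.
#' @return A `viz_bundle`.
#' @export
chromosome_view <- function(clusters, annotation_beta, annotation_gamma,
                            focus_scaffold) {
  if (!focus_scaffold %in% names(annotation_beta$scaffold_lengths)) {
    stopf("unknown focus scaffold '%s'", focus_scaffold)
  }
  cl <- if (nrow(clusters)) {
    clusters[clusters$scaffold_beta == focus_scaffold, , drop = FALSE]
  } else clusters
  partners <- if (nrow(cl)) sort(unique(cl$scaffold_gamma)) else character(0)
  if (!length(partners)) warnf("no clusters on scaffold '%s'; karyotype-only bundle",
                               focus_scaffold)
  kar <- rbind(
    karyotype_entry(focus_scaffold, focus_scaffold, 1,
                    annotation_beta$scaffold_lengths[[focus_scaffold]]),
    if (length(partners)) do.call(rbind, lapply(partners, function(p) {
      karyotype_entry(p, p, 1, annotation_gamma$scaffold_lengths[[p]])
    }))
  )
  genes <- rbind(
    gene_tiles(annotation_beta, focus_scaffold),
    if (length(partners)) do.call(rbind, lapply(partners, function(p) {
      gene_tiles(annotation_gamma, p)
    }))
  )
  links <- if (nrow(cl)) {
    data.frame(chr1 = cl$scaffold_beta, start1 = cl$start_beta, end1 = cl$end_beta,
               chr2 = cl$scaffold_gamma, start2 = cl$start_gamma,
               end2 = cl$end_gamma,
               options = sprintf("color=%s", viz_colors$cluster),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chr1 = character(), start1 = numeric(), end1 = numeric(),
               chr2 = character(), start2 = numeric(), end2 = numeric(),
               options = character(), stringsAsFactors = FALSE)
  }
  viz_bundle(kar, genes, links, conf = circos_conf(has_exons = FALSE))
}

#' Region-level visualization of one cluster
#'
#' Zooms into a single reported cluster: the karyotype holds the cluster's
#' two spans extended by `flank_bp` (clipped to the scaffold), gene tiles
#' plus green exon tiles are drawn, and one ribbon per member hit connects
#' its two regions with intensity (alpha) proportional to the hit quality
#' `K`.
#'
#' @param cluster One row of the cluster table.
#' @param hitset The [hit_set()].
#' @param annotation_beta,annotation_gamma Annotations.
#' @param flank_bp Flank (bp) added around both spans (default 0).
#' @return A `viz_bundle` with an `exons` tile track.
#' @export
region_view <- function(cluster, hitset, annotation_beta, annotation_gamma,
                        flank_bp = 0) {
  stopifnot(flank_bp >= 0, nrow(cluster) == 1)
  ids <- cluster$hit_ids[[1]]
  rows <- hitset$hits[match(ids, hitset$hits$hit_id), , drop = FALSE]
  sb <- cluster$scaffold_beta; sg <- cluster$scaffold_gamma
  b_lo <- max(1, cluster$start_beta - flank_bp)
  b_hi <- min(annotation_beta$scaffold_lengths[[sb]], cluster$end_beta + flank_bp)
  g_lo <- max(1, cluster$start_gamma - flank_bp)
  g_hi <- min(annotation_gamma$scaffold_lengths[[sg]], cluster$end_gamma + flank_bp)
  kar <- rbind(karyotype_entry(sb, sb, b_lo, b_hi),
               karyotype_entry(sg, sg, g_lo, g_hi))
  genes <- rbind(gene_tiles(annotation_beta, sb, b_lo, b_hi),
                 gene_tiles(annotation_gamma, sg, g_lo, g_hi))
  exon_track <- function(annotation, scaffold, lo, hi) {
    ex <- annotation$exons
    ex <- ex[ex$scaffold == scaffold & ex$start >= lo & ex$end <= hi, , drop = FALSE]
    data.frame(chr = rep(scaffold, nrow(ex)), start = ex$start, end = ex$end,
               color = viz_colors$exon, stringsAsFactors = FALSE)
  }
  exons <- rbind(exon_track(annotation_beta, sb, b_lo, b_hi),
                 exon_track(annotation_gamma, sg, g_lo, g_hi))
  links <- data.frame(
    chr1 = rows$scaffold_beta, start1 = rows$start_beta, end1 = rows$end_beta,
    chr2 = rows$scaffold_gamma, start2 = rows$start_gamma, end2 = rows$end_gamma,
    options = sprintf("color=%s,alpha=%.4f", viz_colors$cluster,
                      quality_alpha(rows$quality)),
    stringsAsFactors = FALSE
  )
  viz_bundle(kar, genes, links, exons = exons,
             conf = circos_conf(has_exons = TRUE))
}

circos_conf <- function(has_exons) {
  paste(c(
    "karyotype = karyotype.txt",
    "<ideogram>", "thickness = 25p", "show_label = yes", "</ideogram>",
    "<plots>",
    "<plot>", "type = tile", "file = genes.txt", "r0 = 0.85r", "r1 = 0.98r", "</plot>",
    if (has_exons) c("<plot>", "type = tile", "file = exons.txt",
                     "r0 = 0.72r", "r1 = 0.84r", "</plot>"),
    "</plots>",
    "<links>", "<link>", "file = links.txt", "radius = 0.70r",
    "bezier_radius = 0r", "ribbon = yes", "</link>", "</links>",
    "<image>", "dir = .", "file = synteny.png", "</image>",
    "<<include etc/colors_fonts_patterns.conf>>",
    "<<include etc/housekeeping.conf>>"
  ), collapse = "\n")
}

#' Write a visualization bundle as Circos data files
#'
#' Emits `karyotype.txt` (`chr - ID LABEL START END COLOR`), `genes.txt`
#' (and `exons.txt` for region-level bundles) tile tracks, `links.txt`
#' (6 columns plus options) and a `circos.conf` referencing them. All
#' coordinates are 1-based inclusive.
#'
#' @param bundle A `viz_bundle`.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written file paths (the manifest).
#' @export
write_circos <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "viz_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(karyotype = file.path(outdir, "karyotype.txt"),
             genes = file.path(outdir, "genes.txt"),
             links = file.path(outdir, "links.txt"),
             conf = file.path(outdir, "circos.conf"))
  k <- bundle$karyotype
  writeLines(sprintf("chr - %s %s %d %d %s", k$chr, k$label,
                     as.integer(k$start), as.integer(k$end), k$color),
             paths["karyotype"])
  g <- bundle$genes
  writeLines(sprintf("%s %d %d fill_color=%s", g$chr, as.integer(g$start),
                     as.integer(g$end), g$color), paths["genes"])
  if (!is.null(bundle$exons)) {
    paths <- c(paths, exons = file.path(outdir, "exons.txt"))
    e <- bundle$exons
    writeLines(sprintf("%s %d %d fill_color=%s", e$chr, as.integer(e$start),
                       as.integer(e$end), e$color), paths["exons"])
  }
  l <- bundle$links
  writeLines(sprintf("%s %d %d %s %d %d %s", l$chr1, as.integer(l$start1),
                     as.integer(l$end1), l$chr2, as.integer(l$start2),
                     as.integer(l$end2), l$options), paths["links"])
  writeLines(bundle$conf %||% circos_conf(!is.null(bundle$exons)), paths["conf"])
  paths
}

#' Parse a written links.txt back into a data.frame
#'
#' Round-trip check helper for [write_circos()] output.
#'
#' @param path Path to a `links.txt`.
#' @return data.frame with the six coordinate columns and `options`.
#' @export
read_circos_links <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(chr1 = character(), start1 = numeric(), end1 = numeric(),
                      chr2 = character(), start2 = numeric(), end2 = numeric(),
                      options = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, " ", fixed = TRUE)
  data.frame(
    chr1 = vapply(parts, `[`, "", 1),
    start1 = as.numeric(vapply(parts, `[`, "", 2)),
    end1 = as.numeric(vapply(parts, `[`, "", 3)),
    chr2 = vapply(parts, `[`, "", 4),
    start2 = as.numeric(vapply(parts, `[`, "", 5)),
    end2 = as.numeric(vapply(parts, `[`, "", 6)),
    options = vapply(parts, function(p) paste(p[-(1:6)], collapse = " "), ""),
    stringsAsFactors = FALSE
  )
}
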