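#' Specification for a synthetic genome pair with planted synteny
#'
#' Describes a toy two-organism comparison: random gene models on a few
#' scaffolds per organism, planted syntenic blocks (reciprocal full-coverage
#' hits between positionally paired genes), optional duplications (one beta
#' gene hit by several gamma copies), and uniform noise hits with weak
#' qualities. Everything downstream of the external aligner can be exercised
#' from such a fixture; rearrangements (split / fuse events) are expressed by
#' planting the gamma side of one beta range on two different gamma
#' scaffolds.
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: 2 scaffolds per organism, 20 genes per scaffold, 2--4 exons
#' per gene of 90--300 bp (multiples of 3 so a full-coverage hit covers the
#' exon exactly), and 200 noise hits with qualities drawn from Beta(1, 5)
#' (mostly weak, occasionally strong — a plausible e-value-driven tail).
#'
#' @param seed Seed; the whole fixture is deterministic given it.
#' @param n_scaffolds Integer vector `c(beta, gamma)`.
#' @param genes_per_scaffold Genes laid left to right on every scaffold.
#' @param exons_per_gene Range `c(min, max)` of exons per gene.
#' @param exon_bp Range of exon lengths (rounded down to a multiple of 3).
#' @param intron_bp,intergenic_bp Ranges of gap lengths.
#' @param blocks List of planted blocks; each is a list with `beta_scaffold`,
#'   `beta_genes` (integer vector of gene ordinals on that scaffold),
#'   `gamma_scaffold`, `gamma_genes` (same length; paired positionally),
#'   and optionally `evalue` (default 0; planted hits are full-coverage, so
#'   quality is `1 - evalue`).
#' @param duplications List of planted duplications; each is a list with
#'   `beta_scaffold`, `beta_gene` (one ordinal), `gamma_scaffold`,
#'   `gamma_genes` (ordinals of the copies) and optionally `evalue`.
#' @param n_noise Number of uniform noise hits (random exon pairs).
#' @param noise_shape `c(shape1, shape2)` of the Beta distribution noise
#'   qualities are drawn from.
#' @return A validated list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       n_scaffolds = c(beta = 2L, gamma = 2L),
                       genes_per_scaffold = 20L,
                       exons_per_gene = c(2L, 4L),
                       exon_bp = c(90L, 300L),
                       intron_bp = c(60L, 180L),
                       intergenic_bp = c(200L, 800L),
                       blocks = list(),
                       duplications = list(),
                       n_noise = 200L,
                       noise_shape = c(1, 5)) {
  spec <- list(seed = as.integer(seed),
               n_scaffolds = stats::setNames(as.integer(n_scaffolds), c("beta", "gamma")),
               genes_per_scaffold = as.integer(genes_per_scaffold),
               exons_per_gene = as.integer(exons_per_gene),
               exon_bp = as.integer(exon_bp), intron_bp = as.integer(intron_bp),
               intergenic_bp = as.integer(intergenic_bp),
               blocks = blocks, duplications = duplications,
               n_noise = as.integer(n_noise), noise_shape = noise_shape)
  stopifnot(all(spec$n_scaffolds >= 1), spec$genes_per_scaffold >= 1,
            spec$exons_per_gene[1] >= 1, spec$exon_bp[1] >= 3, spec$n_noise >= 0)
  used_b <- character(0); used_g <- character(0)
  for (bl in spec$blocks) {
    if (length(bl$beta_genes) != length(bl$gamma_genes)) {
      stopf("block beta_genes and gamma_genes must pair up one to one")
    }
    if (bl$beta_scaffold > spec$n_scaffolds["beta"] ||
        bl$gamma_scaffold > spec$n_scaffolds["gamma"] ||
        any(bl$beta_genes > spec$genes_per_scaffold) ||
        any(bl$gamma_genes > spec$genes_per_scaffold) ||
        any(bl$beta_genes < 1) || any(bl$gamma_genes < 1)) {
      stopf("planted block outside the generated gene universe")
    }
    kb <- paste(bl$beta_scaffold, bl$beta_genes)
    kg <- paste(bl$gamma_scaffold, bl$gamma_genes)
    if (any(kb %in% used_b) || any(kg %in% used_g)) {
      stopf("planted blocks overlap on one of the organisms")
    }
    used_b <- c(used_b, kb); used_g <- c(used_g, kg)
  }
  structure(spec, class = "synth_spec")
}

# One organism's random annotation: genes left to right per scaffold.
synth_annotation <- function(org, prefix, n_scaf, spec) {
  gene_rows <- list(); exon_rows <- list(); scaf_seq <- character(n_scaf)
  rng_int <- function(rg, n = 1) if (rg[1] == rg[2]) rep(rg[1], n) else
    sample(rg[1]:rg[2], n, replace = TRUE)
  for (s in seq_len(n_scaf)) {
    scaf <- sprintf("%s_s%d", prefix, s)
    pos <- 1L
    for (g in seq_len(spec$genes_per_scaffold)) {
      pos <- pos + rng_int(spec$intergenic_bp)
      gid <- sprintf("%s_s%dg%02d", prefix, s, g)
      strand <- sample(c("+", "-"), 1)
      n_ex <- rng_int(spec$exons_per_gene)
      starts <- ends <- integer(n_ex)
      for (e in seq_len(n_ex)) {
        len <- (rng_int(spec$exon_bp) %/% 3L) * 3L
        starts[e] <- pos
        ends[e] <- pos + len - 1L
        pos <- ends[e] + 1L + (if (e < n_ex) rng_int(spec$intron_bp) else 0L)
      }
      ord <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = gid, scaffold = scaf, strand = strand,
        start = starts[1], end = ends[n_ex], stringsAsFactors = FALSE)
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        exon_id = sprintf("%s.e%d", gid, seq_len(n_ex)),
        gene_id = gid, scaffold = scaf, strand = strand,
        start = starts[ord], end = ends[ord], frame = 0L,
        stringsAsFactors = FALSE)
    }
    total <- pos + rng_int(spec$intergenic_bp)
    scaf_seq[s] <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                         collapse = "")
  }
  seqs <- Biostrings::DNAStringSet(scaf_seq)
  names(seqs) <- sprintf("%s_s%d", prefix, seq_len(n_scaf))
  genome_annotation(org, seqs, do.call(rbind, gene_rows), do.call(rbind, exon_rows))
}

# Copy the coding sequence of each planted beta exon over its gamma partner
# so that a real protein aligner would reproduce the planted hit.
copy_exon_sequence <- function(beta, gamma, exon_b, exon_g) {
  eb <- beta$exons[match(exon_b, beta$exons$exon_id), ]
  eg <- gamma$exons[match(exon_g, gamma$exons$exon_id), ]
  src <- as.character(Biostrings::subseq(beta$sequences[eb$scaffold],
                                         eb$start, eb$end))
  minus_b <- eb$strand == "-"
  if (any(minus_b)) {
    src[minus_b] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(src[minus_b])))
  }
  gseq <- as.character(gamma$sequences)
  names(gseq) <- names(gamma$sequences)
  for (i in seq_along(exon_g)) {
    tlen <- eg$end[i] - eg$start[i] + 1L
    s <- substr(src[i], 1L, tlen)
    if (nchar(s) < tlen) {   # pad with the target's own tail
      s <- paste0(s, substr(gseq[[eg$scaffold[i]]],
                            eg$start[i] + nchar(s), eg$end[i]))
    }
    if (eg$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    substr(gseq[[eg$scaffold[i]]], eg$start[i], eg$end[i]) <- s
  }
  out <- Biostrings::DNAStringSet(gseq)
  names(out) <- names(gseq)
  gamma$sequences <- out
  gamma
}

# positional exon pairing between two genes (first with first, ...)
paired_exons <- function(annotation_b, annotation_g, gene_b, gene_g) {
  xb <- annotation_b$exons$exon_id[annotation_b$exons$gene_id == gene_b]
  xg <- annotation_g$exons$exon_id[annotation_g$exons$gene_id == gene_g]
  n <- min(length(xb), length(xg))
  list(beta = xb[seq_len(n)], gamma = xg[seq_len(n)])
}

#' Generate a synthetic fixture with known ground truth
#'
#' Builds both annotations (with sequences; planted exon pairs share their
#' coding sequence so a real aligner could reproduce the planted hits),
#' translates them, injects the planted and noise hits directly, and records
#' which hit ids belong to which planted block. Deterministic given the
#' spec's seed.
#'
#' @param spec A [synth_spec()].
#' @return List of class `synth_fixture`: `beta`, `gamma`
#'   ([genome_annotation()]s, translated), `hits` (a [hit_set()]), `truth`
#'   (data.frame `block`, `hit_id`; duplications appear as blocks named
#'   `"dup<i>"`), and `spec`.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  beta <- synth_annotation("beta", "b", spec$n_scaffolds["beta"], spec)
  gamma <- synth_annotation("gamma", "g", spec$n_scaffolds["gamma"], spec)

  gene_ord <- function(ann, prefix, scaf, ord) sprintf("%s_s%dg%02d", prefix, scaf, ord)

  planted <- list()   # list of (exon_beta, exon_gamma, evalue, block)
  for (i in seq_along(spec$blocks)) {
    bl <- spec$blocks[[i]]
    ev <- bl$evalue %||% 0
    for (j in seq_along(bl$beta_genes)) {
      pr <- paired_exons(beta, gamma,
                         gene_ord(beta, "b", bl$beta_scaffold, bl$beta_genes[j]),
                         gene_ord(gamma, "g", bl$gamma_scaffold, bl$gamma_genes[j]))
      if (length(pr$beta)) {
        planted[[length(planted) + 1L]] <- data.frame(
          exon_beta = pr$beta, exon_gamma = pr$gamma, evalue = ev,
          block = sprintf("block%d", i), stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_along(spec$duplications)) {
    dp <- spec$duplications[[i]]
    ev <- dp$evalue %||% 0
    for (gg in dp$gamma_genes) {
      pr <- paired_exons(beta, gamma,
                         gene_ord(beta, "b", dp$beta_scaffold, dp$beta_gene),
                         gene_ord(gamma, "g", dp$gamma_scaffold, gg))
      if (length(pr$beta)) {
        planted[[length(planted) + 1L]] <- data.frame(
          exon_beta = pr$beta, exon_gamma = pr$gamma, evalue = ev,
          block = sprintf("dup%d", i), stringsAsFactors = FALSE)
      }
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(exon_beta = character(), exon_gamma = character(),
               evalue = numeric(), block = character(), stringsAsFactors = FALSE)

  if (nrow(planted)) {
    gamma <- copy_exon_sequence(beta, gamma, planted$exon_beta, planted$exon_gamma)
  }
  beta <- translate_exons(beta)
  gamma <- translate_exons(gamma)

  noise <- if (spec$n_noise > 0) {
    q <- stats::rbeta(spec$n_noise, spec$noise_shape[1], spec$noise_shape[2])
    data.frame(
      exon_beta = sample(beta$exons$exon_id, spec$n_noise, replace = TRUE),
      exon_gamma = sample(gamma$exons$exon_id, spec$n_noise, replace = TRUE),
      evalue = 1 - q, block = NA_character_, stringsAsFactors = FALSE)
  } else planted[0, ]

  all_pairs <- rbind(planted, noise)
  all_pairs <- all_pairs[!duplicated(all_pairs[c("exon_beta", "exon_gamma")]), ,
                         drop = FALSE]

  exb <- beta$exons[match(all_pairs$exon_beta, beta$exons$exon_id), ]
  exg <- gamma$exons[match(all_pairs$exon_gamma, gamma$exons$exon_id), ]
  # full-coverage hits: exon lengths are multiples of 3 with frame 0, so the
  # full peptide maps back onto the entire exon and K = 1 - evalue exactly
  hits <- data.frame(
    exon_beta = all_pairs$exon_beta, exon_gamma = all_pairs$exon_gamma,
    scaffold_beta = exb$scaffold, start_beta = exb$start, end_beta = exb$end,
    scaffold_gamma = exg$scaffold, start_gamma = exg$start, end_gamma = exg$end,
    evalue = all_pairs$evalue,
    quality = hit_quality(all_pairs$evalue,
                          interval_len(exb$start, exb$end),
                          interval_len(exg$start, exg$end),
                          interval_len(exb$start, exb$end),
                          interval_len(exg$start, exg$end)),
    block = all_pairs$block,
    stringsAsFactors = FALSE
  )
  ord <- order(hits$scaffold_beta, hits$start_beta, hits$end_beta,
               hits$scaffold_gamma, hits$start_gamma, hits$end_gamma,
               hits$exon_beta, hits$exon_gamma)
  hits <- hits[ord, , drop = FALSE]
  hits <- cbind(hit_id = seq_len(nrow(hits)), hits)
  truth <- hits[!is.na(hits$block), c("block", "hit_id")]
  rownames(truth) <- NULL
  hits$block <- NULL

  structure(list(beta = beta, gamma = gamma,
                 hits = hit_set(hits, "beta", "gamma"),
                 truth = truth, spec = spec),
            class = "synth_fixture")
}

#' Independent noise-only replicates
#'
#' Generates `n_replicates` fixtures from a planted-block-free spec, each
#' with its own derived seed; drives the family-wise type-I error check.
#'
#' @param spec A [synth_spec()] with no blocks or duplications.
#' @param n_replicates Number of replicates.
#' @return List of `n_replicates` [synth_generate()] fixtures.
#' @export
generate_noise_replicates <- function(spec, n_replicates) {
  stopifnot(inherits(spec, "synth_spec"))
  if (length(spec$blocks) || length(spec$duplications)) {
    stopf("noise replicates require a spec without planted blocks")
  }
  lapply(seq_len(n_replicates), function(i) {
    s <- spec
    s$seed <- derive_seed(spec$seed, i)
    synth_generate(s)
  })
}

# hand-rolled GFF3 writer: gene -> mRNA -> exon + CDS rows, phase 0
write_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- annotation$genes
  ex <- annotation$exons
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    mid <- paste0(gid, ".m1")
    sub <- ex[ex$gene_id == gid, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    writeLines(c(
      sprintf("%s\tsyntenr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$scaffold[i], g$start[i], g$end[i], g$strand[i], gid),
      sprintf("%s\tsyntenr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$scaffold[i], g$start[i], g$end[i], g$strand[i], mid, gid),
      sprintf("%s\tsyntenr\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              sub$scaffold, sub$start, sub$end, sub$strand, mid),
      sprintf("%s\tsyntenr\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
              sub$scaffold, sub$start, sub$end, sub$strand, sub$frame, mid)
    ), con)
  }
  invisible(path)
}

# split the bi-directional hits into two directional 12-column tabular files
write_directional_tables <- function(fixture, path_fwd, path_rev) {
  h <- fixture$hits$hits
  plen_b <- nchar(fixture$beta$exons$peptide[match(h$exon_beta,
                                                   fixture$beta$exons$exon_id)])
  plen_g <- nchar(fixture$gamma$exons$peptide[match(h$exon_gamma,
                                                    fixture$gamma$exons$exon_id)])
  row12 <- function(q, s, qlen, slen, ev) {
    sprintf("%s\t%s\t100.00\t%d\t0\t0\t1\t%d\t1\t%d\t%s\t%.1f",
            q, s, pmin(qlen, slen), qlen, slen, sprintf("%.17g", ev),
            2 * pmin(qlen, slen))
  }
  writeLines(row12(h$exon_beta, h$exon_gamma, plen_b, plen_g, h$evalue), path_fwd)
  writeLines(row12(h$exon_gamma, h$exon_beta, plen_g, plen_b, h$evalue), path_rev)
  invisible(c(path_fwd, path_rev))
}

#' Materialize a synthetic fixture on disk
#'
#' Writes, per organism, the genome FASTA and GFF3; plus the two directional
#' 12-column alignment tables, the merged hit table, the ground truth and a
#' JSON manifest recording the spec. The files round-trip through
#' [load_annotation()] / [parse_blast_tabular()] / [make_bidirectional()], so
#' the full command-line path is exercisable offline.
#'
#' @param fixture A [synth_generate()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
synth_write <- function(fixture, dir) {
  stopifnot(inherits(fixture, "synth_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    beta_fasta = file.path(dir, "beta.fasta"),
    beta_gff3 = file.path(dir, "beta.gff3"),
    gamma_fasta = file.path(dir, "gamma.fasta"),
    gamma_gff3 = file.path(dir, "gamma.gff3"),
    beta_to_gamma = file.path(dir, "beta_to_gamma.tsv"),
    gamma_to_beta = file.path(dir, "gamma_to_beta.tsv"),
    hit_table = file.path(dir, "hits.tsv"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  Biostrings::writeXStringSet(fixture$beta$sequences, paths["beta_fasta"])
  Biostrings::writeXStringSet(fixture$gamma$sequences, paths["gamma_fasta"])
  write_gff3(fixture$beta, paths["beta_gff3"])
  write_gff3(fixture$gamma, paths["gamma_gff3"])
  write_directional_tables(fixture, paths["beta_to_gamma"], paths["gamma_to_beta"])
  write_hit_table(fixture$hits, paths["hit_table"])
  utils::write.table(fixture$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spec <- fixture$spec
  class(spec) <- NULL
  jsonlite::write_json(spec, paths["manifest"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths
}
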