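#' Construct a genome annotation object
#'
#' Low-level constructor used by [load_annotation()] and by the synthetic
#' fixture generator. Most users should call [load_annotation()] instead.
#'
#' @param organism_id Short label for the organism (e.g. `"beta"`).
#' @param sequences A named [Biostrings::DNAStringSet] of scaffold sequences,
#'   or `NULL` if only coordinates are needed.
#' @param genes data.frame with columns `gene_id`, `scaffold`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive).
#' @param exons data.frame with columns `exon_id`, `gene_id`, `scaffold`,
#'   `strand`, `start`, `end`, `frame` (0--2) and optionally `peptide`.
#'
#' @return An object of class `genome_annotation`: a list with the fields
#'   above plus `scaffold_lengths` (named integer vector).
#' @export
genome_annotation <- function(organism_id, sequences, genes, exons) {
  stopifnot(is.character(organism_id), length(organism_id) == 1)
  if (!"peptide" %in% names(exons)) exons$peptide <- NA_character_
  need_g <- c("gene_id", "scaffold", "strand", "start", "end")
  need_e <- c("exon_id", "gene_id", "scaffold", "strand", "start", "end", "frame")
  if (!all(need_g %in% names(genes))) stopf("genes table missing columns")
  if (!all(need_e %in% names(exons))) stopf("exons table missing columns")
  if (anyDuplicated(exons$exon_id)) stopf("exon_id values must be unique")
  if (any(exons$end < exons$start)) stopf("exon with end < start")
  lens <- if (!is.null(sequences)) {
    stats::setNames(Biostrings::width(sequences), names(sequences))
  } else {
    ends <- tapply(c(exons$end, genes$end), c(exons$scaffold, genes$scaffold), max)
    stats::setNames(as.integer(ends), names(ends))
  }
  if (!is.null(sequences)) {
    missing_scaf <- setdiff(unique(c(genes$scaffold, exons$scaffold)), names(sequences))
    if (length(missing_scaf)) {
      stopf("annotation references scaffold(s) absent from the sequence set: %s",
            paste(missing_scaf, collapse = ", "))
    }
  }
  ord <- order(exons$scaffold, exons$start, exons$end, exons$exon_id)
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL
  rownames(genes) <- NULL
  structure(
    list(organism_id = organism_id, sequences = sequences,
         genes = genes, exons = exons,
         scaffold_lengths = lens),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> organism '%s': %d scaffold(s), %d gene(s), %d exon(s)\n",
              x$organism_id, length(x$scaffold_lengths),
              nrow(x$genes), nrow(x$exons)))
  n_pep <- sum(!is.na(x$exons$peptide) & nzchar(x$exons$peptide))
  cat(sprintf("  peptides filled for %d exon(s)\n", n_pep))
  invisible(x)
}

#' Load a genome FASTA and GFF3 annotation
#'
#' Reads scaffold sequences and gene models and assembles the exon-level
#' annotation used throughout the package. When a gene carries CDS features
#' these take precedence over exon features for translation (frame is taken
#' from the CDS phase); otherwise exon features are used with frame 0.
#' Features shared by several mRNAs are deduplicated by
#' (scaffold, interval, strand, frame). Exons are stored in transcription
#' order within each gene and assigned stable identifiers
#' `<gene_id>.e<ordinal>`.
#'
#' @param fasta_source Path to the genome FASTA file.
#' @param gff3_source Path to the GFF3 annotation (features `gene`, `mRNA`,
#'   `exon` and/or `CDS`, linked by `ID`/`Parent` attributes).
#' @param organism_id Short label for the organism.
#'
#' @return A [genome_annotation()] object with empty peptides (call
#'   [translate_exons()] to fill them).
#' @examples
#' fx <- synth_generate(synth_spec(seed = 1, genes_per_scaffold = 4, n_noise = 0))
#' dir <- tempfile(); synth_write(fx, dir)
#' ann <- load_annotation(file.path(dir, "beta.fasta"),
#'                        file.path(dir, "beta.gff3"), "beta")
#' ann
#' @export
load_annotation <- function(fasta_source, gff3_source, organism_id) {
  seqs <- Biostrings::readDNAStringSet(fasta_source)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gff3_source, format = "gff3")
  feat <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff),
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    type = as.character(gff$type),
    id = as.character(gff$ID %||% rep(NA_character_, length(gff))),
    parent = first_or_na(gff$Parent %||% vector("list", length(gff))),
    phase = if (!is.null(gff$phase)) suppressWarnings(as.integer(as.character(gff$phase)))
            else rep(NA_integer_, length(gff)),
    stringsAsFactors = FALSE
  )

  bad <- setdiff(unique(feat$scaffold), names(seqs))
  if (length(bad)) {
    stopf("GFF3 references scaffold(s) absent from FASTA: %s",
          paste(bad, collapse = ", "))
  }

  genes <- feat[feat$type == "gene", , drop = FALSE]
  if (!nrow(genes)) stopf("GFF3 contains no gene features")
  mrna <- feat[feat$type == "mRNA", , drop = FALSE]
  mrna2gene <- stats::setNames(mrna$parent, mrna$id)

  coding <- feat[feat$type %in% c("CDS", "exon"), , drop = FALSE]
  # resolve each coding feature to its gene (Parent may be an mRNA or a gene)
  gene_of <- ifelse(coding$parent %in% names(mrna2gene),
                    unname(mrna2gene[coding$parent]), coding$parent)
  coding$gene_id <- gene_of
  coding <- coding[!is.na(coding$gene_id) & coding$gene_id %in% genes$id, , drop = FALSE]

  exon_rows <- vector("list", nrow(genes))
  kept <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sub <- coding[coding$gene_id == g$id, , drop = FALSE]
    if (any(sub$type == "CDS")) sub <- sub[sub$type == "CDS", , drop = FALSE]
    if (!nrow(sub)) next
    sub$frame <- ifelse(is.na(sub$phase), 0L, sub$phase)
    key <- paste(sub$scaffold, sub$start, sub$end, sub$strand, sub$frame)
    sub <- sub[!duplicated(key), , drop = FALSE]
    # transcription order: ascending start on +, descending on -
    sub <- sub[order(if (g$strand == "-") -sub$start else sub$start), , drop = FALSE]
    exon_rows[[i]] <- data.frame(
      exon_id = sprintf("%s.e%d", g$id, seq_len(nrow(sub))),
      gene_id = g$id, scaffold = sub$scaffold, strand = g$strand,
      start = sub$start, end = sub$end, frame = sub$frame,
      stringsAsFactors = FALSE
    )
    kept[i] <- TRUE
  }
  if (any(!kept)) {
    warnf("%d gene(s) without coding features skipped: %s",
          sum(!kept), paste(utils::head(genes$id[!kept], 5), collapse = ", "))
  }
  genes <- genes[kept, , drop = FALSE]
  exons <- do.call(rbind, exon_rows[kept])

  gene_tab <- data.frame(
    gene_id = genes$id, scaffold = genes$scaffold, strand = genes$strand,
    start = pmin(genes$start, tapply(exons$start, exons$gene_id, min)[genes$id]),
    end = pmax(genes$end, tapply(exons$end, exons$gene_id, max)[genes$id]),
    stringsAsFactors = FALSE
  )
  genome_annotation(organism_id, seqs, gene_tab, exons)
}

#' Translate all exons to peptides
#'
#' Extracts each exon's nucleotide sequence (reverse-complemented for
#' minus-strand genes), drops the `frame` leading bases and any trailing
#' partial codon, and translates under the standard genetic code. Internal
#' stop codons are retained as `*` so that homology is judged by the aligner,
#' not the parser. Exons shorter than one codon after the frame offset get an
#' empty peptide (with a warning).
#'
#' @param annotation A [genome_annotation()] with sequences.
#' @return The annotation with the `peptide` column of `$exons` filled.
#' @export
translate_exons <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (is.null(annotation$sequences)) stopf("annotation has no sequences to translate")
  ex <- annotation$exons
  if (!nrow(ex)) return(annotation)
  dna <- Biostrings::subseq(annotation$sequences[ex$scaffold], ex$start, ex$end)
  minus <- ex$strand == "-"
  if (any(minus)) dna[minus] <- Biostrings::reverseComplement(dna[minus])
  avail <- Biostrings::width(dna) - ex$frame
  ncod <- pmax(0L, avail %/% 3L)
  pep <- character(nrow(ex))
  ok <- ncod > 0L
  if (any(ok)) {
    cds <- Biostrings::subseq(dna[ok], start = ex$frame[ok] + 1L,
                              width = 3L * ncod[ok])
    pep[ok] <- as.character(Biostrings::translate(cds, if.fuzzy.codon = "X"))
  }
  if (any(!ok)) {
    warnf("%d exon(s) shorter than one codon after frame offset; peptide left empty",
          sum(!ok))
  }
  annotation$exons$peptide <- pep
  annotation
}

#' Write translated exon peptides to a protein FASTA
#'
#' One record per exon with a non-empty peptide; the FASTA header is the
#' exon identifier. This is the file an external protein aligner (e.g.
#' BLASTp) consumes in each direction.
#'
#' @param annotation A translated [genome_annotation()].
#' @param destination Output FASTA path.
#' @return (Invisibly) the number of records written.
#' @export
write_exon_fasta <- function(annotation, destination) {
  stopifnot(inherits(annotation, "genome_annotation"))
  ex <- annotation$exons
  keep <- !is.na(ex$peptide) & nzchar(ex$peptide)
  aa <- Biostrings::AAStringSet(stats::setNames(ex$peptide[keep], ex$exon_id[keep]))
  Biostrings::writeXStringSet(aa, destination)
  invisible(sum(keep))
}

# peptide length per exon (0 for empty/NA)
exon_peptide_length <- function(annotation) {
  p <- annotation$exons$peptide
  ifelse(is.na(p), 0L, nchar(p))
}
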