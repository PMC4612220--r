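#' Parse a 12-column tabular protein alignment file
#'
#' Reads the standard BLAST tabular dialect (`-outfmt 6`): `qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore`.
#' Query and subject identifiers are interpreted as exon identifiers of the
#' query and subject organism respectively; rows naming unknown exons are
#' dropped with a warning, malformed rows are a hard error naming the line.
#'
#' @param source Path to the tabular file.
#' @param annotation_query,annotation_subject [genome_annotation()] objects
#'   defining the exon universes of the two organisms.
#' @return data.frame of directional hits with columns `query_exon`,
#'   `subject_exon`, `query_start`, `query_end`, `subject_start`,
#'   `subject_end` (peptide coordinates, 1-based inclusive), `evalue`,
#'   `bitscore`.
#' @export
parse_blast_tabular <- function(source, annotation_query, annotation_subject) {
  lines <- readLines(source)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(query_exon = character(), subject_exon = character(),
                      query_start = integer(), query_end = integer(),
                      subject_start = integer(), subject_end = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    stopf("malformed alignment row at line %d: %d column(s), expected 12",
          lineno[i], nf[i])
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  df <- data.frame(
    query_exon = m[, 1], subject_exon = m[, 2],
    query_start = as.integer(m[, 7]), query_end = as.integer(m[, 8]),
    subject_start = as.integer(m[, 9]), subject_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  known <- df$query_exon %in% annotation_query$exons$exon_id &
    df$subject_exon %in% annotation_subject$exons$exon_id
  if (any(!known)) {
    warnf("%d alignment row(s) referencing unknown exon ids dropped", sum(!known))
    df <- df[known, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Map a peptide interval on an exon back to genomic coordinates
#'
#' Codons `p_start..p_end` of the exon's peptide occupy a genomic
#' sub-interval of the exon: on the plus strand it starts at
#' `exon_start + frame + 3*(p_start - 1)`; on the minus strand the mirrored
#' interval is measured leftwards from the exon end. The result always lies
#' within the exon interval.
#'
#' @param annotation A translated [genome_annotation()].
#' @param exon_id Exon identifier.
#' @param p_start,p_end Peptide positions, 1-based inclusive.
#' @return Named numeric vector `c(start, end)` (1-based inclusive genomic).
#' @examples
#' # A 60 bp plus-strand exon at [101, 160], frame 0: codons 1-5 sit at [101, 115]
#' @export
map_to_genomic <- function(annotation, exon_id, p_start, p_end) {
  ex <- annotation$exons
  i <- match(exon_id, ex$exon_id)
  if (is.na(i)) stopf("unknown exon '%s'", exon_id)
  plen <- nchar(ex$peptide[i])
  if (is.na(plen) || p_start < 1 || p_end > plen || p_start > p_end) {
    stopf("peptide interval [%s, %s] outside peptide of exon '%s'",
          p_start, p_end, exon_id)
  }
  r <- map_to_genomic_vec(ex$start[i], ex$end[i], ex$strand[i], ex$frame[i],
                          p_start, p_end)
  c(start = r$start, end = r$end)
}

# vectorised core of map_to_genomic (no validation)
map_to_genomic_vec <- function(ex_start, ex_end, strand, frame, ps, pe) {
  plus <- strand != "-"
  start <- ifelse(plus, ex_start + frame + 3 * (ps - 1), ex_end - frame - 3 * pe + 1)
  end <- ifelse(plus, ex_start + frame + 3 * pe - 1, ex_end - frame - 3 * (ps - 1))
  list(start = start, end = end)
}

#' Hit quality score
#'
#' The quality of a bi-directional hit combines its e-value significance and
#' how much of the two exons the aligned regions cover:
#' \deqn{K(h) = (1 - \min(1, E)) \cdot \frac{\|r^\beta\| + \|r^\gamma\|}{\|x^\beta\| + \|x^\gamma\|}}
#' where lengths are in bp. `K` is in `[0, 1]`; hits with `E >= 1` score 0 but
#' are retained in the hit universe.
#'
#' @param evalue Hit e-value(s).
#' @param region_beta_len,region_gamma_len Aligned genomic region lengths (bp).
#' @param exon_beta_len,exon_gamma_len Exon interval lengths (bp).
#' @return Numeric vector of qualities in `[0, 1]`.
#' @examples
#' hit_quality(0, 60, 60, 60, 60)       # perfect hit -> 1
#' hit_quality(0.5, 30, 30, 60, 60)     # -> 0.25
#' hit_quality(2, 60, 60, 60, 60)       # e-value clamp -> 0
#' @export
hit_quality <- function(evalue, region_beta_len, region_gamma_len,
                        exon_beta_len, exon_gamma_len) {
  (1 - pmin(1, evalue)) *
    (region_beta_len + region_gamma_len) / (exon_beta_len + exon_gamma_len)
}

#' Construct a hit set
#'
#' Wraps a table of bi-directional hits together with the per-exon best-hit
#' indexes required by the cluster score and the permutation null. Normally
#' produced by [make_bidirectional()] or [synth_generate()].
#'
#' @param hits data.frame with columns `hit_id`, `exon_beta`, `exon_gamma`,
#'   `scaffold_beta`, `start_beta`, `end_beta`, `scaffold_gamma`,
#'   `start_gamma`, `end_gamma`, `evalue`, `quality`.
#' @param organism_beta,organism_gamma Organism labels.
#' @return An object of class `hit_set` with fields `hits`, `organisms`,
#'   `best_beta` and `best_gamma` (named vectors: exon id to best quality over
#'   all hits touching the exon).
#' @export
hit_set <- function(hits, organism_beta = "beta", organism_gamma = "gamma") {
  need <- c("hit_id", "exon_beta", "exon_gamma", "scaffold_beta", "start_beta",
            "end_beta", "scaffold_gamma", "start_gamma", "end_gamma",
            "evalue", "quality")
  if (!all(need %in% names(hits))) {
    stopf("hit table missing column(s): %s",
          paste(setdiff(need, names(hits)), collapse = ", "))
  }
  if (anyDuplicated(hits$hit_id)) stopf("hit_id values must be unique")
  rownames(hits) <- NULL
  best <- function(exon, quality) {
    if (!length(exon)) return(stats::setNames(numeric(0), character(0)))
    v <- tapply(quality, exon, max)
    stats::setNames(as.numeric(v), names(v))
  }
  structure(
    list(hits = hits,
         organisms = c(beta = organism_beta, gamma = organism_gamma),
         best_beta = best(hits$exon_beta, hits$quality),
         best_gamma = best(hits$exon_gamma, hits$quality)),
    class = "hit_set"
  )
}

#' @export
print.hit_set <- function(x, ...) {
  np <- length(unique(scaffold_pair_key(x$hits$scaffold_beta, x$hits$scaffold_gamma)))
  cat(sprintf("<hit_set> %s vs %s: %d bi-directional hit(s) on %d scaffold pair(s)\n",
              x$organisms["beta"], x$organisms["gamma"], nrow(x$hits), np))
  invisible(x)
}

#' Merge two directional alignment sets into bi-directional hits
#'
#' A hit is emitted for every exon pair reported in *both* directions whose
#' aligned peptide intervals mutually overlap (>= 1 position on each exon).
#' The hit's peptide footprint on each exon is the intersection of the two
#' directions' intervals, mapped to genomic coordinates; its e-value is the
#' maximum (more conservative) of the two directions. Pairs seen in only one
#' direction are discarded. Multiple reciprocal local-alignment pairs for the
#' same exon pair yield multiple hits.
#'
#' @param hits_beta_to_gamma Directional hits with organism beta as query
#'   (from [parse_blast_tabular()]).
#' @param hits_gamma_to_beta Directional hits with organism gamma as query.
#' @param annotation_beta,annotation_gamma Translated annotations.
#' @return A [hit_set()].
#' @export
make_bidirectional <- function(hits_beta_to_gamma, hits_gamma_to_beta,
                               annotation_beta, annotation_gamma) {
  fwd <- hits_beta_to_gamma
  rev <- hits_gamma_to_beta
  f <- data.frame(exon_beta = fwd$query_exon, exon_gamma = fwd$subject_exon,
                  fb_start = fwd$query_start, fb_end = fwd$query_end,
                  fg_start = fwd$subject_start, fg_end = fwd$subject_end,
                  f_evalue = fwd$evalue, stringsAsFactors = FALSE)
  r <- data.frame(exon_beta = rev$subject_exon, exon_gamma = rev$query_exon,
                  rb_start = rev$subject_start, rb_end = rev$subject_end,
                  rg_start = rev$query_start, rg_end = rev$query_end,
                  r_evalue = rev$evalue, stringsAsFactors = FALSE)
  m <- merge(f, r, by = c("exon_beta", "exon_gamma"))
  b_lo <- pmax(m$fb_start, m$rb_start); b_hi <- pmin(m$fb_end, m$rb_end)
  g_lo <- pmax(m$fg_start, m$rg_start); g_hi <- pmin(m$fg_end, m$rg_end)
  ok <- b_lo <= b_hi & g_lo <= g_hi
  m <- m[ok, , drop = FALSE]
  b_lo <- b_lo[ok]; b_hi <- b_hi[ok]; g_lo <- g_lo[ok]; g_hi <- g_hi[ok]

  exb <- annotation_beta$exons
  exg <- annotation_gamma$exons
  ib <- match(m$exon_beta, exb$exon_id)
  ig <- match(m$exon_gamma, exg$exon_id)
  rb <- map_to_genomic_vec(exb$start[ib], exb$end[ib], exb$strand[ib],
                           exb$frame[ib], b_lo, b_hi)
  rg <- map_to_genomic_vec(exg$start[ig], exg$end[ig], exg$strand[ig],
                           exg$frame[ig], g_lo, g_hi)
  ev <- pmax(m$f_evalue, m$r_evalue)
  hits <- data.frame(
    exon_beta = m$exon_beta, exon_gamma = m$exon_gamma,
    scaffold_beta = exb$scaffold[ib], start_beta = rb$start, end_beta = rb$end,
    scaffold_gamma = exg$scaffold[ig], start_gamma = rg$start, end_gamma = rg$end,
    evalue = ev,
    quality = hit_quality(ev,
                          interval_len(rb$start, rb$end),
                          interval_len(rg$start, rg$end),
                          interval_len(exb$start[ib], exb$end[ib]),
                          interval_len(exg$start[ig], exg$end[ig])),
    stringsAsFactors = FALSE
  )
  hits <- unique(hits)
  ord <- order(hits$scaffold_beta, hits$start_beta, hits$end_beta,
               hits$scaffold_gamma, hits$start_gamma, hits$end_gamma,
               hits$exon_beta, hits$exon_gamma, hits$evalue)
  hits <- hits[ord, , drop = FALSE]
  hits <- cbind(hit_id = seq_len(nrow(hits)), hits)
  hit_set(hits, annotation_beta$organism_id, annotation_gamma$organism_id)
}

#' Run an external protein aligner in both directions
#'
#' Builds a BLAST database from each exon-peptide FASTA and runs `blastp`
#' (default parameters, tabular output) in both directions. Users who already
#' have tabular alignment files can skip this and feed them directly to
#' [parse_blast_tabular()].
#'
#' @param fasta_beta,fasta_gamma Exon-peptide FASTA files (from
#'   [write_exon_fasta()]).
#' @param workdir Directory for databases and outputs.
#' @param makeblastdb,blastp Binary names or paths.
#' @return Named list with paths `beta_to_gamma`, `gamma_to_beta`.
#' @export
run_external_aligner <- function(fasta_beta, fasta_gamma, workdir,
                                 makeblastdb = "makeblastdb", blastp = "blastp") {
  if (!nzchar(Sys.which(makeblastdb)) || !nzchar(Sys.which(blastp))) {
    stopf(paste("protein aligner not found on PATH; either install BLAST+ or",
                "supply precomputed 12-column tabular files to parse_blast_tabular()"))
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  db_b <- file.path(workdir, "db_beta")
  db_g <- file.path(workdir, "db_gamma")
  out_fw <- file.path(workdir, "beta_to_gamma.tsv")
  out_rv <- file.path(workdir, "gamma_to_beta.tsv")
  run <- function(cmd, args) {
    status <- system2(cmd, args, stdout = FALSE, stderr = FALSE)
    if (status != 0) stopf("'%s' exited with status %d", cmd, status)
  }
  run(makeblastdb, c("-in", fasta_beta, "-dbtype", "prot", "-out", db_b))
  run(makeblastdb, c("-in", fasta_gamma, "-dbtype", "prot", "-out", db_g))
  run(blastp, c("-query", fasta_beta, "-db", db_g, "-outfmt", "6", "-out", out_fw))
  run(blastp, c("-query", fasta_gamma, "-db", db_b, "-outfmt", "6", "-out", out_rv))
  list(beta_to_gamma = out_fw, gamma_to_beta = out_rv)
}

#' Write / read the merged hit table checkpoint
#'
#' Plain TSV exchange format so expensive alignment and merging can be reused
#' across runs.
#'
#' @param hitset A [hit_set()].
#' @param path Output (or input) TSV path.
#' @return `write_hit_table()` returns the path invisibly; `read_hit_table()`
#'   returns a [hit_set()].
#' @export
write_hit_table <- function(hitset, path) {
  df <- hitset$hits
  df$evalue <- sprintf("%.17g", df$evalue)
  df$quality <- sprintf("%.17g", df$quality)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_table
#' @param organism_beta,organism_gamma Organism labels for the restored set.
#' @export
read_hit_table <- function(path, organism_beta = "beta", organism_gamma = "gamma") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(hit_id = "integer",
                                         evalue = "numeric", quality = "numeric"))
  hit_set(df, organism_beta, organism_gamma)
}
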