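test_that("tabular parsing maps fields, drops unknown ids, rejects malformed rows", {
  fx <- synth_generate(synth_spec(seed = 3, genes_per_scaffold = 4, n_noise = 5))
  qx <- fx$beta$exons$exon_id[1]
  sx <- fx$gamma$exons$exon_id[1]
  path <- withr::local_tempfile()
  writeLines(sprintf("%s\t%s\t95.0\t31\t1\t0\t10\t40\t5\t35\t1e-20\t80.1", qx, sx), path)
  df <- parse_blast_tabular(path, fx$beta, fx$gamma)
  expect_equal(df$query_start, 10L)
  expect_equal(df$query_end, 40L)
  expect_equal(df$subject_start, 5L)
  expect_equal(df$subject_end, 35L)
  expect_equal(df$evalue, 1e-20)

  writeLines(character(0), path)
  expect_equal(nrow(parse_blast_tabular(path, fx$beta, fx$gamma)), 0L)

  writeLines(sprintf("%s\t%s\t95.0\t31\t1\t0\t10\t40\t5\t35\t1e-20", qx, sx), path)
  expect_error(parse_blast_tabular(path, fx$beta, fx$gamma), "line 1")

  writeLines(c(sprintf("%s\t%s\t95.0\t31\t1\t0\t10\t40\t5\t35\t1e-20\t80", qx, sx),
               sprintf("ghost\t%s\t95.0\t31\t1\t0\t10\t40\t5\t35\t1e-20\t80", sx)),
             path)
  expect_warning(df <- parse_blast_tabular(path, fx$beta, fx$gamma), "unknown")
  expect_equal(nrow(df), 1L)
})

test_that("peptide-to-genomic mapping follows strand arithmetic", {
  exons <- rbind(exon_row("p.e1", "p", "s1", 101, 160, "+"),
                 exon_row("m.e1", "m", "s1", 101, 160, "-"))
  ann <- make_annotation("t", exons)
  ann$exons$peptide <- strrep("K", 20)
  expect_equal(unname(map_to_genomic(ann, "p.e1", 1, 5)), c(101, 115))
  expect_equal(unname(map_to_genomic(ann, "p.e1", 1, 20)), c(101, 160))
  expect_equal(unname(map_to_genomic(ann, "m.e1", 1, 5)), c(146, 160))
  expect_equal(unname(map_to_genomic(ann, "m.e1", 1, 20)), c(101, 160))
  expect_error(map_to_genomic(ann, "p.e1", 1, 21), "outside")
})

test_that("hit quality follows the e-value clamp and coverage ratio", {
  expect_equal(hit_quality(0, 60, 60, 60, 60), 1)
  expect_equal(hit_quality(2, 60, 60, 60, 60), 0)
  expect_equal(hit_quality(1, 60, 60, 60, 60), 0)
  expect_equal(hit_quality(0.5, 30, 30, 60, 60), 0.25)
  # always within [0, 1] for admissible regions
  set.seed(1)
  e <- runif(50, 0, 2); rb <- sample(1:60, 50, TRUE); rg <- sample(1:60, 50, TRUE)
  k <- hit_quality(e, rb, rg, 60, 60)
  expect_true(all(k >= 0 & k <= 1))
})

test_that("bidirectional merge intersects footprints, takes max e-value, drops one-way pairs", {
  exons_b <- exon_row("bA.e1", "bA", "s1", 1, 120, "+")
  exons_g <- exon_row("gA.e1", "gA", "s1", 1, 120, "+")
  ann_b <- make_annotation("beta", exons_b); ann_b$exons$peptide <- strrep("K", 40)
  ann_g <- make_annotation("gamma", exons_g); ann_g$exons$peptide <- strrep("K", 40)
  fwd <- data.frame(query_exon = "bA.e1", subject_exon = "gA.e1",
                    query_start = 10L, query_end = 40L,
                    subject_start = 5L, subject_end = 35L,
                    evalue = 1e-20, bitscore = 80)
  rev <- data.frame(query_exon = "gA.e1", subject_exon = "bA.e1",
                    query_start = 7L, query_end = 33L,
                    subject_start = 12L, subject_end = 38L,
                    evalue = 1e-10, bitscore = 60)
  hs <- make_bidirectional(fwd, rev, ann_b, ann_g)
  expect_equal(nrow(hs$hits), 1L)
  # intersected peptide footprints [12,38] and [7,33] mapped to genomic bp
  expect_equal(hs$hits$start_beta, 1 + 3 * (12 - 1))
  expect_equal(hs$hits$end_beta, 3 * 38)
  expect_equal(hs$hits$start_gamma, 1 + 3 * (7 - 1))
  expect_equal(hs$hits$end_gamma, 3 * 33)
  expect_equal(hs$hits$evalue, 1e-10)

  # one-way pair vanishes
  hs2 <- make_bidirectional(fwd, rev[0, ], ann_b, ann_g)
  expect_equal(nrow(hs2$hits), 0L)

  # two local alignments each way: only mutually overlapping pairings survive
  fwd2 <- rbind(fwd, transform(fwd, query_start = 60L, query_end = 80L,
                               subject_start = 60L, subject_end = 80L))
  rev2 <- rbind(rev, transform(rev, query_start = 62L, query_end = 78L,
                               subject_start = 62L, subject_end = 78L))
  hs3 <- make_bidirectional(fwd2, rev2, ann_b, ann_g)
  expect_equal(nrow(hs3$hits), 2L)
})

test_that("merge is symmetric in the two organisms", {
  fx <- synth_generate(synth_spec(seed = 5, genes_per_scaffold = 6, n_noise = 30))
  dir <- withr::local_tempdir()
  p <- synth_write(fx, dir)
  fwd <- parse_blast_tabular(p["beta_to_gamma"], fx$beta, fx$gamma)
  rev <- parse_blast_tabular(p["gamma_to_beta"], fx$gamma, fx$beta)
  ab <- make_bidirectional(fwd, rev, fx$beta, fx$gamma)
  ba <- make_bidirectional(rev, fwd, fx$gamma, fx$beta)
  key_ab <- sort(paste(ab$hits$exon_beta, ab$hits$exon_gamma,
                       ab$hits$start_beta, ab$hits$start_gamma))
  key_ba <- sort(paste(ba$hits$exon_gamma, ba$hits$exon_beta,
                       ba$hits$start_gamma, ba$hits$start_beta))
  expect_equal(key_ab, key_ba)
})

test_that("hit regions stay inside their exons and best-by-exon is the argmax", {
  fx <- synth_generate(synth_spec(seed = 29, n_noise = 150))
  h <- fx$hits$hits
  exb <- fx$beta$exons[match(h$exon_beta, fx$beta$exons$exon_id), ]
  exg <- fx$gamma$exons[match(h$exon_gamma, fx$gamma$exons$exon_id), ]
  expect_true(all(h$start_beta >= exb$start & h$end_beta <= exb$end))
  expect_true(all(h$start_gamma >= exg$start & h$end_gamma <= exg$end))
  expect_true(all(h$quality >= 0 & h$quality <= 1))
  brute <- tapply(h$quality, h$exon_beta, max)
  expect_equal(unname(fx$hits$best_beta[names(brute)]), as.numeric(brute))
  expect_equal(sort(names(fx$hits$best_beta)), sort(unique(h$exon_beta)))
})

test_that("the external aligner reproduces a planted identical peptide pair", {
  fx <- synth_generate(synth_spec(
    seed = 31, genes_per_scaffold = 3, n_noise = 0,
    blocks = list(list(beta_scaffold = 1, beta_genes = 1:2,
                       gamma_scaffold = 1, gamma_genes = 1:2))))
  dir <- withr::local_tempdir()
  fa_b <- file.path(dir, "b.faa"); fa_g <- file.path(dir, "g.faa")
  write_exon_fasta(fx$beta, fa_b)
  write_exon_fasta(fx$gamma, fa_g)
  tabs <- run_external_aligner(fa_b, fa_g, file.path(dir, "aln"))
  fwd <- parse_blast_tabular(tabs$beta_to_gamma, fx$beta, fx$gamma)
  rev <- parse_blast_tabular(tabs$gamma_to_beta, fx$gamma, fx$beta)
  hs <- make_bidirectional(fwd, rev, fx$beta, fx$gamma)
  planted <- fx$hits$hits[fx$hits$hits$hit_id %in% fx$truth$hit_id, ]
  found <- paste(hs$hits$exon_beta, hs$hits$exon_gamma)
  expect_true(all(paste(planted$exon_beta, planted$exon_gamma) %in% found))
})

test_that("hit tables round-trip through the checkpoint format", {
  fx <- synth_generate(synth_spec(seed = 37, n_noise = 40))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(fx$hits, path)
  back <- read_hit_table(path)
  expect_equal(back$hits, fx$hits$hits)
  expect_equal(back$best_beta, fx$hits$best_beta)
})
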