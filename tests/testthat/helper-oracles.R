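# Independent oracles and compact fixture builders shared across tests.
# These deliberately re-derive results by brute force / enumeration and never
# call the code paths they are used to check.

# Naive O(n^3) single-linkage: returns the sorted multiset of merge heights.
naive_single_linkage_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          d <- min(D[clusters[[i]], clusters[[j]]])
          if (d < best) best <- d
        }
      }
    }
    # merge the first pair achieving the minimum (heights don't depend on
    # which tied pair merges first under single linkage)
    done <- FALSE
    for (i in seq_along(clusters)) {
      if (done) break
      for (j in seq_along(clusters)) {
        if (i < j && min(D[clusters[[i]], clusters[[j]]]) == best) {
          clusters[[i]] <- c(clusters[[i]], clusters[[j]])
          clusters[[j]] <- NULL
          heights <- c(heights, best)
          done <- TRUE
          break
        }
      }
    }
  }
  sort(heights)
}

# Flat partition at height h: connected components of the graph with edges
# D <= h (union-find; independent of any tree construction).
components_at_height <- function(D, h) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (D[i, j] <= h) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  out <- unname(split(seq_len(n), roots))
  out <- lapply(out, sort)
  out[order(vapply(out, `[`, 0L, 1))]
}

# Exact permutation-null p-value by exhaustive enumeration of all unordered
# without-replacement draw combinations from the three pools.
enumerate_exact_p <- function(pool_all, pool_beta, pool_gamma,
                              n_c, n_cbeta, n_cgamma, s_obs, eps = 1e-9) {
  combo_sums <- function(pool, k) {
    if (k == 0) return(0)
    combn(pool, k, sum)
  }
  sa <- 2 * combo_sums(pool_all, n_c)
  sb <- combo_sums(pool_beta, n_cbeta)
  sg <- combo_sums(pool_gamma, n_cgamma)
  grid <- expand.grid(a = sa, b = sb, g = sg)
  mean(grid$a - grid$b - grid$g >= s_obs - eps)
}

# Compact hit-set builder: one row per hit, genomic regions given directly.
make_hits <- function(start_beta, end_beta, start_gamma, end_gamma,
                      quality = 1, evalue = 0,
                      scaffold_beta = "b1", scaffold_gamma = "g1",
                      exon_beta = NULL, exon_gamma = NULL) {
  n <- length(start_beta)
  df <- data.frame(
    hit_id = seq_len(n),
    exon_beta = exon_beta %||% sprintf("bx%d", seq_len(n)),
    exon_gamma = exon_gamma %||% sprintf("gx%d", seq_len(n)),
    scaffold_beta = rep_len(scaffold_beta, n),
    start_beta = start_beta, end_beta = end_beta,
    scaffold_gamma = rep_len(scaffold_gamma, n),
    start_gamma = start_gamma, end_gamma = end_gamma,
    evalue = rep_len(evalue, n), quality = rep_len(quality, n),
    stringsAsFactors = FALSE
  )
  hit_set(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny two-gene annotation for scoring tests: exons laid out explicitly.
make_annotation <- function(organism, exons) {
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(s) {
    data.frame(gene_id = s$gene_id[1], scaffold = s$scaffold[1],
               strand = s$strand[1], start = min(s$start), end = max(s$end),
               stringsAsFactors = FALSE)
  }))
  if (!"frame" %in% names(exons)) exons$frame <- 0L
  genome_annotation(organism, NULL, genes, exons)
}

exon_row <- function(exon_id, gene_id, scaffold, start, end, strand = "+") {
  data.frame(exon_id = exon_id, gene_id = gene_id, scaffold = scaffold,
             strand = strand, start = start, end = end, frame = 0L,
             stringsAsFactors = FALSE)
}

# Default planted-recovery spec: three dense blocks plus background noise.
recovery_spec <- function(seed) {
  synth_spec(
    seed = seed,
    n_scaffolds = c(beta = 2L, gamma = 2L),
    blocks = list(
      list(beta_scaffold = 1, beta_genes = 3:8, gamma_scaffold = 1, gamma_genes = 3:8),
      list(beta_scaffold = 1, beta_genes = 12:17, gamma_scaffold = 2, gamma_genes = 5:10),
      list(beta_scaffold = 2, beta_genes = 2:7, gamma_scaffold = 2, gamma_genes = 14:19)
    ),
    n_noise = 200L
  )
}
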