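#' Exons inside a span that a cluster does not account for
#'
#' An exon is *unaccounted* for a cluster if its interval is fully contained
#' in the cluster's genomic span on that organism and no hit of the cluster
#' has it as an endpoint. Exons only partially overlapping the span boundary
#' are excluded (containment is the conservative reading: partial-overlap
#' counting would penalise every boundary).
#'
#' @param annotation [genome_annotation()] of the organism.
#' @param scaffold Scaffold of the span.
#' @param span_start,span_end Span interval (1-based inclusive).
#' @param accounted_exon_ids Exon ids touched by the cluster's hits on this
#'   organism.
#' @return Character vector of unaccounted exon ids.
#' @export
unaccounted_exons <- function(annotation, scaffold, span_start, span_end,
                              accounted_exon_ids) {
  ex <- annotation$exons
  inside <- ex$scaffold == scaffold & ex$start >= span_start & ex$end <= span_end
  setdiff(ex$exon_id[inside], accounted_exon_ids)
}

#' Cluster score from member and penalty qualities
#'
#' The score of a candidate cluster accumulates twice the qualities of its
#' member hits and subtracts, for every unaccounted exon, the best quality
#' that exon achieves anywhere in the whole hit universe (0 — no penalty —
#' for exons with no hit at all):
#' \deqn{s(C) = 2 \sum_{h \in C} K(h) - \sum_{e \in U_C^\beta \cup U_C^\gamma} \max_{h \in H_e} K(h)}
#'
#' @param member_qualities Qualities `K` of the hits in the cluster.
#' @param unaccounted_best Best genome-wide qualities of the penalised
#'   unaccounted exons (may be empty).
#' @return The score `s(C)` (numeric scalar).
#' @examples
#' cluster_score(c(0.8, 0.9))        # 3.4
#' cluster_score(c(0.8, 0.9), 0.5)   # 2.9
#' @export
cluster_score <- function(member_qualities, unaccounted_best = numeric(0)) {
  2 * sum(member_qualities) - sum(unaccounted_best)
}

#' Conservation ratio of a cluster
#'
#' `(n_C + 1) / (n_Cbeta + n_Cgamma + 1)`, where `n_C` is the number of hits
#' in the cluster and `n_Cchi` the number of unaccounted exons on organism
#' `chi` that have a hit elsewhere in the genome. A user threshold `tau`
#' demands clusters be dense in accounted hits relative to penalised gaps.
#'
#' @param n_hits Number of hits in the cluster (`n_C`).
#' @param n_penalized_beta,n_penalized_gamma Penalised unaccounted-exon
#'   counts per organism.
#' @return The ratio (numeric, always > 0).
#' @examples
#' conservation_ratio(3, 1, 0)  # 2
#' conservation_ratio(1, 2, 2)  # 0.4
#' @export
conservation_ratio <- function(n_hits, n_penalized_beta, n_penalized_gamma) {
  (n_hits + 1) / (n_penalized_beta + n_penalized_gamma + 1)
}

# Precomputed lookup tables shared by all per-node evaluations of one run.
synteny_context <- function(annotation_beta, annotation_gamma, hitset) {
  exb <- annotation_beta$exons
  exg <- annotation_gamma$exons
  list(
    beta = annotation_beta, gamma = annotation_gamma, hitset = hitset,
    hit_row = stats::setNames(seq_len(nrow(hitset$hits)), hitset$hits$hit_id),
    gene_of_beta = stats::setNames(exb$gene_id, exb$exon_id),
    gene_of_gamma = stats::setNames(exg$gene_id, exg$exon_id)
  )
}

#' Evaluate a dendrogram node as a candidate cluster
#'
#' Computes the full cluster evaluation of one node: unaccounted exons per
#' organism, penalised counts, cluster score and conservation ratio, plus the
#' gene sets its hits touch (used by the two-gene rule).
#'
#' @param tree A [build_dendrogram()] result.
#' @param node_id Node index in the tree.
#' @param annotation_beta,annotation_gamma The two annotations.
#' @param hitset The [hit_set()] the tree was built from.
#' @return List with `node_id`, `n_hits`, `score`, `conservation_ratio`,
#'   `unaccounted_beta`, `unaccounted_gamma` (exon ids),
#'   `n_penalized_beta`, `n_penalized_gamma`, `genes_beta`, `genes_gamma`
#'   (gene ids touched by member hits), and the spans.
#' @export
evaluate_cluster <- function(tree, node_id, annotation_beta, annotation_gamma,
                             hitset) {
  ctx <- synteny_context(annotation_beta, annotation_gamma, hitset)
  evaluate_cluster_ctx(tree, node_id, ctx)
}

evaluate_cluster_ctx <- function(tree, node_id, ctx) {
  ids <- tree$members[[node_id]]
  rows <- ctx$hitset$hits[ctx$hit_row[as.character(ids)], , drop = FALSE]
  span_b <- tree$span_beta[node_id, ]
  span_g <- tree$span_gamma[node_id, ]
  touched_b <- unique(rows$exon_beta)
  touched_g <- unique(rows$exon_gamma)
  u_b <- unaccounted_exons(ctx$beta, tree$scaffold_beta, span_b[1], span_b[2],
                           touched_b)
  u_g <- unaccounted_exons(ctx$gamma, tree$scaffold_gamma, span_g[1], span_g[2],
                           touched_g)
  pen_b <- ctx$hitset$best_beta[intersect(u_b, names(ctx$hitset$best_beta))]
  pen_g <- ctx$hitset$best_gamma[intersect(u_g, names(ctx$hitset$best_gamma))]
  n <- length(ids)
  list(
    node_id = node_id,
    n_hits = n,
    score = cluster_score(rows$quality, c(pen_b, pen_g)),
    n_penalized_beta = length(pen_b),
    n_penalized_gamma = length(pen_g),
    conservation_ratio = conservation_ratio(n, length(pen_b), length(pen_g)),
    unaccounted_beta = u_b,
    unaccounted_gamma = u_g,
    genes_beta = unique(unname(ctx$gene_of_beta[touched_b])),
    genes_gamma = unique(unname(ctx$gene_of_gamma[touched_g])),
    span_beta = span_b,
    span_gamma = span_g
  )
}
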