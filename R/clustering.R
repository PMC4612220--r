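#' Genomic distance between two regions on the same scaffold
#'
#' The gap (in bp) between two 1-based inclusive intervals:
#' `max(0, max(s1, s2) - min(e1, e2))`. Overlapping intervals are at distance
#' 0; adjacent intervals (`[10,20]` vs `[21,30]`) are at distance 1.
#' Symmetric and non-negative; not a metric.
#'
#' @param start1,end1,start2,end2 Interval coordinates (vectorised).
#' @param scaffold1,scaffold2 Optional scaffold ids; if given they must be
#'   equal (cross-scaffold distances are undefined by construction).
#' @return Numeric vector of bp distances.
#' @examples
#' region_distance(10, 20, 30, 40)  # 10
#' region_distance(10, 25, 20, 40)  # 0 (overlap)
#' @export
region_distance <- function(start1, end1, start2, end2,
                            scaffold1 = NULL, scaffold2 = NULL) {
  if (!is.null(scaffold1) && !is.null(scaffold2) && any(scaffold1 != scaffold2)) {
    stopf("region_distance called on regions from different scaffolds")
  }
  pmax(0, pmax(start1, start2) - pmin(end1, end2))
}

#' Distance between two hits
#'
#' Sum of the region distances on the two genomes. Both hits must belong to
#' the same scaffold pair.
#'
#' @param h1,h2 Single rows of a hit table (see [hit_set()]).
#' @return bp distance (numeric scalar).
#' @export
hit_distance <- function(h1, h2) {
  if (h1$scaffold_beta != h2$scaffold_beta || h1$scaffold_gamma != h2$scaffold_gamma) {
    stopf("hit_distance called on hits from different scaffold pairs")
  }
  region_distance(h1$start_beta, h1$end_beta, h2$start_beta, h2$end_beta) +
    region_distance(h1$start_gamma, h1$end_gamma, h2$start_gamma, h2$end_gamma)
}

#' Pairwise hit-distance matrix for one scaffold pair
#'
#' @param hits Hit table rows, all on one scaffold pair.
#' @return Symmetric numeric matrix of bp distances.
#' @export
hit_distance_matrix <- function(hits) {
  if (length(unique(hits$scaffold_beta)) > 1 ||
      length(unique(hits$scaffold_gamma)) > 1) {
    stopf("hit_distance_matrix requires hits from a single scaffold pair")
  }
  db <- outer(hits$start_beta, hits$start_beta, pmax) -
    outer(hits$end_beta, hits$end_beta, pmin)
  dg <- outer(hits$start_gamma, hits$start_gamma, pmax) -
    outer(hits$end_gamma, hits$end_gamma, pmin)
  db[db < 0] <- 0
  dg[dg < 0] <- 0
  db + dg
}

#' Single-linkage dendrogram over the hits of one scaffold pair
#'
#' Agglomerative single-linkage clustering under [hit_distance()]. Every node
#' of the binary merge tree is a candidate syntenic cluster carrying its
#' member hits, merge height (bp), and genomic spans on both organisms.
#' Tie-breaking is deterministic: among merges at equal distance, the pair
#' whose smallest member `hit_id` is smallest (then the smaller partner id)
#' is merged first, so the tree is independent of input order.
#'
#' @param hits Hit table rows for one scaffold pair (>= 1 row).
#' @return An object of class `hit_dendrogram`: a list with parallel node
#'   vectors `child1`, `child2` (0 for leaves), `height`, `n_hits`,
#'   `min_hit`, span matrices `span_beta`/`span_gamma` (columns start, end),
#'   and `members` (list of member `hit_id`s per node). Leaves are nodes
#'   `1..n` in input row order; the root is node `2n - 1`.
#' @export
build_dendrogram <- function(hits) {
  n <- nrow(hits)
  if (is.null(n) || n < 1) stopf("build_dendrogram needs at least one hit")
  n_nodes <- 2L * n - 1L
  child1 <- child2 <- integer(n_nodes)
  height <- numeric(n_nodes)
  n_hits <- integer(n_nodes); n_hits[1:n] <- 1L
  min_hit <- numeric(n_nodes); min_hit[1:n] <- hits$hit_id
  members <- vector("list", n_nodes)
  members[1:n] <- as.list(hits$hit_id)
  span_b <- matrix(0, n_nodes, 2, dimnames = list(NULL, c("start", "end")))
  span_g <- span_b
  span_b[1:n, ] <- cbind(hits$start_beta, hits$end_beta)
  span_g[1:n, ] <- cbind(hits$start_gamma, hits$end_gamma)

  if (n > 1) {
    D <- hit_distance_matrix(hits)
    diag(D) <- Inf
    node_of <- 1:n              # active position -> node id
    for (k in seq_len(n - 1L)) {
      m0 <- min(D)
      cand <- which(D == m0, arr.ind = TRUE)
      cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
      a <- min_hit[node_of[cand[, 1]]]
      b <- min_hit[node_of[cand[, 2]]]
      lo <- pmin(a, b); hi <- pmax(a, b)
      pick <- order(lo, hi)[1]
      i <- cand[pick, 1]; j <- cand[pick, 2]
      ni <- node_of[i]; nj <- node_of[j]
      new <- n + k
      if (min_hit[ni] > min_hit[nj]) { tmp <- ni; ni <- nj; nj <- tmp }
      child1[new] <- ni; child2[new] <- nj
      height[new] <- m0
      n_hits[new] <- n_hits[ni] + n_hits[nj]
      min_hit[new] <- min(min_hit[ni], min_hit[nj])
      members[[new]] <- c(members[[ni]], members[[nj]])
      span_b[new, ] <- c(min(span_b[ni, 1], span_b[nj, 1]),
                         max(span_b[ni, 2], span_b[nj, 2]))
      span_g[new, ] <- c(min(span_g[ni, 1], span_g[nj, 1]),
                         max(span_g[ni, 2], span_g[nj, 2]))
      # single-linkage update: fold column j into i, drop j
      new_row <- pmin(D[i, ], D[j, ])
      D[i, ] <- new_row; D[, i] <- new_row
      D[i, i] <- Inf
      D <- D[-j, -j, drop = FALSE]
      node_of[i] <- new
      node_of <- node_of[-j]
    }
  }
  structure(
    list(scaffold_beta = hits$scaffold_beta[1],
         scaffold_gamma = hits$scaffold_gamma[1],
         n_leaves = n, root = n_nodes,
         child1 = child1, child2 = child2, height = height,
         n_hits = n_hits, min_hit = min_hit, members = members,
         span_beta = span_b, span_gamma = span_g,
         leaf_hit_ids = hits$hit_id),
    class = "hit_dendrogram"
  )
}

#' @export
print.hit_dendrogram <- function(x, ...) {
  cat(sprintf("<hit_dendrogram> %s vs %s: %d hit(s), root height %.0f bp\n",
              x$scaffold_beta, x$scaffold_gamma, x$n_leaves, x$height[x$root]))
  invisible(x)
}

#' Build one dendrogram per scaffold pair
#'
#' Hits are first bucketed by the pair of scaffolds they fall on (one per
#' organism); a single-linkage dendrogram is built independently for each
#' non-empty bucket. An exon with hits on several partner scaffolds therefore
#' appears in several trees, which is how duplications are handled.
#'
#' @param hitset A [hit_set()].
#' @return An object of class `synteny_forest`: list with `trees` (named list
#'   of [build_dendrogram()] results keyed `"<scaffold_beta>|<scaffold_gamma>"`)
#'   and `pairs` (data.frame of scaffold pairs and hit counts).
#' @export
build_forest <- function(hitset) {
  stopifnot(inherits(hitset, "hit_set"))
  h <- hitset$hits
  key <- scaffold_pair_key(h$scaffold_beta, h$scaffold_gamma)
  keys <- sort(unique(key))
  trees <- lapply(keys, function(k) build_dendrogram(h[key == k, , drop = FALSE]))
  names(trees) <- keys
  pairs <- data.frame(
    key = keys,
    scaffold_beta = vapply(trees, `[[`, "", "scaffold_beta"),
    scaffold_gamma = vapply(trees, `[[`, "", "scaffold_gamma"),
    n_hits = vapply(trees, function(t) t$n_leaves, 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(trees = trees, pairs = pairs), class = "synteny_forest")
}

#' @export
print.synteny_forest <- function(x, ...) {
  cat(sprintf("<synteny_forest> %d scaffold-pair tree(s), %d hit(s) total\n",
              length(x$trees), sum(x$pairs$n_hits)))
  invisible(x)
}

#' Flat clusters of a dendrogram at a height threshold
#'
#' Returns the partition of hits obtained by keeping only merges at height
#' `<= h` — the clusters the tree implies at that height.
#'
#' @param tree A [build_dendrogram()] result.
#' @param h Height threshold (bp).
#' @return List of integer vectors of `hit_id`s, one per cluster, each sorted;
#'   the list is sorted by first element.
#' @export
clusters_at_height <- function(tree, h) {
  keep_node <- function(v) {
    if (tree$child1[v] == 0L || tree$height[v] <= h) return(list(sort(tree$members[[v]])))
    c(keep_node(tree$child1[v]), keep_node(tree$child2[v]))
  }
  out <- keep_node(tree$root)
  out[order(vapply(out, `[`, 0, 1))]
}

#' Serialize a dendrogram to Newick
#'
#' Debug helper: leaf names are `h<hit_id>`, branch lengths are the height
#' differences between parent and child merges.
#'
#' @param tree A [build_dendrogram()] result.
#' @return Newick string (with trailing `;`).
#' @export
as_newick <- function(tree) {
  rec <- function(v, parent_h) {
    bl <- parent_h - tree$height[v]
    if (tree$child1[v] == 0L) {
      sprintf("h%d:%.6g", tree$members[[v]][1], bl)
    } else {
      sprintf("(%s,%s):%.6g", rec(tree$child1[v], tree$height[v]),
              rec(tree$child2[v], tree$height[v]), bl)
    }
  }
  v <- tree$root
  if (tree$child1[v] == 0L) return(sprintf("(h%d:0);", tree$members[[v]][1]))
  sprintf("(%s,%s);", rec(tree$child1[v], tree$height[v]),
          rec(tree$child2[v], tree$height[v]))
}
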