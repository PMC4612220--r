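#' Run configuration for synteny detection
#'
#' Collects the tunable parameters of the statistical engine.
#'
#' @param alpha Family-wise significance threshold (default 0.05).
#' @param tau Minimum conservation ratio a reported cluster must satisfy.
#'   1 is appropriate for divergent genomes; 2 for closely related strains.
#' @param clt_min_n Minimum cluster size (`n_C`) at which the normal (CLT)
#'   approximation replaces the permutation test (default 30).
#' @param early_stop_k Stop a permutation test once this many exceedances
#'   have been seen (the node can then never be significant; default 10).
#' @param max_perms_cap Hard ceiling on permutations per node (default 2e5).
#' @param seed Base seed; every random draw in a run derives from it.
#' @return A list of class `synteny_config`.
#' @export
synteny_config <- function(alpha = 0.05, tau = 1, clt_min_n = 30,
                           early_stop_k = 10, max_perms_cap = 200000L,
                           seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, tau >= 0, clt_min_n >= 2,
            early_stop_k >= 1, max_perms_cap >= 1)
  structure(list(alpha = alpha, tau = tau, clt_min_n = clt_min_n,
                 early_stop_k = as.integer(early_stop_k),
                 max_perms_cap = as.integer(max_perms_cap),
                 seed = as.integer(seed)),
            class = "synteny_config")
}

#' Construct a permutation null model from raw quality pools
#'
#' The null distribution of cluster scores is induced by drawing hit
#' qualities at random (without replacement) from three pools: all hit
#' qualities in the hit universe, and the per-exon best-hit qualities of each
#' organism (for exons with at least one hit). Exact pool moments
#' (population mean and variance) back the CLT approximation.
#'
#' @param pool_all Numeric vector of all hit qualities (`|H|` values).
#' @param pool_best_beta,pool_best_gamma Per-exon best-hit qualities.
#' @param seed Seed recorded with the model.
#' @return Object of class `null_model` with the pools and their `moments`.
#' @export
null_model <- function(pool_all, pool_best_beta, pool_best_gamma, seed = 1L) {
  if (!length(pool_all)) stopf("null model requires a non-empty hit universe")
  mom <- function(x) {
    m <- mean(x)
    list(n = length(x), mean = m, var = mean((x - m)^2))
  }
  structure(
    list(pool_all = as.numeric(pool_all),
         pool_best_beta = as.numeric(pool_best_beta),
         pool_best_gamma = as.numeric(pool_best_gamma),
         moments = list(all = mom(pool_all), beta = mom(pool_best_beta),
                        gamma = mom(pool_best_gamma)),
         seed = as.integer(seed)),
    class = "null_model"
  )
}

#' Build the permutation null model from a hit set
#'
#' @param hitset A [hit_set()].
#' @param seed Seed recorded with the model.
#' @return A [null_model()].
#' @export
build_null_model <- function(hitset, seed = 1L) {
  stopifnot(inherits(hitset, "hit_set"))
  if (!nrow(hitset$hits)) stopf("null model requires a non-empty hit set")
  null_model(hitset$hits$quality,
             unname(hitset$best_beta), unname(hitset$best_gamma), seed)
}

#' Draw permuted cluster scores from the null model
#'
#' One permuted score is
#' \deqn{s_p = 2 \sum_{k=1}^{n_C} P_k - \left( \sum_{k=1}^{n_{C\beta}} P_k^{\beta*} + \sum_{k=1}^{n_{C\gamma}} P_k^{\gamma*} \right)}
#' with each sum drawn without replacement from a freshly shuffled copy of
#' its pool. Requested draw counts exceeding a pool size are truncated to the
#' pool size (a without-replacement sample cannot exceed its population).
#'
#' @param null A [null_model()].
#' @param n_c,n_cbeta,n_cgamma Cluster size and penalised-exon counts.
#' @param n_draws Number of permuted scores to draw.
#' @return Numeric vector of `n_draws` permuted scores. Uses (and advances)
#'   the current RNG state; seed upstream for reproducibility.
#' @export
permuted_scores <- function(null, n_c, n_cbeta, n_cgamma, n_draws = 1L) {
  pa <- null$pool_all; pb <- null$pool_best_beta; pg <- null$pool_best_gamma
  na_ <- length(pa); nb_ <- length(pb); ng_ <- length(pg)
  n_c <- min(n_c, na_); n_cbeta <- min(n_cbeta, nb_); n_cgamma <- min(n_cgamma, ng_)
  out <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    s <- if (n_c > 0) 2 * sum(pa[sample.int(na_, n_c)]) else 0
    if (n_cbeta > 0) s <- s - sum(pb[sample.int(nb_, n_cbeta)])
    if (n_cgamma > 0) s <- s - sum(pg[sample.int(ng_, n_cgamma)])
    out[i] <- s
  }
  out
}

# comparisons between observed and permuted scores tolerate float noise
SCORE_EPS <- 1e-9

# Extend a permutation test record to `target_draws` draws (or an early stop
# at `k` exceedances), reusing its stored RNG state so earlier permutations
# are never repeated or wasted.
perm_extend <- function(rec, null, s_obs, n_c, n_cbeta, n_cgamma,
                        target_draws, k, chunk = 256L) {
  if (rec$n_exceed >= k || rec$n_draws >= target_draws) return(rec)
  old_rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv()))
  if (is.null(rec$rng_state)) set.seed(rec$seed) else
    assign(".Random.seed", rec$rng_state, globalenv())
  while (rec$n_draws < target_draws && rec$n_exceed < k) {
    b <- min(chunk, target_draws - rec$n_draws)
    sp <- permuted_scores(null, n_c, n_cbeta, n_cgamma, b)
    rec$n_exceed <- rec$n_exceed + sum(sp >= s_obs - SCORE_EPS)
    rec$n_draws <- rec$n_draws + b
  }
  rec$rng_state <- get(".Random.seed", globalenv())
  rec$p_raw <- (rec$n_exceed + 1) / (rec$n_draws + 1)
  rec$stopped <- rec$n_exceed >= k
  rec
}

#' Permutation p-value for an observed cluster score
#'
#' Draws permuted scores until either `early_stop_k` of them reach the
#' observed score (the cluster can then never be significant: further draws
#' can only increase the p estimate past any threshold the budget could
#' resolve) or `max_perms` draws have been consumed. The estimate is the
#' add-one estimator `(n_exceed + 1) / (n_draws + 1)`.
#'
#' @param null A [null_model()].
#' @param s_obs Observed cluster score.
#' @param n_c,n_cbeta,n_cgamma Cluster size and penalised-exon counts.
#' @param max_perms Permutation budget.
#' @param early_stop_k Exceedance count triggering the early stop; `Inf`
#'   disables early stopping.
#' @param seed Seed for this test's private RNG substream.
#' @return A test record: list with `p_raw`, `n_draws`, `n_exceed`,
#'   `stopped`, `method = "permutation"` and the saved RNG state (so the test
#'   can later be extended without re-drawing).
#' @export
p_value_permutation <- function(null, s_obs, n_c, n_cbeta, n_cgamma,
                                max_perms = 10000L, early_stop_k = 10L,
                                seed = 1L) {
  stopifnot(max_perms >= 1)
  rec <- list(seed = seed, rng_state = NULL, n_draws = 0L, n_exceed = 0L,
              p_raw = NA_real_, stopped = FALSE, method = "permutation")
  perm_extend(rec, null, s_obs, n_c, n_cbeta, n_cgamma, max_perms, early_stop_k)
}

#' Normal (CLT) approximation to the permutation null
#'
#' For large clusters the permuted score is a sum of many draws and its null
#' distribution is well approximated by a normal with
#' `mean = 2 n_C mu_all - n_Cbeta mu_beta - n_Cgamma mu_gamma` and
#' `variance = 4 n_C sigma2_all f_all + n_Cbeta sigma2_beta f_beta +
#' n_Cgamma sigma2_gamma f_gamma`, where `f = (N - n) / (N - 1)` is the
#' finite-population correction of each pool (draws are without replacement;
#' the three pools are treated as independent). The p-value is the upper-tail
#' probability at the observed score.
#'
#' @inheritParams p_value_permutation
#' @param clt_min_n Minimum `n_C` for the approximation to be trusted; below
#'   it the caller must use [p_value_permutation()].
#' @return Test record with `p_raw`, `mean`, `sd`, `method = "clt"`.
#' @export
p_value_clt <- function(null, s_obs, n_c, n_cbeta, n_cgamma, clt_min_n = 30) {
  if (n_c < clt_min_n) {
    stopf("cluster too small for the CLT approximation (n_C = %d < %d); use the permutation test",
          n_c, clt_min_n)
  }
  mom <- null$moments
  fpc <- function(N, n) if (N <= 1) 0 else (N - n) / (N - 1)
  n_c <- min(n_c, mom$all$n)
  n_cbeta <- min(n_cbeta, mom$beta$n)
  n_cgamma <- min(n_cgamma, mom$gamma$n)
  mu <- 2 * n_c * mom$all$mean - n_cbeta * mom$beta$mean - n_cgamma * mom$gamma$mean
  v <- 4 * n_c * mom$all$var * fpc(mom$all$n, n_c) +
    n_cbeta * mom$beta$var * fpc(mom$beta$n, n_cbeta) +
    n_cgamma * mom$gamma$var * fpc(mom$gamma$n, n_cgamma)
  p <- if (v <= 0) as.numeric(s_obs <= mu + SCORE_EPS) else
    stats::pnorm(s_obs, mean = mu, sd = sqrt(v), lower.tail = FALSE)
  list(p_raw = p, mean = mu, sd = sqrt(max(v, 0)), n_draws = 0L,
       n_exceed = NA_integer_, stopped = FALSE, method = "clt")
}

#' Two-gene rule
#'
#' Clusters touching fewer than two distinct genes on either organism are
#' homology statements, not synteny, and are never tested.
#'
#' @param tree,node_id The node to check.
#' @param annotation_beta,annotation_gamma Annotations.
#' @param hitset The [hit_set()].
#' @return `TRUE` iff the node's hits touch >= 2 distinct genes on *each*
#'   organism.
#' @export
passes_two_gene_rule <- function(tree, node_id, annotation_beta,
                                 annotation_gamma, hitset) {
  ev <- evaluate_cluster(tree, node_id, annotation_beta, annotation_gamma, hitset)
  length(ev$genes_beta) >= 2 && length(ev$genes_gamma) >= 2
}

#' Worst-case Bonferroni correction
#'
#' Testing every node of every dendrogram would in the worst case perform
#' `2|H|` tests; the dynamically grown correction factor never exceeds this
#' bound.
#'
#' @param hitset A [hit_set()] (or an integer hit count).
#' @return `2 |H|` (0 for an empty hit universe).
#' @export
worst_case_correction <- function(hitset) {
  n <- if (inherits(hitset, "hit_set")) nrow(hitset$hits) else as.integer(hitset)
  2L * n
}

# permutation budget needed to resolve significance at correction factor m:
# enough draws that p can fall below alpha/m with a 10x margin, and few
# enough that an early stop at k exceedances is already conclusive.
perm_target <- function(m, alpha, cap) {
  min(as.integer(cap), as.integer(ceiling(10 * m / alpha)))
}

#' Greedy dynamic cut of the dendrogram forest
#'
#' Traverses every scaffold-pair dendrogram depth-first from the root. A node
#' is reported (cut) when it passes the two-gene rule, satisfies the
#' conservation-ratio threshold `tau`, is significant at the current
#' Bonferroni level (`p_raw * m <= alpha`, where the correction factor `m` is
#' the number of distinct nodes tested so far across the whole forest), and
#' no child has a strictly lower p-value while satisfying `tau` (ties go to
#' the parent, preferring the larger syntenic context). Otherwise the
#' traversal descends, which grows `m`. Because `m` grows, nodes already
#' called significant are revisited — reusing their earlier permutation
#' draws — and the whole procedure iterates to a fixed point.
#'
#' @param forest A [build_forest()] result.
#' @param annotation_beta,annotation_gamma Annotations.
#' @param hitset The [hit_set()] behind the forest.
#' @param null A [null_model()]; built from `hitset` if `NULL`.
#' @param config A [synteny_config()].
#' @return List with `clusters` (data.frame, one row per reported cluster:
#'   spans, `n_hits`, gene counts, `score`, `conservation_ratio`, `p_raw`,
#'   `p_corrected`, `method`), `correction_factor` (final `m`), `n_tested`,
#'   and `ledger` (data.frame of every tested node for auditability).
#' @export
dynamic_cut <- function(forest, annotation_beta, annotation_gamma, hitset,
                        null = NULL, config = synteny_config()) {
  stopifnot(inherits(forest, "synteny_forest"))
  if (is.null(null)) null <- build_null_model(hitset, config$seed)
  ctx <- synteny_context(annotation_beta, annotation_gamma, hitset)
  alpha <- config$alpha; tau <- config$tau; k_stop <- config$early_stop_k

  st <- new.env(parent = emptyenv())
  st$m <- 0L                 # correction factor = distinct nodes tested
  st$recs <- list()          # per-node test records
  st$evals <- list()         # per-node cluster evaluations

  node_key <- function(tkey, v) paste(tkey, v, sep = "#")

  get_eval <- function(tkey, tree, v) {
    key <- node_key(tkey, v)
    ev <- st$evals[[key]]
    if (is.null(ev)) {
      ev <- evaluate_cluster_ctx(tree, v, ctx)
      st$evals[[key]] <- ev
    }
    ev
  }

  two_gene <- function(ev) length(ev$genes_beta) >= 2 && length(ev$genes_gamma) >= 2

  get_rec <- function(tkey, tree, v, ti) {
    key <- node_key(tkey, v)
    rec <- st$recs[[key]]
    if (is.null(rec)) {
      st$m <- st$m + 1L
      ev <- get_eval(tkey, tree, v)
      if (ev$n_hits >= config$clt_min_n) {
        rec <- p_value_clt(null, ev$score, ev$n_hits, ev$n_penalized_beta,
                           ev$n_penalized_gamma, config$clt_min_n)
      } else {
        rec <- p_value_permutation(
          null, ev$score, ev$n_hits, ev$n_penalized_beta, ev$n_penalized_gamma,
          max_perms = perm_target(st$m, alpha, config$max_perms_cap),
          early_stop_k = k_stop,
          seed = derive_seed(config$seed, ti, v))
      }
      st$recs[[key]] <- rec
    }
    rec
  }

  # Extend a permutation record to the resolution required at factor m.
  ensure_res <- function(tkey, v, target) {
    key <- node_key(tkey, v)
    rec <- st$recs[[key]]
    if (rec$method == "permutation" && !rec$stopped && rec$n_draws < target) {
      ev <- st$evals[[key]]
      rec <- perm_extend(rec, null, ev$score, ev$n_hits, ev$n_penalized_beta,
                         ev$n_penalized_gamma, target, k_stop)
      st$recs[[key]] <- rec
    }
    rec
  }

  visit <- function(tkey, tree, v, ti, cuts) {
    ev <- get_eval(tkey, tree, v)
    if (!two_gene(ev)) return(cuts)
    rec_v <- get_rec(tkey, tree, v, ti)
    kids <- c(tree$child1[v], tree$child2[v])
    kids <- kids[kids != 0L]
    kid_info <- lapply(kids, function(w) {
      evw <- get_eval(tkey, tree, w)
      if (!two_gene(evw)) return(NULL)
      list(node = w, ev = evw, rec = get_rec(tkey, tree, w, ti))
    })
    kid_info <- Filter(Negate(is.null), kid_info)
    # compare parent and children at a common permutation resolution so a
    # later-tested node cannot win on draw count alone
    target <- perm_target(st$m, alpha, config$max_perms_cap)
    rec_v <- ensure_res(tkey, v, target)
    for (ki in kid_info) ki$rec <- ensure_res(tkey, ki$node, target)
    kid_recs <- lapply(kid_info, function(ki) st$recs[[node_key(tkey, ki$node)]])
    better_child <- FALSE
    for (i in seq_along(kid_info)) {
      if (kid_recs[[i]]$p_raw < rec_v$p_raw - SCORE_EPS &&
          kid_info[[i]]$ev$conservation_ratio >= tau) {
        better_child <- TRUE
      }
    }
    significant <- !rec_v$stopped && rec_v$p_raw * st$m <= alpha
    if (ev$conservation_ratio >= tau && significant && !better_child) {
      cuts[[node_key(tkey, v)]] <- list(tkey = tkey, node = v, tree_index = ti)
      return(cuts)
    }
    for (ki in kid_info) cuts <- visit(tkey, tree, ki$node, ti, cuts)
    # children failing the two-gene rule end their branch: all their
    # descendants touch no more genes than they do
    cuts
  }

  tkeys <- names(forest$trees)
  cuts <- list(); sig_prev <- NULL
  for (round in seq_len(50L)) {
    cuts <- list()
    for (ti in seq_along(tkeys)) {
      tkey <- tkeys[ti]
      tree <- forest$trees[[tkey]]
      cuts <- visit(tkey, tree, tree$root, ti, cuts)
    }
    sig <- paste(sort(names(cuts)), collapse = ";")
    sig <- paste(sig, st$m)
    if (identical(sig, sig_prev)) break
    sig_prev <- sig
  }

  clusters <- do.call(rbind, lapply(cuts, function(cc) {
    ev <- st$evals[[node_key(cc$tkey, cc$node)]]
    rec <- st$recs[[node_key(cc$tkey, cc$node)]]
    tree <- forest$trees[[cc$tkey]]
    data.frame(
      scaffold_beta = tree$scaffold_beta,
      start_beta = ev$span_beta[1], end_beta = ev$span_beta[2],
      scaffold_gamma = tree$scaffold_gamma,
      start_gamma = ev$span_gamma[1], end_gamma = ev$span_gamma[2],
      n_hits = ev$n_hits,
      n_genes_beta = length(ev$genes_beta),
      n_genes_gamma = length(ev$genes_gamma),
      score = ev$score,
      conservation_ratio = ev$conservation_ratio,
      p_raw = rec$p_raw,
      method = rec$method,
      tree = cc$tkey, node = cc$node,
      hit_ids = I(list(sort(tree$members[[cc$node]]))),
      genes_beta = I(list(sort(ev$genes_beta))),
      genes_gamma = I(list(sort(ev$genes_gamma))),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(clusters)) {
    clusters <- data.frame()
  } else {
    clusters <- clusters[order(clusters$scaffold_beta, clusters$start_beta,
                               clusters$scaffold_gamma, clusters$start_gamma), ,
                         drop = FALSE]
    clusters <- cbind(cluster_id = seq_len(nrow(clusters)), clusters)
    clusters$p_corrected <- pmin(1, clusters$p_raw * st$m)
    clusters$correction_factor <- st$m
    rownames(clusters) <- NULL
  }

  ledger <- do.call(rbind, lapply(names(st$recs), function(key) {
    rec <- st$recs[[key]]; ev <- st$evals[[key]]
    data.frame(node = key, n_hits = ev$n_hits, score = ev$score,
               conservation_ratio = ev$conservation_ratio,
               method = rec$method, p_raw = rec$p_raw,
               n_draws = rec$n_draws, stopped = rec$stopped,
               stringsAsFactors = FALSE)
  }))

  list(clusters = clusters, correction_factor = st$m, n_tested = st$m,
       ledger = ledger %||% data.frame())
}
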