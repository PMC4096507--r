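#' Weighted clustering coefficient (Onnela-type)
#'
#' Geometric-mean triangle intensity: for node i with degree `k_i` in the
#' graph's skeleton (edges with nonzero weight),
#' `Cw_i = sum_(j,h) (w_ij * w_jh * w_hi)^(1/3) / (k_i * (k_i - 1))`, and Cw
#' the mean over all nodes (nodes with fewer than 2 neighbours contribute 0).
#' Weights are overlaps in \[0, 1\], so no max-weight rescaling is applied.
#' Cw is 1 when every pair overlaps completely, 0 when no triangles exist.
#'
#' @param net an [overlap_network] (or a [diet_matrix]). Edges of weight 0
#'   (or masked to `NA`) are treated as absent.
#' @return Cw in \[0, 1\].
#' @export
weighted_clustering_coefficient <- function(net) {
  if (inherits(net, "diet_matrix")) net <- pairwise_overlap(net)
  w <- net$weights
  n <- nrow(w)
  if (n < 3L) stop("weighted clustering is undefined for fewer than 3 nodes")
  w[is.na(w)] <- 0
  diag(w) <- 0
  a <- w^(1 / 3)
  deg <- rowSums(w > 0)
  tri <- diag(a %*% a %*% a)          # ordered (j,h) walks i->j->h->i
  ci <- ifelse(deg >= 2, tri / (deg * pmax(deg - 1, 1)), 0)
  mean(ci)
}

# mask an overlap weight matrix to its significant edges (threshold matrix
# from pair_overlap_thresholds); non-significant weights become 0
mask_significant <- function(w, theta) {
  out <- w
  out[!(w > theta)] <- 0
  diag(out) <- NA_real_
  out
}

# per-pair 95% null-overlap cut-offs under the diet bootstrap. theta[j,k] is
# the m-th largest of n_boot null overlaps with m = floor(alpha*(n_boot+1)),
# so that (observed > theta) is exactly the add-one p <= alpha rule.
# Each pair consumes an independent sub-stream of the master seed.
pair_overlap_thresholds <- function(m, n_boot, seed, alpha = 0.05) {
  q <- pooled_proportions(m)
  totals <- rowSums(m$counts)
  n <- length(totals)
  m0 <- max(1L, floor(alpha * (n_boot + 1)))
  theta <- matrix(Inf, n, n, dimnames = list(names(totals), names(totals)))
  counter <- 0L
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      counter <- counter + 1L
      set.seed(derive_seed(seed, counter))
      pj <- rmultinom(n_boot, totals[j], q) / totals[j]
      pk <- rmultinom(n_boot, totals[k], q) / totals[k]
      null_w <- 1 - 0.5 * colSums(abs(pj - pk))
      theta[j, k] <- theta[k, j] <- sort(null_w, decreasing = TRUE)[m0]
    }
  }
  theta
}

#' Normalize an observed Cw against its null mean
#'
#' The relative clustering index
#' `C_ws = (Cw_obs - mean(Cw_null)) / D`, where `D = 1 - mean(Cw_null)` when
#' the observed value is at or above the null mean and `D = mean(Cw_null)`
#' otherwise. This two-sided normalization maps any observed Cw into
#' \[-1, +1\]: +1 at maximal clustering, -1 at maximal overdispersion, 0 when
#' the network is exactly as clustered as its null expectation.
#'
#' @param cw_obs observed weighted clustering coefficient.
#' @param cw_null_mean mean of the null Cw distribution.
#' @return C_ws in \[-1, 1\].
#' @export
cws_normalize <- function(cw_obs, cw_null_mean) {
  d <- if (cw_obs >= cw_null_mean) 1 - cw_null_mean else cw_null_mean
  if (d <= 0) return(0)
  max(-1, min(1, (cw_obs - cw_null_mean) / d))
}

#' Relative clustering index C_ws with diet-bootstrap null test
#'
#' The clustering statistic is the Onnela-type weighted clustering
#' coefficient of the overlap network restricted to its significant edges:
#' per-pair 95% null-overlap thresholds are computed once under the diet
#' bootstrap (see [significant_overlap_graph()]), the observed network is
#' masked to the edges exceeding them, and Cw is evaluated on that masked
#' graph. The null distribution of Cw re-applies the same thresholds to
#' `n_boot` bootstrap populations, so observed and null values are
#' exchangeable under the no-structure hypothesis. C_ws is the normalized
#' deviation ([cws_normalize()]); the test is two-tailed: `"clustered"` when
#' the observed Cw exceeds the 97.5% null quantile, `"overdispersed"` below
#' the 2.5% quantile, `"neither"` otherwise.
#'
#' @param m a [diet_matrix].
#' @param n_boot bootstrap resamples, used both for the per-pair thresholds
#'   and for the null Cw ensemble (default 10000).
#' @param seed master integer seed.
#' @param alpha two-sided significance level (default 0.05).
#' @param edge_alpha per-pair significance level for the edge mask
#'   (default 0.05, the 95% rule).
#' @return an object of classes `cws_result`, `topology_result` with the
#'   observed `Cw`, `C_ws`, the null band `ci` on the C_ws scale, two-sided
#'   p-value and verdict.
#' @export
cws_index <- function(m, n_boot = 10000, seed = 1L, alpha = 0.05,
                      edge_alpha = 0.05) {
  stopifnot(n_boot >= 1)
  m <- as_diet_matrix(m)
  q <- pooled_proportions(m)
  totals <- rowSums(m$counts)
  n <- length(totals)
  theta <- pair_overlap_thresholds(m, n_boot, seed, edge_alpha)
  w_obs <- pairwise_overlap(m)$weights
  cw_obs <- weighted_clustering_coefficient(
    structure(list(weights = mask_significant(w_obs, theta), ids = names(totals)),
              class = "overlap_network"))
  set.seed(derive_seed(seed, 0L))
  vals <- vapply(seq_len(n_boot), function(b) {
    counts <- t(vapply(totals, function(tt) rmultinom(1L, tt, q)[, 1L],
                       numeric(length(q))))
    wb <- pairwise_overlap(counts / totals)$weights
    weighted_clustering_coefficient(
      structure(list(weights = mask_significant(wb, theta), ids = names(totals)),
                class = "overlap_network"))
  }, numeric(1))
  ens <- null_ensemble(vals, "Cw", "diet_bootstrap", seed)
  nm <- mean(vals)
  cws <- cws_normalize(cw_obs, nm)
  lo <- stats::quantile(vals, alpha / 2, names = FALSE)
  hi <- stats::quantile(vals, 1 - alpha / 2, names = FALSE)
  verdict <- if (cw_obs > hi) "clustered" else if (cw_obs < lo) "overdispersed" else "neither"
  p <- pvalue(cw_obs, ens, "two-sided")
  topology_result("cws_result", "C_ws", cws, ens, p, verdict,
                  extra = list(Cw = cw_obs,
                               ci = c(lower = cws_normalize(lo, nm),
                                      upper = cws_normalize(hi, nm)),
                               alpha = alpha, season = m$season))
}

#' Pairwise-significance (association) graph of an overlap network
#'
#' For every unordered pair of individuals, the observed overlap is compared
#' with its own null distribution: both rows are redrawn `n_boot` times from
#' the pooled proportions ([bootstrap_diets] scheme, each pair on an
#' independent sub-stream derived from the master seed, see [derive_seed()]),
#' and the pair is connected whenever the add-one upper p-value is at most
#' `alpha` — i.e. the observed overlap exceeds the pair's 95% null quantile.
#' Per-pair (rather than global) thresholds are used because pairs differ in
#' sample size. These are the binary association matrices from which cluster
#' affiliation is read ([extract_clusters()]).
#'
#' @param m a [diet_matrix].
#' @param n_boot per-pair null resamples (default 1000).
#' @param seed master integer seed.
#' @param alpha per-pair significance level (default 0.05).
#' @return a square symmetric [binary_matrix] on individuals (the
#'   significant-overlap adjacency).
#' @export
significant_overlap_graph <- function(m, n_boot = 1000, seed = 1L, alpha = 0.05) {
  m <- as_diet_matrix(m)
  theta <- pair_overlap_thresholds(m, n_boot, seed, alpha)
  w <- pairwise_overlap(m)$weights
  adj <- (w > theta) * 1
  adj[is.na(adj)] <- 0
  diag(adj) <- 0
  as_binary_matrix(adj)
}

#' Extract dietary clusters from a pairwise-significance graph
#'
#' Clusters are the connected components of the significant-overlap graph:
#' two individuals belong to the same dietary cluster when a chain of
#' significantly overlapping pairs links them. Labels are deterministic —
#' components are numbered by decreasing size, ties broken by the smallest
#' member id — so the assignment is invariant to node relabeling up to label
#' permutation. Singleton clusters (unattached individuals) are allowed.
#'
#' @param adj a square symmetric binary adjacency ([binary_matrix] or 0/1
#'   matrix), typically from [significant_overlap_graph()].
#' @return an object of class `cluster_assignment`: `labels` (named integer
#'   vector), `n_clusters`, `sizes`, and the `adjacency` used.
#' @export
extract_clusters <- function(adj) {
  b <- if (inherits(adj, "binary_matrix")) adj$cells else as.matrix(adj)
  stopifnot(nrow(b) == ncol(b), all(b == t(b)))
  if (is.null(rownames(b)))
    dimnames(b) <- list(paste0("v", seq_len(nrow(b))), paste0("v", seq_len(nrow(b))))
  g <- igraph::graph_from_adjacency_matrix(b, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  ids <- rownames(b)
  raw <- comp$membership
  # deterministic relabeling: by size desc, then lexically smallest member
  first_id <- vapply(seq_len(comp$no), function(cc) min(ids[raw == cc]), character(1))
  ord <- order(-comp$csize, first_id)
  relab <- integer(comp$no)
  relab[ord] <- seq_len(comp$no)
  labels <- relab[raw]
  names(labels) <- ids
  structure(list(labels = labels,
                 n_clusters = comp$no,
                 sizes = as.integer(table(labels)),
                 adjacency = b),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d clusters (sizes %s) over %d individuals\n",
              x$n_clusters, paste(x$sizes, collapse = ", "), length(x$labels)))
  invisible(x)
}

#' @export
as.data.frame.cluster_assignment <- function(x, ...) {
  data.frame(individual = names(x$labels), cluster = unname(x$labels),
             stringsAsFactors = FALSE)
}
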