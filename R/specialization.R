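#' Row-wise diet proportions
#'
#' Converts counts to within-individual proportions, `p_ij = count_ij / row
#' total`. Rows must have at least one item (the matrix is pre-filtered).
#'
#' @param m a [diet_matrix].
#' @return numeric matrix with rows summing to 1.
#' @export
diet_proportions <- function(m) {
  m <- as_diet_matrix(m)
  totals <- rowSums(m$counts)
  if (any(totals < 1)) stop("zero-total row encountered; filter the matrix first")
  sweep(m$counts, 1, totals, "/")
}

#' Pairwise diet overlap network
#'
#' The complete weighted graph on individuals, with edge weight the
#' proportional similarity of the two diets:
#' `w_jk = 1 - 0.5 * sum_i |p_ij - p_ik|`. Weights lie in \[0, 1\]; 1 means
#' identical diet proportions, 0 disjoint diets. The measure is fixed to
#' proportional similarity (half-Manhattan complement); alternatives such as
#' Pianka's index could be added without changing the E contract.
#'
#' @param m a [diet_matrix], or a matrix of row-wise proportions.
#' @return an object of class `overlap_network` with elements `weights`
#'   (symmetric matrix, diagonal `NA`) and `ids`.
#' @export
pairwise_overlap <- function(m) {
  P <- if (inherits(m, "diet_matrix")) diet_proportions(m) else as.matrix(m)
  if (nrow(P) < 2L) stop("need at least 2 individuals")
  d <- as.matrix(stats::dist(P, method = "manhattan"))
  w <- 1 - 0.5 * d
  w[w < 0] <- 0   # guard tiny negative rounding
  diag(w) <- NA_real_
  structure(list(weights = w, ids = rownames(P)), class = "overlap_network")
}

#' @export
print.overlap_network <- function(x, ...) {
  ut <- x$weights[upper.tri(x$weights)]
  cat(sprintf("Overlap network: %d individuals, mean overlap %.3f\n",
              length(x$ids), mean(ut)))
  invisible(x)
}

#' E index of inter-individual diet variation
#'
#' One minus the mean pairwise diet overlap over all unordered pairs of
#' individuals: 0 when all diets are identical, 1 at maximal inter-individual
#' variation (all pairs disjoint). Invariant to row/column permutation and to
#' rescaling any individual's counts.
#'
#' @param net an [overlap_network] (or a [diet_matrix], converted on the fly).
#' @return E in \[0, 1\].
#' @export
e_index <- function(net) {
  if (inherits(net, "diet_matrix")) net <- pairwise_overlap(net)
  stopifnot(inherits(net, "overlap_network"))
  w <- net$weights[upper.tri(net$weights)]
  1 - mean(w)
}

# all null E values under the diet bootstrap, vectorized across replicates
e_null_values <- function(m, n_boot) {
  m <- as_diet_matrix(m)
  q <- pooled_proportions(m)
  totals <- rowSums(m$counts)
  n <- length(totals)
  # per-individual block of n_boot multinomial redraws, as proportions
  P <- lapply(seq_len(n), function(i)
    rmultinom(n_boot, totals[i], q) / totals[i])
  acc <- numeric(n_boot)
  npair <- 0L
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      acc <- acc + colSums(abs(P[[j]] - P[[k]]))
      npair <- npair + 1L
    }
  }
  0.5 * acc / npair   # E_b = mean pairwise (1 - w) = half mean Manhattan
}

#' Bootstrap significance test for the E index
#'
#' Compares the observed E against a null model in which every individual
#' redraws its diet from the pooled population proportions
#' ([bootstrap_diets]), keeping its own number of prey. The upper-tail
#' p-value uses the add-one estimator `(1 + #\{null E >= observed\}) /
#' (n_boot + 1)`; the population is called specialized at `p <= alpha`
#' (equivalently, observed E above the `1 - alpha` null quantile).
#'
#' @param m a [diet_matrix].
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @param alpha significance level (default 0.05, the 95% rule).
#' @return an object of classes `e_result`, `topology_result`: observed E,
#'   null mean and quantiles, p-value, verdict `"specialized"` or
#'   `"not significant"`, plus `degenerate` flag for single-taxon matrices.
#' @export
e_null_test <- function(m, n_boot = 10000, seed = 1L, alpha = 0.05) {
  stopifnot(n_boot >= 1)
  m <- as_diet_matrix(m)
  obs <- e_index(m)
  set.seed(seed)
  vals <- e_null_values(m, n_boot)
  ens <- null_ensemble(vals, "E", "diet_bootstrap", seed)
  p <- pvalue(obs, ens, "upper")
  degenerate <- ncol(m$counts) < 2L || all(vals == 0)
  verdict <- if (!degenerate && p <= alpha) "specialized" else "not significant"
  topology_result("e_result", "E", obs, ens, p, verdict,
                  extra = list(alpha = alpha, degenerate = degenerate,
                               season = m$season))
}
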