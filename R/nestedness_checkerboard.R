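# NODF paired overlap for the rows of a 0/1 matrix: for each unordered pair
# with strictly unequal marginal totals, 100 * shared presences / smaller
# total; equal totals contribute 0 ("decreasing fill" is strict).
nodf_pair_sum <- function(mat) {
  tot <- rowSums(mat)
  s <- tcrossprod(mat)                 # shared presences
  tmin <- outer(tot, tot, pmin)
  p <- 100 * s / tmin
  p[outer(tot, tot, "==")] <- 0
  sum(p[upper.tri(p)])
}

#' NODF nestedness of a presence/absence matrix
#'
#' Nestedness metric based on overlap and decreasing fill: each ordered pair
#' of rows (and of columns) with strictly decreasing marginal totals
#' contributes `100 * shared presences / smaller marginal total`; pairs with
#' equal totals contribute 0. NODF is the mean over all row pairs and column
#' pairs, ranging from 0 (no nestedness) to 100 (perfect nestedness). The
#' value is invariant to the input row/column order.
#'
#' @param b a [binary_matrix] (or a [diet_matrix], thresholded at >= 1).
#' @return list with `NODF`, `N_rows` (row component), `N_cols` (column
#'   component) — each in \[0, 100\].
#' @export
nodf <- function(b) {
  b <- as_binary_matrix(b)
  cells <- b$cells
  if (nrow(cells) < 2L || ncol(cells) < 2L) stop("need at least a 2 x 2 matrix")
  if (any(rowSums(cells) == 0) || any(colSums(cells) == 0))
    stop("empty rows/columns are not allowed in NODF")
  nr <- nrow(cells); nc <- ncol(cells)
  rs <- nodf_pair_sum(cells)
  cs <- nodf_pair_sum(t(cells))
  nrp <- nr * (nr - 1) / 2
  ncp <- nc * (nc - 1) / 2
  list(NODF = (rs + cs) / (nrp + ncp),
       N_rows = rs / nrp,
       N_cols = cs / ncp)
}

#' Cell occupancy probabilities of the CE null model
#'
#' Under the CE (proportional row and column fill) null model, cell (i, j) is
#' occupied independently with probability the average of the row fill and
#' the column fill: `(row_total_i / ncol + col_total_j / nrow) / 2`.
#'
#' @param b a [binary_matrix].
#' @return matrix of probabilities in \[0, 1\].
#' @export
ce_cell_probs <- function(b) {
  b <- as_binary_matrix(b)
  rfill <- rowSums(b$cells) / ncol(b$cells)
  cfill <- colSums(b$cells) / nrow(b$cells)
  outer(rfill, cfill, function(r, c) (r + c) / 2)
}

#' Draw one matrix from the CE null model
#'
#' Independent Bernoulli cells with [ce_cell_probs()] probabilities. Draws
#' containing an empty row or column are redrawn (the number of redraws is
#' attached as attribute `redraws`); after `max_tries` failures the last draw
#' is returned with a warning.
#'
#' @param b a [binary_matrix] (the template whose fills parameterize the null).
#' @param seed optional integer; seeds the RNG before drawing.
#' @param max_tries redraw budget (default 1000).
#' @return a [binary_matrix] of the same dimensions.
#' @export
ce_null_matrix <- function(b, seed = NULL, max_tries = 1000) {
  b <- as_binary_matrix(b)
  if (!is.null(seed)) set.seed(seed)
  pr <- ce_cell_probs(b)
  nr <- nrow(pr); nc <- ncol(pr)
  redraws <- 0L
  repeat {
    cells <- matrix(as.numeric(stats::runif(nr * nc) < pr), nr, nc,
                    dimnames = dimnames(b$cells))
    if (all(rowSums(cells) > 0) && all(colSums(cells) > 0)) break
    redraws <- redraws + 1L
    if (redraws >= max_tries) {
      warning("CE null: empty row/column persisted after ", max_tries, " redraws")
      break
    }
  }
  out <- as_binary_matrix(cells)
  attr(out, "redraws") <- redraws
  out
}

#' Monte-Carlo nestedness test (NODF vs CE null)
#'
#' Compares the observed NODF with `n_null` draws from the CE null model.
#' Upper-tail add-one p-value; the matrix is called nested when the observed
#' NODF exceeds the 95% null quantile (`p <= alpha`).
#'
#' @param b a [binary_matrix] or [diet_matrix].
#' @param n_null number of null matrices (default 10000).
#' @param seed integer seed.
#' @param alpha significance level (default 0.05).
#' @return an object of classes `nodf_result`, `topology_result` with
#'   observed NODF, row/column components, null summary, p-value and verdict
#'   `"nested"` / `"not significant"`.
#' @export
nodf_test <- function(b, n_null = 10000, seed = 1L, alpha = 0.05) {
  stopifnot(n_null >= 1)
  b <- as_binary_matrix(b)
  obs <- nodf(b)
  set.seed(seed)
  # a CE draw that still holds an empty row/column after the redraw budget is
  # scored on its occupied submatrix (fully empty submatrices score 0)
  null_nodf <- function() {
    d <- ce_null_matrix(b)$cells
    d <- d[rowSums(d) > 0, colSums(d) > 0, drop = FALSE]
    if (nrow(d) < 2L || ncol(d) < 2L) return(0)
    nodf(as_binary_matrix(d))$NODF
  }
  vals <- vapply(seq_len(n_null), function(i) null_nodf(), numeric(1))
  ens <- null_ensemble(vals, "NODF", "CE", seed)
  p <- pvalue(obs$NODF, ens, "upper")
  verdict <- if (p <= alpha) "nested" else "not significant"
  topology_result("nodf_result", "NODF", obs$NODF, ens, p, verdict,
                  extra = list(N_rows = obs$N_rows, N_cols = obs$N_cols,
                               alpha = alpha, season = b$season))
}

#' Stone-Roberts C-score of a presence/absence matrix
#'
#' Mean number of checkerboard units over all unordered pairs of prey taxa
#' (columns): for taxa i and j with occurrence totals `r_i`, `r_j` and `S_ij`
#' shared individuals, `CU_ij = (r_i - S_ij) * (r_j - S_ij)`, normalized per
#' pair by `r_i * r_j` so the average lies in \[0, 1\]: 0 when every pair
#' fully co-occurs, 1 for a perfect checkerboard. Set `normalize = FALSE` for
#' the raw Stone-Roberts mean checkerboard-unit count.
#'
#' @param b a [binary_matrix] or [diet_matrix].
#' @param normalize divide each pair's units by `r_i * r_j` (default TRUE).
#' @return the C-score.
#' @export
cscore <- function(b, normalize = TRUE) {
  b <- as_binary_matrix(b)
  cells <- b$cells
  if (ncol(cells) < 2L) stop("need at least 2 taxa")
  r <- colSums(cells)
  s <- crossprod(cells)
  cu <- (outer(r, r, function(a, bb) a) - s) * (outer(r, r, function(a, bb) bb) - s)
  if (normalize) cu <- cu / outer(r, r)
  mean(cu[upper.tri(cu)])
}

# trial-swap sampler: a random 2x2 submatrix is proposed each step and
# swapped only when it is a checkerboard, preserving every row and column
# total exactly. The proposal is symmetric and self-loops are kept, so the
# chain's stationary distribution is uniform over the fixed-margin set;
# samples are taken at FIXED attempt intervals (sampling at success times
# would weight states by their number of swappable submatrices and bias the
# null toward checkerboardness). Returns list of 0/1 matrices.
swap_chain <- function(cells, n_samples, burnin_attempts, thin_attempts) {
  nr <- nrow(cells); nc <- ncol(cells)
  m <- cells
  samples <- vector("list", n_samples)
  collected <- 0L
  step <- 0
  next_target <- burnin_attempts
  batch <- 8192L
  while (collected < n_samples) {
    ri <- sample.int(nr, batch, replace = TRUE)
    rj <- sample.int(nr, batch, replace = TRUE)
    ca <- sample.int(nc, batch, replace = TRUE)
    cb <- sample.int(nc, batch, replace = TRUE)
    for (t in seq_len(batch)) {
      step <- step + 1
      i <- ri[t]; j <- rj[t]; a <- ca[t]; b2 <- cb[t]
      if (i != j && a != b2) {
        x <- m[i, a]
        if (x == m[j, b2] && m[i, b2] == m[j, a] && x != m[i, b2]) {
          y <- m[i, b2]
          m[i, a] <- y; m[j, b2] <- y; m[i, b2] <- x; m[j, a] <- x
        }
      }
      if (step >= next_target) {
        collected <- collected + 1L
        samples[[collected]] <- m
        if (collected >= n_samples) break
        next_target <- next_target + thin_attempts
      }
    }
  }
  samples
}

# TRUE if the matrix admits at least one 2x2 checkerboard submatrix
has_checkerboard_unit <- function(cells) {
  s <- crossprod(cells)
  r <- colSums(cells)
  cu <- (outer(r, r, function(a, b) a) - s) * (outer(r, r, function(a, b) b) - s)
  any(cu[upper.tri(cu)] > 0)
}

#' Fixed-margin null matrices by sequential checkerboard swaps
#'
#' Generates `n_null` matrices with exactly the row and column totals of the
#' input, by a Markov chain of random 2x2 trial swaps (propose any 2x2
#' submatrix, swap only checkerboards): the symmetric proposal makes the
#' stationary distribution uniform over the fixed-margin set. Burn-in is
#' `50 * fill` trial attempts and consecutive samples are separated by
#' `5 * fill` attempts (fill = number of presences); sampling at fixed
#' attempt intervals, never at swap-success times, keeps the draws unbiased.
#' Matrices with no swappable submatrix yield a degenerate null (copies of
#' the input, flagged with attribute `degenerate`).
#'
#' @param b a [binary_matrix].
#' @param n_null number of null matrices.
#' @param seed integer seed.
#' @return list of 0/1 matrices, with attribute `degenerate`.
#' @export
swap_null_matrices <- function(b, n_null, seed = 1L) {
  b <- as_binary_matrix(b)
  cells <- b$cells
  set.seed(seed)
  if (!has_checkerboard_unit(cells)) {
    out <- replicate(n_null, cells, simplify = FALSE)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fill <- sum(cells)
  out <- swap_chain(cells, n_null, burnin_attempts = 50 * fill,
                    thin_attempts = 5 * fill)
  attr(out, "degenerate") <- FALSE
  out
}

#' Monte-Carlo checkerboard test (C-score vs fixed-margin swap null)
#'
#' Compares the observed C-score against `n_null` fixed-margin matrices from
#' [swap_null_matrices()]. Two-tailed: verdict `"checkerboard"` when the
#' observed C-score exceeds the 97.5% null quantile (taxa co-occur less often
#' than chance), `"aggregated"` below the 2.5% quantile, `"neither"`
#' otherwise. Also reports the never-co-occurring pair count.
#'
#' @param b a [binary_matrix] or [diet_matrix].
#' @param n_null number of null matrices (default 10000).
#' @param seed integer seed.
#' @param alpha two-sided significance level (default 0.05).
#' @param normalize passed to [cscore()].
#' @return an object of classes `cscore_result`, `topology_result` with the
#'   observed C, the (2.5%, 97.5%) null band `ci`, two-sided p-value, verdict
#'   and `checkerboard_pairs` count; `degenerate` flags a null with no
#'   swappable submatrix.
#' @export
swap_null_test <- function(b, n_null = 10000, seed = 1L, alpha = 0.05,
                           normalize = TRUE) {
  stopifnot(n_null >= 1)
  b <- as_binary_matrix(b)
  obs <- cscore(b, normalize = normalize)
  mats <- swap_null_matrices(b, n_null, seed)
  vals <- vapply(mats, function(x) cscore(as_binary_matrix(x), normalize = normalize),
                 numeric(1))
  ens <- null_ensemble(vals, "C", "swap", seed)
  lo <- stats::quantile(vals, alpha / 2, names = FALSE)
  hi <- stats::quantile(vals, 1 - alpha / 2, names = FALSE)
  degenerate <- isTRUE(attr(mats, "degenerate"))
  verdict <- if (degenerate) "degenerate"
             else if (obs > hi) "checkerboard"
             else if (obs < lo) "aggregated"
             else "neither"
  p <- pvalue(obs, ens, "two-sided")
  topology_result("cscore_result", "C", obs, ens, p, verdict,
                  extra = list(ci = c(lower = lo, upper = hi),
                               checkerboard_pairs = nrow(never_cooccurring_pairs(b)$never),
                               alpha = alpha, degenerate = degenerate,
                               season = b$season))
}

#' Census of never-co-occurring prey-taxon pairs
#'
#' All unordered pairs of taxa (both with at least one occurrence) that are
#' never found together in any individual's prey pool (`S_ij = 0`), plus the
#' complementary co-occurring pair list — the input of the co-occurrence
#' mass-difference test.
#'
#' @param b a [binary_matrix] or [diet_matrix].
#' @return list of two data.frames `never` and `cooccurring`, each with
#'   columns `taxon_a`, `taxon_b`, `shared`.
#' @export
never_cooccurring_pairs <- function(b) {
  b <- as_binary_matrix(b)
  cells <- b$cells[, colSums(b$cells) > 0, drop = FALSE]
  s <- crossprod(cells)
  idx <- which(upper.tri(s), arr.ind = TRUE)
  df <- data.frame(taxon_a = colnames(cells)[idx[, 1]],
                   taxon_b = colnames(cells)[idx[, 2]],
                   shared = s[idx],
                   stringsAsFactors = FALSE)
  list(never = df[df$shared == 0, , drop = FALSE],
       cooccurring = df[df$shared > 0, , drop = FALSE])
}
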