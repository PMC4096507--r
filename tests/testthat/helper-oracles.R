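# Independent oracles used across the suite. Everything here is written as
# plain loops from the definitions, deliberately avoiding the package's
# vectorized code paths.

# proportional-similarity E by explicit double loop over pairs
brute_e <- function(counts) {
  P <- sweep(counts, 1, rowSums(counts), "/")
  n <- nrow(P)
  tot <- 0; np <- 0
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      w <- 1 - 0.5 * sum(abs(P[j, ] - P[k, ]))
      tot <- tot + w; np <- np + 1
    }
  }
  1 - tot / np
}

# NODF straight from the definition (pair loops, strict decreasing fill)
brute_nodf <- function(cells) {
  pair_part <- function(m) {
    tot <- rowSums(m); n <- nrow(m); s <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (tot[i] == tot[j]) next
      hi <- if (tot[i] > tot[j]) i else j
      lo <- i + j - hi
      s <- s + 100 * sum(m[hi, ] == 1 & m[lo, ] == 1) / tot[lo]
    }
    s
  }
  nr <- nrow(cells); nc <- ncol(cells)
  unname((pair_part(cells) + pair_part(t(cells))) /
    (nr * (nr - 1) / 2 + nc * (nc - 1) / 2))
}

# normalized Stone-Roberts C-score by pair loop
brute_cscore <- function(cells) {
  r <- colSums(cells); t_ <- ncol(cells)
  tot <- 0; np <- 0
  for (i in seq_len(t_ - 1)) for (j in (i + 1):t_) {
    s <- sum(cells[, i] == 1 & cells[, j] == 1)
    tot <- tot + (r[i] - s) * (r[j] - s) / (r[i] * r[j])
    np <- np + 1
  }
  unname(tot / np)
}

# all binary matrices with the given margins, by row-wise recursion
enumerate_fixed_margin <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  out <- list()
  gen <- function(row, mat, colleft) {
    if (row > nr) {
      if (all(colleft == 0)) out[[length(out) + 1]] <<- mat
      return(invisible())
    }
    combs <- utils::combn(nc, row_sums[row])
    for (ci in seq_len(ncol(combs))) {
      sel <- combs[, ci]
      if (all(colleft[sel] >= 1)) {
        m2 <- mat; m2[row, sel] <- 1
        cl <- colleft; cl[sel] <- cl[sel] - 1
        gen(row + 1, m2, cl)
      }
    }
  }
  gen(1, matrix(0, nr, nc), col_sums)
  out
}

# exact null distribution of E under the diet bootstrap, by enumerating every
# joint multinomial outcome of tiny matrices (row totals <= 2, few taxa)
enumerate_e_null <- function(counts) {
  q <- colSums(counts) / sum(counts)
  totals <- rowSums(counts)
  t_ <- ncol(counts)
  row_outcomes <- function(total) {
    # all count vectors over t_ taxa summing to total, with probabilities
    grid <- expand.grid(rep(list(0:total), t_))
    grid <- grid[rowSums(grid) == total, , drop = FALSE]
    probs <- apply(grid, 1, function(x) stats::dmultinom(x, total, prob = q))
    list(counts = as.matrix(grid), probs = probs)
  }
  per_row <- lapply(totals, row_outcomes)
  idx <- expand.grid(lapply(per_row, function(r) seq_along(r$probs)))
  vals <- numeric(nrow(idx)); ps <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    mat <- do.call(rbind, lapply(seq_along(per_row), function(r)
      per_row[[r]]$counts[idx[i, r], ]))
    vals[i] <- brute_e(mat)
    ps[i] <- prod(vapply(seq_along(per_row), function(r)
      per_row[[r]]$probs[idx[i, r]], numeric(1)))
  }
  list(values = vals, probs = ps)
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b); n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# small deterministic diet matrix used by several tests
toy_matrix <- function() {
  counts <- rbind(c(5, 3, 0, 1),
                  c(4, 0, 2, 0),
                  c(0, 2, 3, 1),
                  c(6, 1, 1, 2))
  dimnames(counts) <- list(paste0("w", 1:4), paste0("t", 1:4))
  diet_matrix(counts)
}
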