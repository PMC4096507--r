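test_that("NODF matches its definition, vegan, and is order-invariant", {
  expect_equal(nodf(as_binary_matrix(matrix(1, 3, 3)))$NODF, 0)
  stepped <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))
  expect_equal(nodf(as_binary_matrix(stepped))$NODF, 100)

  set.seed(8)
  for (i in 1:6) {
    m <- generate_null_population(population_spec(seed = 700 + i))
    b <- to_binary(m)
    res <- nodf(b)
    expect_equal(res$NODF, brute_nodf(b$cells), tolerance = 1e-10)
    vg <- vegan::nestednodf(b$cells, order = TRUE)$statistic
    expect_equal(res$NODF, unname(vg["NODF"]), tolerance = 1e-8)
    expect_equal(res$N_rows, unname(vg["N.rows"]), tolerance = 1e-8)
    expect_equal(res$N_cols, unname(vg["N.columns"]), tolerance = 1e-8)
    # permutation invariance
    perm <- b$cells[sample(nrow(b$cells)), sample(ncol(b$cells))]
    expect_equal(nodf(as_binary_matrix(perm))$NODF, res$NODF, tolerance = 1e-10)
  }

  # monotone response: filling a hole in the fullest row of a stepped matrix
  # never decreases the column-pair component
  m0 <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 1), c(1, 0, 0, 0))
  m1 <- m0; m1[1, 4] <- 1
  expect_gte(nodf(as_binary_matrix(m1))$N_cols, nodf(as_binary_matrix(m0))$N_cols)
  expect_error(nodf(as_binary_matrix(rbind(c(1, 0), c(1, 0)))), "empty")
})

test_that("CE null cell probabilities average row and column fills", {
  b <- as_binary_matrix(rbind(c(1, 1), c(1, 0)))
  pr <- ce_cell_probs(b)
  expect_equal(pr[2, 2], (0.5 + 0.5) / 2)
  expect_equal(pr[1, 1], (1 + 1) / 2)
  expect_true(all(ce_cell_probs(as_binary_matrix(matrix(1, 3, 4))) == 1))
  # all-ones template can only regenerate itself
  expect_true(all(ce_null_matrix(as_binary_matrix(matrix(1, 3, 4)), seed = 1)$cells == 1))
  # draws keep dimensions and never contain empty rows/columns
  set.seed(2)
  m <- to_binary(generate_null_population(population_spec(seed = 44)))
  for (i in 1:20) {
    d <- ce_null_matrix(m)
    expect_equal(dim(d$cells), dim(m$cells))
    expect_true(all(rowSums(d$cells) > 0) && all(colSums(d$cells) > 0))
  }
  # unbiasedness: mean fill of draws tracks the template fill
  set.seed(3)
  fills <- replicate(300, mean(ce_null_matrix(m)$cells))
  expect_equal(mean(fills), mean(ce_cell_probs(m)), tolerance = 0.02)
})

test_that("nodf_test calls a perfectly nested matrix nested and respects add-one p", {
  stepped <- matrix(0, 6, 6)
  for (i in 1:6) stepped[i, seq_len(7 - i)] <- 1
  res <- nodf_test(as_binary_matrix(stepped), n_null = 300, seed = 5)
  expect_identical(res$verdict, "nested")
  expect_equal(res$observed, 100)
  expect_gte(res$p.value, 1 / 301)
})

test_that("C-score matches its definition and is permutation-invariant", {
  expect_equal(cscore(as_binary_matrix(diag(2))), 1)
  expect_equal(cscore(as_binary_matrix(matrix(1, 3, 3))), 0)
  set.seed(10)
  for (i in 1:6) {
    b <- to_binary(generate_null_population(population_spec(seed = 800 + i)))
    expect_equal(cscore(b), brute_cscore(b$cells), tolerance = 1e-12)
    perm <- b$cells[sample(nrow(b$cells)), sample(ncol(b$cells))]
    expect_equal(cscore(as_binary_matrix(perm)), cscore(b), tolerance = 1e-12)
    expect_true(cscore(b) >= 0 && cscore(b) <= 1)
  }
  # raw Stone-Roberts option agrees with the unnormalized definition
  b <- to_binary(generate_null_population(population_spec(seed = 801)))
  r <- colSums(b$cells); S <- crossprod(b$cells)
  cu <- (outer(r, r, function(a, bb) a) - S) * (outer(r, r, function(a, bb) bb) - S)
  expect_equal(cscore(b, normalize = FALSE), mean(cu[upper.tri(cu)]))
})

test_that("swap null preserves margins exactly and samples margins-uniformly", {
  b <- to_binary(generate_null_population(population_spec(seed = 55)))
  mats <- swap_null_matrices(b, 60, seed = 6)
  for (m in mats) {
    expect_equal(rowSums(m), rowSums(b$cells))
    expect_equal(colSums(m), colSums(b$cells))
    expect_true(all(m %in% c(0, 1)))
  }
  expect_false(isTRUE(attr(mats, "degenerate")))

  # chi-square uniformity over the enumerable fixed-margin set
  all5 <- enumerate_fixed_margin(c(2, 1, 1), c(2, 1, 1))
  expect_length(all5, 5)
  start <- all5[[1]]
  dimnames(start) <- list(paste0("r", 1:3), paste0("c", 1:3))
  keys <- vapply(all5, function(m) paste(m, collapse = ""), character(1))
  samp <- swap_null_matrices(as_binary_matrix(start), 3000, seed = 7)
  tab <- table(factor(vapply(samp, function(m) paste(m, collapse = ""), character(1)),
                      levels = keys))
  expect_true(all(tab > 0))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("2x2 checkerboard is its own degenerate-free null with C identically 1", {
  b <- as_binary_matrix(diag(2))
  mats <- swap_null_matrices(b, 50, seed = 8)
  cvals <- vapply(mats, function(m) cscore(as_binary_matrix(m)), numeric(1))
  expect_true(all(cvals == 1))
  # a matrix with no swappable submatrix is flagged degenerate
  noswap <- as_binary_matrix(rbind(c(1, 1), c(1, 0)))
  mats2 <- swap_null_matrices(noswap, 10, seed = 9)
  expect_true(attr(mats2, "degenerate"))
  expect_identical(swap_null_test(noswap, 10, seed = 10)$verdict, "degenerate")
})

test_that("never-co-occurring census partitions all taxon pairs", {
  expect_equal(nrow(never_cooccurring_pairs(as_binary_matrix(matrix(1, 3, 3)))$never), 0)
  prs <- never_cooccurring_pairs(as_binary_matrix(diag(2)))
  expect_equal(nrow(prs$never), 1)
  b <- to_binary(generate_checkerboard_population(
    population_spec(structure = "checkerboard", strength = 1, seed = 66)))
  prs2 <- never_cooccurring_pairs(b)
  t_ <- ncol(b$cells)
  expect_equal(nrow(prs2$never) + nrow(prs2$cooccurring), t_ * (t_ - 1) / 2)
  expect_true(all(prs2$never$shared == 0))
  expect_true(all(prs2$cooccurring$shared > 0))
  # designated antipodal pairs are exclusive by construction at strength 1
  expect_gt(nrow(prs2$never), 0)
})
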