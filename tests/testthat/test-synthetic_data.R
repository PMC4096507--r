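test_that("generators are bit-reproducible per seed and honour the study scale", {
  for (structure in c("null", "nested", "competitive_refuge",
                      "distinct_preferences", "checkerboard")) {
    sp <- population_spec(structure = structure, strength = 0.7, seed = 99L)
    m1 <- generate_population(sp)
    m2 <- generate_population(sp)
    expect_identical(m1$counts, m2$counts)
    expect_true(all(rowSums(m1$counts) >= 4))
    expect_true(all(m1$counts >= 0))
    expect_equal(nrow(m1$counts), 12)
    expect_lte(ncol(m1$counts), 16)
  }
  # pooled proportions: dominant at one half, proportions sum to 1
  sp <- population_spec()
  expect_equal(unname(sp$pooled[1]), 0.5)
  expect_equal(sum(sp$pooled), 1)
})

test_that("column means of null populations track the pooled proportions", {
  sp <- population_spec(seed = 17)
  set.seed(17)
  tot <- 0
  acc <- numeric(sp$n_taxa)
  for (r in 1:200) {
    spr <- population_spec(seed = 9000 + r)
    m <- generate_null_population(spr)
    cs <- stats::setNames(numeric(sp$n_taxa), names(sp$pooled))
    cs[taxon_ids(m)] <- colSums(m$counts)
    acc <- acc + cs
    tot <- tot + sum(m$counts)
  }
  expect_equal(unname(acc / tot), unname(sp$pooled), tolerance = 0.02)
})

test_that("strength zero reduces every structured generator to the null distribution", {
  # distributional check on summary statistics over replicates
  stats_of <- function(gen_fun, n = 120) {
    vapply(seq_len(n), function(r) {
      m <- gen_fun(r)
      c(e = e_index(m), fill = mean(to_binary(m)$cells))
    }, numeric(2))
  }
  s_null <- stats_of(function(r) generate_null_population(population_spec(seed = 5000 + r)))
  for (structure in c("nested", "competitive_refuge", "checkerboard")) {
    s_str <- stats_of(function(r) generate_population(
      population_spec(structure = structure, strength = 0, seed = 5000 + r)))
    expect_gt(suppressWarnings(stats::ks.test(s_null["e", ], s_str["e", ]))$p.value, 0.001)
    expect_equal(mean(s_str["fill", ]), mean(s_null["fill", ]), tolerance = 0.03)
  }
})

test_that("structure strength raises its target index monotonically", {
  strengths <- c(0.2, 0.5, 0.9)
  mean_stat <- function(gen, stat, reps = 60) {
    vapply(strengths, function(s) {
      mean(vapply(seq_len(reps), function(r)
        stat(gen(s, 6000 + r)), numeric(1)))
    }, numeric(1))
  }
  cs <- mean_stat(function(s, seed) generate_checkerboard_population(
    population_spec(structure = "checkerboard", strength = s, seed = seed)),
    function(m) cscore(to_binary(m)))
  expect_true(all(diff(cs) > 0))
  nodfs <- mean_stat(function(s, seed) generate_nested_population(
    population_spec(structure = "nested", strength = s, seed = seed)),
    function(m) nodf(to_binary(m))$NODF)
  expect_true(all(diff(nodfs) > 0))
  es <- mean_stat(function(s, seed) generate_clustered_population(
    population_spec(structure = "distinct_preferences", strength = s, seed = seed)),
    e_index)
  expect_true(all(diff(es) > 0))
})

test_that("checkerboard construction nulls designated pairs at full strength", {
  m <- generate_checkerboard_population(
    population_spec(structure = "checkerboard", strength = 1, seed = 31))
  cells <- to_binary(m)$cells
  kept <- taxon_ids(m)
  sp <- population_spec()
  pm <- rep(c(1L, 2L), length.out = sp$n_taxa)
  names(pm) <- names(sp$pooled)
  # every designated antipodal pair that survived has zero shared presences
  for (t in seq_len(sp$n_taxa %/% 2)) {
    a <- names(sp$pooled)[2 * t - 1]; b <- names(sp$pooled)[2 * t]
    if (a %in% kept && b %in% kept)
      expect_equal(sum(cells[, a] * cells[, b]), 0)
  }
  # the 2x2 limit is the perfect checkerboard
  m2 <- generate_checkerboard_population(
    population_spec(n_individuals = 2, n_taxa = 2, structure = "checkerboard",
                    strength = 1, k = 2, seed = 4))
  expect_equal(unname(to_binary(m2)$cells), diag(2))
  expect_equal(cscore(to_binary(m2)), 1)
})

test_that("nested generator exposes mass and breadth for parameter recovery", {
  m <- generate_nested_population(population_spec(structure = "nested", strength = 1, seed = 61))
  mass <- attr(m, "mass"); breadth <- attr(m, "breadth")
  expect_equal(names(mass), individual_ids(m))
  expect_equal(range(attr(m, "breadth"))[1], 1)
  expect_equal(max(breadth), 16)
  expect_true(all(diff(breadth[order(mass)]) >= 0))
  fit <- mass_breadth_regression(mass, pct_taxa_captured(m))
  expect_gt(fit$effect$slope, 0)
})

test_that("simulate_population writes matrix and truth files that agree", {
  prefix <- file.path(withr::local_tempdir(), "sim")
  sp <- population_spec(structure = "distinct_preferences", strength = 0.8,
                        k = 3, seed = 12)
  paths <- simulate_population(sp, prefix)
  expect_true(all(file.exists(paths)))
  m <- read_diet_matrix(paths["matrix"])
  truth <- utils::read.csv(paths["truth"])
  expect_identical(truth$individual_id, individual_ids(m))
  expect_equal(truth$total, unname(rowSums(m$counts)))
  expect_equal(sort(unique(truth$cluster)), 1:3)
  # same spec, same files
  paths2 <- simulate_population(sp, paste0(prefix, "b"))
  expect_identical(readLines(paths["matrix"]), readLines(paths2["matrix"]))
})
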