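test_that("availability correlation reproduces closed-form Pearson on ln scale", {
  avail <- c(a = 10, b = 100, c = 1000, d = 55, e = 7)
  # predator counts exactly linear in ln(availability): r = 1
  counts <- stats::setNames(round(3 * log(avail)), names(avail))
  res <- availability_correlation(counts, avail)
  expect_equal(res$effect$r, 1, tolerance = 1e-3)
  expect_identical(res$transform, "ln")
  expect_equal(res$effect$n, 5)

  # agreement with cor.test on a hand dataset
  counts2 <- c(a = 4, b = 9, c = 2, d = 7, e = 5)
  ref <- stats::cor.test(log(avail), as.numeric(counts2))
  res2 <- availability_correlation(counts2, avail)
  expect_equal(res2$effect$r, unname(ref$estimate))
  expect_equal(res2$p.value, ref$p.value)
  expect_equal(res2$df, 3)

  # constant predator counts are flagged, not an error
  expect_match(availability_correlation(c(a = 2, b = 2, c = 2), avail[1:3])$flags,
               "constant")
  # taxa with no availability are dropped by the inner join
  res3 <- availability_correlation(c(counts2, zz = 5), avail)
  expect_equal(res3$effect$n, 5)
  expect_error(availability_correlation(counts2[1:2], avail[1:2]), "fewer than 3")
})

test_that("mass-breadth regression returns exact fits and detects lack of signal", {
  x <- c(80, 90, 100, 110, 120)
  res <- suppressWarnings(mass_breadth_regression(x, 2 * x))  # exact fit
  expect_equal(res$effect$slope, 2)
  expect_equal(res$effect$r2_adj, 1)
  expect_equal(res$df, c(1, 3))
  expect_error(mass_breadth_regression(rep(1, 5), 2 * x), "variance")

  # null slope: p approximately uniform over replicates
  set.seed(12)
  ps <- replicate(300, {
    mass <- stats::rnorm(12, 96, 15)
    mass_breadth_regression(mass, stats::runif(12, 20, 80))$p.value
  })
  expect_gte(mean(ps < 0.05), 0.01)
  expect_lte(mean(ps < 0.05), 0.10)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})

test_that("percentage of taxa captured uses the population's taxon pool as 100%", {
  m <- toy_matrix()
  pct <- pct_taxa_captured(m)
  expect_equal(unname(pct["w1"]), 100 * 3 / 4)
  expect_true(all(pct > 0 & pct <= 100))
})

test_that("one-way ANOVA with Tukey matches hand-computed sums of squares", {
  # textbook 3-group data
  vals <- c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 13, 7, 13, 14, 17, 12)
  grp <- rep(c("A", "B", "C"), c(6, 6, 4))
  res <- group_anova_tukey(vals, grp)
  ref <- summary(stats::aov(vals ~ factor(grp)))[[1]]
  expect_equal(res$statistic, ref[1, "F value"])
  expect_equal(res$p.value, ref[1, "Pr(>F)"])
  expect_equal(res$df, c(2, 13))
  expect_equal(sort(rownames(res$effect$tukey)), c("B-A", "C-A", "C-B"))

  # two groups shifted by 10 SDs are separated decisively
  set.seed(3)
  v2 <- c(stats::rnorm(8), stats::rnorm(8, 10))
  expect_lt(group_anova_tukey(v2, rep(1:2, each = 8))$p.value, 1e-3)

  # identical values: degenerate path flagged with F = 0
  res3 <- group_anova_tukey(rep(5, 6), rep(1:2, 3))
  expect_equal(res3$statistic, 0)
  expect_match(res3$flags, "identical")

  # named alignment with a cluster assignment
  m <- generate_clustered_population(
    population_spec(structure = "distinct_preferences", strength = 1, k = 2, seed = 5))
  cl <- stats::setNames(attr(m, "cluster"), individual_ids(m))
  fake <- structure(list(labels = cl), class = "cluster_assignment")
  vals4 <- stats::setNames(stats::rnorm(length(cl)), names(cl))
  expect_s3_class(group_anova_tukey(vals4, fake), "factor_test_result")
})

test_that("Levene variance test (mean-centered) matches car and reports CV", {
  set.seed(7)
  v <- c(stats::rnorm(12, 100, 5), stats::rnorm(12, 100, 5), stats::rnorm(12, 100, 50))
  g <- rep(c("2008", "2009", "2010"), each = 12)
  res <- variance_homogeneity(v, g)
  ref <- car::leveneTest(v ~ factor(g), center = mean)
  expect_equal(res$statistic, ref[1, "F value"])
  expect_equal(res$p.value, ref[1, "Pr(>F)"])
  expect_lt(res$p.value, 0.01)
  expect_equal(unname(res$effect$cv["2010"]),
               stats::sd(v[g == "2010"]) / mean(v[g == "2010"]))

  # equal variances rejected at roughly the nominal rate
  set.seed(8)
  rej <- mean(replicate(400, {
    vv <- stats::rnorm(36, 100, 10)
    variance_homogeneity(vv, rep(1:3, each = 12))$p.value < 0.05
  }))
  expect_gte(rej, 0.005)
  expect_lte(rej, 0.12)
})

test_that("paired shift test gives df = n - 1 and guards degenerate differences", {
  first <- c(20, 35, 10, 42, 28, 33, 18, 25)
  last <- c(22, 30, 15, 40, 31, 30, 20, 24)
  res <- paired_shift_test(first, last)
  ref <- stats::t.test(last, first, paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$df, 7)
  expect_equal(res$p.value, ref$p.value)
  deg <- paired_shift_test(first, first)
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p.value, 1)
  expect_match(deg$flags, "degenerate")
})

test_that("co-occurrence mass test compares pair classes with a Student t", {
  b <- as_binary_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1)))
  prs <- never_cooccurring_pairs(b)
  masses <- c(taxon1 = 10, taxon2 = 30, taxon3 = 22, taxon4 = 95)
  res <- cooccurrence_mass_test(prs, masses)
  d_never <- abs(c(10 - 22, 10 - 95, 30 - 22, 30 - 95))
  d_co <- abs(c(10 - 30, 22 - 95))
  ref <- stats::t.test(d_never, d_co, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$df, 4)
  expect_error(cooccurrence_mass_test(prs, masses[-1]), "taxon1")
  # no class difference: p approximately uniform
  set.seed(13)
  ps <- replicate(200, {
    mm <- stats::setNames(stats::rexp(4, 1 / 30), names(masses))
    cooccurrence_mass_test(prs, mm)$p.value
  })
  expect_gt(mean(ps > 0.2), 0.5)
})

test_that("temporal scores average capture days per female and drop empty ones", {
  df <- data.frame(individual_id = c("a", "a", "b", "c"),
                   day_score = c(1, 17, 9, 4))
  sc <- temporal_scores(df)
  expect_equal(unname(sc["a"]), 9)
  expect_equal(unname(sc["b"]), 9)
  expect_equal(unname(sc["c"]), 4)
  expect_warning(sc2 <- temporal_scores(list(a = c(2, 4), b = numeric(0))), "no scored")
  expect_identical(names(sc2), "a")
})

test_that("inter-nest distance test separates tight far-apart clusters", {
  coords <- data.frame(
    individual_id = paste0("w", 1:8),
    x_cm = c(0, 1, 0, 1, 100, 101, 100, 101),
    y_cm = c(0, 0, 1, 1, 100, 100, 101, 101))
  cl <- stats::setNames(rep(1:2, each = 4), coords$individual_id)
  res <- internest_distance_test(coords, cl)
  expect_lt(res$p.value, 0.01)
  expect_lt(res$effect$mean_within, res$effect$mean_between)
  expect_identical(res$transform, "sqrt")
  expect_equal(res$df, 8 * 7 / 2 - 2)
  # all nests at one point: degenerate
  coords0 <- coords; coords0$x_cm <- 0; coords0$y_cm <- 0
  expect_match(internest_distance_test(coords0, cl)$flags, "degenerate")
})
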