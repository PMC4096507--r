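# light wrapper so every covariate test reports the same surface
factor_test_result <- function(test, statistic, df, p.value, effect = list(),
                               transform = "none", flags = character()) {
  structure(list(test = test, statistic = statistic, df = df,
                 p.value = p.value, effect = effect,
                 transform = transform, flags = flags),
            class = "factor_test_result")
}

#' @export
print.factor_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (transform: %s)\n",
              x$test, x$statistic, paste(x$df, collapse = ","), x$p.value,
              x$transform))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Prey-availability correlation
#'
#' Pearson correlation between the number of predators exploiting each prey
#' taxon and the (natural-log-transformed) environmental availability of that
#' taxon. Taxa are matched by name; taxa missing from either vector, or with
#' non-positive availability, are dropped (inner join).
#'
#' @param predator_counts named integer vector: per-taxon number of
#'   individuals that captured the taxon (column totals of the binary
#'   matrix).
#' @param availability named non-negative vector of per-taxon environmental
#'   availability counts.
#' @return a `factor_test_result` with Pearson r, df = n - 2, two-sided p and
#'   the matched sample size n.
#' @export
availability_correlation <- function(predator_counts, availability) {
  taxa <- intersect(names(predator_counts), names(availability))
  taxa <- taxa[availability[taxa] > 0]
  if (length(taxa) < 3L) stop("fewer than 3 matched taxa with positive availability")
  x <- log(availability[taxa])
  y <- as.numeric(predator_counts[taxa])
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    return(factor_test_result("availability_correlation", NA_real_,
                              length(taxa) - 2L, NA_real_,
                              effect = list(r = NA_real_, n = length(taxa)),
                              transform = "ln",
                              flags = "constant input: correlation undefined"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  factor_test_result("availability_correlation", unname(ct$statistic),
                     unname(ct$parameter), ct$p.value,
                     effect = list(r = unname(ct$estimate), n = length(taxa)),
                     transform = "ln")
}

#' Body mass vs niche-breadth regression
#'
#' Least-squares regression of the percentage of the population's prey taxa
#' captured by each individual on its body mass: a positive slope means
#' larger individuals capture a wider share of the population's prey
#' spectrum (the mass-driven route to nestedness).
#'
#' @param mass per-individual body mass (mg).
#' @param pct_species per-individual percentage of the season's prey taxa
#'   captured, `100 * taxa captured by the individual / taxa captured by the
#'   population`. See [pct_taxa_captured()].
#' @return a `factor_test_result` with F statistic, df (1, n - 2), p, slope
#'   and adjusted R-squared.
#' @export
mass_breadth_regression <- function(mass, pct_species) {
  stopifnot(length(mass) == length(pct_species))
  ok <- is.finite(mass) & is.finite(pct_species)
  mass <- mass[ok]; pct_species <- pct_species[ok]
  if (length(mass) < 3L) stop("need at least 3 individuals with mass and breadth")
  if (stats::sd(mass) == 0) stop("zero variance in mass")
  fit <- stats::lm(pct_species ~ mass)
  sm <- summary(fit)
  fst <- sm$fstatistic
  factor_test_result("mass_breadth_regression", unname(fst[1]),
                     unname(fst[2:3]),
                     stats::pf(fst[1], fst[2], fst[3], lower.tail = FALSE),
                     effect = list(slope = unname(stats::coef(fit)[2]),
                                   r2_adj = sm$adj.r.squared))
}

#' Percentage of the population's prey taxa captured per individual
#'
#' @param m a [diet_matrix].
#' @return named numeric vector, `100 * taxa captured / total taxa`.
#' @export
pct_taxa_captured <- function(m) {
  b <- to_binary(as_diet_matrix(m))
  100 * rowSums(b$cells) / ncol(b$cells)
}

#' One-way ANOVA with Tukey HSD over clusters (or any grouping)
#'
#' @param values per-individual response (e.g. body mass or mean capture-day
#'   score).
#' @param groups a [cluster_assignment], or a vector of group labels aligned
#'   with `values` (or matched by names when both are named).
#' @return a `factor_test_result` with F, df, p, adjusted R-squared, group
#'   means and the Tukey HSD pairwise table.
#' @export
group_anova_tukey <- function(values, groups) {
  if (inherits(groups, "cluster_assignment")) groups <- groups$labels
  if (!is.null(names(values)) && !is.null(names(groups))) {
    common <- intersect(names(values), names(groups))
    values <- values[common]; groups <- groups[common]
  }
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (stats::sd(values) == 0) {
    return(factor_test_result("group_anova_tukey", 0,
                              c(nlevels(g) - 1L, length(values) - nlevels(g)), 1,
                              effect = list(group_means = tapply(values, g, mean),
                                            r2_adj = NA_real_, tukey = NULL),
                              flags = "all values identical: degenerate ANOVA"))
  }
  flags <- character()
  fit <- stats::aov(values ~ g)
  sm <- summary(fit)[[1]]
  fstat <- sm[1, "F value"]
  p <- sm[1, "Pr(>F)"]
  r2 <- summary(stats::lm(values ~ g))$adj.r.squared
  tuk <- if (all(table(g) >= 1) && length(flags) == 0)
    stats::TukeyHSD(fit)$g else NULL
  factor_test_result("group_anova_tukey",
                     if (is.nan(fstat)) 0 else fstat,
                     c(sm[1, "Df"], sm[2, "Df"]),
                     if (is.nan(p)) 1 else p,
                     effect = list(group_means = tapply(values, g, mean),
                                   r2_adj = r2, tukey = tuk),
                     flags = flags)
}

#' Levene's test of variance homogeneity across groups
#'
#' Mean-centered Levene's test (classical form) of equal variances, e.g. of
#' body mass across years; also reports each group's coefficient of
#' variation (sd / mean).
#'
#' @param values numeric response.
#' @param groups group labels aligned with `values` (e.g. season).
#' @return a `factor_test_result` with F, df, p and per-group CV.
#' @export
variance_homogeneity <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  lt <- car::leveneTest(values ~ g, center = mean)
  cv <- tapply(values, g, function(v) stats::sd(v) / mean(v))
  factor_test_result("variance_homogeneity", lt[1, "F value"],
                     c(lt[1, "Df"], lt[2, "Df"]), lt[1, "Pr(>F)"],
                     effect = list(cv = cv))
}

#' Paired first-nest vs last-nest diet-breadth shift
#'
#' Paired t-test of the per-female percentage of the population's prey taxa
#' captured for her first and last observed nest (females with at least two
#' nests). Detects a within-season shift in individual niche breadth.
#'
#' @param first_nest_pct,last_nest_pct paired per-female percentages.
#' @return a `factor_test_result` with t, df = n - 1, two-sided p and the
#'   mean difference.
#' @export
paired_shift_test <- function(first_nest_pct, last_nest_pct) {
  stopifnot(length(first_nest_pct) == length(last_nest_pct),
            length(first_nest_pct) >= 2L)
  d <- last_nest_pct - first_nest_pct
  if (stats::sd(d) == 0) {
    return(factor_test_result("paired_shift_test", 0,
                              length(d) - 1L, 1,
                              effect = list(mean_diff = mean(d)),
                              flags = "zero difference variance: degenerate"))
  }
  tt <- stats::t.test(last_nest_pct, first_nest_pct, paired = TRUE)
  factor_test_result("paired_shift_test", unname(tt$statistic),
                     unname(tt$parameter), tt$p.value,
                     effect = list(mean_diff = unname(tt$estimate)))
}

#' Mass-difference test for never- vs ever-co-occurring prey pairs
#'
#' For every unordered pair of prey taxa, the absolute difference between the
#' two species' mean body masses is computed; the differences of
#' never-co-occurring pairs are compared with those of co-occurring pairs by
#' a two-sample Student's t-test. A significant result would mean the
#' checkerboard pattern tracks prey-mass separation.
#'
#' @param pairs output of [never_cooccurring_pairs()].
#' @param species_mean_masses named vector of per-taxon mean prey mass (mg).
#' @return a `factor_test_result` with t, df, p and the two class means.
#' @export
cooccurrence_mass_test <- function(pairs, species_mean_masses) {
  all_taxa <- unique(c(pairs$never$taxon_a, pairs$never$taxon_b,
                       pairs$cooccurring$taxon_a, pairs$cooccurring$taxon_b))
  missing <- setdiff(all_taxa, names(species_mean_masses))
  if (length(missing))
    stop("mean mass missing for taxa: ", paste(missing, collapse = ", "))
  dmass <- function(df) abs(species_mean_masses[df$taxon_a] -
                            species_mean_masses[df$taxon_b])
  d_never <- dmass(pairs$never)
  d_co <- dmass(pairs$cooccurring)
  if (length(d_never) < 2L || length(d_co) < 2L)
    stop("need at least 2 pairs in each co-occurrence class")
  if (stats::sd(c(d_never, d_co)) == 0) {
    return(factor_test_result("cooccurrence_mass_test", 0,
                              length(d_never) + length(d_co) - 2L, 1,
                              effect = list(mean_never = mean(d_never),
                                            mean_cooccurring = mean(d_co)),
                              flags = "all mass differences identical: degenerate"))
  }
  tt <- stats::t.test(d_never, d_co, var.equal = TRUE)
  factor_test_result("cooccurrence_mass_test", unname(tt$statistic),
                     unname(tt$parameter), tt$p.value,
                     effect = list(mean_never = mean(d_never),
                                   mean_cooccurring = mean(d_co)))
}

#' Mean capture-day score per female
#'
#' Each prey item carries an observation-day score (1 = first observation
#' day, up to the last day of the season, e.g. 17); the per-female arithmetic
#' mean locates her activity in the season. Feed the result to
#' [group_anova_tukey()] with the dietary clusters as groups to test whether
#' clusters are time-structured. Females with no scored prey are excluded
#' with a warning.
#'
#' @param capture_days data.frame with columns `individual_id` and
#'   `day_score` (one row per prey item), or a named list of per-female
#'   score vectors.
#' @return named numeric vector of per-female mean scores.
#' @export
temporal_scores <- function(capture_days) {
  if (is.data.frame(capture_days)) {
    stopifnot(all(c("individual_id", "day_score") %in% names(capture_days)))
    sc <- split(capture_days$day_score, capture_days$individual_id)
  } else {
    sc <- capture_days
  }
  empty <- vapply(sc, function(v) length(v) == 0L || all(!is.finite(v)), logical(1))
  if (any(empty)) {
    warning("excluding females with no scored prey: ",
            paste(names(sc)[empty], collapse = ", "))
    sc <- sc[!empty]
  }
  vapply(sc, mean, numeric(1))
}

#' Within- vs between-cluster inter-nest distance test
#'
#' Euclidean distances between all pairs of nests, square-root transformed,
#' compared by a two-sample Student's t-test between pairs whose females
#' belong to the same dietary cluster and pairs from different clusters.
#' Pairs are treated as independent (a known pseudo-replication caveat of
#' pair-level tests, consistent with df = number of pairs - 2).
#'
#' @param coords data.frame with columns `individual_id`, `x_cm`, `y_cm`.
#' @param assignment a [cluster_assignment] (or named vector of labels).
#' @return a `factor_test_result` with t, df, p and the within/between mean
#'   (sqrt-scale) distances.
#' @export
internest_distance_test <- function(coords, assignment) {
  labels <- if (inherits(assignment, "cluster_assignment")) assignment$labels else assignment
  stopifnot(all(c("individual_id", "x_cm", "y_cm") %in% names(coords)))
  coords <- coords[coords$individual_id %in% names(labels), , drop = FALSE]
  xy <- as.matrix(coords[, c("x_cm", "y_cm")])
  if (any(!is.finite(xy))) stop("non-finite nest coordinates")
  cl <- labels[coords$individual_id]
  d <- as.matrix(stats::dist(xy))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  dist_sqrt <- sqrt(d[idx])
  same <- cl[idx[, 1]] == cl[idx[, 2]]
  if (sum(same) < 2L || sum(!same) < 2L)
    stop("need at least 2 within-cluster and 2 between-cluster nest pairs")
  if (stats::sd(dist_sqrt) == 0) {
    return(factor_test_result("internest_distance_test", 0,
                              length(dist_sqrt) - 2L, 1,
                              effect = list(), transform = "sqrt",
                              flags = "all nests coincide: degenerate"))
  }
  clusters_with_one <- names(which(table(cl) < 2))
  flags <- if (length(clusters_with_one))
    paste("clusters contributing no within pairs:",
          paste(clusters_with_one, collapse = ", ")) else character()
  tt <- stats::t.test(dist_sqrt[same], dist_sqrt[!same], var.equal = TRUE)
  factor_test_result("internest_distance_test", unname(tt$statistic),
                     unname(tt$parameter), tt$p.value,
                     effect = list(mean_within = mean(dist_sqrt[same]),
                                   mean_between = mean(dist_sqrt[!same])),
                     transform = "sqrt", flags = flags)
}
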