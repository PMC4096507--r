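#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Monte-Carlo routines that need independent random streams (for example one
#' null distribution per pair of individuals) derive a per-counter seed from
#' the master seed, so that results are reproducible and no two sub-streams
#' share draws. The mix is a fixed integer hash (multiplicative scramble of
#' the counter XORed with the seed, reduced modulo 2^31 - 1); streams are then
#' consumed with R's default Mersenne-Twister generator via [set.seed()].
#'
#' @param seed master seed, a single integer.
#' @param counter non-negative integer identifying the sub-stream.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(length(seed) == 1L, length(counter) == 1L, is.finite(seed), is.finite(counter))
  a <- as.integer(abs(as.double(seed)) %% 2147483647)
  b <- as.integer((as.double(counter) * 69069 + 12345) %% 2147483647)
  s <- bitwXor(a, b) %% 2147483646L
  s + 1L
}

#' Bootstrap an individual-by-taxon diet matrix from pooled proportions
#'
#' The diet-bootstrap null model: every individual redraws its own number of
#' prey items as a multinomial sample from the pooled population proportions
#' (column totals over the grand total, focal individual included). Row totals
#' are preserved exactly; the expected count in column i is the pooled
#' proportion of taxon i times the row total.
#'
#' @param m a [diet_matrix].
#' @param seed optional integer; when given, the RNG is seeded before drawing.
#' @return a `diet_matrix` with the same dimensions, ids and season.
#' @export
bootstrap_diets <- function(m, seed = NULL) {
  m <- as_diet_matrix(m)
  if (!is.null(seed)) set.seed(seed)
  q <- pooled_proportions(m)
  totals <- rowSums(m$counts)
  counts <- t(vapply(totals, function(tt) rmultinom(1L, tt, q)[, 1L],
                     numeric(length(q))))
  dimnames(counts) <- dimnames(m$counts)
  diet_matrix(counts, season = m$season, validate = FALSE)
}

#' Pooled population diet proportions
#'
#' Column totals divided by the grand total of a diet matrix: the population's
#' aggregate diet, which parameterizes the diet-bootstrap null.
#'
#' @param m a [diet_matrix].
#' @return a named numeric vector summing to 1.
#' @export
pooled_proportions <- function(m) {
  m <- as_diet_matrix(m)
  cs <- colSums(m$counts)
  cs / sum(cs)
}

#' Construct a null ensemble
#'
#' An ordered collection of null statistic values together with the scheme
#' that generated them, the ensemble size and the seed — the common currency
#' of all the Monte-Carlo tests in the package.
#'
#' @param values numeric vector of null statistic values.
#' @param statistic name of the statistic (e.g. "E", "Cw", "NODF", "C").
#' @param scheme one of `"diet_bootstrap"`, `"CE"`, `"swap"`.
#' @param seed the seed used to generate the ensemble.
#' @return an object of class `null_ensemble`.
#' @export
null_ensemble <- function(values, statistic, scheme = c("diet_bootstrap", "CE", "swap"),
                          seed = NA_integer_) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(values), length(values) >= 1L)
  structure(list(values = as.numeric(values), statistic = statistic,
                 scheme = scheme, n = length(values), seed = seed),
            class = "null_ensemble")
}

#' Monte-Carlo p-value against a null ensemble
#'
#' Uses the add-one (permutation-style) estimator so a p-value can never be
#' zero under finite resampling: the upper-tail p-value is
#' `(1 + #\{null >= observed\}) / (n + 1)`, ties counting against the observed
#' value (conservative). The two-sided p-value is twice the smaller tail,
#' capped at 1.
#'
#' @param observed observed statistic value.
#' @param ensemble a [null_ensemble] or plain numeric vector of null values.
#' @param tail `"upper"`, `"lower"` or `"two-sided"`.
#' @return a p-value in (0, 1].
#' @export
pvalue <- function(observed, ensemble, tail = c("upper", "lower", "two-sided")) {
  tail <- match.arg(tail)
  vals <- if (inherits(ensemble, "null_ensemble")) ensemble$values else as.numeric(ensemble)
  stopifnot(length(vals) >= 1L, is.finite(observed))
  n <- length(vals)
  up <- (1 + sum(vals >= observed)) / (n + 1)
  lo <- (1 + sum(vals <= observed)) / (n + 1)
  switch(tail,
         upper = up,
         lower = lo,
         `two-sided` = min(1, 2 * min(up, lo)))
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble: %s (%s scheme), n = %d, seed = %s\n",
              x$statistic, x$scheme, x$n, format(x$seed)))
  cat(sprintf("  mean = %.4f, 2.5%% = %.4f, 97.5%% = %.4f\n",
              mean(x$values), quantile(x$values, 0.025), quantile(x$values, 0.975)))
  invisible(x)
}

# shared constructor for index + null summaries
topology_result <- function(subclass, statistic, observed, ensemble, p.value,
                            verdict, extra = list()) {
  res <- c(list(statistic = statistic,
                observed = observed,
                null_mean = mean(ensemble$values),
                null_q = stats::quantile(ensemble$values, c(0.025, 0.05, 0.95, 0.975),
                                         names = TRUE),
                p.value = p.value,
                verdict = verdict,
                n_null = ensemble$n,
                scheme = ensemble$scheme,
                seed = ensemble$seed),
           extra)
  structure(res, class = c(subclass, "topology_result"))
}

#' @export
print.topology_result <- function(x, ...) {
  cat(sprintf("%s = %.4f  (null mean %.4f, n = %d %s resamples, seed %s)\n",
              x$statistic, x$observed, x$null_mean, x$n_null, x$scheme, format(x$seed)))
  cat(sprintf("  p = %.4g, verdict: %s\n", x$p.value, x$verdict))
  invisible(x)
}
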