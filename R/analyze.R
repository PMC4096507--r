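#' Run the full network analysis over one or more season matrices
#'
#' End-to-end driver: for every season it applies the minimum-prey filter,
#' then computes the four network statistics with their Monte-Carlo nulls —
#' E (diet-bootstrap, one-tailed 95% rule), C_ws (diet-bootstrap, two-tailed
#' 97.5% rule), NODF (CE null, one-tailed) and the C-score (fixed-margin swap
#' null, two-tailed) — plus the never-co-occurring pair census. When
#' clustering is detected (or `force_clusters = TRUE`), the
#' pairwise-significance graph is built and its connected components exported
#' as the dietary clusters. Results are written as CSV (one summary row per
#' season, one cluster table per clustered season) together with Pajek `.net`
#' exports of the overlap network, and returned invisibly.
#'
#' @param matrices named list of [diet_matrix] objects (names = seasons), or
#'   a character vector of CSV paths for [read_diet_matrix()].
#' @param out_dir output directory (created if missing); `NULL` disables file
#'   output.
#' @param n_boot Monte-Carlo resamples for every null model (default 10000).
#' @param seed master integer seed; each season/statistic gets an independent
#'   sub-stream via [derive_seed()].
#' @param threshold minimum prey per individual (default 4).
#' @param analyses subset of `c("E", "Cws", "NODF", "Cscore")` to run.
#' @param force_clusters always extract clusters, not only on a "clustered"
#'   verdict.
#' @return invisibly, a list per season with the result objects, the summary
#'   data.frame (`$summary`) and any cluster assignments.
#' @export
analyze <- function(matrices, out_dir = NULL, n_boot = 10000, seed = 1L,
                    threshold = 4, analyses = c("E", "Cws", "NODF", "Cscore"),
                    force_clusters = FALSE) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (is.character(matrices)) {
    paths <- matrices
    matrices <- lapply(paths, read_diet_matrix)
    names(matrices) <- vapply(matrices, function(m) m$season, character(1))
  }
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    names(matrices) <- vapply(matrices, function(m) m$season, character(1))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_line <- function(...) message(sprintf(...))
  results <- list()
  rows <- list()
  for (season in names(matrices)) {
    m <- filter_min_prey(as_diet_matrix(matrices[[season]]), threshold)
    b <- to_binary(m)
    sseed <- function(k) derive_seed(seed, match(season, names(matrices)) * 100L + k)
    res <- list(matrix = m)
    row <- data.frame(season = season, n_individuals = nrow(m$counts),
                      n_taxa = ncol(m$counts), n_items = sum(m$counts),
                      n_boot = n_boot, seed = seed)
    if ("E" %in% analyses) {
      res$E <- e_null_test(m, n_boot, sseed(1L))
      row$E <- res$E$observed; row$E_p <- res$E$p.value
      row$E_verdict <- res$E$verdict
    }
    if ("Cws" %in% analyses) {
      res$Cws <- cws_index(m, n_boot, sseed(2L))
      row$Cws <- res$Cws$observed
      row$Cws_ci_lower <- res$Cws$ci["lower"]; row$Cws_ci_upper <- res$Cws$ci["upper"]
      row$Cws_verdict <- res$Cws$verdict
      if (identical(res$Cws$verdict, "clustered") || force_clusters) {
        adj <- significant_overlap_graph(m, n_boot = min(n_boot, 2000),
                                         seed = sseed(3L))
        res$clusters <- extract_clusters(adj)
        row$n_clusters <- res$clusters$n_clusters
      }
    }
    if ("NODF" %in% analyses) {
      res$NODF <- nodf_test(b, n_boot, sseed(4L))
      row$NODF <- res$NODF$observed; row$NODF_p <- res$NODF$p.value
      row$NODF_verdict <- res$NODF$verdict
    }
    if ("Cscore" %in% analyses) {
      res$Cscore <- swap_null_test(b, n_boot, sseed(5L))
      row$Cscore <- res$Cscore$observed; row$Cscore_p <- res$Cscore$p.value
      row$Cscore_ci_lower <- res$Cscore$ci["lower"]
      row$Cscore_ci_upper <- res$Cscore$ci["upper"]
      row$Cscore_verdict <- res$Cscore$verdict
      row$never_cooccurring_pairs <- res$Cscore$checkerboard_pairs
    }
    if (!is.null(out_dir)) {
      net <- pairwise_overlap(m)
      export_pajek(net, file.path(out_dir, paste0("overlap_", season, ".net")),
                   partition = res$clusters)
      if (!is.null(res$clusters)) {
        utils::write.csv(as.data.frame(res$clusters),
                         file.path(out_dir, paste0("clusters_", season, ".csv")),
                         row.names = FALSE, quote = FALSE)
      }
      pr <- never_cooccurring_pairs(b)$never
      utils::write.csv(pr[, c("taxon_a", "taxon_b")],
                       file.path(out_dir, paste0("never_cooccurring_", season, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    log_line("[%s] n = %d individuals, %d taxa; seed %d, n_boot %d",
             season, nrow(m$counts), ncol(m$counts), seed, n_boot)
    results[[season]] <- res
    rows[[season]] <- row
  }
  summary <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (mm in miss) r[[mm]] <- NA
    r
  }))
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "season_report.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  results$summary <- summary
  invisible(results)
}
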