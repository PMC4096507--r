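#' Construct a diet matrix
#'
#' The central data object: a non-negative integer count matrix with rows the
#' individual foragers and columns the prey taxa. Validation drops all-zero
#' rows and columns with a warning (unobserved taxa in a season load cleanly),
#' requires unique row and column labels, and requires at least a 2 x 2 matrix
#' after cleaning. Orientation is a documented contract — rows are always
#' individuals — and is never guessed from headers.
#'
#' @param counts numeric matrix of non-negative integers with `dimnames`
#'   (row names = individual ids, column names = taxon ids). Unnamed
#'   dimensions get `ind1..`/`taxon1..` labels.
#' @param season free-text season label (e.g. `"2009"`).
#' @param validate run validation (drop empty rows/columns, check invariants).
#' @return an object of class `diet_matrix` with elements `counts` and
#'   `season`.
#' @export
diet_matrix <- function(counts, season = "", validate = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("ind", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  storage.mode(counts) <- "double"
  m <- structure(list(counts = counts, season = as.character(season)),
                 class = "diet_matrix")
  if (validate) m <- validate_diet_matrix(m) else m
}

validate_diet_matrix <- function(m) {
  counts <- m$counts
  if (anyNA(counts)) stop("diet matrix contains missing values")
  if (any(counts < 0)) stop("diet matrix contains negative counts")
  if (any(counts != round(counts))) stop("diet matrix contains non-integer counts")
  if (anyDuplicated(rownames(counts))) stop("duplicate individual ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon ids")
  zr <- rowSums(counts) == 0
  zc <- colSums(counts) == 0
  if (any(zr)) {
    warning(sprintf("dropping %d all-zero individual row(s): %s",
                    sum(zr), paste(rownames(counts)[zr], collapse = ", ")))
    counts <- counts[!zr, , drop = FALSE]
  }
  if (any(zc)) {
    warning(sprintf("dropping %d all-zero taxon column(s): %s",
                    sum(zc), paste(colnames(counts)[zc], collapse = ", ")))
    counts <- counts[, !zc, drop = FALSE]
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("degenerate diet matrix: fewer than 2 individuals or 2 taxa after cleaning")
  m$counts <- counts
  m
}

#' @export
as_diet_matrix <- function(m, ...) UseMethod("as_diet_matrix")

#' @export
as_diet_matrix.diet_matrix <- function(m, ...) m

#' @export
as_diet_matrix.matrix <- function(m, ...) diet_matrix(m, ...)

#' @export
as_diet_matrix.data.frame <- function(m, ...) diet_matrix(as.matrix(m), ...)

#' @export
print.diet_matrix <- function(x, ...) {
  cat(sprintf("Diet matrix%s: %d individuals x %d prey taxa, %d items\n",
              if (nzchar(x$season)) paste0(" [", x$season, "]") else "",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.diet_matrix <- function(x) dim(x$counts)

#' Individual and taxon labels of a diet matrix
#' @param m a [diet_matrix] or [binary_matrix].
#' @return character vector of labels.
#' @export
individual_ids <- function(m) rownames(if (inherits(m, "binary_matrix")) m$cells else m$counts)

#' @rdname individual_ids
#' @export
taxon_ids <- function(m) colnames(if (inherits(m, "binary_matrix")) m$cells else m$counts)

#' Read a diet matrix from delimited text
#'
#' Expects the first row to hold taxon labels and the first column individual
#' labels, the remaining cells integer counts. All-zero rows/columns are
#' dropped with a warning, per the [diet_matrix] contract. Legacy spreadsheet
#' (XLS) sources must be exported to CSV/TSV first; `dialect = "xls"` raises
#' an informative error.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param season season label to attach; defaults to the file name stem.
#' @return a [diet_matrix].
#' @export
read_diet_matrix <- function(path, dialect = c("csv", "tsv"), season = NULL) {
  if (identical(dialect, "xls"))
    stop("direct XLS ingestion is not supported; export the sheet to CSV first")
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df)
  bad <- which(!is.finite(suppressWarnings(matrix(as.numeric(mat), nrow(mat)))), arr.ind = TRUE)
  if (length(bad)) {
    stop(sprintf("malformed cell at row '%s', column '%s' in %s",
                 rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]], path))
  }
  storage.mode(mat) <- "double"
  if (is.null(season)) season <- sub("\\.[^.]+$", "", basename(path))
  diet_matrix(mat, season = season)
}

#' Write a diet matrix to delimited text
#'
#' Inverse of [read_diet_matrix()]: first column holds individual labels,
#' header row the taxon labels.
#'
#' @param m a [diet_matrix].
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_diet_matrix <- function(m, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  m <- as_diet_matrix(m)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(individual = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop individuals with too few prey
#'
#' Removes rows whose total prey count falls below `threshold` (the study
#' filter guarding against unstable diet proportions from tiny samples), then
#' drops any taxon column left all-zero. Idempotent.
#'
#' @param m a [diet_matrix].
#' @param threshold minimum prey items per retained individual (default 4).
#' @return a filtered [diet_matrix].
#' @export
filter_min_prey <- function(m, threshold = 4) {
  stopifnot(threshold >= 1)
  m <- as_diet_matrix(m)
  keep <- rowSums(m$counts) >= threshold
  if (sum(keep) < 2L)
    stop("degenerate matrix: fewer than 2 individuals meet the prey threshold")
  counts <- m$counts[keep, , drop = FALSE]
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  diet_matrix(counts, season = m$season, validate = FALSE)
}

#' Presence/absence view of a diet matrix
#'
#' Cell = 1 whenever at least one prey item of that taxon was taken by that
#' individual. The marginal totals of the binary matrix (occurrences per
#' individual and per taxon) are retained as metadata.
#'
#' @param m a [diet_matrix].
#' @return an object of class `binary_matrix` with elements `cells`,
#'   `row_totals`, `col_totals`.
#' @export
to_binary <- function(m) {
  m <- as_diet_matrix(m)
  cells <- (m$counts >= 1) * 1
  structure(list(cells = cells,
                 row_totals = rowSums(cells),
                 col_totals = colSums(cells),
                 season = m$season),
            class = "binary_matrix")
}

#' @export
as_binary_matrix <- function(b) {
  if (inherits(b, "binary_matrix")) return(b)
  if (inherits(b, "diet_matrix")) return(to_binary(b))
  cells <- as.matrix(b)
  stopifnot(all(cells %in% c(0, 1)))
  if (is.null(rownames(cells))) rownames(cells) <- paste0("ind", seq_len(nrow(cells)))
  if (is.null(colnames(cells))) colnames(cells) <- paste0("taxon", seq_len(ncol(cells)))
  structure(list(cells = cells, row_totals = rowSums(cells),
                 col_totals = colSums(cells), season = ""),
            class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("Binary matrix: %d x %d, fill %.2f\n",
              nrow(x$cells), ncol(x$cells), mean(x$cells)))
  invisible(x)
}

#' @export
dim.binary_matrix <- function(x) dim(x$cells)

#' Export a graph to a Pajek .net file
#'
#' Writes the standard Pajek format: a `*Vertices n` block with 1-based
#' numbering and quoted labels, then an `*Edges` block of `i j w` lines.
#' Accepts an [overlap_network] (complete weighted graph on individuals) or a
#' square symmetric binary adjacency ([binary_matrix] or 0/1 matrix). An
#' optional cluster partition is written alongside as a Pajek `.clu` file.
#'
#' @param g graph to export.
#' @param path output `.net` path.
#' @param partition optional [cluster_assignment] (or named integer vector);
#'   written to `sub(".net", ".clu", path)`.
#' @return `path`, invisibly.
#' @export
export_pajek <- function(g, path, partition = NULL) {
  if (inherits(g, "overlap_network")) {
    ids <- g$ids
    w <- g$weights
  } else {
    b <- if (inherits(g, "binary_matrix")) g$cells else as.matrix(g)
    stopifnot(nrow(b) == ncol(b))
    ids <- rownames(b)
    if (is.null(ids)) ids <- paste0("v", seq_len(nrow(b)))
    w <- b
  }
  if (any(!is.finite(w[upper.tri(w)]))) stop("non-finite edge weights")
  n <- length(ids)
  lines <- c(sprintf("*Vertices %d", n),
             sprintf('%d "%s"', seq_len(n), ids),
             "*Edges")
  ut <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  if (nrow(ut)) {
    lines <- c(lines, sprintf("%d %d %.10g", ut[, 1], ut[, 2], w[ut]))
  }
  writeLines(lines, path)
  if (!is.null(partition)) {
    cl <- if (inherits(partition, "cluster_assignment")) partition$labels else partition
    cl <- cl[ids]
    writeLines(c(sprintf("*Vertices %d", n), as.character(as.integer(cl))),
               sub("\\.net$", ".clu", path))
  }
  invisible(path)
}

#' Parse a Pajek .net file
#'
#' Minimal reader for the files written by [export_pajek()], mainly for
#' round-trip verification.
#'
#' @param path `.net` path.
#' @return list with `vertices` (character labels) and `edges`
#'   (data.frame `from`, `to`, `weight`).
#' @export
read_pajek <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("^\\*Vertices\\s+", "", lines[1], ignore.case = TRUE))
  vl <- lines[2:(nv + 1)]
  labels <- sub('^\\d+\\s+"(.*)"\\s*$', "\\1", vl)
  eidx <- grep("^\\*Edges", lines, ignore.case = TRUE)
  edges <- data.frame(from = integer(), to = integer(), weight = numeric())
  if (length(eidx) && eidx < length(lines)) {
    el <- lines[(eidx + 1):length(lines)]
    el <- el[nzchar(trimws(el))]
    if (length(el)) {
      parts <- do.call(rbind, strsplit(trimws(el), "\\s+"))
      edges <- data.frame(from = as.integer(parts[, 1]),
                          to = as.integer(parts[, 2]),
                          weight = as.numeric(parts[, 3]))
    }
  }
  list(vertices = labels, edges = edges)
}

#' Read per-individual or per-taxon covariates
#'
#' Covariates are stored in plain CSV keyed by `individual_id` (columns such
#' as `mass_mg`, nest coordinates `x_cm`/`y_cm`, per-prey `day_score`) or by
#' `taxon_id` (columns such as `availability`, `mean_mass_mg`). Validation is
#' light: the key column must exist and be duplicate-free (per-prey day-score
#' tables, with one row per prey item, are exempt), numeric columns must be
#' finite and the non-negative ones non-negative.
#'
#' @param path CSV path.
#' @param key `"individual_id"` or `"taxon_id"`.
#' @param unique_key require the key to be duplicate-free (default TRUE).
#' @return a data.frame.
#' @export
read_covariates <- function(path, key = c("individual_id", "taxon_id"),
                            unique_key = TRUE) {
  key <- match.arg(key)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!key %in% names(df)) stop("covariate file lacks key column ", key)
  if (unique_key && anyDuplicated(df[[key]])) stop("duplicate keys in ", path)
  nonneg <- intersect(c("mass_mg", "availability", "mean_mass_mg"), names(df))
  for (cc in nonneg) {
    if (any(!is.finite(df[[cc]])) || any(df[[cc]] < 0))
      stop("column ", cc, " must be finite and non-negative")
  }
  if ("day_score" %in% names(df)) {
    if (any(df$day_score != round(df$day_score)) || any(df$day_score < 1))
      stop("day_score must be a positive integer")
  }
  df
}
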