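#' ASV count table
#'
#' The unit of community data: a samples x ASVs matrix of non-negative integer
#' counts labelled with the kingdom the marker gene targets (16S bacteria,
#' 18S protists, or g23 T4-like viruses).
#'
#' @param counts integer matrix, samples in rows, ASVs in columns, with
#'   row and column names.
#' @param kingdom one of `"bacteria"`, `"protist"`, `"virus"`.
#' @return an `asv_table` object.
#' @export
asv_table <- function(counts, kingdom = c("bacteria", "protist", "virus")) {
  kingdom <- match.arg(kingdom)
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no samples")
  if (ncol(counts) == 0L) stop("no ASVs")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry sample (row) and ASV (column) names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate ASV ids")
  if (anyNA(counts)) stop("counts contain NA")
  if (any(counts < 0)) stop("negative counts")
  if (max(abs(counts - round(counts))) > 0) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, kingdom = kingdom), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %s: %d samples x %d ASVs, total %d reads\n",
              x$kingdom, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

#' Sample identifiers of an ASV table
#' @param x an `asv_table`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' ASV identifiers of an ASV table
#' @param x an `asv_table`.
#' @return character vector of ASV ids.
#' @export
asv_ids <- function(x) colnames(x$counts)

#' Subset an ASV table by samples and/or ASVs
#' @param x an `asv_table`.
#' @param samples,asvs index vectors (character, logical or integer).
#' @return the subset `asv_table`.
#' @export
subset_asv <- function(x, samples = NULL, asvs = NULL) {
  m <- x$counts
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(asvs)) m <- m[, asvs, drop = FALSE]
  asv_table(m, x$kingdom)
}

#' Read an ASV table from TSV
#'
#' Expects a tab-separated file with a header row of ASV ids and the first
#' column holding sample ids (`transpose = TRUE` accepts the transposed
#' dialect with ASVs in rows). Cells must be non-negative integers.
#'
#' @param path file path (plain or gzipped TSV).
#' @param kingdom kingdom label for the table.
#' @param transpose set `TRUE` when the file stores ASVs as rows.
#' @return an `asv_table`.
#' @export
read_asv_table <- function(path, kingdom = "bacteria", transpose = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("no samples")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in ASV table")
  rownames(m) <- ids
  if (transpose) m <- t(m)
  asv_table(m, kingdom)
}

#' Write an ASV table to TSV
#'
#' Inverse of [read_asv_table()]: header row of ASV ids, first column
#' `sample_id`.
#'
#' @param x an `asv_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_asv_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Rarefy an ASV table to even depth
#'
#' Subsamples each sample's reads without replacement
#' (multivariate-hypergeometric) to a common depth. Samples whose total is
#' below an explicit `depth` are dropped with a warning; with
#' `depth = "min"` the minimum row sum over all samples is used.
#'
#' @param x an `asv_table`.
#' @param depth positive integer, or `"min"` (the default) for the minimum
#'   sample total.
#' @param seed integer seed; the draw is reproducible.
#' @return a rarefied `asv_table`; every retained row sums to `depth`.
#' @export
rarefy <- function(x, depth = "min", seed = 1L) {
  totals <- rowSums(x$counts)
  if (identical(depth, "min")) {
    depth <- min(totals)
  } else {
    stopifnot(is.numeric(depth), length(depth) == 1L)
    depth <- as.integer(depth)
  }
  if (depth <= 0L) stop("rarefaction depth must be positive")
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) below rarefaction depth %d",
                    sum(!keep), depth))
  }
  if (!any(keep)) stop("no samples reach rarefaction depth")
  m <- x$counts[keep, , drop = FALSE]
  out <- with_seed(seed, {
    t(apply(m, 1L, function(row) {
      pool <- rep.int(seq_along(row), row)
      picked <- if (length(pool) == depth) pool else sample(pool, depth)
      tabulate(picked, nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(m)
  asv_table(out, x$kingdom)
}

#' Prevalence-filter an ASV table
#'
#' Retains ASVs detected in strictly more than `threshold` of the samples
#' ("detected over 30% of sampling sites" with the default threshold).
#'
#' @param x an `asv_table`.
#' @param threshold occupancy fraction in (0, 1); default 0.3.
#' @return the filtered `asv_table`.
#' @export
prevalence_filter <- function(x, threshold = 0.3) {
  stopifnot(threshold > 0, threshold < 1)
  occ <- colSums(x$counts > 0L)
  keep <- occ > threshold * nrow(x$counts)
  if (!any(keep)) stop("empty table after filtering")
  subset_asv(x, asvs = keep)
}

#' Relative abundance profiles
#'
#' @param x an `asv_table`.
#' @return numeric matrix of per-sample fractions; each row sums to 1.
#' @export
relative_abundance <- function(x) {
  totals <- rowSums(x$counts)
  if (any(totals == 0)) stop("all-zero sample(s); cannot normalize")
  x$counts / totals
}

#' Per-sample richness (observed ASV count)
#' @param x an `asv_table`.
#' @return named integer vector of observed ASVs per sample.
#' @export
richness <- function(x) rowSums(x$counts > 0L)

metadata_columns <- c("site_id", "latitude", "longitude", "elevation",
                      "MAT", "MAP", "MTCM", "PSCV", "pH", "SWC", "SOM",
                      "TN", "TC", "NO3", "NH4", "AP", "C_N")

#' Read site metadata from TSV
#'
#' Fixed column schema: site_id, latitude, longitude, elevation, MAT, MAP,
#' MTCM, PSCV, pH, SWC, SOM, TN, TC, NO3, NH4, AP, C_N. Checks physical
#' ranges for pH (0-14) and SWC (0-100).
#'
#' @param path TSV path.
#' @return a `data.frame` with one row per site.
#' @export
read_site_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

validate_metadata <- function(df) {
  missing <- setdiff(setdiff(metadata_columns, "elevation"), names(df))
  if (length(missing)) {
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$site_id)) stop("duplicate site ids")
  if (any(df$pH < 0 | df$pH > 14)) stop("pH outside 0-14")
  if (any(df$SWC < 0 | df$SWC > 100)) stop("SWC outside 0-100")
  df
}

#' Write site metadata to TSV
#' @param df metadata `data.frame`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_site_metadata <- function(df, path) write_tsv(df, path)

#' Harmonize an ASV table and metadata to their shared sites
#'
#' @param x an `asv_table`.
#' @param metadata metadata `data.frame` with a `site_id` column.
#' @return list with the subset `table` and `metadata` in matching order.
#' @export
harmonize_sites <- function(x, metadata) {
  shared <- intersect(sample_ids(x), metadata$site_id)
  if (length(shared) == 0L) stop("no shared site ids")
  list(table = subset_asv(x, samples = shared),
       metadata = metadata[match(shared, metadata$site_id), , drop = FALSE])
}
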