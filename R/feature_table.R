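#' Feature tables: abundances across samples with study factors
#'
#' A `feature_table` couples a features x samples abundance matrix with
#' per-feature metadata (m/z, retention time, ion mode) and per-sample
#' study factors (herbarium condition fresh/dry, species code). Feature
#' identifiers are rendered as `M<mz>T<rt><mode>` strings; collisions get
#' an ordinal suffix.
#'
#' @param abundances Numeric matrix, features x samples, finite and >= 0.
#' @param features Data frame with columns `mz`, `rt`, `ion_mode` (one row
#'   per feature), or `NULL` to derive placeholder metadata from rownames.
#' @param factors Data frame with columns `sample_id`, `herbarium`
#'   (`fresh`/`dry`) and `species`; every column of `abundances` must be
#'   present.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(abundances, features = NULL, factors = NULL) {
  abundances <- as.matrix(abundances)
  storage.mode(abundances) <- "double"
  abundances[is.na(abundances)] <- 0
  if (any(!is.finite(abundances)))
    stop("abundances must be finite")
  if (any(abundances < 0)) stop("abundances must be >= 0")
  if (!is.null(features)) {
    features <- as.data.frame(features)
    if (nrow(features) != nrow(abundances))
      stop("feature metadata rows must match abundance rows")
    ids <- feature_ids(features$mz, features$rt, features$ion_mode)
    rownames(abundances) <- ids
    rownames(features) <- ids
  } else if (is.null(rownames(abundances))) {
    rownames(abundances) <- sprintf("F%04d", seq_len(nrow(abundances)))
  }
  if (is.null(colnames(abundances)))
    stop("abundance matrix needs sample ids as column names")
  if (!is.null(factors)) {
    factors <- as.data.frame(factors)
    missing <- setdiff(colnames(abundances), factors$sample_id)
    if (length(missing))
      stop("samples missing from factor table: ",
           paste(missing, collapse = ", "))
    factors <- factors[match(colnames(abundances), factors$sample_id), ,
                       drop = FALSE]
    rownames(factors) <- factors$sample_id
  }
  structure(list(abundances = abundances, features = features,
                 factors = factors, transformed = FALSE),
            class = "feature_table")
}

feature_ids <- function(mz, rt, mode) {
  tag <- ifelse(substr(as.character(mode), 1, 1) %in% c("n", "N"), "n", "p")
  ids <- sprintf("M%.4fT%.1f%s", mz, rt, tag)
  while (anyDuplicated(ids)) {
    d <- which(duplicated(ids))
    ids[d] <- paste0(ids[d], "_", seq_along(d))
  }
  ids
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples%s\n",
              nrow(x$abundances), ncol(x$abundances),
              if (x$transformed) " (log10-transformed)" else ""))
  if (!is.null(x$factors))
    cat("  factors:", paste(setdiff(names(x$factors), "sample_id"),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Read a feature table and its factor table from delimited text
#'
#' The abundance file has feature ids in the first column and one column per
#' sample; the factor file maps every sample to its herbarium condition and
#' species code. Missing abundance cells are read as zero.
#'
#' @param file Path to the TSV/CSV abundance matrix.
#' @param factor_file Path to the TSV/CSV factor table with columns
#'   `sample_id`, `herbarium`, `species`.
#' @param sep Field separator (default tab).
#' @return A [feature_table].
#' @export
read_feature_table <- function(file, factor_file, sep = "\t") {
  m <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(m)
  m[is.na(m)] <- 0
  fac <- utils::read.table(factor_file, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  feature_table(m, factors = fac)
}

#' Write a feature table (and optionally its factors) to delimited text
#' @param ft A [feature_table].
#' @param file Output path for the abundance matrix.
#' @param factor_file Optional output path for the factor table.
#' @param sep Field separator.
#' @export
write_feature_table <- function(ft, file, factor_file = NULL, sep = "\t") {
  df <- data.frame(feature_id = rownames(ft$abundances), ft$abundances,
                   check.names = FALSE)
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(factor_file) && !is.null(ft$factors))
    utils::write.table(ft$factors, factor_file, sep = sep, quote = FALSE,
                       row.names = FALSE)
  invisible(file)
}
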