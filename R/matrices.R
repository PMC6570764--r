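#' Validate a labelled count matrix
#'
#' A count matrix holds non-negative integer abundances with sites (or map
#' cells) in rows and features (species, clades, or map cells) in columns.
#' Every row must contain at least one positive entry: an empty site carries
#' no information for a multinomial motif model and almost always indicates
#' an upstream data error, so it is rejected at load rather than silently
#' dropped.
#'
#' @param x A numeric matrix, or something coercible to one, with unique row
#'   and column names.
#' @return The validated integer matrix with class `count_matrix` prepended.
#' @export
as_count_matrix <- function(x) {
  x <- .as_labelled_matrix(x)
  if (any(x < 0)) stop("count matrix has negative entries")
  if (any(x != round(x))) stop("count matrix has non-integer entries")
  zero <- rownames(x)[rowSums(x) == 0]
  if (length(zero) > 0) {
    stop("all-zero rows not allowed: ", paste(zero, collapse = ", "))
  }
  storage.mode(x) <- "double"
  class(x) <- c("count_matrix", class(x))
  x
}

#' Validate a labelled presence-absence matrix
#'
#' Entries must be strictly 0/1 and every row (map cell or site) must record
#' at least one presence.
#'
#' @inheritParams as_count_matrix
#' @return The validated binary matrix with class `presence_matrix` prepended.
#' @export
as_presence_matrix <- function(x) {
  x <- .as_labelled_matrix(x)
  if (!all(x %in% c(0, 1))) stop("presence matrix entries must be 0 or 1")
  zero <- rownames(x)[rowSums(x) == 0]
  if (length(zero) > 0) {
    stop("rows with no presences not allowed: ", paste(zero, collapse = ", "))
  }
  class(x) <- c("presence_matrix", class(x))
  x
}

.as_labelled_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("expected a numeric matrix")
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("col", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate row ids")
  if (anyDuplicated(colnames(x))) stop("duplicate column ids")
  x <- unclass(x)
  attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <- NULL
  x
}

#' Read a site-by-feature matrix from CSV/TSV
#'
#' The first column holds row ids and the header holds feature ids; cells are
#' integers.  The separator is taken from the file extension (`.tsv`/`.txt`
#' means tab, anything else comma) unless given explicitly.
#'
#' @param path File path.
#' @param type `"count"` or `"presence"`; selects the validator applied.
#' @param sep Field separator; `NULL` to infer from the extension.
#' @return A `count_matrix` or `presence_matrix`.
#' @export
read_motif_matrix <- function(path, type = c("count", "presence"), sep = NULL) {
  type <- match.arg(type)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  switch(type, count = as_count_matrix(m), presence = as_presence_matrix(m))
}

#' Write a site-by-feature matrix to CSV/TSV
#'
#' Inverse of [read_motif_matrix()]; integer cells round-trip exactly.
#'
#' @param m Matrix with row and column names.
#' @param path Destination file.
#' @param sep Field separator; `NULL` to infer from the extension.
#' @export
write_motif_matrix <- function(m, path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- data.frame(id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a site table
#'
#' Expects columns `site_id`, `lon`, `lat`, `elevation_m`, `region`.
#'
#' @param path CSV file path.
#' @return A data frame with one row per site.
#' @export
read_site_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("site_id", "lon", "lat", "elevation_m", "region")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("site table missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$site_id)) stop("duplicate site ids")
  df
}
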