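#' Construct a binary association matrix
#'
#' Wraps a binary miRNA-by-disease incidence matrix in a light container
#' after validation. Rows are miRNAs, columns are diseases; a 1 in cell
#' (i, j) records a known association between miRNA i and disease j.
#'
#' @param values Numeric matrix with entries in \{0, 1\}.
#' @param row_ids,col_ids Optional character identifiers for rows
#'   (miRNAs) and columns (diseases). Defaults to existing dimnames or
#'   generated labels.
#' @param require_positive If `TRUE` (default), reject an all-zero
#'   matrix: a network with no known association cannot be trained on.
#'
#' @return The validated matrix with class `assoc_matrix` and dimnames
#'   set to the identifiers.
#' @export
#'
#' @examples
#' n <- association_matrix(matrix(c(1, 0, 0, 1), 2, 2))
#' attr(n, "n_m")
association_matrix <- function(values, row_ids = NULL, col_ids = NULL,
                               require_positive = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("association matrix must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(values)) stop("association matrix contains NA", call. = FALSE)
  if (!all(values %in% c(0, 1))) {
    stop("association matrix entries must be 0 or 1", call. = FALSE)
  }
  row_ids <- row_ids %||% rownames(values) %||% paste0("m", seq_len(nrow(values)))
  col_ids <- col_ids %||% colnames(values) %||% paste0("d", seq_len(ncol(values)))
  if (length(row_ids) != nrow(values)) {
    stop("row_ids length does not match the miRNA axis (rows)", call. = FALSE)
  }
  if (length(col_ids) != ncol(values)) {
    stop("col_ids length does not match the disease axis (columns)", call. = FALSE)
  }
  if (anyDuplicated(row_ids)) stop("duplicate miRNA ids", call. = FALSE)
  if (anyDuplicated(col_ids)) stop("duplicate disease ids", call. = FALSE)
  if (require_positive && sum(values) == 0) {
    stop("association matrix has no positive entry", call. = FALSE)
  }
  dimnames(values) <- list(row_ids, col_ids)
  structure(values, class = c("assoc_matrix", class(values)),
            n_m = nrow(values), n_d = ncol(values))
}

#' Read an association edge list into a binary matrix
#'
#' Reads a two-column TSV of (miRNA id, disease id), one known
#' association per line, and densifies it into a binary matrix. Ids are
#' mapped to indices in first-appearance order unless explicit id
#' vectors are supplied, in which case every edge id must be present in
#' them.
#'
#' @param path Path to the TSV file.
#' @param header Does the file carry a header line? Default `FALSE`.
#' @param mirna_ids,disease_ids Optional character vectors fixing the
#'   row/column universe and order (so entities with no known edge are
#'   retained).
#'
#' @return An [association_matrix()].
#' @export
read_associations <- function(path, header = FALSE,
                              mirna_ids = NULL, disease_ids = NULL) {
  lines <- readLines(path)
  if (header && length(lines) > 0) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no edges in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop("line ", bad[1] + header, " of ", path,
         ": expected 2 tab-separated fields, got ", lengths(parts)[bad[1]],
         call. = FALSE)
  }
  edges <- do.call(rbind, parts)
  m_id <- trimws(edges[, 1])
  d_id <- trimws(edges[, 2])
  mirna_ids <- mirna_ids %||% unique(m_id)
  disease_ids <- disease_ids %||% unique(d_id)
  mi <- match(m_id, mirna_ids)
  di <- match(d_id, disease_ids)
  if (anyNA(mi)) {
    stop("line ", which(is.na(mi))[1] + header, ": miRNA id '",
         m_id[which(is.na(mi))[1]], "' not in the supplied id list",
         call. = FALSE)
  }
  if (anyNA(di)) {
    stop("line ", which(is.na(di))[1] + header, ": disease id '",
         d_id[which(is.na(di))[1]], "' not in the supplied id list",
         call. = FALSE)
  }
  n <- matrix(0, length(mirna_ids), length(disease_ids))
  n[cbind(mi, di)] <- 1
  association_matrix(n, mirna_ids, disease_ids)
}

#' Write an association matrix as an edge list
#'
#' Inverse of [read_associations()]: emits one (miRNA id, disease id)
#' line per positive cell, tab-separated, in row-major order.
#'
#' @param n An [association_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(n, path) {
  idx <- which(t(unclass(n)) == 1)  # row-major order
  j <- (idx - 1) %% ncol(n) + 1
  i <- (idx - 1) %/% ncol(n) + 1
  writeLines(paste(rownames(n)[i], colnames(n)[j], sep = "\t"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
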