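#' Gaussian interaction profile kernel similarity
#'
#' Computes the standard Gaussian interaction profile (GIP) kernel from
#' a binary association matrix, as a self-contained similarity fallback
#' when no externally computed miRNA functional similarity or disease
#' semantic similarity is available. The interaction profile of an
#' entity is its row (miRNA axis) or column (disease axis) of the
#' association matrix, and
#' \deqn{K(i, j) = \exp(-\gamma \| ip_i - ip_j \|^2)}
#' with bandwidth \eqn{\gamma = 1 / \mathrm{mean}_i \| ip_i \|^2}, the
#' usual mean-squared-profile-norm rule with multiplier 1.
#'
#' @param n An [association_matrix()] (or plain binary matrix).
#' @param axis `"mirna"` for a miRNA-by-miRNA kernel from rows,
#'   `"disease"` for a disease-by-disease kernel from columns.
#'
#' @return A symmetric similarity matrix with unit diagonal and entries
#'   in (0, 1], carrying the bandwidth as attribute `gamma`.
#' @export
#'
#' @examples
#' n <- association_matrix(diag(2))
#' gip_kernel(n, "mirna")[1, 2]  # exp(-2)
gip_kernel <- function(n, axis = c("mirna", "disease")) {
  axis <- match.arg(axis)
  p <- if (axis == "mirna") unclass(n) else t(unclass(n))
  norms <- rowSums(p^2)
  if (mean(norms) == 0) {
    stop("all-zero association matrix: GIP bandwidth undefined", call. = FALSE)
  }
  gamma <- 1 / mean(norms)
  # ||ip_i - ip_j||^2 = ||ip_i||^2 + ||ip_j||^2 - 2 <ip_i, ip_j>
  d2 <- outer(norms, norms, "+") - 2 * tcrossprod(p)
  d2[d2 < 0] <- 0  # numeric jitter from the expansion
  k <- exp(-gamma * d2)
  diag(k) <- 1
  k <- (k + t(k)) / 2
  ids <- if (axis == "mirna") rownames(n) else colnames(n)
  if (!is.null(ids)) dimnames(k) <- list(ids, ids)
  structure(k, gamma = gamma)
}

#' Validate (and mildly repair) a similarity matrix
#'
#' Checks that a supplied similarity matrix is square, finite,
#' symmetric, in \[0, 1\] and unit-diagonal. Mild defects common in
#' published similarity files are repaired: asymmetry up to `1e-6` is
#' symmetrised by averaging with the transpose, out-of-range values are
#' clamped to \[0, 1\] with a warning counting the clamped cells, and
#' the diagonal is set to 1. Larger asymmetry is rejected.
#'
#' @param s Square numeric matrix.
#' @param ids Optional identifiers; length must match the dimension.
#' @param tol Asymmetry tolerance beyond which the matrix is rejected
#'   (maximum absolute difference with the transpose). Default `1e-6`.
#'
#' @return The validated matrix, dimnames set to `ids` when given.
#' @export
validate_similarity <- function(s, ids = NULL, tol = 1e-6) {
  if (!is.matrix(s) || !is.numeric(s)) {
    stop("similarity must be a numeric matrix", call. = FALSE)
  }
  if (nrow(s) != ncol(s)) stop("similarity matrix must be square", call. = FALSE)
  if (anyNA(s) || any(!is.finite(s))) {
    stop("similarity matrix contains NA or non-finite values", call. = FALSE)
  }
  if (!is.null(ids)) {
    if (length(ids) != nrow(s)) {
      stop("ids length ", length(ids), " does not match similarity dimension ",
           nrow(s), call. = FALSE)
    }
    dimnames(s) <- list(ids, ids)
  }
  asym <- max(abs(s - t(s)))
  if (asym > tol) {
    stop("similarity matrix asymmetric beyond tolerance (max |s - t(s)| = ",
         format(asym), ")", call. = FALSE)
  }
  if (asym > 0) s <- (s + t(s)) / 2
  n_clamped <- sum(s < 0 | s > 1)
  if (n_clamped > 0) {
    warning(n_clamped, " similarity cells outside [0, 1] were clamped",
            call. = FALSE)
    s[s < 0] <- 0
    s[s > 1] <- 1
  }
  diag(s) <- 1
  s
}

#' Read a dense similarity matrix from TSV/CSV
#'
#' Accepts either a matrix with a header row and an index column of ids,
#' or a headerless square numeric matrix with ids supplied separately.
#' Parsing is strict: ragged rows, non-numeric cells or NaN abort with a
#' line-numbered message; values are then passed through
#' [validate_similarity()].
#'
#' @param path Path to the file; the delimiter is taken from the
#'   extension (`.csv` comma, otherwise tab) unless `sep` is given.
#' @param ids Optional id vector for headerless files.
#' @param header Whether the file has a header row + id column.
#'   Default `TRUE`.
#' @param sep Field separator override.
#'
#' @return A validated similarity matrix.
#' @export
read_similarity <- function(path, ids = NULL, header = TRUE, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty similarity file ", path, call. = FALSE)
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (header) {
    hdr <- parts[[1]]
    body <- parts[-1]
    # header may or may not carry a leading cell above the id column
    file_ids <- vapply(body, `[[`, "", 1)
    vals <- lapply(body, function(x) x[-1])
    expected <- length(file_ids)
    offset <- 1L
  } else {
    body <- parts
    file_ids <- ids %||% paste0("e", seq_along(body))
    vals <- body
    expected <- length(body)
    offset <- 0L
  }
  widths <- lengths(vals)
  bad <- which(widths != expected)
  if (length(bad) > 0) {
    stop("line ", bad[1] + offset, " of ", path, ": expected ", expected,
         " values, got ", widths[bad[1]], call. = FALSE)
  }
  s <- matrix(NA_real_, expected, expected)
  for (i in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[i]]))
    if (anyNA(v) || any(is.nan(v))) {
      stop("line ", i + offset, " of ", path, ": non-numeric or NaN value",
           call. = FALSE)
    }
    s[i, ] <- v
  }
  validate_similarity(s, ids = if (header) file_ids else ids)
}

#' Write a similarity matrix as TSV with ids
#'
#' @param s Similarity matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(s, path) {
  ids <- rownames(s) %||% paste0("e", seq_len(nrow(s)))
  hdr <- paste(c("id", ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(ids[i], format(s[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
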