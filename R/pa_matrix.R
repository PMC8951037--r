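#' Presence/absence insertion matrix
#'
#' A `pa_matrix` is an integer matrix with taxa as rows and insertion loci
#' as columns. Cells are `1` (insertion present), `0` (absent) or `NA`
#' (not genotyped, written as `?` on disk). It is the "01" matrix consumed
#' by every downstream analysis.
#'
#' @param x integer (or coercible) matrix of 0/1/NA values.
#' @param taxa character vector of unique taxon labels; defaults to
#'   `rownames(x)`.
#' @param locus_ids character vector of unique locus identifiers; defaults
#'   to `colnames(x)`, or `locus_<i>` if absent.
#' @param loci_meta optional data frame of per-locus metadata (columns
#'   `locus_id`, `chrom`, `pos`), carried through I/O.
#' @return an object of class `pa_matrix`.
#' @examples
#' m <- pa_matrix(rbind(A = c(1, 0), B = c(1, 1), C = c(0, 1), D = c(0, 0)))
#' m
#' @export
pa_matrix <- function(x, taxa = rownames(x), locus_ids = colnames(x),
                      loci_meta = NULL) {
  x <- as.matrix(x)
  if (is.null(taxa)) stop("taxa labels are required (rownames or `taxa`)")
  if (is.null(locus_ids)) {
    locus_ids <- if (ncol(x) > 0) sprintf("locus_%d", seq_len(ncol(x))) else character()
  }
  taxa <- as.character(taxa)
  locus_ids <- as.character(locus_ids)
  if (length(taxa) != nrow(x)) stop("length(taxa) != nrow(x)")
  if (length(locus_ids) != ncol(x)) stop("length(locus_ids) != ncol(x)")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  if (anyDuplicated(locus_ids)) stop("duplicate locus ids")
  storage.mode(x) <- "integer"
  bad <- !is.na(x) & !(x %in% c(0L, 1L))
  if (any(bad)) stop("matrix states must be 0, 1 or NA")
  dimnames(x) <- list(taxa, locus_ids)
  structure(x, loci_meta = loci_meta, class = c("pa_matrix", "matrix", "array"))
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("Presence/absence matrix: %d taxa x %d loci (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  k <- min(ncol(x), 60L)
  for (i in seq_len(nrow(x))) {
    s <- ifelse(is.na(x[i, seq_len(k)]), "?", as.character(x[i, seq_len(k)]))
    cat(sprintf("  %-12s %s%s\n", rownames(x)[i], paste(s, collapse = ""),
                if (ncol(x) > k) "..." else ""))
  }
  invisible(x)
}

#' @export
`[.pa_matrix` <- function(x, i, j, ..., drop = TRUE) {
  y <- NextMethod()
  if (is.matrix(y)) {
    meta <- attr(x, "loci_meta")
    if (!is.null(meta)) meta <- meta[match(colnames(y), meta$locus_id), , drop = FALSE]
    y <- pa_matrix(y, loci_meta = meta)
  }
  y
}

#' @rdname pa_matrix
#' @param m an object to test.
#' @export
is_pa_matrix <- function(m) inherits(m, "pa_matrix")

# Collapse identical columns into unique patterns with multiplicities.
# Scoring a tree on the collapsed matrix with `weights` equals scoring the
# full matrix; the collapse is what keeps bootstrap searches cheap.
pa_collapse <- function(m, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, ncol(m))
  if (ncol(m) == 0) return(list(m = m, weights = numeric()))
  key <- apply(m, 2, paste, collapse = "")
  first <- !duplicated(key)
  w <- as.numeric(tapply(weights, key, sum)[key[first]])
  list(m = m[, first, drop = FALSE], weights = w)
}

# Internal: check a matrix is complete (no missing states).
stopifnot_complete <- function(m) {
  if (anyNA(m)) stop("matrix contains missing states ('?'); run filter_complete() first")
  invisible(m)
}
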