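#' @useDynLib phylodup, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# IUPAC nucleotide alphabet accepted in alignments.  'U' is folded into 'T'
# on read; '-' and '?' are both treated as missing inside the likelihood but
# '-' is preserved on write.
DNA_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-", "?")

#' Construct a multiple sequence alignment object
#'
#' An alignment is stored as a character matrix (one row per specimen, one
#' column per aligned position) with unique row names.  All characters must
#' belong to the IUPAC nucleotide alphabet plus \code{-} (gap) and \code{?}
#' (missing).
#'
#' @param seqs named character vector of aligned sequences (equal lengths),
#'   or a character matrix of single characters with row names.
#' @return an object of class \code{"dup_alignment"} with elements
#'   \code{taxa}, \code{mat} (character matrix) and \code{n_columns}.
#' @export
alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("all sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- which(lens != lens[1L])[1L]
      stop(sprintf("sequence lengths differ: record %d ('%s') has %d characters, expected %d",
                   bad, names(seqs)[bad], lens[bad], lens[1L]))
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat)) || any(!nzchar(rownames(mat))))
    stop("alignment rows must be named")
  if (anyDuplicated(rownames(mat)))
    stop(sprintf("duplicate specimen label: '%s'",
                 rownames(mat)[duplicated(rownames(mat))][1L]))
  mat[mat == "U"] <- "T"
  bad <- setdiff(unique(as.vector(mat)), DNA_CHARS)
  if (length(bad))
    stop("invalid characters in alignment: ", paste(bad, collapse = " "))
  structure(list(taxa = rownames(mat), mat = mat, n_columns = ncol(mat)),
            class = "dup_alignment")
}

#' @export
print.dup_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d taxa, %d columns\n", length(x$taxa), x$n_columns))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Records must all have the same length (it is an alignment, not a raw
#' sequence set).  Characters are upper-cased and \code{U} is mapped to
#' \code{T}.
#'
#' @param path path to a FASTA file.
#' @return a \code{dup_alignment}.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  names(seqs) <- trimws(names(recs))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop(sprintf("unequal sequence lengths in '%s': record %d ('%s') has %d characters, expected %d",
                 path, bad, names(seqs)[bad], lens[bad], lens[1L]))
  }
  alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln a \code{dup_alignment}.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "dup_alignment"))
  seqs <- apply(aln$mat, 1L, paste0, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = aln$taxa, file.out = path,
                      nbchar = 80)
  invisible(path)
}

#' Subset an alignment by partition class and taxa
#'
#' Restricts the character matrix to the columns of one partition class
#' (e.g. all plastid regions) and, optionally, to a subset of specimens.
#' Column order is preserved.
#'
#' @param aln a \code{dup_alignment}.
#' @param scheme a \code{dup_partitions} scheme.
#' @param klass partition class, \code{"plastid"} or \code{"nuclear"}, or
#'   \code{NULL} for all columns.
#' @param taxa optional character vector of specimen labels to keep.
#' @return a \code{dup_alignment} over the selected columns/taxa.
#' @export
subset_alignment <- function(aln, scheme = NULL, klass = NULL, taxa = NULL) {
  stopifnot(inherits(aln, "dup_alignment"))
  cols <- seq_len(aln$n_columns)
  if (!is.null(klass)) {
    if (is.null(scheme)) stop("a partition scheme is required to subset by class")
    cols <- class_columns(scheme, klass)
    if (max(cols) > aln$n_columns)
      stop("partition scheme extends beyond the alignment")
  }
  if (is.null(taxa)) taxa <- aln$taxa
  missing <- setdiff(taxa, aln$taxa)
  if (length(missing))
    stop("taxa not in alignment: ", paste(missing, collapse = ", "))
  alignment(aln$mat[taxa, cols, drop = FALSE])
}

#' Proportion of defined (non-missing, non-gap) characters per taxon
#' @param aln a \code{dup_alignment}.
#' @return named numeric vector in [0, 1].
#' @export
defined_fraction <- function(aln) {
  apply(aln$mat, 1L, function(r) mean(!(r %in% c("-", "?"))))
}
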