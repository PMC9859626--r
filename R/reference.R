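#' Reference sequence accessors
#'
#' The caller touches the reference through a plain accessor function
#' `f(start0, end0)` returning the bases of `[start0, end0)` (0-based,
#' half-open) as an upper-case string.  `ref_accessor()` builds one from a
#' character string (optionally offset so that position `offset` is the
#' string's first base), and `fasta_accessors()` builds one per contig from
#' an indexed FASTA via Rsamtools.
#'
#' @param x A character scalar of bases.
#' @param offset 0-based reference position of the first character of `x`.
#' @return A function `(start0, end0) -> character`.
#' @examples
#' acc <- ref_accessor("ACGTACGT")
#' acc(2, 5)
#' @export
ref_accessor <- function(x, offset = 0L) {
  x <- toupper(x)
  n <- nchar(x)
  offset <- as.integer(offset)
  function(start0, end0) {
    if (end0 <= start0) return("")
    s <- start0 - offset
    e <- end0 - offset
    if (s < 0L || e > n) stop("reference window [", start0, ",", end0,
                              ") outside loaded sequence")
    substr(x, s + 1L, e)
  }
}

#' @param fasta Path to a FASTA file; an `.fai` index is created if absent.
#' @param contigs Contigs to load (default: all).
#' @rdname ref_accessor
#' @export
fasta_accessors <- function(fasta, contigs = NULL) {
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  fa <- Rsamtools::FaFile(fasta)
  idx <- Rsamtools::scanFaIndex(fa)
  nm <- as.character(GenomicRanges::seqnames(idx))
  if (!is.null(contigs)) {
    missing <- setdiff(contigs, nm)
    if (length(missing)) stop("contigs absent from FASTA: ",
                              paste(missing, collapse = ", "))
    idx <- idx[nm %in% contigs]
    nm <- as.character(GenomicRanges::seqnames(idx))
  }
  seqs <- as.character(Rsamtools::scanFa(fa, idx))
  names(seqs) <- nm
  lapply(setNames(nm, nm), function(ct) ref_accessor(seqs[[ct]], 0L))
}

contig_lengths_fasta <- function(fasta) {
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  idx <- Rsamtools::scanFaIndex(Rsamtools::FaFile(fasta))
  setNames(GenomicRanges::width(idx),
           as.character(GenomicRanges::seqnames(idx)))
}
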