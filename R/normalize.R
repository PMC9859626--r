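#' Normalize a variant representation
#'
#' Left-aligns and minimally represents an allele pair against the
#' reference: shared suffix bases are trimmed (extending left through
#' repeat copies, which left-shifts pure indels), then shared prefix bases
#' are trimmed while both alleles keep at least one base.  The result is
#' the conventional minimal form: pure insertions/deletions carry a single
#' left anchor base; block substitutions (MNV, complex) keep non-empty
#' `ref` and `alt` with no extra anchor (`GG>A` stays `GG>A`).
#' Normalization is idempotent.
#'
#' @param pos 0-based reference position of the first `ref` base (for a
#'   pure insertion with empty `ref`, the insertion point).
#' @param ref,alt Allele strings (either may be empty, not both).
#' @param ref_fun Reference accessor ([ref_accessor()]).
#' @param check Verify `ref` matches the reference at `pos` (default TRUE).
#' @return A list with `pos` (0-based), `ref`, `alt`, `vtype`.
#' @examples
#' acc <- ref_accessor("GGTACACACAGGT")
#' # deletion of "CA" inside the CA repeat left-aligns to the repeat start
#' normalize_variant(7, "ACA", "A", acc)
#' @export
normalize_variant <- function(pos, ref, alt, ref_fun, check = TRUE) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) stop("ref equals alt")
  if (check && nchar(ref) > 0L &&
      !identical(ref_fun(pos, pos + nchar(ref)), ref))
    stop("reference mismatch at position ", pos + 1L, ": expected '",
         ref_fun(pos, pos + nchar(ref)), "', got '", ref, "'")
  last <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    if (nchar(ref) > 0L && nchar(alt) > 0L && last(ref) == last(alt)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    } else if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos == 0L) break  # cannot extend left of the contig
      b <- ref_fun(pos - 1L, pos)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      pos <- pos - 1L
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  vtype <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
    else if (nchar(ref) == nchar(alt)) "MNV"
    else if (startsWith(alt, ref)) "insertion"
    else if (startsWith(ref, alt)) "deletion"
    else "complex"
  list(pos = pos, ref = ref, alt = alt, vtype = vtype)
}

## vectorised over a candidates table; returns updated copy
normalize_candidates <- function(cand, ref_funs, check = TRUE) {
  cand <- as.data.table(cand)
  if (nrow(cand) == 0L) return(cand)
  for (i in seq_len(nrow(cand))) {
    nv <- normalize_variant(cand$pos[i], cand$ref[i], cand$alt[i],
                            ref_funs[[cand$contig[i]]], check = check)
    set(cand, i, "pos", nv$pos)
    set(cand, i, "ref", nv$ref)
    set(cand, i, "alt", nv$alt)
    set(cand, i, "vtype", nv$vtype)
  }
  cand[]
}
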