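#' Bayesian classifier LOD for single-nucleotide variants
#'
#' At a candidate site with reference base `r` and alternate `m`, each
#' observed base `b_i` with Phred quality `q_i` (error probability
#' `e_i = 10^(-q_i/10)`) has likelihood `P(b_i | a) = 1 - e_i` when
#' `b_i == a` and `e_i / 3` otherwise.  The site score is the log10 ratio
#' of the data likelihood under a mutant model with allele fraction
#' `f_hat` versus the reference-only model (`f = 0`):
#' `LOD = sum_i log10[(f_hat P(b_i|m) + (1 - f_hat) P(b_i|r)) / P(b_i|r)]`.
#' `f_hat` is the duplicate-collapsed alternate fraction; candidates with
#' `LOD < lod_threshold` (3.9) are rejected.
#'
#' @param observed_base,allele Single bases (A/C/G/T).
#' @param q Phred quality.
#' @return `allele_likelihood()`: the probability of observing
#'   `observed_base` given true allele `allele`.
#' @examples
#' allele_likelihood("A", 30, "A")   # 0.999
#' allele_likelihood("C", 30, "A")   # 0.001 / 3
#' @export
allele_likelihood <- function(observed_base, q, allele) {
  if (!all(c(observed_base, allele) %in% c("A", "C", "G", "T")))
    stop("non-ACGT base in likelihood evaluation")
  e <- 10^(-q / 10)
  ifelse(observed_base == allele, 1 - e, e / 3)
}

## Vectorised log10 LOD terms from alt/ref match indicators.  `match_alt`
## and `match_ref` are logicals per observation; a base matching neither
## contributes 0 (both models assign it e/3).
lod_terms <- function(match_alt, match_ref, qual, f) {
  e <- 10^(-qual / 10)
  p_alt <- ifelse(match_alt, 1 - e, e / 3)
  p_ref <- ifelse(match_ref, 1 - e, e / 3)
  log10(f * p_alt + (1 - f) * p_ref) - log10(p_ref)
}

lod_from_indicators <- function(match_alt, match_ref, qual, f) {
  if (f == 0) return(0)
  sum(lod_terms(match_alt, match_ref, qual, f))
}

#' @param obs Site observations: a data.frame with columns `allele`
#'   (single bases) and `qual`.  Pass duplicate-collapsed representatives
#'   to keep the LOD coherent with the collapsed VAF (use
#'   `collapse = FALSE` semantics by passing raw observations instead).
#' @param ref,alt Reference and alternate base at the site.
#' @param config A [caller_config()].
#' @param f Allele fraction used by the mutant model; default is the
#'   fraction of `alt` observations in `obs`.
#' @return `tumor_lod()`: a list with `allele`, `f_hat`, `lod`, `keep`.
#' @rdname allele_likelihood
#' @export
tumor_lod <- function(obs, ref, alt, config = caller_config(), f = NULL) {
  config <- as_config(config)
  if (ref == alt) stop("alt equals ref")
  if (nrow(obs) == 0L) stop("empty site")
  if (is.null(f)) f <- mean(obs$allele == alt)
  lod <- lod_from_indicators(obs$allele == alt, obs$allele == ref,
                             obs$qual, f)
  list(allele = alt, f_hat = f, lod = lod,
       keep = lod >= config$lod_threshold)
}

#' Merge adjacent same-read SNVs into substitution (MNV) records
#'
#' Two mutated loci at adjacent positions whose supporting reads co-occur
#' are one substitution event on one DNA molecule and are reported as a
#' single record (e.g. `CA>AG`), not two SNVs.  Runs merge transitively at
#' distance 1; co-occurrence requires that at least `mnv_cooccurrence`
#' (90%) of the lower-support member's reads also support the neighbour.
#' In paired mode the caller classifies each SNV against the normal first,
#' so a neighbour that is not somatic is never absorbed.
#'
#' @param candidates `data.table` of SNV candidates with columns `contig`,
#'   `pos` (0-based), `ref`, `alt` and a list-column `support_reads` of
#'   supporting read ids.
#' @param config A [caller_config()].
#' @return The candidates with merged runs replaced by MNV rows (`vtype`
#'   `"MNV"`); merged rows carry the intersected read set.
#' @export
merge_adjacent_snvs <- function(candidates, config = caller_config()) {
  config <- as_config(config)
  cand <- as.data.table(candidates)
  if (nrow(cand) <= 1L) return(cand)
  setorder(cand, contig, pos, alt)
  cooccur <- function(a, b) {
    lo <- min(length(a), length(b))
    if (lo == 0L) return(FALSE)
    length(intersect(a, b)) >= config$mnv_cooccurrence * lo
  }
  n <- nrow(cand)
  comp <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    same <- cand$contig[i + 1L] == cand$contig[i] &&
      cand$pos[i + 1L] == cand$pos[i] + nchar(cand$ref[i])
    if (same && cooccur(cand$support_reads[[i]],
                        cand$support_reads[[i + 1L]]))
      comp[i + 1L] <- comp[i]
  }
  merged <- lapply(split(seq_len(n), comp), function(idx) {
    if (length(idx) == 1L) return(cand[idx])
    run <- cand[idx]
    out <- run[1L]
    out[, `:=`(
      ref = paste(run$ref, collapse = ""),
      alt = paste(run$alt, collapse = ""),
      vtype = "MNV",
      support_reads = list(Reduce(intersect, run$support_reads))
    )]
    ## conservative scalar stats: weakest member of the run
    for (col in intersect(c("lod_tumor", "vaf_tumor", "tumor_support",
                            "site_bq"), names(run)))
      set(out, j = col, value = min(unlist(run[[col]])))
    out
  })
  res <- rbindlist(merged, fill = TRUE)
  setorder(res, contig, pos, alt)
  res[]
}
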