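#' Match calls against a truth set
#'
#' Both sides are normalized ([normalize_variant()]) and compared on exact
#' `(contig, pos, ref, alt)` identity: true positives are calls present in
#' the truth set, false positives are calls absent from it, false
#' negatives are truth variants not called.
#'
#' @param calls Call table (`contig`, `pos` 0-based, `ref`, `alt`).
#' @param truth Truth table (`contig`, `pos` 1-based as written by
#'   [simulate_reads()], `ref`, `alt`); set `truth_one_based = FALSE` if
#'   already 0-based.
#' @param ref Reference (as in [call_from_reads()]) used to normalize both
#'   sides.
#' @param truth_one_based Is `truth$pos` 1-based? (default `TRUE`).
#' @return List: `tp`, `fp`, `fn`, plus `matched`, `missed`, `spurious`
#'   key tables.
#' @export
match_variants <- function(calls, truth, ref, truth_one_based = TRUE) {
  calls <- as.data.table(calls)
  truth <- as.data.table(truth)
  contigs <- unique(c(calls$contig, truth$contig))
  ref_funs <- as_ref_funs(ref, contigs)
  truth <- copy(truth)
  if (truth_one_based && nrow(truth)) truth[, pos := pos - 1L]
  truth[, ref := toupper(gsub("^-$", "", ref))]
  truth[, alt := toupper(gsub("^-$", "", alt))]
  ## pure insertions in simulator convention insert after `pos`
  if (nrow(truth)) truth[nchar(ref) == 0L, pos := pos + 1L]
  norm_keys <- function(dt) {
    if (nrow(dt) == 0L) return(character(0))
    vapply(seq_len(nrow(dt)), function(i) {
      nv <- normalize_variant(dt$pos[i], dt$ref[i], dt$alt[i],
                              ref_funs[[dt$contig[i]]], check = FALSE)
      paste(dt$contig[i], nv$pos, nv$ref, nv$alt, sep = ":")
    }, character(1))
  }
  ck <- norm_keys(calls)
  tk <- norm_keys(truth)
  list(tp = sum(ck %in% tk), fp = sum(!ck %in% tk),
       fn = sum(!tk %in% ck),
       matched = intersect(ck, tk), missed = setdiff(tk, ck),
       spurious = setdiff(ck, tk))
}

#' Precision, sensitivity and both F1 conventions
#'
#' Sensitivity is the fraction of truth variants detected; precision is
#' the fraction of detected variants that are true.  Two F1 summaries are
#' reported and always labelled: the harmonic mean `2PS/(P+S)` and the
#' plain product `P*S` — both conventions appear in the benchmarking
#' literature, so neither is silently chosen.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return List: `tp`, `fp`, `fn`, `precision`, `sensitivity` (fractions,
#'   `NA` when undefined), `f1_harmonic`, `f1_product`.
#' @examples
#' eval_metrics(tp = 684, fp = 2, fn = 39)
#' @export
eval_metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1h <- if (!is.na(precision) && !is.na(sensitivity) &&
             precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = precision,
       sensitivity = sensitivity, f1_harmonic = f1h,
       f1_product = precision * sensitivity)
}

#' The 2017 external-quality-assessment standard variant list
#'
#' The 94-variant standard list distributed for the 2017 tumor-somatic-
#' mutation external quality assessment, shipped as a plain TSV.  Genomic
#' coordinates are retained as labels only; the package exercises these
#' variants on synthetic contigs ([simulate_reads()] plants each variant's
#' reference allele in random sequence), so no reference genome is
#' required.
#'
#' @return `data.table`: `chrom`, `pos` (1-based; for insertions the base
#'   after which the sequence is inserted), `ref`, `alt` (`""` for pure
#'   insertions/deletions), `gene`, `vtype`, `vaf` (percent).
#' @export
eqa_2017_variants <- function() {
  path <- system.file("extdata", "eqa2017_standard_variants.tsv",
                      package = "tumorvar")
  dt <- fread(path, colClasses = list(character = c("ref", "alt")))
  dt[, ref := gsub("^-$", "", ref)]
  dt[, alt := gsub("^-$", "", alt)]
  dt[]
}

#' Recover the standard variant panel from synthetic reads
#'
#' The single-sample evaluation harness: every variant of
#' [eqa_2017_variants()] is planted on its own synthetic contig at a fixed
#' offset, tumor reads are simulated at its printed frequency, tumor-only
#' calling runs with default thresholds, and the variant counts as
#' recovered when its normalized `(position, ref, alt)` appears among the
#' calls.
#'
#' @param seed Base seed; each variant's simulation derives its own seed
#'   from it.
#' @param depth Mean per-base coverage (default 2000).
#' @param contig_length Synthetic contig length (default 500).
#' @param offset 1-based position at which each variant is planted
#'   (default 250).
#' @param read_length,base_quality Passed to [sim_spec()].
#' @param config A [caller_config()] (defaults).
#' @param variants Variant table (default the standard panel).
#' @return List: `recovered`, `total`, `per_variant` (`data.table` with a
#'   logical `recovered` column).
#' @export
standard_panel_recovery <- function(seed, depth = 2000L,
                                    contig_length = 500L, offset = 250L,
                                    read_length = 100L,
                                    base_quality = 30L,
                                    config = caller_config(),
                                    variants = eqa_2017_variants()) {
  variants <- as.data.table(variants)
  got <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    row <- variants[i]
    ctg <- sprintf("v%03d", i)
    v <- data.table(contig = ctg, pos = offset, ref = row$ref,
                    alt = row$alt, vtype = row$vtype,
                    target_vaf = row$vaf)
    sp <- sim_spec(v, contig_length = contig_length, depth = depth,
                   read_length = read_length,
                   base_quality = base_quality,
                   seed = as.integer((as.numeric(seed) * 131 + i) %%
                                       2147483647))
    sim <- simulate_reads(sp)
    regs <- regions(ctg, max(0L, offset - 100L),
                    min(contig_length, offset + nchar(row$ref) + 100L))
    calls <- call_from_reads(sim$reads, NULL, sim$ref, regs, config)
    got[i] <- match_variants(calls, sim$truth, sim$ref)$tp >= 1L
  }
  list(recovered = sum(got), total = nrow(variants),
       per_variant = cbind(variants, recovered = got))
}

#' Smallest same-read gap separation reported as two variants
#'
#' Sweeps the reference distance between two single-base deletions carried
#' on one read and reports the smallest separation at which the same-read
#' merger returns them as two distinct events instead of one combined
#' variant — a functional read-out of the gap-gap merge bound.
#'
#' @param config A [caller_config()].
#' @param max_sep Largest separation swept (default 15).
#' @return List: `boundary` (smallest separating distance) and `n_merged`
#'   per separation.
#' @export
gap_separation_boundary <- function(config = caller_config(),
                                    max_sep = 15L) {
  refseq <- paste(rep("ACGT", 40L), collapse = "")
  ref_fun <- ref_accessor(refseq)
  n_events <- integer(max_sep)
  for (d in seq_len(max_sep)) {
    cigar <- sprintf("20M1D%dM1D20M", d)
    seq <- paste(rep("A", 40L + d), collapse = "")
    rd <- read_records("r1", "c", 10L, cigar, seq, 30L)
    ev <- extract_indel_events(rd, config)
    merged <- merge_same_read_events(ev, data.frame(pos = integer(),
                                                    alt = character()),
                                     rd, ref_fun, config)
    n_events[d] <- nrow(merged)
  }
  list(boundary = which(n_events == 2L)[1], n_merged = n_events)
}
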