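#' Caller configuration
#'
#' Bundles every tunable threshold of the caller into one list.  Defaults
#' reflect the method's published operating point where a value is printed
#' (LOD emission threshold 3.9, normal/tumor frequency ratio 0.2,
#' normal-LOD gate ratio 0.5, same-read merge windows of 5 and 10 bases,
#' duplicate-group support fraction 0.8, hypermutated-read cutoff of 3
#' mismatches) and standard practice elsewhere (mapping quality 20, base
#' quality 13, evidence floors of 2 supporting reads / depth 8 / VAF 1%).
#'
#' @param min_base_quality Minimum Phred base quality for a pileup
#'   observation to count (default 13).
#' @param min_mapping_quality Reads below this MAPQ are discarded as
#'   multiply mapped (default 20).
#' @param min_support_reads Minimum duplicate-collapsed supporting reads
#'   for a call (default 2).
#' @param min_depth Minimum duplicate-collapsed depth at the site
#'   (default 8).
#' @param min_vaf Minimum variant allele frequency, in percent (default 1).
#' @param lod_threshold Tumor LOD emission threshold (default 3.9).
#' @param fet_p_threshold Fisher's exact test p-value cutoff for paired
#'   calling (default 0.05).
#' @param nf Maximum normal-sample VAF, in percent, below which the
#'   normal-frequency gate passes unconditionally (default 2).
#' @param normal_ratio The normal-frequency gate also passes when the
#'   normal VAF is below this multiple of the tumor VAF (default 0.2).
#' @param normal_lod_gate_ratio When the normal VAF is below this multiple
#'   of the tumor VAF, the normal-sample LOD decides before Fisher's test
#'   (default 0.5).
#' @param snv_gap_merge_distance An SNV within this many reference bases of
#'   a same-read gap/insertion is absorbed into a complex variant,
#'   inclusive (default 5).
#' @param gap_gap_merge_distance Two same-read gaps/insertions closer than
#'   this (strictly) are combined into one variant (default 10).
#' @param max_mismatches_per_read Reads carrying at least this many
#'   mismatches are dropped from SNV evidence (default 3).
#' @param dup_support_fraction A duplicate group supports the variant when
#'   the fraction of its mutated members is strictly greater than this
#'   (default 0.8).
#' @param germline_popaf_threshold Population allele frequency, in percent,
#'   at or above which a variant is labelled germline (default 1).
#' @param mnv_cooccurrence Fraction of the lower-support member's reads
#'   that must also carry the neighbouring SNV for the pair to merge into a
#'   substitution record (default 0.9).
#' @param max_indel_events_per_read Reads with more gap/insertion events
#'   than this are excluded from indel evidence (default 2).
#' @param fet_mode `"one_sided"` (tail toward tumor enrichment, default) or
#'   `"point"` (the bare hypergeometric point probability).
#' @param drop_flag_duplicates Drop reads whose duplicate flag is set at
#'   the read-filter stage instead of collapsing them later (default
#'   `FALSE`).
#' @param count_overlapping_mates Count both mates of a pair when they
#'   overlap the same site (default `TRUE`; mates have distinct alignment
#'   signatures, so both are kept).
#' @param strand_filter Require supporting reads on both strands when both
#'   strands cover the site (default `FALSE`).
#' @param end_distance_filter Optional minimum distance of the variant base
#'   from either read end; `0` disables (default 0).
#' @param emit_all Keep filtered records (with filter labels) in the output
#'   instead of PASS-only (default `FALSE`).
#' @param threads Number of region chunks processed per run; output is
#'   invariant to this value (default 1).
#' @param seed Seed recorded in the run manifest (default 1).
#'
#' @return A named list of class `caller_config`.
#' @examples
#' cfg <- caller_config(min_vaf = 5)
#' cfg$lod_threshold
#' @export
caller_config <- function(min_base_quality = 13L,
                          min_mapping_quality = 20L,
                          min_support_reads = 2L,
                          min_depth = 8L,
                          min_vaf = 1,
                          lod_threshold = 3.9,
                          fet_p_threshold = 0.05,
                          nf = 2,
                          normal_ratio = 0.2,
                          normal_lod_gate_ratio = 0.5,
                          snv_gap_merge_distance = 5L,
                          gap_gap_merge_distance = 10L,
                          max_mismatches_per_read = 3L,
                          dup_support_fraction = 0.8,
                          germline_popaf_threshold = 1,
                          mnv_cooccurrence = 0.9,
                          max_indel_events_per_read = 2L,
                          fet_mode = c("one_sided", "point"),
                          drop_flag_duplicates = FALSE,
                          count_overlapping_mates = TRUE,
                          strand_filter = FALSE,
                          end_distance_filter = 0L,
                          emit_all = FALSE,
                          threads = 1L,
                          seed = 1L) {
  fet_mode <- match.arg(fet_mode)
  cfg <- list(
    min_base_quality = as.integer(min_base_quality),
    min_mapping_quality = as.integer(min_mapping_quality),
    min_support_reads = as.integer(min_support_reads),
    min_depth = as.integer(min_depth),
    min_vaf = as.numeric(min_vaf),
    lod_threshold = as.numeric(lod_threshold),
    fet_p_threshold = as.numeric(fet_p_threshold),
    nf = as.numeric(nf),
    normal_ratio = as.numeric(normal_ratio),
    normal_lod_gate_ratio = as.numeric(normal_lod_gate_ratio),
    snv_gap_merge_distance = as.integer(snv_gap_merge_distance),
    gap_gap_merge_distance = as.integer(gap_gap_merge_distance),
    max_mismatches_per_read = as.integer(max_mismatches_per_read),
    dup_support_fraction = as.numeric(dup_support_fraction),
    germline_popaf_threshold = as.numeric(germline_popaf_threshold),
    mnv_cooccurrence = as.numeric(mnv_cooccurrence),
    max_indel_events_per_read = as.integer(max_indel_events_per_read),
    fet_mode = fet_mode,
    drop_flag_duplicates = isTRUE(drop_flag_duplicates),
    count_overlapping_mates = isTRUE(count_overlapping_mates),
    strand_filter = isTRUE(strand_filter),
    end_distance_filter = as.integer(end_distance_filter),
    emit_all = isTRUE(emit_all),
    threads = as.integer(threads),
    seed = as.integer(seed)
  )
  stopifnot(
    all(vapply(cfg[!(names(cfg) %in% "fet_mode")], function(x)
      all(is.finite(as.numeric(x)) | is.logical(x)), logical(1))),
    cfg$lod_threshold > 0,
    cfg$threads >= 1L
  )
  class(cfg) <- "caller_config"
  cfg
}

#' @export
print.caller_config <- function(x, ...) {
  cat("caller_config:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_config <- function(config) {
  if (is.null(config)) return(caller_config())
  stopifnot(inherits(config, "caller_config"))
  config
}
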