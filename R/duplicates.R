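#' PCR-duplicate grouping and duplicate-collapsed quantification
#'
#' Reads sharing an alignment signature — contig, start, CIGAR reference
#' end, strand, and mate start when paired — are presumed PCR copies of a
#' single molecule and are counted once.  A duplicate group supports a
#' variant when the fraction of its mutated members is strictly greater
#' than `dup_support_fraction` (0.8); the variant allele frequency is then
#' the percentage of supporting groups among eligible groups.
#'
#' @param reads Read table.
#' @return `group_duplicates()`: the reads with a `dup_grp` integer column;
#'   group metadata is in attribute `"groups"` (`dup_grp`, `contig`,
#'   `start`, `end`, `strand`, `mpos`, `size`).
#' @examples
#' r <- read_records(c("a", "b", "c"), "chr1", c(10, 10, 12), "4M",
#'                   c("ACGT", "ACGT", "GTAC"), 30)
#' attr(group_duplicates(r), "groups")
#' @export
group_duplicates <- function(reads) {
  reads <- as.data.table(reads)
  reads[, dup_grp := .GRP, by = .(contig, pos, end, strand, mpos)]
  groups <- reads[, .(contig = contig[1], start = pos[1], end = end[1],
                      strand = strand[1], mpos = mpos[1], size = .N),
                  by = dup_grp]
  setattr(reads, "groups", groups)
  reads[]
}

#' @param group_fracs Per-group fractions of mutated members.
#' @param config A [caller_config()].
#' @rdname group_duplicates
#' @export
supporting_group_count <- function(group_fracs, config = caller_config()) {
  config <- as_config(config)
  sum(group_fracs > config$dup_support_fraction)
}

#' @param supporting Number of supporting duplicate groups.
#' @param eligible Number of eligible duplicate groups (for indels, only
#'   groups whose reads span every indel site).
#' @return `compute_vaf()`: VAF in percent.
#' @rdname group_duplicates
#' @export
compute_vaf <- function(supporting, eligible) {
  if (eligible <= 0L) stop("VAF undefined: no eligible duplicate groups")
  100 * supporting / eligible
}

#' @param quals Base qualities of the variant-supporting observations.
#' @return `site_base_quality()`: the maximum supporting base quality.
#' @rdname group_duplicates
#' @export
site_base_quality <- function(quals) {
  if (length(quals) == 0L) stop("no supporting observation at site")
  max(quals)
}

## Collapse per-site base observations to one representative per duplicate
## group: majority allele (ties broken lexicographically), maximum quality
## among observations of that allele.  Input obs must carry grp.
collapse_site_obs <- function(obs) {
  cnt <- obs[, .(n_allele = .N, rep_qual = max(qual)),
             by = .(pos, grp, allele, strand)]
  setorder(cnt, pos, grp, -n_allele, allele)
  rep <- cnt[, .SD[1L], by = .(pos, grp)]
  tot <- obs[, .(n_tot = .N), by = .(pos, grp)]
  rep[tot, on = .(pos, grp), n_tot := i.n_tot][]
}
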