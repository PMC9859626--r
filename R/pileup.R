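## Pileup construction: expand reads into per-site observations keyed by
## read id.  Per-read identity is what enables same-read phasing of
## adjacent events (substitution/complex merging), so the expansion is done
## here rather than through a summarising pileup engine.

decode_quals <- function(qual, width) {
  ## all strings must share `width`
  as.integer(charToRaw(paste(qual, collapse = ""))) - 33L
}

#' Build a per-site pileup
#'
#' Expands reads into one observation per aligned base: reference position
#' (0-based), read id, allele (`A/C/G/T`, `-` for a deletion anchored at
#' its first deleted base, or `+SEQ` for an insertion anchored at the
#' preceding aligned base), Phred quality (flanking-base quality for
#' indel tokens), strand and offset in read.  Observations below
#' `min_base_quality` and outside `region` are dropped.
#'
#' @param reads Read table (already past [passes_read_filters()]).
#' @param region Single region (`contig`, `start`, `end`, 0-based
#'   half-open) as a one-row data.frame/list.
#' @param config A [caller_config()].
#' @return `data.table` with columns `pos`, `qname`, `allele`, `qual`,
#'   `strand`, `offset`.
#' @export
build_pileup <- function(reads, region, config = caller_config()) {
  config <- as_config(config)
  reads <- as.data.table(reads)
  validate_reads(reads)
  reads <- reads[contig == region$contig & pos < region$end &
                 end > region$start]
  if (nrow(reads) == 0L) {
    return(data.table(pos = integer(), qname = character(),
                      allele = character(), qual = integer(),
                      strand = character(), offset = integer()))
  }
  out <- vector("list", 0L)
  for (cg in unique(reads$cigar)) {
    g <- reads[cigar == cg]
    lay <- cigar_layout(cg)
    L <- lay$query_len
    ngr <- nrow(g)
    bases <- matrix(strsplit(paste(g$seq, collapse = ""), "")[[1]],
                    nrow = L)
    quals <- matrix(decode_quals(g$qual, L), nrow = L)
    if (length(lay$m_q)) {
      m <- length(lay$m_q)
      out[[length(out) + 1L]] <- data.table(
        pos = rep(g$pos, each = m) + lay$m_r,
        qname = rep(g$qname, each = m),
        allele = as.vector(bases[lay$m_q + 1L, , drop = FALSE]),
        qual = as.vector(quals[lay$m_q + 1L, , drop = FALSE]),
        strand = rep(g$strand, each = m),
        offset = rep(lay$m_q, ngr)
      )
    }
    if (length(lay$d_r)) {
      d <- length(lay$d_r)
      out[[length(out) + 1L]] <- data.table(
        pos = rep(g$pos, each = d) + lay$d_r,
        qname = rep(g$qname, each = d),
        allele = rep("-", d * ngr),
        qual = as.vector(quals[lay$d_q + 1L, , drop = FALSE]),
        strand = rep(g$strand, each = d),
        offset = rep(lay$d_q, ngr)
      )
    }
    if (length(lay$i_q)) {
      for (k in seq_along(lay$i_q)) {
        qs <- lay$i_q[k]; ln <- lay$i_len[k]
        out[[length(out) + 1L]] <- data.table(
          pos = g$pos + lay$i_r[k] - 1L,
          qname = g$qname,
          allele = paste0("+", substr(g$seq, qs + 1L, qs + ln)),
          qual = quals[qs + 1L, ],
          strand = g$strand,
          offset = rep(qs, ngr)
        )
      }
    }
  }
  obs <- rbindlist(out)
  obs <- obs[pos >= region$start & pos < region$end &
             qual >= config$min_base_quality]
  if (config$end_distance_filter > 0L) {
    ## optional end-of-read distance cut (off by default)
    qlen <- setNames(cigar_query_length(reads$cigar), reads$qname)
    obs <- obs[offset >= config$end_distance_filter &
               (qlen[qname] - 1L - offset) >= config$end_distance_filter]
  }
  setkey(obs, pos)
  obs[]
}

## Count mismatched aligned bases per read against the reference (base
## observations only, at or above min_base_quality).
read_mismatch_counts <- function(obs, ref_fun) {
  base_obs <- obs[allele %chin% c("A", "C", "G", "T")]
  if (nrow(base_obs) == 0L)
    return(data.table(qname = character(), mismatches = integer()))
  pos_range <- range(base_obs$pos)
  refseq <- strsplit(ref_fun(pos_range[1], pos_range[2] + 1L), "")[[1]]
  base_obs[, is_ref := allele == refseq[pos - pos_range[1] + 1L]]
  base_obs[, .(mismatches = sum(!is_ref)), by = qname]
}

#' Remove hypermutated reads from SNV evidence
#'
#' Reads carrying `max_mismatches_per_read` (default 3) or more mismatched
#' aligned bases — mostly alignment artifacts — are excluded from SNV
#' evidence.  Indel evidence is unaffected (complex variants legitimately
#' place several mismatches on one read next to a gap).
#'
#' @param reads Read table.
#' @param ref_fun Reference accessor ([ref_accessor()]).
#' @param config A [caller_config()].
#' @param obs Optional pre-built pileup over the reads' span (otherwise
#'   built internally over the reads' footprint).
#' @return The reads with hypermutated rows removed.
#' @export
discard_hypermutated_reads <- function(reads, ref_fun,
                                       config = caller_config(),
                                       obs = NULL) {
  config <- as_config(config)
  reads <- as.data.table(reads)
  if (nrow(reads) == 0L) return(reads)
  if (is.null(obs)) {
    region <- list(contig = reads$contig[1], start = min(reads$pos),
                   end = max(reads$end))
    obs <- build_pileup(reads, region, config)
  }
  mm <- read_mismatch_counts(obs, ref_fun)
  bad <- mm[mm$mismatches >= config$max_mismatches_per_read, qname]
  reads[!qname %chin% bad]
}
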