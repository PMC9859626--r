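#' Extract insertion/deletion events from read CIGARs
#'
#' One event per I/D CIGAR operation, with its reference anchor (first
#' deleted base for deletions; insertion point — the reference offset of
#' the next aligned base — for insertions).  Reads with more than
#' `max_indel_events_per_read` (2) gap/insertion events are excluded from
#' indel evidence.
#'
#' @param reads Read table.
#' @param config A [caller_config()].
#' @return `data.table` with columns `qname`, `contig`, `kind`
#'   (`"del"`/`"ins"`), `pos` (0-based anchor), `len`, `seq` (inserted
#'   bases, `""` for deletions), `qoff` (query offset of the event's first
#'   altered/flanking base).  Attribute `"dropped"` lists read names
#'   excluded for carrying too many events.
#' @export
extract_indel_events <- function(reads, config = caller_config()) {
  config <- as_config(config)
  reads <- as.data.table(reads)
  out <- vector("list", 0L)
  if (nrow(reads)) {
    for (cg in unique(reads$cigar)) {
      g <- reads[cigar == cg]
      lay <- cigar_layout(cg)
      nev <- length(lay$d_r) + length(lay$i_q)
      if (nev == 0L) next
      ev <- list()
      for (k in seq_along(lay$d_r)) {
        ev[[length(ev) + 1L]] <- data.table(
          qname = g$qname, contig = g$contig, kind = "del",
          pos = g$pos + lay$d_r[k], len = lay$d_len[k], seq = "",
          qoff = lay$d_q[k])
      }
      for (k in seq_along(lay$i_q)) {
        qs <- lay$i_q[k]; ln <- lay$i_len[k]
        ev[[length(ev) + 1L]] <- data.table(
          qname = g$qname, contig = g$contig, kind = "ins",
          pos = g$pos + lay$i_r[k], len = ln,
          seq = substr(g$seq, qs + 1L, qs + ln), qoff = qs)
      }
      out[[length(out) + 1L]] <- rbindlist(ev)
    }
  }
  events <- if (length(out)) rbindlist(out) else
    data.table(qname = character(), contig = character(),
               kind = character(), pos = integer(), len = integer(),
               seq = character(), qoff = integer())
  nev <- events[, .N, by = qname]
  dropped <- nev[nev$N > config$max_indel_events_per_read, qname]
  events <- events[!qname %chin% dropped]
  setorder(events, qname, pos)
  setattr(events, "dropped", dropped)
  events[]
}

## span of an event on the reference: [start, end), zero-width for ins
event_span <- function(kind, pos, len) {
  list(start = pos, end = ifelse(kind == "del", pos + len, pos))
}

#' Merge same-read events into indel and complex alleles
#'
#' Events observed on one read are combined exactly as the detection rules
#' require: two gaps/insertions whose reference distance is strictly less
#' than `gap_gap_merge_distance` (10) become one variant, and an SNV
#' within `snv_gap_merge_distance` (5) bases (inclusive) of a gap or
#' insertion is absorbed into a complex variant.  Events on different
#' reads are never merged.  The merged allele's reference sequence is read
#' off the reference over the merged span and the alternate off the read.
#'
#' @param events Events for one read ([extract_indel_events()] rows).
#' @param snvs Data frame of the same read's mismatches: columns `pos`
#'   (0-based), `alt`; may be empty.
#' @param read One-row read table for the read (used to reconstruct the
#'   alternate allele across the span).
#' @param ref_fun Reference accessor.
#' @param config A [caller_config()].
#' @return `data.table` of merged alleles: `contig`, `pos`, `ref`, `alt`,
#'   `vtype`, `span_start`, `span_end`, `site_qual` (un-normalized
#'   representation; see [normalize_variant()]).
#' @export
merge_same_read_events <- function(events, snvs, read, ref_fun,
                                   config = caller_config()) {
  config <- as_config(config)
  events <- as.data.table(events)
  if (nrow(events) == 0L)
    return(data.table(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      vtype = character(), span_start = integer(),
                      span_end = integer(), site_qual = integer()))
  setorder(events, pos)
  sp <- event_span(events$kind, events$pos, events$len)
  ## cluster gaps/inss: inner-edge distance < gap_gap_merge_distance
  cl <- integer(nrow(events)); cl[1] <- 1L
  if (nrow(events) > 1L) {
    for (i in 2L:nrow(events)) {
      d <- sp$start[i] - max(sp$end[seq_len(i - 1L)][cl == cl[i - 1L]])
      cl[i] <- if (d < config$gap_gap_merge_distance) cl[i - 1L] else
        cl[i - 1L] + 1L
    }
  }
  snvs <- as.data.table(snvs)
  lay <- cigar_layout(read$cigar)
  quals <- decode_quals(read$qual, lay$query_len)
  out <- vector("list", 0L)
  for (c_id in unique(cl)) {
    idx <- which(cl == c_id)
    ## absorb SNVs within the merge window of any member event (distance
    ## measured to event edges, inclusive)
    absorbed <- integer(0)
    if (nrow(snvs)) {
      dmin <- vapply(snvs$pos, function(p) {
        min(vapply(idx, function(i) {
          if (p < sp$start[i]) as.numeric(sp$start[i] - p)
          else if (p >= sp$end[i]) as.numeric(p - (sp$end[i] - 1L))
          else 0
        }, numeric(1)))
      }, numeric(1))
      absorbed <- which(dmin <= config$snv_gap_merge_distance)
    }
    s <- min(sp$start[idx], if (length(absorbed)) snvs$pos[absorbed] else Inf)
    e <- max(sp$end[idx], if (length(absorbed)) snvs$pos[absorbed] + 1L else -Inf)
    s <- as.integer(s); e <- as.integer(e)
    pure_ins <- length(idx) == 1L && length(absorbed) == 0L &&
      events$kind[idx] == "ins"
    pure_del <- length(idx) == 1L && length(absorbed) == 0L &&
      events$kind[idx] == "del"
    if (pure_ins) {
      ref_a <- ""
      alt_a <- events$seq[idx]
      vtype <- "insertion"
      sq <- quals[events$qoff[idx] + 1L]
    } else {
      ref_a <- ref_fun(s, e)
      ## query indices consumed within [s, e): aligned bases plus
      ## insertions anchored inside the span
      r0 <- read$pos
      qidx <- lay$m_q[lay$m_r + r0 >= s & lay$m_r + r0 < e]
      for (k in seq_along(lay$i_q)) {
        ip <- lay$i_r[k] + r0
        if (ip > s && ip <= e)
          qidx <- c(qidx, lay$i_q[k] + seq_len(lay$i_len[k]) - 1L)
      }
      if (length(qidx) == 0L) {
        alt_a <- ""
        vtype <- "deletion"
        sq <- quals[events$qoff[idx[1]] + 1L]
      } else {
        qidx <- sort(qidx)
        alt_a <- substr(read$seq, min(qidx) + 1L, max(qidx) + 1L)
        vtype <- if (length(idx) > 1L || length(absorbed)) "complex"
          else if (events$kind[idx] == "ins") "insertion" else "deletion"
        sq <- max(quals[pmin(qidx, lay$query_len - 1L) + 1L])
      }
    }
    out[[length(out) + 1L]] <- data.table(
      contig = read$contig, pos = s, ref = ref_a, alt = alt_a,
      vtype = vtype, span_start = s, span_end = e,
      site_qual = as.integer(sq))
  }
  rbindlist(out)
}
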