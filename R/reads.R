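#' Aligned read records
#'
#' Reads are carried through the caller as a `data.table` with one row per
#' alignment record: `qname`, `flag`, `contig`, `pos` (0-based leftmost
#' reference position), `mapq`, `cigar`, `seq`, `qual` (ASCII Phred+33),
#' `strand`, `mpos` (0-based mate position or `NA`), and the derived `end`
#' (0-based exclusive reference end).  `read_records()` builds such a table
#' directly — convenient for tests and small examples; `read_alignments()`
#' fetches one from an indexed BAM.
#'
#' @param qname Read names.
#' @param contig Contig names.
#' @param pos 0-based leftmost aligned positions.
#' @param cigar CIGAR strings.
#' @param seq Read sequences.
#' @param qual Per-base qualities: ASCII strings, a single integer applied
#'   to every base, or a list of integer vectors.
#' @param mapq Mapping qualities (default 60).
#' @param strand `"+"` or `"-"` (default `"+"`).
#' @param flag SAM flags (default: 0 for `+`, 16 for `-` reads).
#' @param mpos 0-based mate positions or `NA`.
#' @return A `data.table` of read records.
#' @examples
#' read_records("r1", "chr1", 100, "4M", "ACGT", 30)
#' @export
read_records <- function(qname, contig, pos, cigar, seq, qual = 30L,
                         mapq = 60L, strand = "+", flag = NULL,
                         mpos = NA_integer_) {
  n <- length(qname)
  seq <- rep_len(toupper(seq), n)
  pos <- rep_len(pos, n)
  cigar <- rep_len(cigar, n)
  mapq <- rep_len(mapq, n)
  if (is.numeric(qual)) {
    qual <- rep_len(as.integer(qual), n)
    qual <- vapply(seq_len(n), function(i)
      intToUtf8(rep(qual[i] + 33L, nchar(seq[i]))), character(1))
  } else if (is.list(qual)) {
    qual <- vapply(qual, function(q) intToUtf8(q + 33L), character(1))
  }
  strand <- rep_len(strand, n)
  if (is.null(flag)) flag <- ifelse(strand == "-", 16L, 0L)
  dt <- data.table(
    qname = as.character(qname),
    flag = as.integer(rep_len(flag, n)),
    contig = as.character(rep_len(contig, n)),
    pos = as.integer(pos),
    mapq = as.integer(mapq),
    cigar = as.character(cigar),
    seq = seq,
    qual = as.character(rep_len(qual, n)),
    strand = strand,
    mpos = as.integer(rep_len(mpos, n))
  )
  validate_reads(dt)
  dt[, end := pos + cigar_ref_length(cigar)]
  dt[]
}

validate_reads <- function(dt) {
  ql <- cigar_query_length(dt$cigar)
  bad <- which(nchar(dt$seq) != ql | nchar(dt$seq) != nchar(dt$qual))
  if (length(bad)) stop("malformed read '", dt$qname[bad[1]],
                        "': CIGAR/sequence/quality length mismatch")
  invisible(dt)
}

## ---- CIGAR utilities ------------------------------------------------------

parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1L) stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("malformed CIGAR: ", cigar)
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

cigar_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% c("M", "=", "X", "D", "N")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% c("M", "=", "X", "I", "S")])
  }, integer(1), USE.NAMES = FALSE)
}

## Per-base layout of one CIGAR: query/reference offsets of aligned bases,
## deletion anchors, and insertion anchors.  Cached per unique CIGAR string
## by the callers (reads are grouped by CIGAR before expansion).
cigar_layout <- function(cigar) {
  p <- parse_cigar(cigar)
  qoff <- 0L; roff <- 0L
  m_q <- integer(0); m_r <- integer(0)
  d_r <- integer(0); d_len <- integer(0); d_q <- integer(0)
  i_q <- integer(0); i_len <- integer(0); i_r <- integer(0)
  for (k in seq_along(p$op)) {
    op <- p$op[k]; len <- p$len[k]
    if (op %in% c("M", "=", "X")) {
      m_q <- c(m_q, qoff + seq_len(len) - 1L)
      m_r <- c(m_r, roff + seq_len(len) - 1L)
      qoff <- qoff + len; roff <- roff + len
    } else if (op == "I") {
      i_q <- c(i_q, qoff); i_len <- c(i_len, len); i_r <- c(i_r, roff)
      qoff <- qoff + len
    } else if (op == "D") {
      d_r <- c(d_r, roff); d_len <- c(d_len, len)
      d_q <- c(d_q, max(qoff - 1L, 0L))
      roff <- roff + len
    } else if (op == "N") {
      roff <- roff + len
    } else if (op == "S") {
      qoff <- qoff + len
    } # H, P consume nothing
  }
  list(m_q = m_q, m_r = m_r,
       d_r = d_r, d_len = d_len, d_q = d_q,
       i_q = i_q, i_len = i_len, i_r = i_r,
       ref_len = roff, query_len = qoff)
}

## ---- BAM input ------------------------------------------------------------

#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param regs Region table ([load_regions()]); reads overlapping any
#'   region (with `pad` extra bases) are fetched.
#' @param pad Padding in bases around each region when fetching (so reads
#'   whose variant bases fall inside the region are not missed).
#' @rdname read_records
#' @export
read_alignments <- function(bam, regs, pad = 500L) {
  bf <- Rsamtools::BamFile(bam)
  regs <- as.data.table(regs)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    regs$contig, IRanges::IRanges(pmax(regs$start - pad, 0L) + 1L,
                                  regs$end + pad)))
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
            "mpos", "seq", "qual")
  res <- Rsamtools::scanBam(bf, param = Rsamtools::ScanBamParam(
    which = gr, what = what))
  dt <- rbindlist(lapply(res, function(r) data.table(
    qname = r$qname,
    flag = as.integer(r$flag),
    contig = as.character(r$rname),
    pos = as.integer(r$pos) - 1L,
    mapq = as.integer(r$mapq),
    cigar = r$cigar,
    seq = as.character(r$seq),
    qual = as.character(r$qual),
    strand = as.character(r$strand),
    mpos = as.integer(r$mpos) - 1L
  )))
  if (nrow(dt) == 0L) {
    dt <- data.table(qname = character(), flag = integer(),
                     contig = character(), pos = integer(),
                     mapq = integer(), cigar = character(),
                     seq = character(), qual = character(),
                     strand = character(), mpos = integer())
  }
  ## the same read can be returned once per overlapping query range
  dt <- unique(dt, by = c("qname", "flag", "contig", "pos", "cigar"))
  dt <- dt[!is.na(pos) & !is.na(cigar)]
  if (nrow(dt)) dt[, end := pos + cigar_ref_length(cigar)] else dt[, end := integer()]
  dt[]
}

## ---- Read-level filters ---------------------------------------------------

FLAG_PAIRED <- 1L; FLAG_UNMAPPED <- 4L; FLAG_REVERSE <- 16L
FLAG_SECONDARY <- 256L; FLAG_QCFAIL <- 512L; FLAG_DUP <- 1024L
FLAG_SUPPLEMENTARY <- 2048L

#' Read-level filtering
#'
#' Applies the read screens that precede variant detection: unmapped,
#' secondary/supplementary (multiply mapped), QC-fail and (optionally)
#' flag-marked duplicate reads are rejected, as are reads below the
#' minimum mapping quality or without overlap of any target region.  Base
#' quality is screened later, per pileup observation.
#'
#' @param reads A read table ([read_records()]/[read_alignments()]).
#' @param regs Region table; reads overlapping none of the regions fail.
#' @param config A [caller_config()].
#' @param keep Return only passing reads (default) or, when `FALSE`, the
#'   full table with `passed` and `reasons` columns.
#' @return Filtered read table, or annotated table when `keep = FALSE`.
#' @export
passes_read_filters <- function(reads, regs, config = caller_config(),
                                keep = TRUE) {
  config <- as_config(config)
  reads <- as.data.table(reads)
  regs <- as.data.table(regs)
  n <- nrow(reads)
  reasons <- vector("list", n)
  add <- function(which, label) {
    for (i in which) reasons[[i]] <<- c(reasons[[i]], label)
  }
  fl <- reads$flag
  add(which(bitwAnd(fl, FLAG_UNMAPPED) > 0L), "unmapped")
  add(which(bitwAnd(fl, FLAG_SECONDARY) > 0L |
            bitwAnd(fl, FLAG_SUPPLEMENTARY) > 0L),
      "secondary_or_supplementary")
  add(which(bitwAnd(fl, FLAG_QCFAIL) > 0L), "qcfail")
  if (config$drop_flag_duplicates)
    add(which(bitwAnd(fl, FLAG_DUP) > 0L), "flagged_duplicate")
  add(which(reads$mapq < config$min_mapping_quality), "low_mapq")
  ov <- rep(FALSE, n)
  for (i in seq_len(nrow(regs))) {
    ov <- ov | (reads$contig == regs$contig[i] &
                reads$pos < regs$end[i] & reads$end > regs$start[i])
  }
  add(which(!ov), "outside_interval")
  passed <- vapply(reasons, function(r) length(r) == 0L, logical(1))
  if (keep) return(reads[passed])
  out <- copy(reads)
  out[, `:=`(passed = passed, reasons = reasons)]
  out[]
}
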