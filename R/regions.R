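#' Target regions
#'
#' `load_regions()` reads a 3+ column BED file (0-based half-open) and
#' returns merged, sorted, non-overlapping regions.  `regions()` builds the
#' same structure from vectors, and `split_regions()` partitions the bases
#' of a region set into `n_chunks` disjoint chunks for parallel-style
#' processing (output of the caller is invariant to the chunking).
#'
#' @param bed_path Path to a BED file.
#' @return A `data.table` with columns `contig`, `start` (0-based,
#'   inclusive) and `end` (0-based, exclusive).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t10\t20", "chr1\t15\t30"), bed)
#' load_regions(bed)
#' @export
load_regions <- function(bed_path) {
  lines <- readLines(bed_path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("empty BED file: ", bed_path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", bed_path)
  contig <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | end <= start)
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", bed_path,
                        " (need 0 <= start < end)")
  regions(contig, start, end)
}

#' @param contig,start,end Region coordinates, 0-based half-open.
#' @rdname load_regions
#' @export
regions <- function(contig, start, end) {
  stopifnot(length(contig) == length(start), length(start) == length(end),
            all(start >= 0), all(end > start))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    contig, IRanges::IRanges(start + 1L, end)))
  gr <- GenomicRanges::sort(gr)
  data.table(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' @param regs A region table from [load_regions()] or [regions()].
#' @param n_chunks Number of chunks (>= 1).
#' @rdname load_regions
#' @export
split_regions <- function(regs, n_chunks) {
  n_chunks <- as.integer(n_chunks)
  if (is.na(n_chunks) || n_chunks < 1L) stop("n_chunks must be >= 1")
  regs <- as.data.table(regs)
  total <- sum(regs$end - regs$start)
  n_chunks <- min(n_chunks, total)
  per <- ceiling(total / n_chunks)
  chunks <- vector("list", n_chunks)
  ci <- 1L; used <- 0L; cur <- list()
  for (i in seq_len(nrow(regs))) {
    s <- regs$start[i]; e <- regs$end[i]
    while (s < e) {
      room <- per - used
      take <- min(room, e - s)
      cur[[length(cur) + 1L]] <- data.table(contig = regs$contig[i],
                                            start = s, end = s + take)
      s <- s + take; used <- used + take
      if (used >= per && ci < n_chunks) {
        chunks[[ci]] <- rbindlist(cur); cur <- list(); used <- 0L
        ci <- ci + 1L
      }
    }
  }
  chunks[[ci]] <- if (length(cur)) rbindlist(cur) else
    data.table(contig = character(), start = integer(), end = integer())
  chunks[lengths(chunks) > 0 & vapply(chunks, NROW, integer(1)) > 0]
}
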