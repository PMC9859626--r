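#' Specify a read simulation
#'
#' Describes a synthetic sequencing experiment: one or more contigs of
#' random sequence with planted variants, paired-end fragments drawn
#' uniformly, constant base quality with uniform sequencing error,
#' and PCR duplication of a fraction of fragments.  Reads are emitted as
#' alignment records with exact CIGARs (insertions, deletions and complex
#' alleles produce I/D operations; reads that only partially cover an
#' event are soft-clipped at its edge, as an aligner would tend to do), so
#' no aligner is needed and the true placement is known.
#'
#' @param variants `data.frame` with columns `contig`, `pos` (1-based
#'   position of the first reference-allele base; for pure insertions the
#'   base after which the sequence is inserted), `ref`, `alt` (either may
#'   be `""`/`"-"`), `vtype`, `target_vaf` (percent).  The `ref` allele is
#'   planted into the random contig at `pos`.
#' @param contig_length Length of every contig (default 500).
#' @param depth Mean per-base coverage (default 2000).
#' @param read_length Read length (default 100).
#' @param base_quality Constant Phred base quality (default 30).
#' @param error_rate Per-base substitution error rate (default 0.001).
#' @param duplicate_rate Fraction of fragments receiving one PCR copy
#'   (default 0.05).
#' @param fragment_min,fragment_max Fragment size range (default 230-320).
#' @param strand_balance Probability that a fragment's left read is on the
#'   forward strand (default 0.5).
#' @param seed Mandatory seed; all randomness derives from it.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(variants, contig_length = 500L, depth = 2000L,
                     read_length = 100L, base_quality = 30L,
                     error_rate = 0.001, duplicate_rate = 0.05,
                     fragment_min = 230L, fragment_max = 320L,
                     strand_balance = 0.5, seed) {
  if (missing(seed)) stop("sim_spec requires an explicit seed")
  variants <- as.data.table(variants)
  variants[, ref := toupper(gsub("^-$", "", ref))]
  variants[, alt := toupper(gsub("^-$", "", alt))]
  stopifnot(all(variants$target_vaf >= 0 & variants$target_vaf <= 100),
            depth >= 1, read_length > 1,
            fragment_min >= read_length, fragment_max >= fragment_min)
  if (any(variants$pos - 1L + nchar(variants$ref) > contig_length))
    stop("variant outside contig")
  structure(list(
    variants = variants, contig_length = as.integer(contig_length),
    depth = as.integer(depth), read_length = as.integer(read_length),
    base_quality = as.integer(base_quality),
    error_rate = as.numeric(error_rate),
    duplicate_rate = as.numeric(duplicate_rate),
    fragment_min = as.integer(fragment_min),
    fragment_max = as.integer(fragment_max),
    strand_balance = as.numeric(strand_balance),
    seed = as.integer(seed)), class = "sim_spec")
}

## CIGAR and reference start for a read drawn on variant-haplotype
## coordinates [a, b) given an edit of (lr -> la) bases at hap position
## `pos`.  Returns NULL when the read cannot be aligned (entirely inside
## an unbalanced event).
align_hap_read <- function(a, b, pos, lr, la) {
  ops <- character(0); lens <- integer(0)
  push <- function(op, len) {
    if (len <= 0L) return()
    if (length(ops) && ops[length(ops)] == op && op != "S") {
      lens[length(lens)] <<- lens[length(lens)] + len
    } else { ops <<- c(ops, op); lens <<- c(lens, len) }
  }
  if (b <= pos) return(list(ref_start = a, cigar = paste0(b - a, "M")))
  if (a >= pos + la)
    return(list(ref_start = a - la + lr, cigar = paste0(b - a, "M")))
  j <- max(a, pos) - pos          # covered block offsets [j, k)
  k <- min(b, pos + la) - pos
  left <- max(0L, pos - a)
  right <- max(0L, b - (pos + la))
  ref_start <- NA_integer_
  lead_clip <- 0L; tail_clip <- 0L
  if (j == 0L && k == la) {               # block fully covered
    m <- min(lr, la)
    ref_start <- a
    push("M", left); push("M", m)
    if (la > lr) push("I", la - lr) else if (lr > la) push("D", lr - la)
    push("M", right)
  } else if (j == 0L) {                   # read ends inside the block
    ref_start <- a
    m <- min(k, lr)
    push("M", left); push("M", m)
    tail_clip <- k - m
  } else if (k == la) {                   # read starts inside the block
    t <- la - j
    m <- min(t, lr)
    lead_clip <- t - m
    ref_start <- pos + lr - m
    push("M", m); push("M", right)
  } else {                                # entirely inside the block
    if (la == lr) {
      ref_start <- pos + j
      push("M", k - j)
    } else return(NULL)
  }
  cigar <- paste0(
    if (lead_clip > 0L) paste0(lead_clip, "S") else "",
    paste0(lens, ops, collapse = ""),
    if (tail_clip > 0L) paste0(tail_clip, "S") else "")
  list(ref_start = ref_start, cigar = cigar)
}

#' Simulate aligned reads with ground truth
#'
#' Generates random reference contigs (with each variant's reference
#' allele planted at its position), builds per-variant haplotypes, draws
#' paired-end fragments, assigns each fragment the variant haplotype with
#' probability `target_vaf`, injects sequencing errors and PCR duplicates,
#' and emits alignment records with exact CIGARs.  Fully reproducible from
#' the spec seed.
#'
#' @param spec A [sim_spec()].
#' @param dir Output directory; when given, writes `ref.fa` (+ `.fai`),
#'   `reads.bam` (+ `.bai`) and `truth.tsv` and returns their paths.
#' @param prefix File name prefix used under `dir` (default `"sim"`).
#' @param ref Optional named character vector of contig sequences to use
#'   instead of generating random ones — pass the tumor simulation's `ref`
#'   when simulating the matched normal so both samples share a reference.
#' @return List: `reads` (read table), `ref` (named character vector of
#'   contig sequences), `truth` (`data.table`), and — when `dir` is given
#'   — `fasta`, `bam`, `truth_tsv` paths.
#' @export
simulate_reads <- function(spec, dir = NULL, prefix = "sim", ref = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  rl <- spec$read_length
  contigs <- unique(spec$variants$contig)
  if (length(contigs) == 0L) stop("spec contains no variants")
  refs <- setNames(character(length(contigs)), contigs)
  all_reads <- vector("list", 0L)
  for (ct in contigs) {
    L <- spec$contig_length
    refseq <- if (!is.null(ref)) {
      if (is.null(ref[[ct]])) stop("contig ", ct, " missing from ref")
      ref[[ct]]
    } else paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    vs <- spec$variants[contig == ct]
    ## plant reference alleles
    for (i in seq_len(nrow(vs))) {
      if (nchar(vs$ref[i]) > 0L)
        substr(refseq, vs$pos[i], vs$pos[i] - 1L + nchar(vs$ref[i])) <-
          vs$ref[i]
    }
    refs[[ct]] <- refseq
    ## per-variant haplotypes; hap edit position is 0-based
    haps <- lapply(seq_len(nrow(vs)), function(i) {
      p0 <- vs$pos[i] - 1L
      lr <- nchar(vs$ref[i]); la <- nchar(vs$alt[i])
      if (lr == 0L) p0 <- p0 + 1L  # insertion: after the stated base
      hap <- paste0(substr(refseq, 1L, p0), vs$alt[i],
                    substr(refseq, p0 + lr + 1L, L))
      list(pos = p0, lr = lr, la = la, hap = hap, hap_len = nchar(hap))
    })
    nfrag <- ceiling(spec$depth * L / (2 * rl))
    flen <- sample(spec$fragment_min:spec$fragment_max, nfrag,
                   replace = TRUE)
    flen <- pmin(flen, L - 1L)
    fs <- vapply(flen, function(fl)
      sample.int(L - fl, 1L) - 1L, integer(1))
    ## variant assignment: each fragment draws one uniform and each
    ## overlapping variant owns a slot of width target_vaf, so the
    ## marginal carrier fraction at every site equals its target VAF
    ## (co-overlapping variants land on distinct molecules)
    vidx <- rep(0L, nfrag)
    if (nrow(vs)) {
      u <- runif(nfrag)
      slot <- numeric(nfrag)
      for (i in seq_len(nrow(vs))) {
        s <- vs$pos[i] - 1L
        e <- s + max(nchar(vs$ref[i]), 1L)
        hit <- fs < e & (fs + flen) > s
        p <- vs$target_vaf[i] / 100
        sel <- hit & vidx == 0L & u >= slot & u < slot + p
        vidx[sel] <- i
        slot[hit] <- slot[hit] + p
      }
    }
    carrier <- vidx > 0L
    ## PCR duplication: copy a fraction of fragments
    dup_of <- which(runif(nfrag) < spec$duplicate_rate)
    frag_id <- c(seq_len(nfrag), dup_of)
    copy_no <- c(rep(0L, nfrag), seq_along(dup_of))
    ori <- runif(nfrag) < spec$strand_balance
    qn <- sprintf("%s_f%d%s", ct, frag_id,
                  ifelse(copy_no > 0L, paste0("_d", copy_no), ""))
    keep <- rep(TRUE, length(frag_id))
    n2 <- length(frag_id)
    pos1 <- fs[frag_id]; pos2 <- fs[frag_id] + flen[frag_id] - rl
    cig1 <- rep(paste0(rl, "M"), n2); cig2 <- cig1
    seq1 <- substr(rep(refseq, n2), pos1 + 1L, pos1 + rl)
    seq2 <- substr(rep(refseq, n2), pos2 + 1L, pos2 + rl)
    for (w in which(carrier[frag_id])) {
      f <- frag_id[w]
      hv <- haps[[vidx[f]]]
      a1 <- fs[f]; b1 <- min(fs[f] + rl, hv$hap_len)
      b2 <- min(fs[f] + flen[f], hv$hap_len)
      a2 <- min(fs[f] + flen[f] - rl, b2 - 1L)
      al1 <- align_hap_read(a1, b1, hv$pos, hv$lr, hv$la)
      al2 <- align_hap_read(a2, b2, hv$pos, hv$lr, hv$la)
      if (is.null(al1) || is.null(al2)) { keep[w] <- FALSE; next }
      pos1[w] <- al1$ref_start; cig1[w] <- al1$cigar
      pos2[w] <- al2$ref_start; cig2[w] <- al2$cigar
      seq1[w] <- substr(hv$hap, a1 + 1L, b1)
      seq2[w] <- substr(hv$hap, a2 + 1L, b2)
    }
    st1 <- ifelse(ori[frag_id], "+", "-")
    all_reads[[length(all_reads) + 1L]] <- data.table(
      qname = rep(qn[keep], 2L),
      contig = ct,
      pos = c(pos1[keep], pos2[keep]),
      cigar = c(cig1[keep], cig2[keep]),
      seq = c(seq1[keep], seq2[keep]),
      strand = c(st1[keep], ifelse(ori[frag_id], "-", "+")[keep]),
      mate = rep(c(1L, 2L), each = sum(keep)))
  }
  reads <- rbindlist(all_reads)
  ## sequencing errors
  nch <- nchar(reads$seq)
  nerr <- rbinom(nrow(reads), nch, spec$error_rate)
  for (i in which(nerr > 0L)) {
    s <- strsplit(reads$seq[i], "")[[1]]
    at <- sample.int(length(s), nerr[i])
    for (p in at) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    set(reads, i, "seq", paste(s, collapse = ""))
  }
  ## flags, mate positions, qualities
  reads[, mpos := rev(pos), by = qname]
  reads[, flag := 1L + 2L +
          ifelse(strand == "-", 16L, 0L) +
          ifelse(rev(strand) == "-", 32L, 0L) +
          ifelse(mate == 1L, 64L, 128L), by = qname]
  qch <- intToUtf8(spec$base_quality + 33L)
  reads[, qual := vapply(nchar(seq), function(n)
    paste(rep(qch, n), collapse = ""), character(1))]
  reads[, mapq := 60L]
  reads[, end := pos + cigar_ref_length(cigar)]
  setcolorder(reads, c("qname", "flag", "contig", "pos", "mapq", "cigar",
                       "seq", "qual", "strand", "mpos", "end"))
  setorder(reads, contig, pos)
  truth <- spec$variants[, .(contig, pos, ref, alt, vtype, target_vaf)]
  out <- list(reads = reads[, !"mate"], ref = refs, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(dir, paste0(prefix, ".fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs), fasta)
    Rsamtools::indexFa(fasta)
    bam <- write_reads_bam(out$reads, refs,
                           file.path(dir, paste0(prefix, ".bam")))
    truth_tsv <- file.path(dir, paste0(prefix, "_truth.tsv"))
    fwrite(truth, truth_tsv, sep = "\t")
    out$fasta <- fasta; out$bam <- bam; out$truth_tsv <- truth_tsv
  }
  out
}

#' Write a read table to an indexed BAM
#'
#' Serialises simulator output (or any [read_records()] table) as SAM and
#' converts to a sorted, indexed BAM via Rsamtools.
#'
#' @param reads Read table.
#' @param refs Named character vector of contig sequences (for header
#'   lengths).
#' @param bam_path Destination path ending in `.bam`.
#' @return The BAM path, invisibly.
#' @export
write_reads_bam <- function(reads, refs, bam_path) {
  reads <- as.data.table(reads)
  sam <- sub("\\.bam$", ".sam", bam_path)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)))
  dt <- copy(reads)
  setorder(dt, contig, pos)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  dt$qname, dt$flag, dt$contig, dt$pos + 1L, dt$mapq,
                  dt$cigar, "=",
                  ifelse(is.na(dt$mpos), 0L, dt$mpos + 1L), 0L,
                  dt$seq, dt$qual)
  writeLines(c(hdr, body), sam)
  out <- Rsamtools::asBam(sam, sub("\\.bam$", "", bam_path),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  invisible(out)
}
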