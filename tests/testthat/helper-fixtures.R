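## Fixture builders shared across the suite.  All randomness is seeded at
## the call site.

library(data.table)

## n reads with the same alignment but distinct duplicate signatures
## (distinct mate starts), so each counts as its own molecule.
stacked_reads <- function(n, contig, pos, cigar, seq, qual = 30L,
                          prefix = "r", strand = "+", mpos_base = 10000L) {
  read_records(sprintf("%s%03d", prefix, seq_len(n)), contig, pos, cigar,
               seq, qual, strand = strand,
               mpos = mpos_base + seq_len(n))
}

## a reference string with given bases planted at 1-based position
plant <- function(refseq, pos, allele) {
  if (nchar(allele)) substr(refseq, pos, pos + nchar(allele) - 1L) <- allele
  refseq
}

random_ref <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## direct product-form LOD evaluation (independent oracle for the
## log-space implementation)
lod_oracle <- function(alleles, quals, ref, alt, f) {
  e <- 10^(-quals / 10)
  p <- function(b, a) ifelse(b == a, 1 - e, e / 3)
  num <- prod(f * p(alleles, alt) + (1 - f) * p(alleles, ref))
  den <- prod(p(alleles, ref))
  log10(num / den)
}

## simulate one variant on one contig and call it tumor-only
sim_and_call <- function(pos, ref, alt, vtype, vaf, depth = 400,
                        seed = 1, contig_length = 500L,
                        config = caller_config(), normal_vaf = NULL,
                        normal_seed = NULL) {
  v <- data.frame(contig = "c1", pos = pos, ref = ref, alt = alt,
                  vtype = vtype, target_vaf = vaf)
  sp <- sim_spec(v, contig_length = contig_length, depth = depth,
                 seed = seed)
  sim <- simulate_reads(sp)
  regs <- regions("c1", max(0L, pos - 100L),
                  min(contig_length, pos + nchar(ref) + 100L))
  normal <- NULL
  if (!is.null(normal_vaf)) {
    vn <- data.frame(contig = "c1", pos = pos, ref = ref, alt = alt,
                     vtype = vtype, target_vaf = normal_vaf)
    spn <- sim_spec(vn, contig_length = contig_length, depth = depth,
                    seed = normal_seed %||% (seed + 5000L))
    normal <- simulate_reads(spn, ref = sim$ref)$reads
  }
  calls <- call_from_reads(sim$reads, normal, sim$ref, regs, config)
  list(calls = calls, sim = sim, regs = regs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## sample one element from a vector (safe for length-1 vectors)
pick1 <- function(x) x[sample.int(length(x), 1L)]
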