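test_that("read filters reject the documented classes with reasons", {
  regs <- regions("chr1", 100L, 200L)
  reads <- read_records(
    qname = c("ok", "lowmapq_sec", "outside", "dupflag", "qcfail"),
    contig = "chr1",
    pos = c(120L, 120L, 400L, 130L, 140L),
    cigar = "10M",
    seq = "ACGTACGTAC", qual = 30L,
    mapq = c(60L, 0L, 60L, 60L, 60L),
    flag = c(0L, 256L, 0L, 1024L, 512L))
  res <- passes_read_filters(reads, regs, keep = FALSE)
  expect_true(res$passed[1])
  expect_setequal(res$reasons[[2]],
                  c("low_mapq", "secondary_or_supplementary"))
  expect_equal(res$reasons[[3]], "outside_interval")
  expect_true(res$passed[4])  # flagged duplicates kept by default
  expect_false(passes_read_filters(
    reads, regs, caller_config(drop_flag_duplicates = TRUE),
    keep = FALSE)$passed[4])
  expect_equal(res$reasons[[5]], "qcfail")
  expect_equal(passes_read_filters(reads, regs)$qname, c("ok", "dupflag"))
})

test_that("pileup expands reads into per-base observations", {
  region <- list(contig = "c", start = 90L, end = 120L)
  r <- read_records("r1", "c", 100L, "4M", "ACGT",
                    qual = list(c(30L, 30L, 5L, 30L)))
  obs <- build_pileup(r, region)
  ## base below min_base_quality is absent
  expect_equal(obs$pos, c(100L, 101L, 103L))
  expect_equal(obs$allele, c("A", "C", "T"))
  expect_equal(obs$offset, c(0L, 1L, 3L))

  ## 2M1D2M: deletion token at the anchor site between aligned blocks;
  ## oracle = manual CIGAR walk (ref positions 100,101 | del 102 | 103,104)
  r2 <- read_records("r2", "c", 100L, "2M1D2M", "ACGT", 30L)
  obs2 <- build_pileup(r2, region)
  expect_equal(obs2[allele == "-", pos], 102L)
  expect_equal(obs2[allele != "-", pos], c(100L, 101L, 103L, 104L))

  ## insertion token anchored at the preceding aligned base
  r3 <- read_records("r3", "c", 100L, "2M2I2M", "ACGTAC", 30L)
  obs3 <- build_pileup(r3, region)
  ins <- obs3[startsWith(allele, "+")]
  expect_equal(ins$pos, 101L)
  expect_equal(ins$allele, "+GT")
})

test_that("pileup is invariant to read order and bounded by read count", {
  set.seed(5)
  refseq <- random_ref(60, 5)
  n <- 20L
  reads <- read_records(sprintf("r%02d", 1:n), "c",
                        sample(0:40, n, replace = TRUE), "10M",
                        vapply(1:n, function(i)
                          paste(sample(c("A", "C", "G", "T"), 10,
                                       replace = TRUE), collapse = ""),
                          character(1)),
                        30L)
  region <- list(contig = "c", start = 0L, end = 60L)
  obs1 <- build_pileup(reads, region)
  obs2 <- build_pileup(reads[sample(n)], region)
  setorder(obs1, pos, qname); setorder(obs2, pos, qname)
  expect_equal(obs1, obs2)
  percov <- obs1[, .N, by = pos]
  for (p in percov$pos) {
    covering <- sum(reads$pos <= p & reads$end > p)
    expect_lte(percov[pos == p, N], covering)
  }
})

test_that("malformed reads are rejected", {
  expect_error(read_records("x", "c", 1L, "5M", "ACGT", 30L), "mismatch")
})
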