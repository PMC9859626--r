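test_that("indel events are extracted per CIGAR operation", {
  r <- read_records("a", "c", 100L, "5M2D5M", "ACGTACGTAC", 30L)
  ev <- extract_indel_events(r)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "del")
  expect_equal(ev$pos, 105L)
  expect_equal(ev$len, 2L)

  r2 <- read_records("b", "c", 100L, "5M1I4M2D5M", "ACGTACGTACGTACG", 30L)
  ev2 <- extract_indel_events(r2)
  expect_equal(ev2$kind, c("ins", "del"))
  expect_equal(ev2$pos, c(105L, 109L))
  expect_equal(ev2$seq, c("C", ""))

  ## three indel operations: read excluded from indel evidence
  r3 <- read_records("three", "c", 100L, "3M1D3M1D3M1I2M", "ACGTACGTACGA",
                     30L)
  ev3 <- extract_indel_events(r3)
  expect_equal(nrow(ev3), 0L)
  expect_equal(attr(ev3, "dropped"), "three")
})

test_that("same-read gaps merge below 10 bases and SNVs within 5 of a gap", {
  cfg <- caller_config()
  refseq <- random_ref(200, 9)
  acc <- ref_accessor(refseq)

  ## gap-gap boundary: merged iff separation < 10 (sweep 1..15)
  sweep <- gap_separation_boundary(cfg)
  expect_equal(sweep$n_merged, ifelse(1:15 < 10, 1L, 2L))
  expect_equal(sweep$boundary, 10L)

  ## SNV-gap boundary: absorbed iff distance <= 5 (sweep 1..8)
  for (d in 1:8) {
    cigar <- sprintf("%dM1D%dM", 20L + d, 20L)
    seqlen <- 40L + d
    s <- substr(refseq, 11L, 10L + seqlen)  # read at 0-based pos 10
    substr(s, 20L, 20L) <- if (substr(refseq, 30L, 30L) == "A") "C" else "A"
    rd <- read_records("r1", "c", 10L, cigar, s, 30L)
    ev <- extract_indel_events(rd, cfg)
    snv_pos <- 29L                           # 0-based reference position
    gap_start <- 10L + 20L + d
    stopifnot(gap_start - snv_pos == d + 1L)  # distance to gap edge - 1
    merged <- merge_same_read_events(
      ev, data.frame(pos = snv_pos, alt = substr(s, 20L, 20L)),
      rd, acc, cfg)
    if (gap_start - snv_pos <= 5L) {
      expect_equal(merged$vtype, "complex")
      expect_equal(merged$span_start, snv_pos)
    } else {
      expect_equal(merged$vtype, "deletion")
    }
  }
})

test_that("a same-read deletion plus adjacent SNV yields one complex allele", {
  ## reference ...GG... where the first G is deleted and the second
  ## mutates to A on the same read: one complex GG->A
  refseq <- plant(random_ref(120, 21), 51, "GG")
  acc <- ref_accessor(refseq)
  readseq <- paste0(substr(refseq, 31, 50), "A", substr(refseq, 53, 71))
  rd <- read_records("r1", "c", 30L, "20M1D20M", readseq, 30L)
  ev <- extract_indel_events(rd)
  merged <- merge_same_read_events(ev, data.frame(pos = 51L, alt = "A"),
                                   rd, acc, caller_config())
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$vtype, "complex")
  nv <- normalize_variant(merged$pos, merged$ref, merged$alt, acc)
  expect_equal(nv$ref, "GG")
  expect_equal(nv$alt, "A")
  expect_equal(nv$pos, 50L)
})

test_that("complex ref allele always equals the reference over its span", {
  cfg <- caller_config()
  set.seed(31)
  refseq <- random_ref(400, 31)
  acc <- ref_accessor(refseq)
  for (i in 1:25) {
    dlen <- sample(1:6, 1)
    lead <- sample(15:40, 1)
    cigar <- sprintf("%dM%dD%dM", lead, dlen, 60L - lead)
    rd <- read_records("r", "c", 100L, cigar,
                       paste(sample(c("A", "C", "G", "T"), 60L,
                                    replace = TRUE), collapse = ""), 30L)
    ev <- extract_indel_events(rd, cfg)
    merged <- merge_same_read_events(ev, data.frame(pos = integer(),
                                                    alt = character()),
                                     rd, acc, cfg)
    for (j in seq_len(nrow(merged)))
      expect_identical(merged$ref[j],
                       acc(merged$span_start[j], merged$span_end[j]))
  }
})

test_that("identical deletions at shifted anchors group as one allele", {
  ## two reads carry the same 2-base deletion inside a CACA repeat but
  ## with different raw anchors; after normalization they share a key
  refseq <- plant(random_ref(200, 13), 91, "TACACACAG")
  acc <- ref_accessor(refseq)
  r1 <- read_records("a", "c", 70L, "23M2D20M",
                     paste0(substr(refseq, 71, 93), substr(refseq, 96, 115)),
                     30L)
  r2raw <- paste0(substr(refseq, 71, 95), substr(refseq, 98, 115))
  r2 <- read_records("b", "c", 70L, "25M2D18M", r2raw, 30L)
  cfg <- caller_config()
  a1 <- merge_same_read_events(extract_indel_events(r1, cfg),
                               data.frame(pos = integer(), alt = character()),
                               r1, acc, cfg)
  a2 <- merge_same_read_events(extract_indel_events(r2, cfg),
                               data.frame(pos = integer(), alt = character()),
                               r2, acc, cfg)
  n1 <- normalize_variant(a1$pos, a1$ref, a1$alt, acc)
  n2 <- normalize_variant(a2$pos, a2$ref, a2$alt, acc)
  expect_identical(n1[c("pos", "ref", "alt")], n2[c("pos", "ref", "alt")])
})

test_that("merging is independent of event order within a read", {
  cfg <- caller_config()
  refseq <- random_ref(200, 17)
  acc <- ref_accessor(refseq)
  rd <- read_records("r", "c", 50L, "10M1D5M1D10M",
                     paste(rep("A", 25), collapse = ""), 30L)
  ev <- extract_indel_events(rd, cfg)
  m1 <- merge_same_read_events(ev, data.frame(pos = integer(),
                                              alt = character()),
                               rd, acc, cfg)
  m2 <- merge_same_read_events(ev[c(2, 1)], data.frame(pos = integer(),
                                                       alt = character()),
                               rd, acc, cfg)
  expect_equal(m1, m2)
})
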