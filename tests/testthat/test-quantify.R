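test_that("duplicate groups partition reads by alignment signature", {
  r <- read_records(sprintf("r%d", 1:4), "c", c(10L, 10L, 10L, 10L), "4M",
                    "ACGT", 30L, mpos = c(200L, 200L, 200L, 200L))
  g <- attr(group_duplicates(r), "groups")
  expect_equal(nrow(g), 1L)
  expect_equal(g$size, 4L)

  r2 <- read_records(sprintf("r%d", 1:4), "c", c(10L, 10L, 20L, 20L), "4M",
                     "ACGT", 30L, mpos = 200L)
  expect_equal(nrow(attr(group_duplicates(r2), "groups")), 2L)

  ## same start, opposite strands: different molecules
  r3 <- read_records(c("a", "b"), "c", 10L, "4M", "ACGT", 30L,
                     strand = c("+", "-"), mpos = 200L)
  expect_equal(nrow(attr(group_duplicates(r3), "groups")), 2L)
})

test_that("a group supports only above the 0.8 mutated fraction, strictly", {
  expect_equal(supporting_group_count(c(1.0)), 1L)
  expect_equal(supporting_group_count(c(4 / 5)), 0L)   # exactly 0.8
  expect_equal(supporting_group_count(c(1, 0.8, 0.81, 0.5, 1)), 3L)
})

test_that("VAF arithmetic is duplicate-collapsed and spanning-restricted", {
  expect_equal(compute_vaf(5, 10), 50)
  expect_equal(compute_vaf(2, 10), 20)   # 12 overlap, 10 span, 2 support
  expect_equal(compute_vaf(3, 10), 30)   # 20 reads in 10 groups
  expect_error(compute_vaf(0, 0), "undefined")
})

test_that("site quality is the maximum supporting base quality", {
  expect_equal(site_base_quality(c(20L, 30L, 25L)), 30L)
  expect_equal(site_base_quality(15L), 15L)
  expect_equal(site_base_quality(c(30L, 30L)), 30L)
  expect_error(site_base_quality(integer(0)), "no supporting")
})

test_that("the filter ledger labels every failed screen, order-free", {
  calls <- data.table::data.table(
    contig = "c", pos = 1:4, ref = "A", alt = "T", vtype = "SNV",
    tumor_support = c(2L, 1L, 5L, 2L),
    tumor_depth = c(8L, 50L, 7L, 100L),
    vaf_tumor = c(25, 2, 71.4, 0.5),
    site_bq = c(30L, 30L, 30L, 12L),
    strand_plus = c(1L, 1L, 5L, 0L), strand_minus = c(1L, 0L, 0L, 2L))
  f <- apply_variant_filters(calls)
  expect_equal(f$filters[1], "")                       # all screens met
  expect_equal(f$filters[2], "low_support")
  expect_equal(f$filters[3], "low_depth")
  expect_equal(f$filters[4], "low_site_quality;low_vaf")
  f2 <- apply_variant_filters(calls, caller_config(strand_filter = TRUE))
  expect_true(grepl("strand_bias", f2$filters[3]))
})

test_that("origin classification uses population AF and hotspot lists", {
  calls <- data.table::data.table(
    contig = "c", pos = c(10L, 20L, 30L, 40L), ref = "A",
    alt = c("T", "G", "C", "T"))
  pop <- data.table::data.table(contig = "c", pos = c(10L, 30L),
                                ref = "A", alt = c("T", "C"),
                                af = c(2, 5))
  hot <- data.table::data.table(contig = "c", pos = c(20L, 30L),
                                ref = "A", alt = c("G", "C"))
  out <- classify_origin(calls, pop, hot)
  expect_equal(out$origin, c("germline", "somatic", "both", "unknown"))
  ## below the 1% population threshold: not germline
  pop$af <- c(0.5, 5)
  expect_equal(classify_origin(calls, pop, hot)$origin[1], "unknown")
})

test_that("site tables load from TSV with 1-based positions", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\taf", "chr1\t100\tA\tT\t2.5"), tsv)
  dt <- load_site_table(tsv)
  expect_equal(dt$pos, 99L)
  expect_equal(dt$af, 2.5)
  writeLines("chrom\tpos", tsv)
  expect_error(load_site_table(tsv), "columns")
})

test_that("VAF is invariant to duplicating every read", {
  res <- sim_and_call(250, "A", "T", "SNV", 20, depth = 120, seed = 19)
  base <- res$calls[ref == "A" & alt == "T"]
  expect_equal(nrow(base), 1L)
  reads <- res$sim$reads
  dup3 <- data.table::rbindlist(list(
    reads,
    data.table::copy(reads)[, qname := paste0(qname, "_c1")],
    data.table::copy(reads)[, qname := paste0(qname, "_c2")]))
  calls3 <- call_from_reads(dup3, NULL, res$sim$ref, res$regs)
  trip <- calls3[ref == "A" & alt == "T"]
  expect_equal(trip$vaf_tumor, base$vaf_tumor)
  expect_equal(trip$tumor_depth, base$tumor_depth)
})
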