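test_that("allele likelihood follows the quality error model", {
  expect_equal(allele_likelihood("A", 30, "A"), 0.999)
  expect_equal(allele_likelihood("C", 30, "A"), 0.001 / 3)
  expect_equal(allele_likelihood("G", 0, "G"), 0)
  expect_error(allele_likelihood("N", 30, "A"), "non-ACGT")
})

test_that("tumor LOD matches direct product-form evaluation", {
  ## 47 ref + 3 alt at q30; oracle evaluates the likelihood ratio as a
  ## plain product at f_hat = 0.06
  alleles <- c(rep("A", 47), rep("T", 3))
  obs <- data.frame(allele = alleles, qual = 30)
  res <- tumor_lod(obs, "A", "T")
  expect_equal(res$f_hat, 0.06)
  expect_equal(res$lod, lod_oracle(alleles, rep(30, 50), "A", "T", 0.06),
               tolerance = 1e-12)
  expect_true(res$keep)

  ## zero alt support: identical likelihoods, LOD exactly 0, rejected
  obs0 <- data.frame(allele = rep("A", 30), qual = 30)
  res0 <- tumor_lod(obs0, "A", "T")
  expect_identical(res0$lod, 0)
  expect_false(res0$keep)

  expect_error(tumor_lod(obs, "A", "A"), "alt equals ref")
  expect_error(tumor_lod(obs[0, ], "A", "T"), "empty site")
})

test_that("log-space LOD equals the product form within 1e-9 up to depth 100", {
  set.seed(11)
  for (i in 1:40) {
    depth <- sample(5:100, 1)
    nalt <- sample(0:depth, 1)
    quals <- sample(13:40, depth, replace = TRUE)
    alleles <- c(rep("T", nalt), sample(c("A", "G"), depth - nalt,
                                        replace = TRUE, prob = c(.9, .1)))
    f <- nalt / depth
    got <- tumor_lod(data.frame(allele = alleles, qual = quals),
                     "A", "T", f = f)$lod
    want <- lod_oracle(alleles, quals, "A", "T", f)
    if (f == 0) expect_identical(got, 0) else
      expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("adding an alt observation strictly increases the LOD", {
  ## brute-force sweep over support 0..depth at fixed depth
  depth <- 40L
  lods <- vapply(0:depth, function(k) {
    obs <- data.frame(allele = c(rep("T", k), rep("A", depth - k)),
                      qual = 30)
    tumor_lod(obs, "A", "T", f = k / depth)$lod
  }, numeric(1))
  expect_true(all(diff(lods) > 0))
})

test_that("hypermutated reads are dropped from SNV evidence at the 3-mismatch cutoff", {
  refseq <- strrep("A", 60)
  acc <- ref_accessor(refseq)
  mk <- function(id, k) {
    s <- strrep("A", 20)
    if (k > 0) for (p in seq_len(k)) substr(s, p * 4L, p * 4L) <- "T"
    read_records(id, "c", 10L, "20M", s, 30L)
  }
  reads <- data.table::rbindlist(lapply(0:4, function(k)
    mk(sprintf("mm%d", k), k)))
  kept <- discard_hypermutated_reads(reads, acc)$qname
  expect_setequal(kept, c("mm0", "mm1", "mm2"))
})

test_that("adjacent same-read SNVs merge into one substitution record", {
  cand <- data.table::data.table(
    contig = "c", pos = c(100L, 101L), ref = c("C", "A"),
    alt = c("A", "G"), vtype = "SNV",
    support_reads = list(sprintf("r%d", 1:10), sprintf("r%d", 1:10)))
  m <- merge_adjacent_snvs(cand)
  expect_equal(nrow(m), 1L)
  expect_equal(m$ref, "CA")
  expect_equal(m$alt, "AG")
  expect_equal(m$vtype, "MNV")

  ## disjoint read sets stay separate
  cand2 <- data.table::copy(cand)
  cand2$support_reads <- list(sprintf("r%d", 1:10), sprintf("s%d", 1:10))
  expect_equal(nrow(merge_adjacent_snvs(cand2)), 2L)

  ## non-adjacent same-read SNVs (distance 2) are never merged
  cand3 <- data.table::copy(cand)
  cand3$pos <- c(100L, 102L)
  cand3$ref <- c("C", "A")
  expect_equal(nrow(merge_adjacent_snvs(cand3)), 2L)
})

test_that("merged output never leaves adjacent SNVs with identical read sets", {
  set.seed(3)
  rs <- sprintf("r%d", 1:20)
  cand <- data.table::data.table(
    contig = "c", pos = 200:204, ref = c("A", "C", "G", "T", "A"),
    alt = c("C", "G", "T", "A", "C"), vtype = "SNV",
    support_reads = list(rs, rs, rs[1:4], rs, rs))
  m <- merge_adjacent_snvs(cand)
  expect_lte(nrow(m), nrow(cand))
  expect_true(any(m$vtype == "MNV"))
  snvs <- m[m$vtype == "SNV"]
  if (nrow(snvs) > 1L) {
    for (i in seq_len(nrow(snvs) - 1L)) {
      adjacent <- snvs$pos[i + 1L] == snvs$pos[i] + 1L
      same <- setequal(snvs$support_reads[[i]], snvs$support_reads[[i + 1L]])
      expect_false(adjacent && same)
    }
  }
})
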