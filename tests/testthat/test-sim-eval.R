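test_that("simulated alt fraction tracks the binomial expectation", {
  v <- data.frame(contig = "c1", pos = 250, ref = "A", alt = "T",
                  vtype = "SNV", target_vaf = 50)
  sp <- sim_spec(v, depth = 1000, seed = 101)
  sim <- simulate_reads(sp)
  obs <- build_pileup(sim$reads, list(contig = "c1", start = 249L,
                                      end = 250L), caller_config())
  frac <- mean(obs$allele == "T")
  n <- nrow(obs)
  expect_lt(abs(frac - 0.5), 5 * sqrt(0.25 / n))
})

test_that("variant reads carry the exact expected CIGAR operations", {
  v <- data.frame(contig = "c1", pos = 250, ref = "ACT", alt = "",
                  vtype = "Deletion", target_vaf = 30)
  sim <- simulate_reads(sim_spec(v, depth = 200, seed = 7))
  dels <- sim$reads[grepl("D", cigar)]
  expect_gt(nrow(dels), 10)
  expect_true(all(grepl("3D", dels$cigar)))

  ## complex allele: variant reads carry the merged haplotype on single
  ## reads (here 15 ref bases replaced by 3)
  v2 <- data.frame(contig = "c1", pos = 250, ref = "AATTAAGAGAAGCAA",
                   alt = "TTC", vtype = "Complex", target_vaf = 50)
  sim2 <- simulate_reads(sim_spec(v2, depth = 200, seed = 8))
  spanning <- sim2$reads[grepl("12D", cigar)]
  expect_gt(nrow(spanning), 10)
  ev <- extract_indel_events(spanning[1])
  expect_equal(ev$kind, "del")
  expect_equal(ev$len, 12L)
})

test_that("simulation is reproducible from its seed", {
  v <- data.frame(contig = "c1", pos = 100, ref = "G", alt = "C",
                  vtype = "SNV", target_vaf = 10)
  s1 <- simulate_reads(sim_spec(v, depth = 100, seed = 77))
  s2 <- simulate_reads(sim_spec(v, depth = 100, seed = 77))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$ref, s2$ref)
  s3 <- simulate_reads(sim_spec(v, depth = 100, seed = 78))
  expect_false(identical(s1$reads, s3$reads))
})

test_that("variant matching normalizes both sides before comparing", {
  refseq <- plant(random_ref(300, 55), 140, "GTACACACAG")
  acc <- list(c1 = ref_accessor(refseq))
  truth <- data.frame(contig = "c1", pos = 141, ref = "TAC", alt = "T")
  ## call reported at a right-shifted, un-anchored equivalent form
  calls <- data.frame(contig = "c1", pos = 143L, ref = "AC", alt = "")
  m <- match_variants(calls, truth, acc)
  expect_equal(m$tp, 1L)
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)

  m2 <- match_variants(calls[0, ], data.frame(
    contig = "c1", pos = c(10, 20, 30), ref = "A", alt = "T"), acc)
  expect_equal(m2$fn, 3L)
})

test_that("metrics report both F1 conventions explicitly", {
  m <- eval_metrics(684, 2, 39)
  expect_equal(round(100 * m$precision, 2), 99.71)
  expect_equal(round(100 * m$sensitivity, 2), 94.61)
  expect_equal(round(m$f1_harmonic, 2), 0.97)
  m2 <- eval_metrics(968, 1445 - 968, 1045 - 968)
  expect_equal(round(m2$f1_product, 2), 0.62)
  m3 <- eval_metrics(10, 0, 0)
  expect_equal(m3$f1_harmonic, 1)
  expect_equal(m3$f1_product, 1)
  expect_true(is.na(eval_metrics(0, 0, 5)$precision))

  ## harmonic mean dominates the product on (0,1]^2, equal only at P=S=1
  grid <- expand.grid(p = seq(0.05, 1, by = 0.05),
                      s = seq(0.05, 1, by = 0.05))
  for (i in seq_len(nrow(grid))) {
    m <- eval_metrics(round(1000 * grid$s[i]),
                      fp = round(1000 * grid$s[i] * (1 / grid$p[i] - 1)),
                      fn = round(1000 * (1 - grid$s[i])))
    expect_gte(m$f1_harmonic, m$f1_product - 1e-12)
  }
})

test_that("the standard panel table has the printed composition", {
  tab <- eqa_2017_variants()
  expect_equal(nrow(tab), 94L)
  expect_equal(sum(tab$vtype == "SNV"), 74L)
  expect_equal(sum(tab$vtype == "Insertion"), 8L)
  expect_equal(sum(tab$vtype == "Deletion"), 9L)
  expect_equal(sum(tab$vtype == "Complex"), 3L)
  expect_true(all(tab$vaf >= 1 & tab$vaf <= 25))
})
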