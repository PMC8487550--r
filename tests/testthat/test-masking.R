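test_that("masking-pair draws follow the population distribution", {
  # degenerate distribution
  v1 <- population_variant("c1", 5L, c("A", "T"), c(1, 0))
  set.seed(1)
  for (i in 1:50) expect_identical(sample_masking_pair(v1), c("A", "A"))

  # analytic het-pair rate 2 * 0.75 * 0.25 = 0.375 from two independent draws
  v2 <- population_variant("c1", 6L, c("A", "C"), c(0.75, 0.25))
  n <- 20000L
  set.seed(202)
  het <- 0L
  for (i in seq_len(n)) {
    p <- sample_masking_pair(v2)
    if (p[1] != p[2]) het <- het + 1L
  }
  p0 <- 0.375
  expect_lt(abs(het / n - p0), 3 * sqrt(p0 * (1 - p0) / n))

  # determinism under a fixed seed
  set.seed(77); a <- sample_masking_pair(v2)
  set.seed(77); b <- sample_masking_pair(v2)
  expect_identical(a, b)
})

test_that("HOM replacement maps every personal observation to the masking allele", {
  col <- make_column(rep("A", 15))
  call <- call_personal_alleles(col)
  plan <- plan_site_replacement(col, call, c("C", "C"))
  expect_identical(plan$target, rep("C", 15))
  expect_identical(plan$base, rep("A", 15))
})

test_that("HOM with an unequal masking pair splits observations ~Bernoulli(1/2)", {
  col <- make_column(rep("A", 10000))
  call <- call_personal_alleles(col)
  set.seed(55)
  plan <- plan_site_replacement(col, call, c("C", "G"))
  expect_setequal(unique(plan$target), c("C", "G"))
  frac_c <- mean(plan$target == "C")
  expect_lt(abs(frac_c - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("HET replacement is slot-wise and error bases land outside the masking pair", {
  col <- make_column(c(rep("A", 9), rep("C", 8), "G"))
  call <- call_personal_alleles(col)
  expect_identical(call$allele_pair, c("A", "C"))
  set.seed(5)
  plan <- plan_site_replacement(col, call, c("A", "C"))
  expect_identical(plan$target[plan$base == "A"], rep("A", 9))
  expect_identical(plan$target[plan$base == "C"], rep("C", 8))
  expect_true(plan$target[plan$base == "G"] %in% c("G", "T"))
})

test_that("SKIP/UNCOVERED calls cannot be planned", {
  col <- make_column(rep("A", 3))
  expect_condition_class(
    plan_site_replacement(col, readmask:::personal_call("SKIP"), c("A", "A")),
    "readmask_config_error")
})

test_that("empty population table leaves records byte-identical with an empty diff", {
  ds <- simulate_dataset(sim_config(contig_length = 2000L, n_sites = 0L,
                                    depth = 10), seed = 2)
  res <- mask_alignments(ds$aln, vof_table(contigs = "sim1"), seed = 1)
  expect_identical(res$alignments$records, ds$aln$records)
  expect_length(res$bdiff$records, 0L)
})

test_that("a hom-alt site with a degenerate reference-only distribution becomes masked", {
  # all reads carry T, population says the site is A with certainty
  aln <- make_sam(pos = rep(11, 12), cigar = "1M", seq = rep("T", 12))
  vof <- vof_table(list(population_variant("c1", 10L, c("A", "T"), c(1, 0))),
                   contigs = "c1")
  res <- mask_alignments(aln, vof, seed = 3)
  col <- pileup_column(res$alignments, "c1", 10L)
  expect_identical(unique(col$obs$base), "A")
  expect_length(res$bdiff$records, 1L)
  expect_identical(res$bdiff$records[[1]]$bases, rep("T", 12))
})

test_that("masking preserves structure: count, order, positions, CIGARs, flags, depth", {
  fx <- small_masked_fixture(seed = 13, mask_seed = 21, error_rate = 0.005)
  orig <- fx$aln$records; msk <- fx$alignments$records
  for (fld in c("qname", "flag", "rname", "pos", "mapq", "cigar", "rnext",
                "pnext", "tlen", "tags")) {
    expect_identical(msk[[fld]], orig[[fld]])
  }
  expect_identical(nchar(msk$seq), nchar(orig$seq))
  # per-site depth unchanged at every table site
  for (p in fx$vof$position[1:10]) {
    expect_identical(nrow(pileup_column(fx$alignments, "sim1", p)$obs),
                     nrow(pileup_column(fx$aln, "sim1", p)$obs))
  }
})

test_that("qualities of all counted observations at processed sites carry the placeholder", {
  fx <- small_masked_fixture(seed = 17, mask_seed = 23)
  r <- fx$bdiff$records[[1]]
  col <- pileup_column(fx$alignments, r$contig, r$position)
  counted <- col$obs$base %in% c("A", "C", "G", "T")
  expect_identical(unique(col$obs$qual[counted]), 60L)
})

test_that("masking is reproducible from the seed and differs across seeds", {
  ds <- simulate_dataset(sim_config(contig_length = 4000L, n_sites = 40L,
                                    depth = 15), seed = 5)
  a <- mask_alignments(ds$aln, ds$vof, seed = 11)
  b <- mask_alignments(ds$aln, ds$vof, seed = 11)
  c <- mask_alignments(ds$aln, ds$vof, seed = 12)
  expect_identical(a$alignments$records, b$alignments$records)
  expect_identical(a$bdiff$header$checksum, b$bdiff$header$checksum)
  expect_false(identical(a$alignments$records$seq, c$alignments$records$seq))
})

test_that("sites on contigs absent from the alignment header are skipped with a warning", {
  aln <- make_sam(pos = rep(11, 5), cigar = "1M", seq = rep("A", 5))
  vof <- vof_table(list(
    population_variant("c1", 10L, c("A", "C"), c(0.9, 0.1)),
    population_variant("cX", 10L, c("A", "C"), c(0.9, 0.1))),
    contigs = c("c1", "cX"))
  expect_warning(res <- mask_alignments(aln, vof, seed = 1), "absent")
  expect_identical(vapply(res$bdiff$records, `[[`, character(1), "contig"),
                   "c1")
})

test_that("unmapped-read concealment is a tagged involution with key checking", {
  ds <- simulate_dataset(sim_config(contig_length = 2000L, n_sites = 5L,
                                    depth = 8, n_unmapped = 6L), seed = 19)
  key <- openssl::rand_bytes(32)
  expect_identical(conceal_unmapped_reads(ds$aln, key, enable = FALSE), ds$aln)
  hidden <- conceal_unmapped_reads(ds$aln, key)
  un <- bitwAnd(hidden$records$flag, 4L) != 0L
  expect_false(identical(hidden$records$seq[un], ds$aln$records$seq[un]))
  expect_identical(hidden$records$seq[!un], ds$aln$records$seq[!un])
  expect_identical(reveal_unmapped_reads(hidden, key), ds$aln)
  expect_condition_class(conceal_unmapped_reads(hidden, key),
                         "readmask_format_error")
  expect_condition_class(reveal_unmapped_reads(hidden, openssl::rand_bytes(32)),
                         "readmask_key_error")
})
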