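fake_calls <- function(depth, quality, filter = "PASS") {
  data.frame(contig = "c1", position = seq_along(depth) * 10L, ref = "A",
             alt = "C", zygosity = "HET", af = 0.5, depth = depth,
             quality = quality, filter = filter, stringsAsFactors = FALSE)
}

test_that("depth/quality cutoffs are strictly exclusive ('above 30')", {
  recs <- fake_calls(depth = c(29, 30, 31, 100), quality = c(50, 50, 50, 50))
  kept <- filter_calls(recs)
  expect_identical(kept$depth, c(31, 100))

  recs2 <- fake_calls(depth = rep(50, 3), quality = c(30, 31, 29))
  expect_identical(filter_calls(recs2)$quality, 31)

  # both at the boundary
  expect_identical(nrow(filter_calls(fake_calls(30, 30))), 0L)
  expect_identical(nrow(filter_calls(fake_calls(31, 31))), 1L)
})

test_that("non-PASS records are dropped only when a PASS filter is required", {
  recs <- fake_calls(depth = c(50, 50), quality = c(50, 50),
                     filter = c("PASS", "LowQual"))
  expect_identical(nrow(filter_calls(recs)), 1L)
  expect_identical(nrow(filter_calls(recs, require_pass = FALSE)), 2L)
  expect_identical(nrow(filter_calls(recs[0, ])), 0L)
})

test_that("five-category classification matches brute-force set arithmetic", {
  cls <- classify_positions(personal = c(3, 4, 11), masked = c(4, 7),
                            population = 1:10)
  expect_identical(unname(cls$counts),
                   c(7L, 1L, 1L, 1L, 1L))
  expect_setequal(cls$sets$not_found, c(1, 2, 5, 6, 8, 9, 10))
  expect_identical(cls$sets$masked, 3)
  expect_identical(cls$sets$not_masked, 4)
  expect_identical(cls$sets$introduced, 7)
  expect_identical(cls$sets$not_covered, 11)
})

test_that("degenerate classifications behave: empty call sets, identity masking", {
  all_notfound <- classify_positions(numeric(), numeric(), 1:10)
  expect_identical(unname(all_notfound$counts), c(10L, 0L, 0L, 0L, 0L))

  ident <- classify_positions(c(2, 5), c(2, 5), 1:10)
  expect_identical(ident$counts[["masked"]], 0L)
  expect_identical(ident$counts[["introduced"]], 0L)
  expect_identical(ident$counts[["not_covered"]], 0L)
  expect_identical(ident$counts[["not_masked"]], 2L)
})

test_that("categories partition the position universe over random pipeline-shaped triples", {
  set.seed(101)
  for (rep in 1:1000) {
    population <- sample.int(200, sample(5:60, 1))
    personal <- sample.int(250, sample(0:40, 1))
    # masking only creates/removes variants at population sites
    masked <- c(intersect(personal, population)[
                  sample(c(TRUE, FALSE), length(intersect(personal, population)),
                         replace = TRUE)],
                sample(setdiff(population, personal),
                       min(5, length(setdiff(population, personal)))))
    cls <- classify_positions(personal, masked, population)
    expect_identical(sum(cls$counts), cls$universe)
  }
})

test_that("masked ratio per frequency bin: all-masked bins, empty bins undefined", {
  r <- masked_ratio_by_frequency(af = c(0.05, 0.15, 0.25),
                                 masked = c(TRUE, TRUE, TRUE))
  expect_true(all(r$ratio[r$n > 0] == 1))
  expect_true(all(is.na(r$ratio[r$n == 0])))

  empty <- masked_ratio_by_frequency(numeric(), logical())
  expect_true(all(is.na(empty$ratio)))
})

test_that("masked ratio falls with allele frequency under the (1-q)^2 law", {
  set.seed(113)
  qs <- c(0.01, 0.05, 0.1, 0.25, 0.5)
  af <- rep(qs, each = 400)
  masked <- runif(length(af)) < (1 - af)^2
  r <- masked_ratio_by_frequency(af, masked,
                                 breaks = c(0, 0.02, 0.07, 0.15, 0.3, 0.6))
  expect_false(any(is.na(r$ratio)))
  expect_true(all(diff(r$ratio) < 0))
  expect_lt(cor(seq_along(r$ratio), r$ratio, method = "spearman"), -0.9)
})

test_that("the naive caller reports hom and het sites with expected allele fractions", {
  # error-free hom-alt site at depth 20
  ref <- setNames(strrep("A", 200), "c1")
  hom <- make_sam(pos = rep(91, 20), cigar = "1M", seq = rep("G", 20),
                  contig_len = 200L)
  calls <- naive_caller(hom, ref)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$position, 90L)
  expect_identical(calls$alt, "G")
  expect_identical(calls$zygosity, "HOM")
  expect_identical(calls$af, 1)

  # error-free het site at depth 1000: af within 0.5 +/- 0.05
  set.seed(7)
  het <- make_sam(pos = rep(51, 1000), cigar = "1M",
                  seq = sample(c("A", "T"), 1000, replace = TRUE),
                  contig_len = 200L)
  calls2 <- naive_caller(het, ref)
  expect_identical(calls2$zygosity, "HET")
  expect_lt(abs(calls2$af - 0.5), 0.05)

  # all-reference input produces no record
  refonly <- make_sam(pos = rep(11, 30), cigar = "1M", seq = rep("A", 30),
                      contig_len = 200L)
  expect_identical(nrow(naive_caller(refonly, ref)), 0L)

  # contig missing from the reference is a hard error
  expect_condition_class(naive_caller(hom, setNames("AAAA", "other")),
                         "readmask_format_error")
})

test_that("caller agrees with per-column genotyping across an error-bearing simulation", {
  ds <- simulate_dataset(sim_config(contig_length = 20000L, n_sites = 120L,
                                    depth = 30, error_rate = 0.005), seed = 127)
  calls <- naive_caller(ds$aln, ds$reference, min_depth = 10)
  # route 2: per-site pileup genotyping against the simulated truth
  refseq <- ds$reference[[1]]
  for (i in seq_len(nrow(ds$truth))) {
    p <- ds$truth$position[i]
    col <- pileup_column(ds$aln, "sim1", p)
    if (nrow(col$obs) < 10L) next
    g <- call_personal_alleles(col)
    if (!g$kind %in% c("HOM", "HET")) next
    refb <- substr(refseq, p + 1L, p + 1L)
    has_alt <- any(g$allele_pair != refb)
    expect_identical(p %in% calls$position, has_alt,
                     info = paste("site", p))
  }
})

test_that("allele-frequency histogram counts every site once", {
  set.seed(5)
  af <- runif(500)
  h <- af_histogram(af)
  expect_identical(sum(h$count), 500L)
})
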