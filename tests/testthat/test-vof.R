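write_test_vcf <- function(body_lines, af_in_header = TRUE) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           if (af_in_header)
             "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
           "##contig=<ID=chr1,length=100000>",
           "##contig=<ID=chr2,length=100000>",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, body_lines), path)
  path
}

test_that("same-position PASS SNVs merge into one multiallelic entry with complement reference frequency", {
  vcf <- write_test_vcf(c(
    "chr1\t101\t.\tA\tC\t50\tPASS\tAF=0.10",
    "chr1\t101\t.\tA\tG\t50\tPASS\tAF=0.05"))
  tab <- build_vof(vcf)
  expect_length(tab$entries, 1L)
  e <- query_site(tab, "chr1", 100L) # 0-based
  expect_identical(e$alleles, c("A", "C", "G"))
  expect_equal(e$frequencies, c(0.85, 0.10, 0.05))
  expect_equal(sum(e$frequencies), 1, tolerance = 1e-9)
})

test_that("merging is order-insensitive for same-position records", {
  a <- build_vof(write_test_vcf(c(
    "chr1\t101\t.\tA\tC\t50\tPASS\tAF=0.10",
    "chr1\t101\t.\tA\tG\t50\tPASS\tAF=0.05")))
  b <- build_vof(write_test_vcf(c(
    "chr1\t101\t.\tA\tG\t50\tPASS\tAF=0.05",
    "chr1\t101\t.\tA\tC\t50\tPASS\tAF=0.10")))
  expect_equal(query_site(a, "chr1", 100L), query_site(b, "chr1", 100L))
})

test_that("non-PASS, indel and out-of-region records are dropped; empty input yields empty table", {
  vcf <- write_test_vcf(c(
    "chr1\t101\t.\tA\tC\t50\tLowQual\tAF=0.10",
    "chr1\t201\t.\tA\tAT\t50\tPASS\tAF=0.10",
    "chr1\t301\t.\tAT\tA\t50\tPASS\tAF=0.10"))
  expect_length(build_vof(vcf)$entries, 0L)
  expect_length(build_vof(write_test_vcf(character()))$entries, 0L)

  vcf2 <- write_test_vcf(c(
    "chr1\t101\t.\tA\tC\t50\tPASS\tAF=0.10",
    "chr1\t901\t.\tG\tT\t50\tPASS\tAF=0.20"))
  regions <- data.frame(contig = "chr1", start = 0L, end = 500L)
  tab <- build_vof(vcf2, regions = regions)
  expect_length(tab$entries, 1L)
  expect_identical(tab$position, 100L)
})

test_that("multiallelic ALT lines split their AF values", {
  vcf <- write_test_vcf("chr1\t101\t.\tA\tC,T\t50\tPASS\tAF=0.2,0.05")
  e <- query_site(build_vof(vcf), "chr1", 100L)
  expect_identical(e$alleles, c("A", "C", "T"))
  expect_equal(e$frequencies, c(0.75, 0.2, 0.05))
})

test_that("corrupt input is a hard error: missing AF, AF sum > 1, conflicting REF", {
  expect_condition_class(
    build_vof(write_test_vcf("chr1\t101\t.\tA\tC\t50\tPASS\tDP=5")),
    "readmask_format_error")
  expect_condition_class(
    build_vof(write_test_vcf(c(
      "chr1\t101\t.\tA\tC\t50\tPASS\tAF=0.7",
      "chr1\t101\t.\tA\tG\t50\tPASS\tAF=0.5"))),
    "readmask_format_error")
  expect_condition_class(
    build_vof(write_test_vcf(c(
      "chr1\t101\t.\tA\tC\t50\tPASS\tAF=0.1",
      "chr1\t101\t.\tG\tC\t50\tPASS\tAF=0.1"))),
    "readmask_format_error")
})

test_that("reference frequency is clamped at zero only for float noise", {
  vcf <- write_test_vcf("chr1\t101\t.\tA\tC,G\t50\tPASS\tAF=0.6,0.4000000001")
  e <- query_site(build_vof(vcf), "chr1", 100L)
  expect_identical(e$frequencies[1], 0)
  expect_equal(sum(e$frequencies), 1, tolerance = 1e-9)
})

test_that("every produced entry sums to 1 and alleles stay canonical over random inputs", {
  set.seed(71)
  for (rep in 1:20) {
    tab <- random_vof(40)
    sums <- vapply(tab$entries, function(e) sum(e$frequencies), numeric(1))
    expect_true(all(abs(sums - 1) < 1e-9))
    for (e in tab$entries) {
      expect_identical(e$alleles[-1], sort(e$alleles[-1]))
      expect_false(anyDuplicated(e$alleles) > 0)
    }
  }
})

test_that("binary serialization round-trips arbitrary valid tables", {
  set.seed(42)
  path <- tempfile(fileext = ".vof")
  for (n in c(0L, 1L, 1000L)) {
    tab <- if (n == 0L) vof_table() else random_vof(n)
    write_vof(tab, path)
    expect_identical(read_vof(path), tab)
  }
})

test_that("corrupt VOF files fail loudly, never silently truncate", {
  path <- tempfile(fileext = ".vof")
  set.seed(7)
  write_vof(random_vof(50), path)
  bytes <- readBin(path, "raw", file.size(path))

  bad <- tempfile(); writeBin(bytes[1:30], bad)
  expect_condition_class(read_vof(bad), "readmask_format_error")

  bad2 <- tempfile(); writeBin(c(as.raw(c(0x56, 0x4F, 0x46, 0x02)), bytes[-(1:4)]), bad2)
  expect_condition_class(read_vof(bad2), "readmask_format_error")

  plain <- tempfile(); writeLines("not a vof", plain)
  expect_condition_class(read_vof(plain), "readmask_format_error")
})

test_that("query_site returns each entry at its coordinates and NULL elsewhere", {
  set.seed(9)
  tab <- random_vof(200)
  for (i in seq_along(tab$entries)) {
    e <- tab$entries[[i]]
    expect_identical(query_site(tab, e$contig, e$position), e)
  }
  expect_null(query_site(tab, "c1", max(tab$position) + 5L))
  expect_null(query_site(tab, "absent-contig", 0L))
})

test_that("TSV debug dump is written with one row per site", {
  set.seed(1)
  tab <- random_vof(25)
  path <- tempfile(fileext = ".tsv")
  write_vof_tsv(tab, path)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_identical(nrow(df), 25L)
  expect_identical(df$position, tab$position)
})
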