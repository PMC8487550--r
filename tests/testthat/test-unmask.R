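test_that("full unmasking restores the original file record-for-record", {
  fx <- small_masked_fixture(seed = 47, mask_seed = 53, error_rate = 0.005)
  restored <- unmask_alignments(fx$alignments, fx$bdiff)
  expect_identical(restored$records, fx$aln$records)
  expect_identical(restored$header, fx$aln$header)
})

test_that("an empty diff leaves the masked input unchanged", {
  fx <- small_masked_fixture()
  empty <- bdiff_document(fx$bdiff$header, list())
  out <- unmask_alignments(fx$alignments, empty)
  expect_identical(out$records, fx$alignments$records)
})

test_that("range-restricted unmasking restores exactly the in-range sites", {
  fx <- small_masked_fixture(seed = 59, mask_seed = 61)
  mid <- 2500L
  part <- unmask_alignments(fx$alignments, fx$bdiff,
                            contig = "sim1", start = 0L, end = mid)
  for (i in seq_along(fx$bdiff$records)) {
    r <- fx$bdiff$records[[i]]
    col <- pileup_column(part, "sim1", r$position)
    counted <- col$obs$base %in% c("A", "C", "G", "T")
    orig_col <- pileup_column(fx$aln, "sim1", r$position)
    masked_col <- pileup_column(fx$alignments, "sim1", r$position)
    if (r$position < mid) {
      expect_identical(col$obs$base, orig_col$obs$base,
                       info = paste("restored site", r$position))
    } else {
      expect_identical(col$obs$base, masked_col$obs$base,
                       info = paste("still-masked site", r$position))
    }
  }
})

test_that("re-applying the same range is idempotent", {
  fx <- small_masked_fixture(seed = 67, mask_seed = 71)
  once <- unmask_alignments(fx$alignments, fx$bdiff,
                            contig = "sim1", start = 1000L, end = 3000L)
  twice <- unmask_alignments(once, fx$bdiff, contig = "sim1",
                             start = 1000L, end = 3000L, verify = FALSE)
  expect_identical(twice$records, once$records)
})

test_that("checksum verification catches edits and reordering", {
  fx <- small_masked_fixture()
  expect_true(verify_masked_checksum(fx$alignments, fx$bdiff$header))

  edited <- fx$alignments
  substr(edited$records$seq[3], 5, 5) <- "N"
  expect_false(verify_masked_checksum(edited, fx$bdiff$header))
  expect_condition_class(unmask_alignments(edited, fx$bdiff),
                         "readmask_checksum_error")

  # permute two same-position records: content-equal, order-sensitive digest
  reordered <- fx$alignments
  pos <- reordered$records$pos
  dup <- which(duplicated(pos) | duplicated(pos, fromLast = TRUE))
  i <- dup[1]; j <- dup[which(pos[dup] == pos[i])[2]]
  reordered$records[c(i, j), ] <- reordered$records[c(j, i), ]
  expect_false(verify_masked_checksum(reordered, fx$bdiff$header))
})

test_that("a diff whose column length disagrees with the file is refused by site", {
  fx <- small_masked_fixture()
  doc <- fx$bdiff
  r1 <- doc$records[[1]]
  doc$records[[1]] <- bdiff_record(r1$contig, r1$position,
                                   c(r1$bases, "A"), c(r1$quals, 40L))
  err <- tryCatch(unmask_alignments(fx$alignments, doc),
                  condition = conditionMessage)
  expect_match(err, as.character(r1$position))
  expect_match(err, "mismatch")
})

test_that("a range outside the effective ranges is refused", {
  fx <- small_masked_fixture()
  expect_condition_class(
    unmask_alignments(fx$alignments, fx$bdiff, contig = "sim1",
                      start = 0L, end = 99999999L),
    "readmask_format_error")
  sliced <- slice_bdiff(fx$bdiff, "sim1", 0L, 1000L)
  expect_condition_class(
    unmask_alignments(fx$alignments, sliced, contig = "sim1",
                      start = 500L, end = 1500L),
    "readmask_format_error")
})

test_that("variant calls on original and fully unmasked files are identical", {
  fx <- small_masked_fixture(seed = 73, mask_seed = 79, error_rate = 0.005,
                             n_sites = 50L, contig_length = 8000L, depth = 25)
  restored <- unmask_alignments(fx$alignments, fx$bdiff)
  calls_orig <- naive_caller(fx$aln, fx$reference)
  calls_rest <- naive_caller(restored, fx$reference)
  expect_identical(calls_orig, calls_rest)
  expect_gt(nrow(calls_orig), 0L)
})

test_that("file-level pipeline round-trips through mask_bam/unmask_bam including concealment", {
  k <- .keys()
  td <- tempfile("pipe"); dir.create(td)
  ds <- simulate_dataset(sim_config(contig_length = 3000L, n_sites = 25L,
                                    depth = 15, n_unmapped = 4L), seed = 83)
  in_sam <- file.path(td, "in.sam"); write_alignments(ds$aln, in_sam)
  masked_sam <- file.path(td, "masked.sam")
  enc <- file.path(td, "d.bdiff.enc")
  out_sam <- file.path(td, "restored.sam")
  mask_bam(in_sam, ds$vof, masked_sam, enc, k$pub_a, k$priv_a, seed = 5,
           conceal_unmapped = TRUE)
  unmask_bam(masked_sam, enc, out_sam, k$priv_a, k$pub_a,
             reveal_unmapped = TRUE)
  expect_identical(readLines(out_sam), readLines(in_sam))
  # partial range through the file API (1-based inclusive region string)
  out2 <- file.path(td, "partial.sam")
  unmask_bam(masked_sam, enc, out2, k$priv_a, k$pub_a, range = "sim1:1-1500")
  expect_false(identical(readLines(out2), readLines(in_sam)))
})
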