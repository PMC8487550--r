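#' Verify that masked alignments match a BDIFF header checksum
#'
#' Recomputes the canonical digest of the alignment records and compares it
#' with the checksum stored when the file was masked. This ties a BDIFF
#' document to its masked file and detects any modification — including
#' record reordering, since order is part of the canonical serialization.
#'
#' @param aln masked `sam_file`.
#' @param header a `bdiff_header`.
#' @return `TRUE`/`FALSE`; pure, no side effects.
#' @export
verify_masked_checksum <- function(aln, header) {
  stopifnot(inherits(header, "bdiff_header"))
  identical(alignment_checksum(aln), header$checksum)
}

#' Restore original alignments from a masked file and a BDIFF document
#'
#' For each in-scope diff record, the pileup column of the masked file is
#' enumerated exactly as it was during masking (positions, flags and CIGARs
#' are untouched by masking, so the enumeration is identical) and each stored
#' original base and quality is written back by its position in the column.
#' Restoring by column order rather than read name keeps the format robust to
#' duplicate read names. Sites outside the requested range remain masked.
#'
#' @param aln masked `sam_file`.
#' @param doc a `bdiff_document` (already decrypted).
#' @param contig,start,end optional half-open 0-based range restriction;
#'   default restores everything. The range must lie within the document's
#'   effective ranges.
#' @param reveal_unmapped also reveal concealed unmapped reads (requires
#'   `secret`).
#' @param secret the container's 64-byte symmetric secret (only needed for
#'   `reveal_unmapped`).
#' @param verify verify the masked-file checksum first (default). Disable
#'   only when re-applying a range to an already partially restored file,
#'   which by construction no longer matches the checksum of the fully
#'   masked file.
#' @return the restored `sam_file`.
#' @export
unmask_alignments <- function(aln, doc, contig = NULL, start = 0L, end = NA,
                              reveal_unmapped = FALSE, secret = NULL,
                              verify = TRUE) {
  stopifnot(inherits(aln, "sam_file"), inherits(doc, "bdiff_document"))
  if (verify && !verify_masked_checksum(aln, doc$header)) {
    stop_checksum("masked alignments do not match the BDIFF header checksum")
  }
  eff <- doc$header$effective_ranges
  if (is.null(contig)) {
    keep <- rep(TRUE, length(doc$records))
  } else {
    if (is.na(end)) {
      on_ctg <- eff$end[eff$contig == contig]
      end <- if (length(on_ctg)) max(on_ctg) else start
    }
    covered <- intersect_ranges(
      data.frame(contig = contig, start = as.integer(start),
                 end = as.integer(end), stringsAsFactors = FALSE), eff)
    span <- sum(covered$end - covered$start)
    if (span < (as.integer(end) - as.integer(start))) {
      stop_format("requested range extends outside the document's effective ranges")
    }
    keep <- doc$contig == contig & doc$position >= start & doc$position < end
  }
  records <- aln$records
  sites <- data.frame(contig = doc$contig[keep],
                      position = doc$position[keep],
                      stringsAsFactors = FALSE)
  recs_in_scope <- doc$records[keep]
  idx <- pileup_index(records, sites)
  for (si in seq_along(recs_in_scope)) {
    r <- recs_in_scope[[si]]
    column <- column_from_rows(records, idx[[si]], r$contig, r$position)
    obs <- column$obs[column$obs$base %in% BASES, , drop = FALSE]
    if (nrow(obs) != length(r$bases)) {
      stop_format(sprintf(
        "column at %s:%d has %d counted observations but the diff stores %d (file/document mismatch)",
        r$contig, r$position, nrow(obs), length(r$bases)))
    }
    for (k in seq_len(nrow(obs))) {
      i <- obs$row[k]; qi <- obs$qidx[k]
      substr(records$seq[i], qi, qi) <- r$bases[k]
      substr(records$qual[i], qi, qi) <- intToUtf8(r$quals[k] + PHRED_OFFSET)
    }
  }
  out <- structure(list(header = aln$header, records = records),
                   class = "sam_file")
  if (reveal_unmapped) {
    if (!doc$header$concealed_unmapped) {
      stop_format("document does not mark unmapped reads as concealed")
    }
    if (is.null(secret)) stop_config("reveal_unmapped requires the container secret")
    out <- reveal_unmapped_reads(out, secret[1:32])
  }
  out
}

#' End-to-end file pipelines
#'
#' `mask_bam()` masks a SAM/BAM against a VOF table and writes the masked
#' file plus an encrypted BDIFF container; `unmask_bam()` decrypts, verifies
#' and restores. These are the operations the command-line interface exposes;
#' the underlying steps are available individually.
#'
#' @param bam_in,bam_out,masked_bam,restored_out SAM/BAM paths.
#' @param vof a `vof_table` or path to a `.vof` file.
#' @param bdiff_out,bdiff_in encrypted-container path (`.bdiff.enc`).
#' @param recipient_pub,signer_priv,recipient_priv,signer_pub PEM key paths
#'   or openssl key objects.
#' @param seed master masking seed.
#' @param range optional `"contig:start-end"` (1-based inclusive) region.
#' @param conceal_unmapped,reveal_unmapped toggle the unmapped-read layer.
#' @param ... passed to [mask_alignments()].
#' @return `mask_bam()` returns the [mask_alignments()] result invisibly;
#'   `unmask_bam()` the restored `sam_file` invisibly.
#' @export
mask_bam <- function(bam_in, vof, bam_out, bdiff_out, recipient_pub,
                     signer_priv, seed, conceal_unmapped = FALSE, ...) {
  if (is.character(vof)) vof <- read_vof(vof)
  if (is.character(recipient_pub)) recipient_pub <- load_public_key(recipient_pub)
  if (is.character(signer_priv)) signer_priv <- load_private_key(signer_priv)
  aln <- read_alignments(bam_in)
  res <- mask_alignments(aln, vof, seed = seed, ...)
  secret <- openssl::rand_bytes(64)
  if (conceal_unmapped) {
    res$alignments <- conceal_unmapped_reads(res$alignments, secret[1:32])
    res$bdiff$header$concealed_unmapped <- TRUE
    res$bdiff$header$checksum <- alignment_checksum(res$alignments)
  }
  write_alignments(res$alignments, bam_out)
  container <- encrypt_container(serialize_bdiff(res$bdiff), recipient_pub,
                                 signer_priv, secret = secret)
  write_container(container, bdiff_out)
  invisible(res)
}

#' @rdname mask_bam
#' @export
unmask_bam <- function(masked_bam, bdiff_in, restored_out, recipient_priv,
                       signer_pub, range = NULL, reveal_unmapped = FALSE) {
  if (is.character(recipient_priv)) recipient_priv <- load_private_key(recipient_priv)
  if (is.character(signer_pub)) signer_pub <- load_public_key(signer_pub)
  container <- read_container(bdiff_in)
  pt <- decrypt_container(container, recipient_priv, signer_pub)
  doc <- deserialize_bdiff(pt)
  aln <- read_alignments(masked_bam)
  rg <- if (is.null(range)) list(contig = NULL, start = 0L, end = NA) else
    parse_region(range)
  secret <- if (reveal_unmapped) container_secret(container, recipient_priv)
  restored <- unmask_alignments(aln, doc, contig = rg$contig, start = rg$start,
                                end = rg$end, reveal_unmapped = reveal_unmapped,
                                secret = secret)
  write_alignments(restored, restored_out)
  invisible(restored)
}
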