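#' BDIFF building blocks
#'
#' A BDIFF document is the complete difference between an original and a
#' masked alignment file: per processed site, the original base and quality
#' of every counted observation, in pileup-column order; plus a header with a
#' checksum of the masked file, the effective genomic ranges the document is
#' valid for, and the masking parameters, making the file self-describing.
#'
#' @param contig contig name.
#' @param position 0-based site position.
#' @param bases original bases, one per counted observation, column order.
#' @param quals original integer Phred qualities, parallel to `bases`.
#' @return `bdiff_record()` returns a `bdiff_record`; `bdiff_header()` a
#'   `bdiff_header`; `bdiff_document()` a `bdiff_document`.
#' @name bdiff
NULL

#' @rdname bdiff
#' @export
bdiff_record <- function(contig, position, bases, quals) {
  if (length(bases) == 0L) stop_format("bdiff record must hold >= 1 observation")
  if (length(bases) != length(quals)) {
    stop_format("bases and qualities must be parallel")
  }
  structure(list(contig = as.character(contig), position = as.integer(position),
                 bases = as.character(bases), quals = as.integer(quals)),
            class = "bdiff_record")
}

#' @rdname bdiff
#' @param checksum hex SHA-256 digest of the masked alignment records.
#' @param effective_ranges data frame `contig/start/end`, 0-based half-open.
#' @param min_fraction,placeholder_qual,seed_fingerprint masking parameters
#'   recorded for self-description.
#' @param concealed_unmapped logical: were unmapped reads concealed.
#' @export
bdiff_header <- function(checksum, effective_ranges, min_fraction,
                         placeholder_qual, seed_fingerprint,
                         concealed_unmapped = FALSE) {
  stopifnot(is.data.frame(effective_ranges),
            all(c("contig", "start", "end") %in% names(effective_ranges)))
  structure(list(version = 1L,
                 checksum_algorithm = "sha256",
                 checksum = checksum,
                 effective_ranges = effective_ranges[c("contig", "start", "end")],
                 min_fraction = min_fraction,
                 placeholder_qual = as.integer(placeholder_qual),
                 seed_fingerprint = seed_fingerprint,
                 concealed_unmapped = isTRUE(concealed_unmapped)),
            class = "bdiff_header")
}

#' @rdname bdiff
#' @param header a `bdiff_header`.
#' @param records list of `bdiff_record`s (any order; sorted on construction).
#' @export
bdiff_document <- function(header, records = list()) {
  stopifnot(inherits(header, "bdiff_header"))
  for (r in records) stopifnot(inherits(r, "bdiff_record"))
  ctg <- vapply(records, `[[`, character(1), "contig")
  pos <- vapply(records, `[[`, integer(1), "position")
  o <- order(match(ctg, unique(ctg)), pos)
  records <- records[o]; ctg <- ctg[o]; pos <- pos[o]
  if (anyDuplicated(paste(ctg, pos))) {
    stop_format("duplicate site in BDIFF records")
  }
  structure(list(header = header, records = records,
                 contig = ctg, position = pos),
            class = "bdiff_document")
}

#' @export
print.bdiff_document <- function(x, ...) {
  cat(sprintf("<bdiff_document> %d site record(s), checksum %s..., %d effective range(s)\n",
              length(x$records), substr(x$header$checksum, 1, 12),
              nrow(x$header$effective_ranges)))
  invisible(x)
}

BDIFF_MAGIC <- as.raw(c(0x42, 0x44, 0x49, 0x46, 0x46, 0x01)) # "BDIFF\x01"

#' Serialize / deserialize a BDIFF document
#'
#' Byte layout: magic `BDIFF\x01`; a length-prefixed JSON header; per-contig
#' blocks of records with positions delta-encoded within the block. Every
#' record must lie inside one of the header's effective ranges, which is
#' enforced on write and re-checked on read.
#'
#' @param doc a `bdiff_document`.
#' @return `serialize_bdiff()` returns a raw vector; `deserialize_bdiff()` the
#'   reconstructed `bdiff_document`.
#' @export
serialize_bdiff <- function(doc) {
  stopifnot(inherits(doc, "bdiff_document"))
  check_records_in_ranges(doc)
  con <- rawConnection(raw(0), "wb"); on.exit(close(con), add = TRUE)
  writeBin(BDIFF_MAGIC, con)
  hdr <- doc$header
  hjson <- charToRaw(jsonlite::toJSON(list(
    version = hdr$version,
    checksum_algorithm = hdr$checksum_algorithm,
    checksum = hdr$checksum,
    effective_ranges = hdr$effective_ranges,
    min_fraction = hdr$min_fraction,
    placeholder_qual = hdr$placeholder_qual,
    seed_fingerprint = hdr$seed_fingerprint,
    concealed_unmapped = hdr$concealed_unmapped
  ), auto_unbox = TRUE, digits = NA))
  writeBin(length(hjson), con, size = 4, endian = "little")
  writeBin(hjson, con)
  ctgs <- unique(doc$contig)
  writeBin(length(ctgs), con, size = 4, endian = "little")
  for (ct in ctgs) {
    rows <- which(doc$contig == ct)
    ctr <- charToRaw(ct)
    writeBin(length(ctr), con, size = 4, endian = "little")
    writeBin(ctr, con)
    writeBin(length(rows), con, size = 4, endian = "little")
    last <- 0L
    for (i in rows) {
      r <- doc$records[[i]]
      writeBin(r$position - last, con, size = 4, endian = "little")
      last <- r$position
      writeBin(length(r$bases), con, size = 4, endian = "little")
      writeBin(charToRaw(paste(r$bases, collapse = "")), con)
      writeBin(as.raw(r$quals), con)
    }
  }
  rawConnectionValue(con)
}

#' @rdname serialize_bdiff
#' @param bytes raw vector produced by `serialize_bdiff()`.
#' @export
deserialize_bdiff <- function(bytes) {
  con <- rawConnection(bytes, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", n = length(BDIFF_MAGIC))
  if (length(magic) < length(BDIFF_MAGIC) || !identical(magic, BDIFF_MAGIC)) {
    stop_format("not a BDIFF payload (bad magic)")
  }
  hlen <- read_i32(con, "BDIFF header length")
  hraw <- readBin(con, "raw", n = hlen)
  if (length(hraw) < hlen) stop_format("truncated BDIFF header")
  h <- jsonlite::fromJSON(rawToChar(hraw))
  if (!identical(as.integer(h$version), 1L)) {
    stop_format(sprintf("unsupported BDIFF version %s", h$version))
  }
  eff <- as.data.frame(h$effective_ranges, stringsAsFactors = FALSE)
  if (nrow(eff) == 0L) {
    eff <- data.frame(contig = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  eff$start <- as.integer(eff$start); eff$end <- as.integer(eff$end)
  header <- bdiff_header(h$checksum, eff, h$min_fraction,
                         h$placeholder_qual, h$seed_fingerprint,
                         h$concealed_unmapped)
  n_ctg <- read_i32(con, "BDIFF contig count")
  records <- list()
  for (ci in seq_len(n_ctg)) {
    ct <- read_lp_string(con)
    n <- read_i32(con, "BDIFF record count")
    last <- 0L
    for (i in seq_len(n)) {
      delta <- read_i32(con, "BDIFF position delta")
      if (i > 1L && delta <= 0L) stop_format("BDIFF records out of order")
      pos <- last + delta; last <- pos
      k <- read_i32(con, "BDIFF observation count")
      bb <- readBin(con, "raw", n = k)
      qq <- readBin(con, "raw", n = k)
      if (length(bb) < k || length(qq) < k) stop_format("truncated BDIFF record")
      records[[length(records) + 1L]] <-
        bdiff_record(ct, pos, strsplit(rawToChar(bb), "")[[1]], as.integer(qq))
    }
  }
  if (length(readBin(con, "raw", n = 1)) != 0L) {
    stop_format("trailing bytes after BDIFF records")
  }
  doc <- bdiff_document(header, records)
  check_records_in_ranges(doc)
  doc
}

check_records_in_ranges <- function(doc) {
  eff <- doc$header$effective_ranges
  for (i in seq_along(doc$records)) {
    if (!point_in_ranges(doc$contig[i], doc$position[i], eff)) {
      stop_format(sprintf("BDIFF record %s:%d outside the effective ranges",
                          doc$contig[i], doc$position[i]))
    }
  }
  invisible(TRUE)
}

#' Slice a BDIFF document to a genomic range
#'
#' Retains the records whose position falls inside the half-open query
#' interval and narrows the header's effective ranges to the intersection of
#' the old ranges with the query; checksum and masking parameters are copied
#' unchanged, so the slice still verifies against the same masked file. A
#' range that intersects nothing yields an empty but valid document. Slicing
#' composes: slicing by `r1` then `r2` equals slicing by their intersection.
#'
#' @param doc a `bdiff_document`.
#' @param contig contig name.
#' @param start,end 0-based half-open interval; `end = NA` means the contig
#'   end as bounded by the current effective ranges.
#' @return the sliced `bdiff_document`.
#' @export
slice_bdiff <- function(doc, contig, start = 0L, end = NA) {
  stopifnot(inherits(doc, "bdiff_document"))
  eff <- doc$header$effective_ranges
  if (is.na(end)) {
    on_ctg <- eff$end[eff$contig == contig]
    end <- if (length(on_ctg)) max(on_ctg) else start
  }
  start <- as.integer(start); end <- as.integer(end)
  if (end < start) stop_format("slice range must have start <= end")
  query <- data.frame(contig = contig, start = start, end = end,
                      stringsAsFactors = FALSE)
  new_eff <- intersect_ranges(eff, query)
  keep <- doc$contig == contig & doc$position >= start & doc$position < end
  hdr <- doc$header
  hdr$effective_ranges <- new_eff
  bdiff_document(hdr, doc$records[keep])
}

#' Dump a BDIFF document as TSV (debug aid)
#'
#' @param doc a `bdiff_document`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bdiff_tsv <- function(doc, path) {
  df <- data.frame(
    contig = doc$contig, position = doc$position,
    bases = vapply(doc$records, function(r) paste(r$bases, collapse = ""),
                   character(1)),
    quals = vapply(doc$records, function(r) paste(r$quals, collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
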