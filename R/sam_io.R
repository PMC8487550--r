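#' Read alignments from a SAM or BAM file
#'
#' Alignments are held in memory as a `sam_file` object: the verbatim header
#' lines plus a data frame with one row per record and the eleven mandatory
#' SAM columns (optional tags are kept as a single tab-joined string). Keeping
#' records verbatim is what makes masking exactly reversible: every field that
#' the masking step does not touch round-trips byte-for-byte.
#'
#' BAM input is converted through [Rsamtools::asSam()] at the file boundary;
#' everything downstream works on the text representation.
#'
#' @param path path to a `.sam` (or `.bam`, if Rsamtools is installed) file.
#' @return a `sam_file` object: `list(header = character(), records = data.frame)`.
#' @seealso [write_alignments()], [mask_alignments()]
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop_format("BAM input requires the Rsamtools package")
    }
    tmp <- tempfile(fileext = "")
    sam <- Rsamtools::asSam(path, tmp)
    on.exit(unlink(sam), add = TRUE)
    path <- sam
  }
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "@")
  n_hdr <- if (any(!is_hdr)) which(!is_hdr)[1] - 1L else length(lines)
  header <- lines[seq_len(n_hdr)]
  body <- lines[-seq_len(n_hdr)]
  body <- body[nzchar(body)]
  if (length(body) && any(startsWith(body, "@"))) {
    stop_format("header line found after first alignment record")
  }
  records <- parse_sam_records(body)
  structure(list(header = header, records = records), class = "sam_file")
}

parse_sam_records <- function(lines) {
  n <- length(lines)
  if (n == 0L) return(empty_sam_records())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    stop_format(sprintf("truncated SAM record on line with %d fields", min(nf)))
  }
  tags <- vapply(parts, function(p) {
    if (length(p) > 11L) paste(p[-(1:11)], collapse = "\t") else ""
  }, character(1))
  f <- function(i) vapply(parts, `[[`, character(1), i)
  data.frame(
    qname = f(1), flag = as.integer(f(2)), rname = f(3),
    pos = as.integer(f(4)), mapq = as.integer(f(5)), cigar = f(6),
    rnext = f(7), pnext = as.integer(f(8)), tlen = as.integer(f(9)),
    seq = f(10), qual = f(11), tags = tags,
    stringsAsFactors = FALSE
  )
}

empty_sam_records <- function() {
  data.frame(
    qname = character(), flag = integer(), rname = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    rnext = character(), pnext = integer(), tlen = integer(),
    seq = character(), qual = character(), tags = character(),
    stringsAsFactors = FALSE
  )
}

# Canonical per-record text lines; also the digest input for the masked-file
# checksum, so the serialization must be stable across read/write cycles.
sam_record_lines <- function(records) {
  if (nrow(records) == 0L) return(character())
  base <- paste(records$qname, records$flag, records$rname, records$pos,
                records$mapq, records$cigar, records$rnext, records$pnext,
                records$tlen, records$seq, records$qual, sep = "\t")
  ifelse(nzchar(records$tags), paste(base, records$tags, sep = "\t"), base)
}

#' Write alignments to a SAM or BAM file
#'
#' @param aln a `sam_file` object.
#' @param path output path; a `.bam` suffix triggers conversion through
#'   [Rsamtools::asBam()].
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  stopifnot(inherits(aln, "sam_file"))
  to_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  sam_path <- if (to_bam) tempfile(fileext = ".sam") else path
  writeLines(c(aln$header, sam_record_lines(aln$records)), sam_path)
  if (to_bam) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop_format("BAM output requires the Rsamtools package")
    }
    on.exit(unlink(sam_path), add = TRUE)
    Rsamtools::asBam(sam_path, sub("\\.bam$", "", path, ignore.case = TRUE),
                     overwrite = TRUE, indexDestination = TRUE)
  }
  invisible(path)
}

#' @export
print.sam_file <- function(x, ...) {
  cat(sprintf("<sam_file> %d header lines, %d records, contigs: %s\n",
              length(x$header), nrow(x$records),
              paste(names(contig_lengths(x)), collapse = ", ")))
  invisible(x)
}

# Contig name -> length map from @SQ header lines.
contig_lengths <- function(aln) {
  sq <- aln$header[startsWith(aln$header, "@SQ")]
  if (length(sq) == 0L) return(setNames(integer(), character()))
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  setNames(ln, sn)
}

is_mapped <- function(records) {
  bitwAnd(records$flag, 4L) == 0L & records$rname != "*" & records$cigar != "*"
}

# Unique key for one read observation: name + pair-of-mate flag bits +
# alignment start, per the pileup-column contract.
read_keys <- function(records, rows) {
  pairbits <- bitwAnd(records$flag[rows], bitwOr(64L, 128L))
  paste(records$qname[rows], pairbits, records$pos[rows], sep = "/")
}

# Assert coordinate order (non-decreasing pos within each contig block).
check_sorted <- function(records) {
  m <- which(is_mapped(records))
  if (length(m) < 2L) return(invisible(TRUE))
  rn <- records$rname[m]; po <- records$pos[m]
  same <- rn[-1] == rn[-length(rn)]
  if (any(same & po[-1] < po[-length(po)])) {
    stop_format("input alignments are not coordinate-sorted")
  }
  blocks <- rle(rn)$values
  if (anyDuplicated(blocks)) {
    stop_format("input alignments are not coordinate-sorted (contig blocks interleaved)")
  }
  invisible(TRUE)
}

#' Checksum of masked alignment records
#'
#' SHA-256 over the canonical uncompressed serialization of the alignment
#' records (header lines excluded), so that re-compression or header edits do
#' not break verification while any change to a record — including reordering —
#' does.
#'
#' @param aln a `sam_file` object.
#' @return hex digest string.
#' @export
alignment_checksum <- function(aln) {
  stopifnot(inherits(aln, "sam_file"))
  payload <- charToRaw(paste(sam_record_lines(aln$records), collapse = "\n"))
  hex_digest(openssl::sha256(payload))
}
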