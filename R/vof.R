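#' Construct a population variant
#'
#' One genomic site with its full single-base allele set and population
#' frequencies. The first allele is the reference allele; its frequency is the
#' complement of the summed alternative-allele frequencies, so the vector sums
#' to one. Alternative alleles are kept in lexicographic order so that merging
#' and diffing are deterministic.
#'
#' @param contig contig name.
#' @param position 0-based position.
#' @param alleles character vector of distinct single bases (`A/C/G/T`),
#'   reference first.
#' @param frequencies numeric vector parallel to `alleles`, summing to 1.
#' @return a `population_variant` object.
#' @export
population_variant <- function(contig, position, alleles, frequencies) {
  alleles <- as.character(alleles)
  frequencies <- as.numeric(frequencies)
  if (length(alleles) < 2L || length(alleles) != length(frequencies)) {
    stop_format("need >= 2 alleles with parallel frequencies")
  }
  if (anyDuplicated(alleles) || !all(alleles %in% BASES)) {
    stop_format("alleles must be distinct single bases A/C/G/T")
  }
  if (any(frequencies < 0) || any(frequencies > 1) ||
      abs(sum(frequencies) - 1) > 1e-9) {
    stop_format("frequencies must lie in [0,1] and sum to 1 (tolerance 1e-9)")
  }
  # canonical order: reference first, then alts lexicographically
  o <- order(alleles[-1])
  structure(list(contig = as.character(contig), position = as.integer(position),
                 alleles = c(alleles[1], alleles[-1][o]),
                 frequencies = c(frequencies[1], frequencies[-1][o])),
            class = "population_variant")
}

#' @export
print.population_variant <- function(x, ...) {
  cat(sprintf("<population_variant> %s:%d  %s\n", x$contig, x$position,
              paste(sprintf("%s=%.4g", x$alleles, x$frequencies), collapse = " ")))
  invisible(x)
}

#' Construct a population variant-frequency table (VOF)
#'
#' @param entries list of [population_variant()] objects.
#' @param contigs declared contig order; defaults to order of first appearance.
#' @return a `vof_table` (entries sorted by declared contig order, then
#'   position; at most one entry per site).
#' @export
vof_table <- function(entries = list(), contigs = NULL) {
  stopifnot(is.list(entries))
  for (e in entries) stopifnot(inherits(e, "population_variant"))
  ctg <- vapply(entries, `[[`, character(1), "contig")
  pos <- vapply(entries, `[[`, integer(1), "position")
  if (is.null(contigs)) contigs <- unique(ctg)
  if (!all(ctg %in% contigs)) stop_format("entry contig not in declared contig list")
  o <- order(match(ctg, contigs), pos)
  entries <- entries[o]; ctg <- ctg[o]; pos <- pos[o]
  if (anyDuplicated(paste(ctg, pos))) {
    stop_format("duplicate (contig, position) entries; merge as multiallelic first")
  }
  structure(list(contigs = contigs, entries = entries,
                 contig = ctg, position = pos),
            class = "vof_table")
}

#' @export
print.vof_table <- function(x, ...) {
  cat(sprintf("<vof_table> %d sites on %d contig(s)\n",
              length(x$entries), length(x$contigs)))
  invisible(x)
}

#' @export
length.vof_table <- function(x) length(x$entries)

#' Build a VOF table from a sites VCF
#'
#' Keeps only `FILTER == PASS` biallelic-by-record SNV lines (single-base REF
#' and ALT), merges lines at the same site into one multiallelic entry, and
#' sets the reference-allele frequency to the complement of the summed
#' alternative frequencies. VCF 1-based coordinates are converted to the
#' package's 0-based convention here, at the reader boundary.
#'
#' @param vcf_path path to a VCF (plain or bgzip) carrying an allele-frequency
#'   INFO field.
#' @param regions optional data frame `contig/start/end` (0-based half-open);
#'   sites outside are dropped. See [read_bed()].
#' @param af_field INFO field holding alternative allele frequencies
#'   (comma-separated for multiallelic lines). Default `"AF"`.
#' @return a `vof_table`.
#' @export
build_vof <- function(vcf_path, regions = NULL, af_field = "AF") {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(vof_table())
  af_raw <- vcfR::extract.info(v, element = af_field)
  recs <- data.frame(
    contig = fix$CHROM, pos0 = as.integer(fix$POS) - 1L,
    ref = fix$REF, alt = fix$ALT,
    pass = !is.na(fix$FILTER) & fix$FILTER == "PASS",
    af = af_raw, stringsAsFactors = FALSE
  )
  build_vof_from_records(recs, regions = regions, af_field = af_field)
}

# `recs`: contig, pos0, ref, alt (comma-separated), pass, af (comma-separated).
# Separated from the VCF reader so merging logic is testable on bare records.
build_vof_from_records <- function(recs, regions = NULL, af_field = "AF") {
  snv <- nchar(recs$ref) == 1L & recs$ref %in% BASES &
    grepl("^[ACGT](,[ACGT])*$", recs$alt)
  keep <- recs$pass & snv
  recs <- recs[keep, , drop = FALSE]
  if (!is.null(regions) && nrow(recs) > 0L) {
    inside <- vapply(seq_len(nrow(recs)), function(i) {
      point_in_ranges(recs$contig[i], recs$pos0[i], regions)
    }, logical(1))
    recs <- recs[inside, , drop = FALSE]
  }
  if (nrow(recs) == 0L) return(vof_table())

  missing_af <- is.na(recs$af) | recs$af == "" | recs$af == "."
  if (any(missing_af)) {
    i <- which(missing_af)[1]
    stop_format(sprintf("record %s:%d %s>%s lacks INFO field '%s'",
                        recs$contig[i], recs$pos0[i] + 1L, recs$ref[i],
                        recs$alt[i], af_field))
  }

  key <- paste(recs$contig, recs$pos0)
  entries <- lapply(split(seq_len(nrow(recs)), factor(key, levels = unique(key))),
                    function(rows) {
    g <- recs[rows, , drop = FALSE]
    if (length(unique(g$ref)) != 1L) {
      stop_format(sprintf("conflicting REF bases at %s:%d",
                          g$contig[1], g$pos0[1] + 1L))
    }
    alts <- unlist(strsplit(g$alt, ",", fixed = TRUE))
    afs <- as.numeric(unlist(strsplit(g$af, ",", fixed = TRUE)))
    if (length(alts) != length(afs) || anyNA(afs)) {
      stop_format(sprintf("AF count does not match ALT count at %s:%d",
                          g$contig[1], g$pos0[1] + 1L))
    }
    # same alt listed twice across merged lines: sum its frequency
    afs <- tapply(afs, factor(alts, levels = unique(alts)), sum)
    alts <- unique(alts)
    drop_ref <- alts == g$ref[1]
    if (any(drop_ref)) { afs <- afs[!drop_ref]; alts <- alts[!drop_ref] }
    tot <- sum(afs)
    if (tot > 1 + 1e-6) {
      stop_format(sprintf("summed alt AF %.8g > 1 at %s:%d (corrupt input)",
                          tot, g$contig[1], g$pos0[1] + 1L))
    }
    ref_freq <- min(1, max(0, 1 - tot))
    population_variant(g$contig[1], g$pos0[1],
                       c(g$ref[1], alts), c(ref_freq, afs))
  })
  vof_table(unname(entries), contigs = unique(recs$contig))
}

#' Read a BED file of regions
#'
#' @param path BED path (0-based half-open, first three columns used).
#' @return data frame with `contig`, `start`, `end`.
#' @export
read_bed <- function(path) {
  b <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  data.frame(contig = as.character(b[[1]]), start = as.integer(b[[2]]),
             end = as.integer(b[[3]]), stringsAsFactors = FALSE)
}

#' Query a VOF table at one site
#'
#' Binary search over the sorted entry list.
#'
#' @param table a `vof_table`.
#' @param contig contig name.
#' @param position 0-based position.
#' @return the `population_variant` at that site, or `NULL` if absent.
#' @export
query_site <- function(table, contig, position) {
  stopifnot(inherits(table, "vof_table"))
  idx <- which(table$contig == contig)
  if (length(idx) == 0L) return(NULL)
  pos <- table$position[idx]
  j <- findInterval(position, pos)
  if (j >= 1L && pos[j] == position) table$entries[[idx[j]]] else NULL
}

VOF_MAGIC <- as.raw(c(0x56, 0x4F, 0x46, 0x01)) # "VOF\x01"

#' Serialize / deserialize a VOF table
#'
#' Binary dialect: 4-byte magic `VOF\x01`, a format-version integer, the
#' declared contig list, then per-contig blocks of entries with little-endian
#' 32-bit positions. [write_vof_tsv()] writes a human-readable debug dump.
#'
#' @param table a `vof_table`.
#' @param path file path.
#' @return `read_vof()` returns a `vof_table`; writers return `path` invisibly.
#' @export
write_vof <- function(table, path) {
  stopifnot(inherits(table, "vof_table"))
  con <- file(path, "wb"); on.exit(close(con), add = TRUE)
  writeBin(VOF_MAGIC, con)
  writeBin(1L, con, size = 4, endian = "little")
  write_lp_string <- function(s) {
    r <- charToRaw(s)
    writeBin(length(r), con, size = 4, endian = "little")
    writeBin(r, con)
  }
  writeBin(length(table$contigs), con, size = 4, endian = "little")
  for (ct in table$contigs) write_lp_string(ct)
  for (ci in seq_along(table$contigs)) {
    rows <- which(table$contig == table$contigs[ci])
    writeBin(length(rows), con, size = 4, endian = "little")
    for (i in rows) {
      e <- table$entries[[i]]
      writeBin(e$position, con, size = 4, endian = "little")
      writeBin(length(e$alleles), con, size = 4, endian = "little")
      writeBin(charToRaw(paste(e$alleles, collapse = "")), con)
      writeBin(e$frequencies, con, size = 8, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_vof
#' @export
read_vof <- function(path) {
  con <- file(path, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", n = 4)
  if (length(magic) < 4L || !identical(magic, VOF_MAGIC)) {
    stop_format("not a VOF file (bad magic)")
  }
  ver <- read_i32(con, "VOF version")
  if (ver != 1L) stop_format(sprintf("unsupported VOF version %d", ver))
  n_ctg <- read_i32(con, "VOF contig count")
  contigs <- vapply(seq_len(n_ctg), function(i) read_lp_string(con), character(1))
  entries <- list()
  for (ci in seq_len(n_ctg)) {
    n <- read_i32(con, "VOF entry count")
    last_pos <- -1L
    for (i in seq_len(n)) {
      pos <- read_i32(con, "VOF position")
      if (pos <= last_pos) stop_format("VOF entries out of order on read")
      last_pos <- pos
      k <- read_i32(con, "VOF allele count")
      ab <- readBin(con, "raw", n = k)
      if (length(ab) < k) stop_format("truncated VOF file")
      fr <- readBin(con, "double", n = k, size = 8, endian = "little")
      if (length(fr) < k) stop_format("truncated VOF file")
      entries[[length(entries) + 1L]] <-
        population_variant(contigs[ci], pos,
                           strsplit(rawToChar(ab), "")[[1]], fr)
    }
  }
  vof_table(entries, contigs = contigs)
}

read_i32 <- function(con, what) {
  v <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(v) == 0L) stop_format(sprintf("truncated file while reading %s", what))
  v
}

read_lp_string <- function(con) {
  n <- read_i32(con, "string length")
  r <- readBin(con, "raw", n = n)
  if (length(r) < n) stop_format("truncated file while reading string")
  rawToChar(r)
}

#' @rdname write_vof
#' @export
write_vof_tsv <- function(table, path) {
  stopifnot(inherits(table, "vof_table"))
  df <- data.frame(
    contig = table$contig, position = table$position,
    alleles = vapply(table$entries, function(e) paste(e$alleles, collapse = ","),
                     character(1)),
    frequencies = vapply(table$entries,
                         function(e) paste(format(e$frequencies, digits = 10),
                                           collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
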