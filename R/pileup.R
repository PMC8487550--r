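CIGAR_RE <- "([0-9]+)([MIDNSHP=X])"

parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr(CIGAR_RE, cigar))[[1]]
  if (length(m) == 0L) stop_format(sprintf("cannot parse CIGAR '%s'", cigar))
  list(len = as.integer(sub(CIGAR_RE, "\\1", m)),
       op = sub(CIGAR_RE, "\\2", m))
}

# Locate the query offset holding the base aligned to reference position
# `pos0` (0-based) for a record starting at `start0` (0-based). Returns the
# 1-based query index, or NA for a deletion/skip (GAP), or NULL when the
# alignment does not cover the position. M/=/X consume both sequences, I/S
# consume the query only, D/N the reference only, H/P neither.
query_index_at <- function(cigar, start0, pos0) {
  cg <- parse_cigar(cigar)
  ref <- start0
  q <- 1L
  for (i in seq_along(cg$op)) {
    len <- cg$len[i]
    switch(cg$op[i],
      "M" = , "=" = , "X" = {
        if (pos0 < ref + len) {
          if (pos0 >= ref) return(q + (pos0 - ref))
          return(NULL)
        }
        ref <- ref + len; q <- q + len
      },
      "I" = , "S" = { q <- q + len },
      "D" = , "N" = {
        if (pos0 >= ref && pos0 < ref + len) return(NA_integer_)
        ref <- ref + len
      },
      "H" = , "P" = NULL
    )
    if (ref > pos0) break
  }
  NULL
}

new_pileup_column <- function(contig, position, obs) {
  structure(list(contig = contig, position = as.integer(position), obs = obs),
            class = "pileup_column")
}

empty_obs <- function() {
  data.frame(row = integer(), key = character(), base = character(),
             qual = integer(), qidx = integer(), stringsAsFactors = FALSE)
}

# Build one column given the record rows whose alignments span the position
# (row order == input record order, which fixes the observation order).
column_from_rows <- function(records, rows, contig, pos0) {
  if (length(rows) == 0L) return(new_pileup_column(contig, pos0, empty_obs()))
  base <- character(length(rows)); qual <- integer(length(rows))
  qidx <- integer(length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    qi <- query_index_at(records$cigar[i], records$pos[i] - 1L, pos0)
    if (is.null(qi)) { qidx[k] <- -1L; next }
    if (is.na(qi)) {
      base[k] <- "GAP"; qual[k] <- NA_integer_; qidx[k] <- NA_integer_
    } else {
      base[k] <- substr(records$seq[i], qi, qi)
      qual[k] <- utf8ToInt(substr(records$qual[i], qi, qi)) - 33L
      qidx[k] <- qi
    }
  }
  covered <- is.na(qidx) | qidx > 0L
  rows <- rows[covered]
  obs <- data.frame(row = rows, key = read_keys(records, rows),
                    base = base[covered], qual = qual[covered],
                    qidx = qidx[covered], stringsAsFactors = FALSE)
  new_pileup_column(contig, pos0, obs)
}

#' Extract the pileup column at one reference position
#'
#' Returns the ordered bases and base qualities of every read whose alignment
#' spans the position, resolved through the CIGAR string: aligned segments
#' (`M/=/X`) contribute the corresponding query base, deletions and reference
#' skips (`D/N`) contribute a `GAP` observation, and inserted or soft-clipped
#' query bases never land on a reference position. Observation order is the
#' record order of the coordinate-sorted input, which is what lets the diff
#' document address observations positionally.
#'
#' @param aln a `sam_file` object (coordinate-sorted).
#' @param contig contig name.
#' @param position 0-based reference position.
#' @return a `pileup_column`: `contig`, `position`, and an `obs` data frame
#'   with `key` (read name + pair flag + start), `base` (`A/C/G/T/N/GAP`) and
#'   `qual` (integer Phred, `NA` for GAP).
#' @export
pileup_column <- function(aln, contig, position) {
  stopifnot(inherits(aln, "sam_file"))
  check_sorted(aln$records)
  idx <- pileup_index(aln$records,
                      data.frame(contig = contig, position = position,
                                 stringsAsFactors = FALSE))
  column_from_rows(aln$records, idx[[1]], contig, as.integer(position))
}

#' @export
print.pileup_column <- function(x, ...) {
  cat(sprintf("<pileup_column> %s:%d depth %d\n", x$contig, x$position,
              nrow(x$obs)))
  invisible(x)
}

# One findOverlaps pass mapping each site to the record rows spanning it.
# `sites`: data.frame(contig, position). Returns a list of integer row vectors
# (ascending == record order), one per site row.
pileup_index <- function(records, sites) {
  n_sites <- nrow(sites)
  out <- rep(list(integer()), n_sites)
  mrows <- which(is_mapped(records))
  if (length(mrows) == 0L || n_sites == 0L) return(out)
  widths <- GenomicAlignments::cigarWidthAlongReferenceSpace(records$cigar[mrows])
  reads_gr <- GenomicRanges::GRanges(
    records$rname[mrows],
    IRanges::IRanges(start = records$pos[mrows], width = widths))
  sites_gr <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(start = sites$position + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(sites_gr, reads_gr)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  sp <- split(mrows[s], q)
  for (nm in names(sp)) out[[as.integer(nm)]] <- sort(sp[[nm]])
  out
}
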