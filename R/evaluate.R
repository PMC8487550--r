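#' Filter variant call records on status, depth and quality
#'
#' Keeps high-confidence calls: `PASS` filter status (optional), total depth
#' strictly above `min_depth`, and quality strictly above `min_quality`. The
#' cutoffs are exclusive — a record at exactly the threshold is dropped.
#'
#' @param records data frame of call records with at least `depth`, `quality`
#'   and (if `require_pass`) `filter` columns (see [naive_caller()]).
#' @param min_depth depth cutoff (exclusive), default 30.
#' @param min_quality quality cutoff (exclusive), default 30.
#' @param require_pass drop records whose `filter != "PASS"`.
#' @return the retained rows.
#' @export
filter_calls <- function(records, min_depth = 30, min_quality = 30,
                         require_pass = TRUE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(records)
  keep <- records$depth > min_depth & records$quality > min_quality
  if (require_pass) keep <- keep & records$filter == "PASS"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify variant positions into the five masking categories
#'
#' Partitions the union of three position sets — population sites, variant
#' positions called on the personal file, and variant positions called on the
#' masked file — into: `not_found` (population sites with no personal or
#' masked variant), `masked` (personal variants erased by masking),
#' `not_masked` (personal variants still called after masking, possibly with
#' a different allele or zygosity), `introduced` (new variants created by
#' masking at covered population sites), and `not_covered` (personal variants
#' at sites absent from the population table, which masking cannot touch).
#'
#' @param personal,masked,population character or integer vectors of variant
#'   positions (use `"contig:pos"` keys for multi-contig data).
#' @return a `category_counts` list: per-category position vectors plus
#'   `counts`.
#' @export
classify_positions <- function(personal, masked, population) {
  personal <- unique(personal); masked <- unique(masked)
  population <- unique(population)
  sets <- list(
    not_found   = setdiff(population, union(personal, masked)),
    masked      = setdiff(intersect(personal, population), masked),
    not_masked  = intersect(personal, masked),
    introduced  = intersect(setdiff(masked, personal), population),
    not_covered = setdiff(personal, population)
  )
  structure(list(sets = sets,
                 counts = vapply(sets, length, integer(1)),
                 universe = length(unique(c(personal, masked, population)))),
            class = "category_counts")
}

#' @export
print.category_counts <- function(x, ...) {
  cat("<category_counts>\n")
  print(x$counts)
  invisible(x)
}

#' Masked/not-masked ratio by population allele frequency
#'
#' Buckets classified sites by their population alternative-allele frequency
#' and reports, per bin, the fraction of sites whose personal variant was
#' masked: `masked / (masked + not_masked)`. Rare alleles are expected to be
#' masked most often (the chance that both masking draws return the reference
#' is `(1 - q)^2` at total alternative frequency `q`), so the curve falls as
#' frequency rises. Empty bins are reported as `NA`, not zero.
#'
#' @param af numeric vector of population alt-allele frequencies, one per
#'   site.
#' @param masked logical vector: was the site's personal variant masked.
#' @param breaks bin breaks on `[0, 1]`.
#' @return data frame with `bin`, `n`, `n_masked`, `ratio`.
#' @export
masked_ratio_by_frequency <- function(af, masked,
                                      breaks = seq(0, 1, by = 0.1)) {
  stopifnot(length(af) == length(masked))
  bins <- cut(af, breaks = breaks, include.lowest = TRUE, right = FALSE)
  n <- tabulate(bins, nbins = nlevels(bins))
  nm <- vapply(seq_len(nlevels(bins)),
               function(i) sum(masked[!is.na(bins) & as.integer(bins) == i]),
               numeric(1))
  data.frame(bin = levels(bins), n = n, n_masked = nm,
             ratio = ifelse(n > 0, nm / n, NA_real_),
             stringsAsFactors = FALSE)
}

#' Histogram of alternative allele frequencies
#'
#' Frequency-spectrum table (exported as TSV by the CLI) comparing sources
#' such as the population table, personal calls, and masked calls.
#'
#' @param af numeric vector of allele frequencies.
#' @param breaks bin breaks on `[0, 1]`.
#' @return data frame with `bin` and `count`.
#' @export
af_histogram <- function(af, breaks = seq(0, 1, by = 0.05)) {
  bins <- cut(af, breaks = breaks, include.lowest = TRUE, right = FALSE)
  data.frame(bin = levels(bins),
             count = tabulate(bins, nbins = nlevels(bins)),
             stringsAsFactors = FALSE)
}

#' Minimal threshold variant caller
#'
#' A deliberately simple deterministic caller so the whole pipeline can be
#' exercised end-to-end without external tools: at every reference position
#' where a non-reference base reaches `min_fraction` of countable
#' observations, a record is emitted with the genotype determined by the same
#' fraction rule used for personal-allele calling. No likelihoods, no error
#' model; quality is a constant placeholder so filtering semantics stay
#' exercisable.
#'
#' @param aln coordinate-sorted `sam_file`.
#' @param reference named character vector (or single string for
#'   single-contig data) of reference sequences.
#' @param min_fraction allele fraction threshold, default 0.2.
#' @param min_depth minimum countable depth to consider a site, default 10.
#' @return data frame of call records: `contig`, `position` (0-based), `ref`,
#'   `alt` (comma-joined), `zygosity` (`HOM`/`HET`), `af` (fraction of the
#'   top alternative), `depth`, `quality`, `filter`.
#' @export
naive_caller <- function(aln, reference, min_fraction = 0.2, min_depth = 10) {
  stopifnot(inherits(aln, "sam_file"))
  check_sorted(aln$records)
  if (is.null(names(reference))) {
    cl <- contig_lengths(aln)
    if (length(cl) != 1L) {
      stop_format("unnamed reference requires single-contig alignments")
    }
    names(reference) <- names(cl)
  }
  records <- aln$records
  mrows <- which(is_mapped(records))
  out <- list()
  for (ct in unique(records$rname[mrows])) {
    if (!ct %in% names(reference)) {
      stop_format(sprintf("contig '%s' missing from the reference", ct))
    }
    rows <- mrows[records$rname[mrows] == ct]
    tal <- tally_mismatches(records, rows, reference[[ct]])
    cand <- tal$positions
    for (j in seq_along(cand)) {
      pos <- cand[j]
      counts <- tal$counts[j, ]
      depth <- sum(counts)
      if (depth < min_depth) next
      call <- call_from_counts(counts, min_fraction)
      if (!call$kind %in% c("HOM", "HET")) next
      refb <- substr(reference[[ct]], pos + 1L, pos + 1L)
      alts <- setdiff(unique(call$allele_pair), refb)
      if (length(alts) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        contig = ct, position = pos, ref = refb,
        alt = paste(alts, collapse = ","),
        zygosity = if (call$allele_pair[1] == call$allele_pair[2]) "HOM" else "HET",
        af = max(counts[alts]) / depth,
        depth = depth, quality = 60, filter = "PASS",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(), position = integer(),
                      ref = character(), alt = character(),
                      zygosity = character(), af = numeric(),
                      depth = integer(), quality = numeric(),
                      filter = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Vectorized mismatch scan for one contig: walks each read's aligned segments,
# compares query to reference, and accumulates per-position base counts at
# candidate (mismatch-bearing) positions. Countable depth per position comes
# from coverage minus deletions/skips minus N observations.
tally_mismatches <- function(records, rows, refseq) {
  mism_pos <- integer(0); mism_base <- character(0)
  starts <- integer(length(rows)); ends <- integer(length(rows))
  del_pos <- integer(0)
  for (k in seq_along(rows)) {
    i <- rows[k]
    cg <- parse_cigar(records$cigar[i])
    ref <- records$pos[i] - 1L  # 0-based
    q <- 1L
    starts[k] <- ref
    for (op_i in seq_along(cg$op)) {
      len <- cg$len[op_i]
      op <- cg$op[op_i]
      if (op %in% c("M", "=", "X")) {
        seg <- substr(records$seq[i], q, q + len - 1L)
        rseg <- substr(refseq, ref + 1L, ref + len)
        if (seg != rseg) {
          sb <- charToRaw(seg); rb <- charToRaw(rseg)
          d <- which(sb != rb)
          mism_pos <- c(mism_pos, ref + d - 1L)
          mism_base <- c(mism_base, rawToChar(sb[d], multiple = TRUE))
        }
        ref <- ref + len; q <- q + len
      } else if (op %in% c("I", "S")) {
        q <- q + len
      } else if (op %in% c("D", "N")) {
        del_pos <- c(del_pos, seq.int(ref, ref + len - 1L))
        ref <- ref + len
      }
    }
    ends[k] <- ref  # exclusive
  }
  cand <- sort(unique(mism_pos[mism_base %in% BASES]))
  if (length(cand) == 0L) {
    return(list(positions = integer(0),
                counts = matrix(0L, 0, 4, dimnames = list(NULL, BASES))))
  }
  # reads spanning each candidate: #(start <= p) - #(end <= p), via sorted
  # boundary arrays (the span includes D/N segments, excluded again below)
  cover <- findInterval(cand, sort(starts)) - findInterval(cand, sort(ends))
  del_tab <- table(del_pos)
  n_del <- as.integer(del_tab[as.character(cand)])
  n_del[is.na(n_del)] <- 0L
  keep <- mism_base %in% c(BASES, "N")
  mp <- mism_pos[keep]; mb <- mism_base[keep]
  ji <- factor(match(mp, cand), levels = seq_along(cand))
  n_n <- as.integer(table(ji[mb == "N"]))
  bi <- factor(match(mb, BASES), levels = 1:4)
  counts <- matrix(as.integer(table(ji, bi)), length(cand), 4,
                   dimnames = list(NULL, BASES))
  # remaining covering reads carry the reference base
  refb <- substring(refseq, cand + 1L, cand + 1L)
  ref_n <- pmax(0L, cover - n_del - n_n - rowSums(counts))
  ri <- match(refb, BASES)
  ok <- !is.na(ri)
  counts[cbind(which(ok), ri[ok])] <- counts[cbind(which(ok), ri[ok])] +
    ref_n[ok]
  list(positions = cand, counts = counts)
}

#' Position keys for call records
#'
#' Convenience for feeding [classify_positions()]: `"contig:position"` keys
#' of the records that carry an alternative allele.
#'
#' @param records a [naive_caller()]-style data frame.
#' @return character vector of keys.
#' @export
call_positions <- function(records) {
  if (nrow(records) == 0L) return(character())
  paste0(records$contig, ":", records$position)
}
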