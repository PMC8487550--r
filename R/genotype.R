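personal_call <- function(kind, allele_pair = NULL) {
  structure(list(kind = kind, allele_pair = allele_pair),
            class = "personal_call")
}

#' @export
print.personal_call <- function(x, ...) {
  cat(sprintf("<personal_call> %s%s\n", x$kind,
              if (is.null(x$allele_pair)) "" else
                paste0(" (", paste(x$allele_pair, collapse = "/"), ")")))
  invisible(x)
}

# Core genotyping rule on base counts (named vector over A/C/G/T). An allele
# is personal when its fraction of countable observations reaches
# `min_fraction`; exactly one such allele gives a homozygous pair, exactly two
# a heterozygous pair, more than two is ambiguous and the site is skipped.
call_from_counts <- function(counts, min_fraction) {
  total <- sum(counts)
  if (total == 0L) return(personal_call("UNCOVERED"))
  suff <- names(counts)[counts > 0 & counts / total >= min_fraction]
  if (length(suff) == 0L) return(personal_call("SKIP"))
  if (length(suff) == 1L) return(personal_call("HOM", c(suff, suff)))
  if (length(suff) > 2L) return(personal_call("SKIP"))
  # heterozygous: order by descending count, ties broken lexicographically
  o <- order(-counts[suff], suff)
  personal_call("HET", suff[o])
}

#' Determine the personal allele pair from a pileup column
#'
#' Counts the `A/C/G/T` observations in the column (`N` and `GAP`
#' observations are excluded) and applies a pure fraction threshold: a base is
#' "sufficiently represented" when its share of countable observations is at
#' least `min_fraction`. One sufficient base yields a homozygous call with the
#' allele duplicated; two yield a heterozygous call (ordered by descending
#' count, then alphabetically); more than two — or none, when coverage is
#' spread too thin — marks the site ambiguous (`SKIP`); an empty column is
#' `UNCOVERED`.
#'
#' @param column a `pileup_column`.
#' @param min_fraction representation threshold in `(0, 0.5]`; default 0.2.
#' @return a `personal_call`: `kind` in `HOM/HET/SKIP/UNCOVERED` plus the
#'   `allele_pair` for HOM/HET.
#' @export
call_personal_alleles <- function(column, min_fraction = 0.2) {
  stopifnot(inherits(column, "pileup_column"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 0.5) {
    stop_config("min_fraction must lie in (0, 0.5]")
  }
  counted <- column$obs$base[column$obs$base %in% BASES]
  counts <- setNames(tabulate(factor(counted, levels = BASES), nbins = 4L), BASES)
  call_from_counts(counts, min_fraction)
}
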