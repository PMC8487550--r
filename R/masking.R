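#' Draw a masking pair of alleles from the population distribution
#'
#' Two independent draws from the site's multinomial population allele
#' distribution. The pair is unordered for zygosity purposes but is returned
#' in draw order so a fixed RNG state reproduces it exactly. Draws come from
#' R's current RNG stream; [mask_alignments()] seeds a private per-site
#' substream before calling this.
#'
#' @param variant a [population_variant()].
#' @return character vector of two bases.
#' @export
sample_masking_pair <- function(variant) {
  stopifnot(inherits(variant, "population_variant"))
  # sample() with prob uses walker/inversion; two independent draws
  idx <- sample.int(length(variant$alleles), size = 2, replace = TRUE,
                    prob = variant$frequencies)
  variant$alleles[idx]
}

#' Plan the per-read base replacement at one site
#'
#' Maps every countable observation in the column to its masked target base.
#' Personal-allele observations are replaced by the masking pair: for a
#' heterozygous call the ordered personal pair maps slot-wise onto the masking
#' pair in draw order; for a homozygous call with an unequal masking pair each
#' observation independently gets either masking allele with probability 1/2,
#' which is what allows a homozygous site to become heterozygous after
#' masking. Remaining observations are sequencing/alignment errors and are
#' re-drawn uniformly from the bases outside the masking pair, so an edited
#' error base never collides with the masked genotype. `N` and `GAP`
#' observations are left untouched.
#'
#' @param column a `pileup_column`.
#' @param call a `personal_call` with kind `HOM` or `HET`.
#' @param pair masking pair from [sample_masking_pair()].
#' @return a `site_plan`: data frame with `row` (record row), `qidx` (query
#'   offset), `target` base, and the original `base`/`qual` per planned
#'   observation, in column order.
#' @export
plan_site_replacement <- function(column, call, pair) {
  stopifnot(inherits(column, "pileup_column"), inherits(call, "personal_call"))
  if (!call$kind %in% c("HOM", "HET")) {
    stop_config("plan_site_replacement requires a HOM or HET call")
  }
  obs <- column$obs
  counted <- obs$base %in% BASES
  obs <- obs[counted, , drop = FALSE]
  n <- nrow(obs)
  target <- character(n)
  personal <- call$allele_pair
  err_pool <- setdiff(BASES, unique(pair))
  for (k in seq_len(n)) {
    b <- obs$base[k]
    if (call$kind == "HET" && b == personal[1]) {
      target[k] <- pair[1]
    } else if (call$kind == "HET" && b == personal[2]) {
      target[k] <- pair[2]
    } else if (call$kind == "HOM" && b == personal[1]) {
      target[k] <- if (pair[1] == pair[2]) pair[1] else
        pair[sample.int(2L, 1L)]
    } else {
      # error observation: keep it off the masking pair when possible
      target[k] <- if (length(err_pool) == 0L) b else
        err_pool[sample.int(length(err_pool), 1L)]
    }
  }
  structure(
    data.frame(row = obs$row, qidx = obs$qidx, target = target,
               base = obs$base, qual = obs$qual, stringsAsFactors = FALSE),
    class = c("site_plan", "data.frame"),
    contig = column$contig, position = column$position)
}

PHRED_OFFSET <- 33L

apply_plan <- function(records, plan, placeholder_qual) {
  qchar <- intToUtf8(placeholder_qual + PHRED_OFFSET)
  for (k in seq_len(nrow(plan))) {
    i <- plan$row[k]; qi <- plan$qidx[k]
    substr(records$seq[i], qi, qi) <- plan$target[k]
    substr(records$qual[i], qi, qi) <- qchar
  }
  records
}

#' Mask personal alleles across a whole alignment file
#'
#' Single coordinated sweep over the sites of the population table. At every
#' site whose personal call is homozygous or heterozygous, a masking pair is
#' drawn from the population allele distribution, all countable observations
#' are rewritten per [plan_site_replacement()], the base qualities of those
#' observations are overwritten with one placeholder value (so the quality
#' pattern cannot reveal which bases were edited), and one diff record holding
#' the original bases and qualities in column order is appended. Ambiguous
#' (`SKIP`) and uncovered sites contribute nothing. Everything else in the
#' file — record order, flags, positions, CIGARs, tags — is preserved.
#'
#' Randomness is drawn from a per-site substream keyed by
#' `(seed, contig, position)`, so results are reproducible and independent of
#' traversal batching.
#'
#' @param aln coordinate-sorted `sam_file`.
#' @param vof a `vof_table` of population variants.
#' @param seed master seed (integer); required.
#' @param min_fraction personal-allele representation threshold, see
#'   [call_personal_alleles()].
#' @param placeholder_qual Phred value written over the qualities of counted
#'   observations at processed sites (default 60).
#' @param random_mask_rate optional per-base probability of additionally
#'   masking a covered non-table site with a uniform allele distribution
#'   (default 0 = off).
#' @return list with `alignments` (masked `sam_file`) and `bdiff`
#'   (a [bdiff_document()] whose header carries the masked-file checksum and
#'   whole-genome effective ranges).
#' @export
mask_alignments <- function(aln, vof, seed, min_fraction = 0.2,
                            placeholder_qual = 60L, random_mask_rate = 0) {
  stopifnot(inherits(aln, "sam_file"), inherits(vof, "vof_table"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop_config("mask_alignments requires a single integer seed")
  }
  seed <- as.integer(seed)
  check_sorted(aln$records)
  clens <- contig_lengths(aln)
  if (length(clens) == 0L) stop_format("input has no @SQ header lines")

  known <- vof$contig %in% names(clens)
  if (any(!known)) {
    warning(sprintf("skipping %d site(s) on contig(s) absent from alignment header: %s",
                    sum(!known), paste(unique(vof$contig[!known]), collapse = ", ")))
  }
  sites <- data.frame(contig = vof$contig[known],
                      position = vof$position[known],
                      entry = which(known), stringsAsFactors = FALSE)

  extra <- random_mask_sites(aln, vof, clens, seed, random_mask_rate)
  records <- aln$records
  rec_list <- vector("list", nrow(sites) + nrow(extra))
  n_rec <- 0L

  idx <- pileup_index(records, rbind(sites[c("contig", "position")],
                                     extra[c("contig", "position")]))
  n_vof <- nrow(sites)
  for (si in seq_len(n_vof + nrow(extra))) {
    rows <- idx[[si]]
    if (length(rows) == 0L) next
    if (si <= n_vof) {
      contig <- sites$contig[si]; pos <- sites$position[si]
      variant <- vof$entries[[sites$entry[si]]]
    } else {
      contig <- extra$contig[si - n_vof]; pos <- extra$position[si - n_vof]
      variant <- NULL
    }
    column <- column_from_rows(records, rows, contig, pos)
    call <- call_personal_alleles(column, min_fraction)
    if (!call$kind %in% c("HOM", "HET")) next
    if (is.null(variant)) variant <- uniform_variant(contig, pos, call)
    res <- with_seed(site_seed(seed, contig, pos), {
      pair <- sample_masking_pair(variant)
      plan_site_replacement(column, call, pair)
    })
    if (nrow(res) == 0L) next
    records <- apply_plan(records, res, placeholder_qual)
    n_rec <- n_rec + 1L
    rec_list[[n_rec]] <- bdiff_record(contig, pos, res$base, res$qual)
  }

  masked <- structure(list(header = aln$header, records = records),
                      class = "sam_file")
  eff <- data.frame(contig = names(clens), start = 0L,
                    end = unname(clens), stringsAsFactors = FALSE)
  header <- bdiff_header(
    checksum = alignment_checksum(masked),
    effective_ranges = eff,
    min_fraction = min_fraction,
    placeholder_qual = as.integer(placeholder_qual),
    seed_fingerprint = substr(hex_digest(openssl::sha256(
      charToRaw(paste0("readmask-seed:", seed)))), 1, 16),
    concealed_unmapped = FALSE)
  list(alignments = masked,
       bdiff = bdiff_document(header, rec_list[seq_len(n_rec)]))
}

# Additional sites for the optional random-masking layer: covered positions
# not in the table, selected i.i.d. at `rate` per base; each gets a uniform
# allele distribution over the four bases.
random_mask_sites <- function(aln, vof, clens, seed, rate) {
  empty <- data.frame(contig = character(), position = integer(),
                      stringsAsFactors = FALSE)
  if (rate <= 0) return(empty)
  out <- list()
  for (ct in names(clens)) {
    picked <- with_seed(site_seed(seed, ct, -1L),
                        which(runif(clens[[ct]]) < rate)) - 1L
    picked <- setdiff(picked, vof$position[vof$contig == ct])
    if (length(picked)) {
      out[[ct]] <- data.frame(contig = ct, position = as.integer(sort(picked)),
                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

uniform_variant <- function(contig, pos, call) {
  major <- call$allele_pair[1]
  population_variant(contig, pos, c(major, setdiff(BASES, major)),
                     rep(0.25, 4))
}

CONCEAL_TAG_PREFIX <- "@CO\treadmask_conceal:"

conceal_fingerprint <- function(aes_key) {
  substr(hex_digest(openssl::sha256(c(charToRaw("readmask-conceal:"),
                                        aes_key))), 1, 16)
}

# Involutive per-byte transform keyed by a per-read keystream:
# bases A/C/G/T are XORed in their 2-bit code; a quality q is swapped with
# q XOR (ks & 0x7f) only when the partner is also a valid Phred value, which
# keeps the map an involution within the printable range.
keystream_transform <- function(seq, qual, qname, flag, aes_key) {
  n <- nchar(seq)
  iv <- openssl::sha256(charToRaw(paste0(qname, "/", flag)))[1:16]
  ks <- openssl::aes_ctr_encrypt(as.raw(rep(0L, 2L * n)), aes_key, iv)
  sq <- charToRaw(seq)
  code <- match(rawToChar(sq, multiple = TRUE), BASES) - 1L
  known <- !is.na(code)
  new_code <- bitwXor(code[known], as.integer(ks[seq_len(n)][known]) %% 4L)
  sq[known] <- charToRaw(paste(BASES[new_code + 1L], collapse = ""))
  q <- as.integer(charToRaw(qual)) - PHRED_OFFSET
  kq <- as.integer(ks[n + seq_len(n)]) %% 128L
  q2 <- bitwXor(q, kq)
  q <- ifelse(q2 >= 0L & q2 <= 93L, q2, q)
  list(seq = rawToChar(sq), qual = intToUtf8(q + PHRED_OFFSET))
}

transform_unmapped <- function(aln, aes_key) {
  un <- which(bitwAnd(aln$records$flag, 4L) != 0L &
                aln$records$seq != "*" & aln$records$qual != "*")
  for (i in un) {
    r <- keystream_transform(aln$records$seq[i], aln$records$qual[i],
                             aln$records$qname[i], aln$records$flag[i], aes_key)
    aln$records$seq[i] <- r$seq
    aln$records$qual[i] <- r$qual
  }
  aln
}

#' Conceal or reveal unmapped reads
#'
#' Unmapped reads are not touched by allele masking but can still carry
#' identifying sequence, so they may optionally be scrambled with a per-read
#' keystream derived from the container's symmetric key (key plus a nonce from
#' the read-name digest). The transform is an involution: revealing with the
#' same key restores the original bytes exactly. A header comment tags a
#' concealed file with a key fingerprint; concealing twice is refused, and
#' revealing with the wrong key fails the fingerprint check.
#'
#' @param aln a `sam_file`.
#' @param aes_key 32-byte raw symmetric key (the container key).
#' @param enable when `FALSE`, returns the input unchanged.
#' @return the transformed `sam_file`.
#' @export
conceal_unmapped_reads <- function(aln, aes_key, enable = TRUE) {
  stopifnot(inherits(aln, "sam_file"), is.raw(aes_key))
  if (!enable) return(aln)
  if (any(startsWith(aln$header, CONCEAL_TAG_PREFIX))) {
    stop_format("file is already concealed (conceal tag present)")
  }
  out <- transform_unmapped(aln, aes_key)
  out$header <- c(out$header,
                  paste0(CONCEAL_TAG_PREFIX, conceal_fingerprint(aes_key)))
  out
}

#' @rdname conceal_unmapped_reads
#' @export
reveal_unmapped_reads <- function(aln, aes_key) {
  stopifnot(inherits(aln, "sam_file"), is.raw(aes_key))
  tag <- which(startsWith(aln$header, CONCEAL_TAG_PREFIX))
  if (length(tag) == 0L) stop_format("no conceal tag present; nothing to reveal")
  fp <- sub(CONCEAL_TAG_PREFIX, "", aln$header[tag[1]], fixed = TRUE)
  if (!identical(fp, conceal_fingerprint(aes_key))) {
    stop_key("conceal-tag fingerprint does not match the supplied key")
  }
  out <- transform_unmapped(aln, aes_key)
  out$header <- out$header[-tag]
  out
}
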