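#' Simulation configuration
#'
#' Bundles the knobs of the synthetic fixture generator. The defaults are the
#' reference study conditions used throughout the test-suite and acceptance
#' checks: a 100 kb contig carrying 500 variant sites, 30x coverage with
#' 100 bp single-end reads, a 0.5% substitution error rate, and a
#' rare-allele-heavy Beta(0.2, 2) site-frequency spectrum (most population
#' alleles are rare, as in real cohort frequency tables).
#'
#' @param contig_length reference length in bases.
#' @param contig contig name.
#' @param n_sites number of population variant sites.
#' @param depth mean coverage.
#' @param read_length read length in bases.
#' @param error_rate per-base substitution error probability.
#' @param af_shape1,af_shape2 Beta shape parameters of the total
#'   alternative-allele frequency at a site.
#' @param base_qual constant Phred base quality written to simulated reads.
#' @param soft_clip_frac,deletion_frac fraction of reads decorated with a
#'   5 bp leading soft-clip / an internal 2 bp deletion, for CIGAR-handling
#'   tests.
#' @param n_unmapped number of additional unmapped reads.
#' @return a `sim_config` list.
#' @export
sim_config <- function(contig_length = 100000L, contig = "sim1",
                       n_sites = 500L, depth = 30, read_length = 100L,
                       error_rate = 0.005, af_shape1 = 0.2, af_shape2 = 2,
                       base_qual = 40L, soft_clip_frac = 0,
                       deletion_frac = 0, n_unmapped = 0L) {
  cfg <- list(contig_length = as.integer(contig_length), contig = contig,
              n_sites = as.integer(n_sites), depth = depth,
              read_length = as.integer(read_length), error_rate = error_rate,
              af_shape1 = af_shape1, af_shape2 = af_shape2,
              base_qual = as.integer(base_qual),
              soft_clip_frac = soft_clip_frac, deletion_frac = deletion_frac,
              n_unmapped = as.integer(n_unmapped))
  if (cfg$error_rate < 0 || cfg$error_rate > 1 ||
      cfg$soft_clip_frac < 0 || cfg$soft_clip_frac > 1 ||
      cfg$deletion_frac < 0 || cfg$deletion_frac > 1) {
    stop_config("rates must lie in [0, 1]")
  }
  if (cfg$contig_length <= 0L || cfg$read_length <= 0L || cfg$depth <= 0) {
    stop_config("lengths and depth must be positive")
  }
  if (cfg$n_sites > cfg$contig_length) {
    stop_config("cannot place more than one variant site per base")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a reference contig and population frequency table
#'
#' Draws a random reference sequence, places `n_sites` distinct variant sites
#' along it, and assigns each site one to three alternative alleles whose
#' total frequency is drawn from the configured Beta distribution (truncated
#' away from 1 so the reference allele always retains some mass). The result
#' satisfies every table invariant: one entry per site, reference allele
#' first, frequencies summing to one.
#'
#' Draws come from R's current RNG stream; call [set.seed()] first for
#' reproducibility.
#'
#' @param config a [sim_config()].
#' @return list with `reference` (named character vector) and `vof`
#'   (a `vof_table`).
#' @export
generate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$contig_length
  reference <- paste(sample(BASES, L, replace = TRUE), collapse = "")
  entries <- list()
  if (config$n_sites > 0L) {
    pos <- sort(sample.int(L, config$n_sites)) - 1L
    n_alt <- sample(1:3, config$n_sites, replace = TRUE,
                    prob = c(0.85, 0.1, 0.05))
    q <- rbeta(config$n_sites, config$af_shape1, config$af_shape2)
    q <- pmin(pmax(q, 1e-4), 0.95)
    entries <- lapply(seq_len(config$n_sites), function(i) {
      refb <- substr(reference, pos[i] + 1L, pos[i] + 1L)
      alts <- sample(setdiff(BASES, refb), n_alt[i])
      w <- runif(n_alt[i]); w <- w / sum(w)
      population_variant(config$contig, pos[i],
                         c(refb, alts), c(1 - q[i], q[i] * w))
    })
  }
  ref <- setNames(reference, config$contig)
  list(reference = ref, vof = vof_table(entries, contigs = config$contig))
}

#' Draw a diploid individual from the population
#'
#' At every site of the table, two alleles are drawn independently from the
#' site's frequency distribution — Hardy–Weinberg genotype proportions by
#' construction. The result is the ground truth that read simulation and
#' parameter-recovery tests are checked against.
#'
#' @param vof a `vof_table`.
#' @param id individual identifier stored on the result.
#' @return a `genotype_truth` data frame: `contig`, `position`, `allele1`,
#'   `allele2`.
#' @export
generate_individual <- function(vof, id = "sim-individual") {
  stopifnot(inherits(vof, "vof_table"))
  n <- length(vof$entries)
  a1 <- character(n); a2 <- character(n)
  for (i in seq_len(n)) {
    e <- vof$entries[[i]]
    d <- sample(e$alleles, 2, replace = TRUE, prob = e$frequencies)
    a1[i] <- d[1]; a2[i] <- d[2]
  }
  structure(data.frame(contig = vof$contig, position = vof$position,
                       allele1 = a1, allele2 = a2, stringsAsFactors = FALSE),
            class = c("genotype_truth", "data.frame"), id = id)
}

#' Simulate error-bearing aligned reads over a diploid individual
#'
#' Reads start uniformly along the contig at the configured depth. Each read
#' copies one of the two haplotypes implied by the ground-truth genotypes
#' (phase follows the draw order in `truth`), then substitution errors are
#' applied i.i.d. per base. Qualities are constant; read names encode
#' haplotype, start and index so tests can target specific reads. Optional
#' decorations add leading soft-clips or internal deletions for
#' CIGAR-handling tests, and `n_unmapped` unmapped reads for the concealment
#' layer. Output records are coordinate-sorted under a proper header.
#'
#' @param reference named character vector from [generate_population()].
#' @param truth a `genotype_truth` from [generate_individual()].
#' @param config a [sim_config()].
#' @return a coordinate-sorted `sam_file`.
#' @export
simulate_alignments <- function(reference, truth, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  contig <- names(reference)[1]
  refseq <- reference[[1]]
  L <- nchar(refseq)
  rl <- config$read_length
  if (rl > L) stop_config("read length exceeds contig length")
  n_reads <- as.integer(round(config$depth * L / rl))
  starts0 <- sort(sample.int(L - rl + 1L, n_reads, replace = TRUE)) - 1L
  hap <- sample(1:2, n_reads, replace = TRUE)

  # haplotype sequences: reference with truth alleles substituted
  hapseq <- c(refseq, refseq)
  tt <- truth[truth$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(tt))) {
    p <- tt$position[i] + 1L
    substr(hapseq[1], p, p) <- tt$allele1[i]
    substr(hapseq[2], p, p) <- tt$allele2[i]
  }

  qual_plain <- strrep(intToUtf8(config$base_qual + PHRED_OFFSET), rl)
  decorate <- runif(n_reads)
  sc <- decorate < config$soft_clip_frac
  dl <- !sc & decorate < config$soft_clip_frac + config$deletion_frac

  qname <- sprintf("sim-h%d-%06d-%05d", hap, starts0, seq_len(n_reads))
  seqv <- character(n_reads); cigv <- character(n_reads)
  posv <- integer(n_reads)
  for (k in seq_len(n_reads)) {
    s0 <- starts0[k]
    if (sc[k]) {
      # 5 clipped junk bases + (rl-5) aligned bases
      aln_len <- rl - 5L
      core <- substr(hapseq[hap[k]], s0 + 1L, s0 + aln_len)
      seqv[k] <- paste0(paste(sample(BASES, 5L, replace = TRUE), collapse = ""),
                        core)
      cigv[k] <- sprintf("5S%dM", aln_len)
    } else if (dl[k] && s0 + rl + 2L <= L) {
      half <- rl %/% 2L
      core <- paste0(substr(hapseq[hap[k]], s0 + 1L, s0 + half),
                     substr(hapseq[hap[k]], s0 + half + 3L, s0 + rl + 2L))
      seqv[k] <- core
      cigv[k] <- sprintf("%dM2D%dM", half, rl - half)
    } else {
      seqv[k] <- substr(hapseq[hap[k]], s0 + 1L, s0 + rl)
      cigv[k] <- sprintf("%dM", rl)
    }
    posv[k] <- s0 + 1L
  }

  # substitution errors, i.i.d. per base
  if (config$error_rate > 0) {
    for (k in seq_len(n_reads)) {
      hits <- which(runif(nchar(seqv[k])) < config$error_rate)
      for (h in hits) {
        cur <- substr(seqv[k], h, h)
        substr(seqv[k], h, h) <- sample(setdiff(BASES, cur), 1L)
      }
    }
  }

  records <- data.frame(
    qname = qname, flag = 0L, rname = contig, pos = posv, mapq = 60L,
    cigar = cigv, rnext = "*", pnext = 0L, tlen = 0L, seq = seqv,
    qual = qual_plain, tags = "", stringsAsFactors = FALSE)

  if (config$n_unmapped > 0L) {
    un <- data.frame(
      qname = sprintf("sim-unmapped-%05d", seq_len(config$n_unmapped)),
      flag = 4L, rname = "*", pos = 0L, mapq = 0L, cigar = "*",
      rnext = "*", pnext = 0L, tlen = 0L,
      seq = vapply(seq_len(config$n_unmapped), function(i)
        paste(sample(BASES, rl, replace = TRUE), collapse = ""), character(1)),
      qual = qual_plain, tags = "", stringsAsFactors = FALSE)
    records <- rbind(records, un)
  }

  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", contig, L),
              "@PG\tID:readmask-sim\tPN:readmask-sim")
  structure(list(header = header, records = records), class = "sam_file")
}

#' One-call synthetic fixture
#'
#' Convenience wrapper producing a coherent population + individual + reads
#' bundle under one seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `reference`, `vof`, `truth`, `aln`, and the `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  with_seed(as.integer(seed), {
    pop <- generate_population(config)
    truth <- generate_individual(pop$vof)
    aln <- simulate_alignments(pop$reference, truth, config)
    list(reference = pop$reference, vof = pop$vof, truth = truth, aln = aln,
         config = config)
  })
}
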