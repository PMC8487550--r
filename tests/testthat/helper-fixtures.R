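# Shared fixture builders. Everything is generated in code; no stored data.

# RSA keygen is the slowest fixture step, so one pair of key pairs is created
# per test run and reused.
.keys <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      td <- tempfile("keys"); dir.create(td)
      generate_keypair(file.path(td, "a.pem"), file.path(td, "a.pub.pem"))
      generate_keypair(file.path(td, "b.pem"), file.path(td, "b.pub.pem"))
      cache <<- list(
        priv_a = load_private_key(file.path(td, "a.pem")),
        pub_a = load_public_key(file.path(td, "a.pub.pem")),
        priv_b = load_private_key(file.path(td, "b.pem")),
        pub_b = load_public_key(file.path(td, "b.pub.pem")),
        paths = list(priv_a = file.path(td, "a.pem"),
                     pub_a = file.path(td, "a.pub.pem"),
                     priv_b = file.path(td, "b.pem"),
                     pub_b = file.path(td, "b.pub.pem")))
    }
    cache
  }
})

# Hand-built single-contig sam_file from parallel vectors.
make_sam <- function(pos, cigar, seq, qual = NULL, contig = "c1",
                     contig_len = 1000L, qname = NULL, flag = 0L) {
  n <- length(pos)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  if (is.null(qname)) qname <- sprintf("r%03d", seq_len(n))
  flag <- rep_len(flag, n)
  cigar <- rep_len(cigar, n); seq <- rep_len(seq, n)
  qual <- rep_len(qual, n)
  records <- if (n == 0L) readmask:::empty_sam_records() else data.frame(
    qname = qname, flag = flag, rname = ifelse(flag == 4L, "*", contig),
    pos = as.integer(pos), mapq = 60L, cigar = cigar, rnext = "*",
    pnext = 0L, tlen = 0L, seq = seq, qual = qual, tags = "",
    stringsAsFactors = FALSE)
  structure(list(
    header = c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len)),
    records = records), class = "sam_file")
}

# A pileup column at `position` whose counted bases are given explicitly,
# built from depth-1 synthetic reads (1M CIGARs).
make_column <- function(bases, position = 10L, contig = "c1") {
  aln <- make_sam(pos = rep(position + 1L, length(bases)),
                  cigar = "1M", seq = bases)
  pileup_column(aln, contig, position)
}

# Random valid population variant at a given site.
random_variant <- function(contig, position) {
  ref <- sample(c("A", "C", "G", "T"), 1)
  n_alt <- sample(1:3, 1)
  alts <- sample(setdiff(c("A", "C", "G", "T"), ref), n_alt)
  q <- runif(1, 0.01, 0.9)
  w <- runif(n_alt); w <- w / sum(w)
  population_variant(contig, position, c(ref, alts), c(1 - q, q * w))
}

random_vof <- function(n, contigs = c("c1", "c2")) {
  per <- table(sample(contigs, n, replace = TRUE))
  entries <- list()
  for (ct in names(per)) {
    pos <- sort(sample.int(10 * n + 100, per[[ct]])) - 1L
    entries <- c(entries, lapply(pos, function(p) random_variant(ct, p)))
  }
  vof_table(entries, contigs = contigs)
}

# Small coherent masked fixture used across crypto/unmask tests.
small_masked_fixture <- function(seed = 3L, mask_seed = 9L, n_sites = 30L,
                                 contig_length = 5000L, depth = 20,
                                 error_rate = 0) {
  ds <- simulate_dataset(
    sim_config(contig_length = contig_length, n_sites = n_sites,
               depth = depth, error_rate = error_rate), seed = seed)
  res <- mask_alignments(ds$aln, ds$vof, seed = mask_seed)
  c(ds, res)
}

expect_condition_class <- function(expr, class) {
  got <- tryCatch({ expr; NULL }, condition = function(c) class(c)[1])
  expect_identical(got, class)
}
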