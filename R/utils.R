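#' @importFrom stats rbeta runif setNames
#' @importFrom utils head modifyList read.table write.table
NULL

BASES <- c("A", "C", "G", "T")

# openssl hashes keep a "hash" class on as.character(); strip to a bare string
hex_digest <- function(x) as.vector(as.character(x))

# Classed conditions so callers (and the CLI exit-code map) can distinguish
# format problems from cryptographic verification failures.
rm_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "readmask_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_format    <- function(msg) rm_stop(msg, "readmask_format_error")
stop_key       <- function(msg) rm_stop(msg, "readmask_key_error")
stop_integrity <- function(msg) rm_stop(msg, "readmask_integrity_error")
stop_signature <- function(msg) rm_stop(msg, "readmask_signature_error")
stop_checksum  <- function(msg) rm_stop(msg, "readmask_checksum_error")
stop_config    <- function(msg) rm_stop(msg, "readmask_config_error")

#' Derive a per-site RNG seed from a master seed
#'
#' Masking must be reproducible and independent of how the input is traversed,
#' so every variant site gets its own RNG substream keyed by
#' `(master seed, contig, 0-based position)`. The substream seed is the first
#' four bytes of the SHA-256 digest of that triple, folded into the non-negative
#' 31-bit integer range accepted by [set.seed()].
#'
#' @param seed master seed (single integer).
#' @param contig contig name.
#' @param position 0-based site position.
#' @return a single integer seed.
#' @keywords internal
site_seed <- function(seed, contig, position) {
  h <- openssl::sha256(charToRaw(paste(seed, contig, position, sep = "\r")))
  v <- sum(as.integer(h[1:4]) * c(1, 256, 65536, 8388608))
  as.integer(v %% .Machine$integer.max)
}

# Run `expr` under a private RNG stream seeded with `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Parse a 1-based inclusive region string
#'
#' Converts the usual `"contig:start-end"` command-line region syntax (1-based,
#' inclusive) into the 0-based half-open interval used internally. A bare
#' `"contig"` selects the whole contig.
#'
#' @param x region string.
#' @return list with `contig`, `start`, `end` (0-based half-open; `end = NA`
#'   means "to the end of the contig").
#' @export
#' @examples
#' parse_region("chr1:101-200") # 0-based half-open [100, 200)
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!grepl(":", x, fixed = TRUE)) {
    return(list(contig = x, start = 0L, end = NA_integer_))
  }
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L) stop_format(sprintf("cannot parse region '%s'", x))
  start1 <- as.integer(m[3]); end1 <- as.integer(m[4])
  if (start1 < 1L || end1 < start1) {
    stop_format(sprintf("malformed region '%s' (need 1 <= start <= end)", x))
  }
  list(contig = m[2], start = start1 - 1L, end = end1)
}

# Intersect two interval tables (contig, start, end), 0-based half-open.
intersect_ranges <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (i in seq_len(nrow(a))) {
    bb <- b[b$contig == a$contig[i], , drop = FALSE]
    if (nrow(bb) == 0L) next
    s <- pmax(a$start[i], bb$start)
    e <- pmin(a$end[i], bb$end)
    keep <- s < e
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        contig = a$contig[i], start = s[keep], end = e[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

point_in_ranges <- function(contig, position, ranges) {
  any(ranges$contig == contig & ranges$start <= position & position < ranges$end)
}
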