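#' RSA key-pair helpers
#'
#' Thin wrappers over the `openssl` package for generating and loading
#' PEM-encoded RSA key pairs used to wrap container keys and to sign
#' payloads.
#'
#' @param bits modulus size; at least 2048.
#' @param priv_path,pub_path output paths for the private and public PEM.
#' @return `generate_keypair()` writes both PEMs and returns their paths;
#'   `load_private_key()`/`load_public_key()` return openssl key objects.
#' @export
generate_keypair <- function(priv_path, pub_path, bits = 2048) {
  if (bits < 2048) stop_config("RSA keys below 2048 bits are refused")
  key <- openssl::rsa_keygen(bits)
  openssl::write_pem(key, priv_path)
  openssl::write_pem(key$pubkey, pub_path)
  invisible(list(priv = priv_path, pub = pub_path))
}

#' @rdname generate_keypair
#' @param path PEM file path.
#' @export
load_private_key <- function(path) openssl::read_key(path)

#' @rdname generate_keypair
#' @export
load_public_key <- function(path) openssl::read_pubkey(path)

key_fingerprint <- function(pubkey) {
  hex_digest(openssl::sha256(openssl::write_der(pubkey)))
}

check_key_size <- function(key) {
  bits <- tryCatch(as.integer(key$size) * 8L, error = function(e) NA_integer_)
  if (!is.na(bits) && bits < 2048L) {
    stop_config("RSA keys below 2048 bits are refused")
  }
  invisible(TRUE)
}

CONTAINER_MAGIC <- as.raw(c(0x42, 0x44, 0x45, 0x43, 0x01)) # "BDEC\x01"

# Hybrid container layout (all blocks length-prefixed, fixed order):
#   magic | wrapped_key | signature | creator_fp | signer_fp | iv | mac | payload
# wrapped_key: RSA-OAEP ciphertext of 64 random bytes (32 AES-CTR + 32 HMAC).
# signature: RSA PKCS#1 v1.5 over SHA-256 of the *plaintext*, so provenance
# survives re-encryption for a new recipient (the re-sharer re-signs; the
# creator fingerprint is retained for audit).
# payload: AES-256-CTR ciphertext, authenticated by HMAC-SHA256 over iv|ct
# (encrypt-then-MAC), giving a clean integrity failure on any flipped byte.

#' Encrypt a BDIFF payload into a hybrid container
#'
#' A fresh 64-byte symmetric secret (AES-256-CTR key plus HMAC-SHA256 key) is
#' generated per container and wrapped with the recipient's RSA public key;
#' the plaintext is signed with the signer's RSA private key. The wrapped key
#' and signature sit at the head of the container so they can be read without
#' touching the payload.
#'
#' @param doc_bytes raw plaintext (normally [serialize_bdiff()] output).
#' @param recipient_public_key openssl RSA public key (wraps the secret).
#' @param signer_private_key openssl RSA private key (signs the plaintext).
#' @param creator_fingerprint fingerprint retained across re-shares; defaults
#'   to the signer's public-key fingerprint.
#' @param secret optional pre-generated 64-byte raw secret; by default a fresh
#'   one is drawn. Exposing it allows unmapped-read concealment to share the
#'   container key.
#' @return an `encrypted_container`.
#' @export
encrypt_container <- function(doc_bytes, recipient_public_key,
                              signer_private_key,
                              creator_fingerprint = NULL, secret = NULL) {
  stopifnot(is.raw(doc_bytes))
  check_key_size(recipient_public_key)
  check_key_size(signer_private_key)
  if (is.null(secret)) secret <- openssl::rand_bytes(64)
  stopifnot(is.raw(secret), length(secret) == 64L)
  enc_key <- secret[1:32]; mac_key <- secret[33:64]
  iv <- openssl::rand_bytes(16)
  ct <- openssl::aes_ctr_encrypt(doc_bytes, enc_key, iv)
  attributes(ct) <- NULL
  mac <- openssl::sha256(c(iv, ct), key = mac_key)
  wrapped <- openssl::rsa_encrypt(secret, recipient_public_key)
  sig <- openssl::signature_create(doc_bytes, openssl::sha256,
                                   signer_private_key)
  signer_fp <- key_fingerprint(signer_private_key$pubkey)
  if (is.null(creator_fingerprint)) creator_fingerprint <- signer_fp
  structure(list(wrapped_key = wrapped, signature = sig,
                 creator_fingerprint = creator_fingerprint,
                 signer_fingerprint = signer_fp,
                 iv = iv, mac = as.raw(mac), payload = ct),
            class = "encrypted_container")
}

#' @export
print.encrypted_container <- function(x, ...) {
  cat(sprintf("<encrypted_container> payload %d B, creator %s..., signer %s...\n",
              length(x$payload), substr(x$creator_fingerprint, 1, 12),
              substr(x$signer_fingerprint, 1, 12)))
  invisible(x)
}

#' Decrypt and verify a hybrid container
#'
#' Unwraps the symmetric secret with the recipient's private key, checks the
#' payload MAC, decrypts, and verifies the signer's signature over the
#' plaintext before returning any bytes. The three failure modes — wrong
#' private key, tampered ciphertext, and signature mismatch — raise
#' distinguishable conditions (`readmask_key_error`,
#' `readmask_integrity_error`, `readmask_signature_error`).
#'
#' @param container an `encrypted_container`.
#' @param recipient_private_key openssl RSA private key (mate of the wrapping
#'   key).
#' @param signer_public_key openssl RSA public key used to verify the
#'   signature.
#' @return raw plaintext bytes.
#' @export
decrypt_container <- function(container, recipient_private_key,
                              signer_public_key) {
  stopifnot(inherits(container, "encrypted_container"))
  secret <- tryCatch(
    openssl::rsa_decrypt(container$wrapped_key, recipient_private_key),
    error = function(e) stop_key(
      paste0("cannot unwrap container key (wrong private key?): ",
             conditionMessage(e))))
  if (length(secret) != 64L) stop_key("unwrapped secret has unexpected size")
  mac <- openssl::sha256(c(container$iv, container$payload),
                         key = secret[33:64])
  if (!identical(as.raw(mac), container$mac)) {
    stop_integrity("payload authentication failed (container tampered)")
  }
  pt <- openssl::aes_ctr_decrypt(container$payload, secret[1:32], container$iv)
  attributes(pt) <- NULL
  ok <- tryCatch(
    openssl::signature_verify(pt, container$signature, openssl::sha256,
                              signer_public_key),
    error = function(e) FALSE)
  if (!isTRUE(ok)) stop_signature("payload signature does not verify")
  pt
}

# The unwrapped symmetric secret, for callers that also need the concealment
# key (unmapped reads); verification is identical to decrypt_container.
container_secret <- function(container, recipient_private_key) {
  tryCatch(
    openssl::rsa_decrypt(container$wrapped_key, recipient_private_key),
    error = function(e) stop_key(
      paste0("cannot unwrap container key (wrong private key?): ",
             conditionMessage(e))))
}

#' Read and write encrypted containers
#'
#' On disk the container is `magic | length-prefixed blocks` in a fixed
#' order, with the wrapped key and signature at the head — a reader can parse
#' key material without touching the payload (see [container_head()]).
#'
#' @param container an `encrypted_container`.
#' @param path file path (conventionally `.bdiff.enc`).
#' @return `read_container()` returns an `encrypted_container`; the writer
#'   returns `path` invisibly.
#' @export
write_container <- function(container, path) {
  stopifnot(inherits(container, "encrypted_container"))
  con <- file(path, "wb"); on.exit(close(con), add = TRUE)
  writeBin(CONTAINER_MAGIC, con)
  wb <- function(r) {
    writeBin(length(r), con, size = 4, endian = "little")
    writeBin(r, con)
  }
  wb(container$wrapped_key)
  wb(container$signature)
  wb(charToRaw(container$creator_fingerprint))
  wb(charToRaw(container$signer_fingerprint))
  wb(container$iv)
  wb(container$mac)
  wb(container$payload)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  con <- file(path, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", n = length(CONTAINER_MAGIC))
  if (length(magic) < length(CONTAINER_MAGIC) ||
      !identical(magic, CONTAINER_MAGIC)) {
    stop_format("not an encrypted BDIFF container (bad magic)")
  }
  rb <- function(what) {
    n <- read_i32(con, what)
    r <- readBin(con, "raw", n = n)
    if (length(r) < n) stop_format(sprintf("truncated container (%s)", what))
    r
  }
  structure(list(wrapped_key = rb("wrapped key"),
                 signature = rb("signature"),
                 creator_fingerprint = rawToChar(rb("creator fingerprint")),
                 signer_fingerprint = rawToChar(rb("signer fingerprint")),
                 iv = rb("iv"), mac = rb("mac"), payload = rb("payload")),
            class = "encrypted_container")
}

#' Parse only the head of a stored container
#'
#' Reads the wrapped key and signature lengths from the beginning of the file
#' without reading the payload — the layout contract that lets key material
#' be examined first.
#'
#' @param path container path.
#' @return list with `wrapped_key_length` and `signature_length` (bytes).
#' @export
container_head <- function(path) {
  con <- file(path, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", n = length(CONTAINER_MAGIC))
  if (!identical(magic, CONTAINER_MAGIC)) {
    stop_format("not an encrypted BDIFF container (bad magic)")
  }
  kl <- read_i32(con, "wrapped key length")
  seek(con, kl, origin = "current")
  sl <- read_i32(con, "signature length")
  list(wrapped_key_length = kl, signature_length = sl)
}

#' Re-encrypt a container for another recipient, optionally range-restricted
#'
#' The owner decrypts and verifies the container, optionally checks that the
#' supplied masked alignments still match the checksum stored in the BDIFF
#' header, optionally slices the document to a genomic range (which narrows
#' the new document's effective ranges), then encrypts the result for the new
#' recipient and re-signs it. The original creator's fingerprint is carried
#' through for audit. Re-sharing can be chained: the accessible region only
#' ever narrows (intersection of ranges).
#'
#' @param container an `encrypted_container`.
#' @param owner_private_key owner's RSA private key (unwraps and re-signs).
#' @param owner_public_key public key verifying the current signature.
#' @param new_recipient_public_key RSA public key of the new recipient.
#' @param contig,start,end optional half-open 0-based range restriction.
#' @param masked_aln optional masked `sam_file`; when given, its checksum must
#'   match the header checksum or the share aborts with a tamper signal.
#' @return a new `encrypted_container` for the recipient.
#' @export
share_reencrypt <- function(container, owner_private_key, owner_public_key,
                            new_recipient_public_key,
                            contig = NULL, start = 0L, end = NA,
                            masked_aln = NULL) {
  pt <- decrypt_container(container, owner_private_key, owner_public_key)
  doc <- deserialize_bdiff(pt)
  if (!is.null(masked_aln)) {
    if (!verify_masked_checksum(masked_aln, doc$header)) {
      stop_checksum("masked alignments do not match the BDIFF header checksum")
    }
  }
  if (!is.null(contig)) {
    doc <- slice_bdiff(doc, contig, start, end)
    pt <- serialize_bdiff(doc)
  }
  encrypt_container(pt, new_recipient_public_key, owner_private_key,
                    creator_fingerprint = container$creator_fingerprint)
}
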