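---
title: "Masking personal SNV alleles in aligned reads: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masking personal SNV alleles in aligned reads: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readmask)
```

## The problem and the model

A coordinate-sorted alignment file exposes its donor's genotype at every
covered polymorphic site. `readmask` removes that personal signal while
keeping everything else researchers use alignments for — coverage, read
placement, CIGARs, flags, mate information — byte-identical. The idea is
substitution rather than suppression: at every site described by a public
population allele-frequency table, the personal pair of alleles is replaced
across all covering reads by a *masking pair* drawn from the population
distribution. A masked file is therefore statistically indistinguishable
from an alignment of a random member of the masking population at those
sites, and an adversary cannot tell from the file alone whether it was
masked at all.

Formally, a site carries alleles $a_1,\dots,a_k$ (reference first) with
frequencies $f_1,\dots,f_k$, $\sum f_i = 1$. The masking pair is two
independent multinomial draws, $P\{(a_i,a_j)\} = f_i f_j$. Three
consequences drive the package's empirical checks:

* at an error-free homozygous-alternative site with total alternative
  frequency $q$, the variant disappears ("is masked") exactly when both
  draws return the reference: probability $(1-q)^2$;
* at a homozygous-reference site a new variant appears ("is introduced")
  with probability $1-(1-q)^2$;
* zygosity can change in either direction, since the two draws are
  independent — a hom site becomes het whenever the draws differ.

Rare alleles are thus hidden most effectively, and masking mimics the
population's site-frequency spectrum rather than erasing variation.

## Personal-allele calling

The genotype at a site is decided by a pure fraction threshold on the pileup
column: a base is *sufficiently represented* when
$\text{count}/\text{countable depth} \ge$ `min_fraction`. `N` observations
and deletion gaps are never counted, never replaced and never stored.
Exactly one sufficient base gives a homozygous call (the allele is
duplicated into a pair); exactly two give a heterozygous call, ordered by
descending count with alphabetical tie-break so downstream output is
deterministic; three or more sufficient bases mark the column ambiguous and
the site is skipped entirely (no replacement, no diff record); an empty
column is untouched. When coverage is spread so thin that *no* base reaches
the threshold, the site is treated as ambiguous and skipped as well.

`min_fraction` defaults to 0.2 and must lie in $(0, 0.5]$ — above 0.5 two
bases could never both qualify and heterozygotes would be uncallable. The
value is recorded in the diff header, so an unmasking party can always see
which calling semantics produced the file. There is deliberately no
base-quality weighting, mapping-quality filter or likelihood model: the
contract is a transparent counting rule, and the diff makes any
misclassification harmless because reversal does not depend on the call.

Overlapping mate pairs are counted as two independent observations. This is
the simplest contract and is stated openly; replacement treats each
observation independently, and reversal is positional, so de-duplication
would add complexity without changing correctness.

## Replacement mechanics

Given a personal call and a masking pair (kept in draw order):

* **het → pair**: observations of the first personal allele become the first
  masking allele, second to second. The orderings of both pairs are fixed
  (count/lexicographic for the personal pair, draw order for the masking
  pair), so the mapping is reproducible.
* **hom → unequal pair**: each personal-allele observation independently
  receives either masking allele with probability 1/2, which makes the
  masked column look like a genuine heterozygote with a balanced binomial
  allele ratio.
* **error bases** (observations outside the personal pair): re-drawn
  uniformly from the bases *outside* the masking pair, so a stray sequencing
  error can never be mistaken for, or collide with, the masked genotype. At
  least two such bases always exist for a pair of at most two distinct
  alleles.
* **qualities**: the base quality of *every* counted observation at a
  processed site is overwritten with one placeholder (default Phred 60),
  not only the changed bases. If only edited bases lost their qualities,
  the quality pattern itself would reveal which bases were replaced; a
  uniform overwrite closes that side channel. The original qualities travel
  in the diff and come back on unmasking.

Sites whose personal allele is absent from the table's allele list are still
masked — the personal observations are replaced by the sampled pair as
usual; the absent allele simply has zero probability of reappearing.

An optional layer (`random_mask_rate`, off by default) additionally masks a
random fraction of covered non-table sites using a uniform allele
distribution anchored at the site's major allele. It exists to blur the
boundary between table and non-table sites; because no principled frequency
model is available for those positions, the default keeps it off.

## Randomness and reproducibility

One master seed governs a run. Every site gets a private RNG substream
seeded by the first four bytes of `SHA-256(seed, contig, position)`, so
masking is bit-reproducible given the seed and independent of traversal or
batching; processing sites in any order yields the same file. The diff
header stores only a fingerprint of the seed (a truncated hash), never the
seed itself — the seed determines the masking pairs, so publishing it with a
public frequency table would leak the original genotype.

## File formats

Both on-disk formats are original to this package and versioned from byte
one.

* **VOF** (`VOF\x01`): declared contig list, then per-contig blocks of
  `(position, allele string, frequencies)` with little-endian fixed-width
  integers. Built from a sites VCF: only `FILTER == PASS` single-base
  REF/ALT records are kept, lines at one site are merged into a single
  multiallelic entry (conflicting REF bases are a hard error — a silent
  merge would corrupt frequencies), the reference frequency is the
  complement of the summed alternative frequencies, clamped at zero only
  within `1e-6` of float noise; a larger excess aborts as corrupt input.
  Coordinates are 0-based internally; the VCF's 1-based convention is
  converted exactly once, at the reader boundary. A TSV debug dialect is
  also writable.
* **BDIFF** (`BDIFF\x01`): a length-prefixed JSON header (format version,
  checksum algorithm + digest of the masked records, effective ranges,
  masking parameters, unmapped-concealment flag) followed by per-contig
  record blocks with delta-encoded positions and per-observation
  `(base, quality)` bytes. Serialization refuses a document whose records
  fall outside its declared effective ranges, and deserialization re-checks
  magic, version, ordering and truncation.

The checksum is SHA-256 over the canonical text serialization of the
alignment *records* (header lines excluded), so recompression or header
edits do not break verification while any record edit — including
reordering — does.

## Encryption container

The encrypted container is `magic | wrapped key | signature | fingerprints |
iv | mac | payload`, all length-prefixed, key material first so a reader can
parse the head without touching the payload. Concrete primitives, chosen by
this package: a fresh 64-byte secret per container (32 bytes AES-256-CTR
encryption key, 32 bytes HMAC-SHA256 key) wrapped with RSA-OAEP; payload
encrypted then authenticated (encrypt-then-MAC), so a flipped ciphertext
byte fails with a clean integrity error before any plaintext is produced;
an RSA PKCS#1 v1.5 signature over SHA-256 of the *plaintext*. Signing the
plaintext rather than the ciphertext is what lets re-encryption for a new
recipient preserve provenance semantics: the re-sharer re-signs, and the
original creator's key fingerprint is carried in the container for audit.
Keys below 2048 bits are refused. The three failure modes — wrong private
key, tampered payload, signature mismatch — raise distinguishable condition
classes, which the CLI maps to distinct exit codes.

Sharing decrypts and verifies in memory, optionally checks the supplied
masked file against the header checksum, slices the document to the
requested range (the new effective ranges are the intersection of old and
requested, so access only ever narrows under repeated sharing), and
re-encrypts for the new recipient. No plaintext is written to durable
storage by any operation.

Unmapped reads are outside the masking model but may carry identifying
sequence, so they can optionally be concealed with a per-read keystream
derived from the container secret (nonce = read-name digest). Sequence
symbols are XORed in their 2-bit code; a quality value `q` swaps with
`q XOR k` only when the partner is also a valid Phred value, which keeps the
per-byte map an involution within the printable range — revealing with the
same key is exact. A tagged fingerprint in the header refuses double
concealment and wrong-key revelation.

## Unmasking

Reversal is positional: for each in-scope diff record the pileup column of
the masked file is enumerated exactly as during masking — guaranteed
identical because masking never touches positions, flags or CIGARs — and
stored `(base, quality)` pairs are written back by column index. Addressing
by column order rather than read name makes the format robust to duplicated
read names. A column whose counted length disagrees with the stored record
aborts naming the site. The checksum is verified first; a requested range
must lie inside the document's effective ranges.

One sharp edge is intentional: after a *partial* unmask the file no longer
matches the checksum of the fully masked file, so re-applying a range (a
no-op by construction) or applying a second range requires
`verify = FALSE`. The alternative — rewriting the diff header's checksum on
every partial restore — would force unmasking to mutate the (signed,
encrypted) document, which crosses a trust boundary this package keeps
clean.

## Evaluation utilities

`classify_positions()` reproduces the five-way comparison of population
sites, personal calls and masked-file calls: *not found* (population sites
with no call in either file), *masked* (personal variants erased), *not
masked* (personal variants still called, possibly with changed allele or
zygosity), *introduced* (new variants at population sites), *not covered*
(personal variants the table does not describe — masking cannot touch
them). The five definitional set formulas partition the position universe
whenever the masked call set stays within `population ∪ personal` with its
novel part confined to population sites, which is exactly what masking
produces: it only ever creates or removes variants at table sites. For call
sets from a noisy caller the formulas are still applied verbatim; positions
violating that envelope (e.g. error-driven calls off the table) are
reported in both or neither of the overlapping categories rather than
silently reassigned.

`filter_calls()` implements the strict "above 30" rule: a record at depth or
quality *exactly* 30 is dropped. The quality compared is the record's
quality field; which caller field populates it is the caller's business —
the bundled `naive_caller()` writes a constant placeholder, since a pure
fraction-threshold caller has no meaningful quality model.
`masked_ratio_by_frequency()` bins masked/not-masked sites by population
frequency and reports empty bins as `NA`, never zero.

`naive_caller()` exists so the pipeline is self-contained: it calls a
variant wherever a non-reference base passes the same fraction rule, with a
coverage floor (default 10). It is deliberately primitive — deterministic,
no likelihoods — because its only jobs are call-set identity checks
(original vs unmasked must agree exactly) and category counting on
synthetic data.

## The synthetic generator

`sim_config()` defaults are the package's reference study conditions: a
100 kb contig, 500 variant sites, 30× coverage with 100 bp single-end
reads, 0.5% substitution errors, and a Beta(0.2, 2) total
alternative-frequency spectrum (mean ≈ 0.09, strongly rare-skewed, the
shape of real cohort tables). Sites get 1–3 alternative alleles (85/10/5%),
individuals are two independent draws per site (Hardy–Weinberg), and reads
copy one haplotype each with i.i.d. substitution errors. Read names encode
haplotype, start and index so tests can target specific reads; optional
decorations add leading soft-clips, internal deletions and unmapped reads
for CIGAR and concealment tests.

What the generator does *not* emulate: indel and context-dependent errors,
quality-score variation, GC and coverage bias, mapping ambiguity, paired-end
fragments (reads are single-end; the overlapping-mate counting contract is
exercised with hand-built records in the tests), linkage between sites. Green tests therefore demonstrate the *mechanics* — exact
reversibility, the frequency laws, format and crypto contracts — on clean
data; they do not certify behaviour under real-world alignment artefacts,
where the positional-reversal contract still holds but calling accuracy
will differ.

## Numerical and scale choices

Frequency sums are enforced to 1 within `1e-9`; reference-frequency
clamping tolerates `1e-6` of excess. Test and acceptance problem sizes were
chosen to make binomial noise small relative to the asserted tolerances
while keeping a full run in the low minutes: the reversibility fixture is
100 kb / 500 sites / 30× / 0.5% errors (~30,000 reads), frequency-law checks
use 2,000 replicates per point on the grid {0.01, 0.05, 0.1, 0.25, 0.5}
with 3-binomial-σ acceptance bands, sampling checks use 20,000 draws, and
the classification partition property is checked on 1,000 random triples.

## Known limitations

Indels, MNVs and short tandem repeats are out of scope — only single-base
substitutions are masked, and a personal indel remains visible. Coverage
itself is a signal the method intentionally preserves, so presence/absence
of reads is not hidden. Sites absent from the population table are untouched
unless the random-masking layer is enabled. The masking seed and the diff
container are the trust anchors: anyone holding both the container key and
the masked file recovers the original exactly.
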