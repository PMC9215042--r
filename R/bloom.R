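# The long-k-mer membership index.
#
# Two interchangeable implementations sit behind one query generic:
# the Bloom filter (production) and an exact hash-set (oracle, used by the
# equivalence tests). Hashing is strand-canonical: a k-mer and its reverse
# complement always produce the same h bit positions, so reads index both
# strands at once.

#' Create a k-mer Bloom filter
#'
#' @param bits size of the bit vector (default 64 MiB worth of bits).
#' @param h number of hash functions.
#' @param k k-mer size the filter stores.
#' @return object of class `kr_bloom`.
#' @export
kmer_bloom <- function(bits = 2^29, h = 7L, k) {
  obj <- list(ptr = cpp_bf_new(as.numeric(bits), as.integer(h),
                               as.integer(k)),
              bits = as.numeric(bits), h = as.integer(h), k = as.integer(k))
  class(obj) <- c("kr_bloom", "kr_kmer_index")
  obj
}

#' @export
print.kr_bloom <- function(x, ...) {
  info <- cpp_bf_info(x$ptr)
  cat(sprintf(
    "kr_bloom: k = %d, %g bits, h = %d, %g inserts, theoretical FPR %.3g\n",
    info$k, info$nbits, info$h, info$n_inserted,
    theoretical_fpr(info$n_inserted, info$nbits, info$h)))
  invisible(x)
}

#' Insert k-mers of a sequence into a Bloom filter
#'
#' Inserts the canonical k-mers at the first `n_kmers` positions from the
#' 5' end of each sequence (all positions if `n_kmers = Inf`).
#'
#' @param bloom a `kr_bloom`.
#' @param seqs character vector of sequences.
#' @param n_kmers how many 5'-anchored k-mers to insert per sequence.
#' @return the number of sequences skipped for non-ACGT content, invisibly.
#' @export
bloom_insert <- function(bloom, seqs, n_kmers = Inf) {
  stopifnot(inherits(bloom, "kr_bloom"))
  if (is.infinite(n_kmers)) {
    skipped <- 0L
    for (s in seqs) {
      if (!grepl("^[ACGT]+$", s)) { skipped <- skipped + 1L; next }
      nk <- nchar(s) - bloom$k + 1L
      cpp_bf_insert_reads(bloom$ptr, s, nk)
    }
    return(invisible(skipped))
  }
  invisible(cpp_bf_insert_reads(bloom$ptr, seqs, as.integer(n_kmers)))
}

#' Query single k-mers against a Bloom filter
#'
#' @param bloom a `kr_bloom`.
#' @param kmers character vector, each exactly `k` long.
#' @return logical vector; no false negatives.
#' @export
bloom_query <- function(bloom, kmers) {
  stopifnot(inherits(bloom, "kr_bloom"))
  vapply(kmers, function(s) cpp_bf_query_starts(bloom$ptr, s, 1L),
         NA, USE.NAMES = FALSE)
}

#' Bloom filter statistics
#'
#' @param bloom a `kr_bloom`.
#' @return list with `bits`, `h`, `k`, `n_inserted`, `bits_set`, `fpr`.
#' @export
bloom_stats <- function(bloom) {
  info <- cpp_bf_info(bloom$ptr)
  list(bits = info$nbits, h = info$h, k = info$k,
       n_inserted = info$n_inserted,
       bits_set = cpp_bf_popcount(bloom$ptr),
       fpr = theoretical_fpr(info$n_inserted, info$nbits, info$h))
}

#' Theoretical Bloom filter false positive rate
#'
#' The standard closed form `(1 - exp(-h n / B))^h` for `n` insertions
#' into `B` bits with `h` hash functions.
#'
#' @param n_inserted number of inserted elements.
#' @param bits bit-vector size `B`.
#' @param h hash function count.
#' @return probability in `[0, 1)`.
#' @export
theoretical_fpr <- function(n_inserted, bits, h) {
  stopifnot(bits > 0, h >= 1, n_inserted >= 0)
  (1 - exp(-h * n_inserted / bits))^h
}

#' Query k-mers at given window starts
#'
#' Generic over index implementations (Bloom filter or exact set). Windows
#' containing non-ACGT return `NA`.
#'
#' @param index a `kr_kmer_index`.
#' @param seq the spelled path sequence.
#' @param starts 1-based window start positions.
#' @return logical vector, one entry per start.
#' @export
query_starts <- function(index, seq, starts) UseMethod("query_starts")

#' @export
query_starts.kr_bloom <- function(index, seq, starts) {
  cpp_bf_query_starts(index$ptr, seq, as.integer(starts))
}

canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Exact k-mer set index (oracle)
#'
#' Same contract as the Bloom filter but with a zero false positive rate:
#' k-mers are held as canonical strings in a hashed environment. Used to
#' pin the Bloom route's support decisions.
#'
#' @param k k-mer size.
#' @return object of class `kr_exact_index`.
#' @export
exact_kmer_index <- function(k) {
  obj <- list(env = new.env(hash = TRUE, parent = emptyenv()),
              k = as.integer(k))
  class(obj) <- c("kr_exact_index", "kr_kmer_index")
  obj
}

#' Insert 5'-anchored k-mers into an exact index
#'
#' @param index a `kr_exact_index`.
#' @param seqs sequences to index.
#' @param n_kmers 5'-anchored k-mers per sequence.
#' @return skipped-sequence count, invisibly.
#' @export
exact_insert <- function(index, seqs, n_kmers = Inf) {
  k <- index$k
  skipped <- 0L
  for (s in seqs) {
    nk <- min(n_kmers, nchar(s) - k + 1L)
    if (nk < 1) stop("sequence shorter than k")
    prefix <- substring(s, 1L, k + nk - 1L)
    if (!grepl("^[ACGT]+$", prefix)) { skipped <- skipped + 1L; next }
    kmers <- substring(prefix, seq_len(nk), seq_len(nk) + k - 1L)
    for (km in canonical_kmer(kmers)) assign(km, TRUE, envir = index$env)
  }
  invisible(skipped)
}

#' @export
query_starts.kr_exact_index <- function(index, seq, starts) {
  k <- index$k
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- grepl("^[ACGT]+$", kmers)
  res <- rep(NA, length(kmers))
  res[ok] <- vapply(canonical_kmer(kmers[ok]),
                    function(km) exists(km, envir = index$env,
                                        inherits = FALSE),
                    NA, USE.NAMES = FALSE)
  res
}

#' Build the read index for one library
#'
#' Inserts the `t` consecutive canonical k-mers anchored at the 5' end of
#' every read (offsets `0 .. t-1`), the published compromise between Bloom
#' filter load and the chance of catching a read along a correct path:
#' finding one read's worth of k-mers is exactly the support threshold.
#' Reads with non-ACGT among the first `k_big + t - 1` bases are skipped
#' and counted.
#'
#' @param library a `kr_read_library`.
#' @param k_big the long k-mer size.
#' @param params [algorithm_params()].
#' @param backend `"bloom"` (default) or `"exact"` (oracle).
#' @return a `kr_kmer_index` with attribute `reads_skipped`.
#' @export
build_read_index <- function(library, k_big, params = algorithm_params(),
                             backend = c("bloom", "exact")) {
  backend <- match.arg(backend)
  k_big <- as.integer(k_big)
  t <- params$t
  if (library$read_length < k_big + t - 1L)
    stop(sprintf(
      "read length %d cannot host t = %d k-mers of size k_big = %d (needs %d)",
      library$read_length, t, k_big, k_big + t - 1L))
  if (backend == "bloom") {
    idx <- kmer_bloom(bits = params$bloom_bits, h = params$h, k = k_big)
    skipped <- cpp_bf_insert_reads(idx$ptr, library$reads, t)
  } else {
    idx <- exact_kmer_index(k_big)
    skipped <- exact_insert(idx, library$reads, t)
  }
  attr(idx, "reads_skipped") <- skipped
  idx
}
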