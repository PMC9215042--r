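#' Algorithm parameters
#'
#' Bundles every tunable of the resolution algorithm with its default.
#' Defaults follow the published tuning of the sliding-window method:
#' support threshold `t = 4` (also the number of k-mers stored per read),
#' minimum tests `m = 18`, maximum tests `M = 40`, coverage-inaccuracy
#' correction factor `f = 4`, minimum window overlap on the nodes adjacent
#' to the repeat `margin = 2` bp, `h = 7` Bloom hash functions, at most 75
#' extension paths per repeat side (hence 5625 path combinations, randomly
#' subsampled beyond that), and 2 evaluation/resolution passes per read
#' length.
#'
#' @param t support threshold: minimum positive window queries for a path
#'   to count as supported; equally the number of `k_big` k-mers inserted
#'   per read (5'-anchored).
#' @param m minimum number of sliding-window tests per path.
#' @param M maximum number of tests; a repeat whose required tests exceed
#'   `M` is skipped.
#' @param f correction factor applied to the estimated read spacing when
#'   computing the required number of tests.
#' @param margin minimum number of bases the window must overlap on each
#'   node adjacent to the repeat (bp).
#' @param h number of Bloom filter hash functions.
#' @param max_side_paths cap on flank extension paths per repeat side.
#' @param max_combinations cap on evaluated path combinations; defaults to
#'   `max_side_paths^2` and must equal it.
#' @param iterations evaluation/resolution passes per read-size library.
#' @param k_big optional override of the long k-mer size; `NULL` selects
#'   `min(k_assembly + 60, read_length - t + 1)` per library.
#' @param bloom_bits Bloom filter size in bits (default 64 MiB).
#' @param seed integer seed driving combination subsampling (and anything
#'   else stochastic in a run).
#'
#' @return an object of class `kr_params` (a validated list).
#' @export
algorithm_params <- function(t = 4L, m = 18L, M = 40L, f = 4, margin = 2L,
                             h = 7L, max_side_paths = 75L,
                             max_combinations = max_side_paths^2,
                             iterations = 2L, k_big = NULL,
                             bloom_bits = 2^29, seed = 1L) {
  p <- list(t = as.integer(t), m = as.integer(m), M = as.integer(M),
            f = as.numeric(f), margin = as.integer(margin), h = as.integer(h),
            max_side_paths = as.integer(max_side_paths),
            max_combinations = as.integer(max_combinations),
            iterations = as.integer(iterations),
            k_big = if (is.null(k_big)) NULL else as.integer(k_big),
            bloom_bits = as.numeric(bloom_bits), seed = as.integer(seed))
  if (p$t < 1L) stop("support threshold t must be >= 1")
  if (p$m < p$t) stop("minimum tests m must be >= t")
  if (p$M < p$m) stop("maximum tests M must be >= m")
  if (p$f < 1) stop("correction factor f must be >= 1")
  if (p$margin < 0L) stop("margin must be >= 0")
  if (p$h < 1L) stop("hash count h must be >= 1")
  if (p$max_side_paths < 1L) stop("max_side_paths must be >= 1")
  if (p$max_combinations != p$max_side_paths^2)
    stop("max_combinations must equal max_side_paths^2")
  if (p$iterations < 1L) stop("iterations must be >= 1")
  if (p$bloom_bits < 64) stop("bloom_bits must be >= 64")
  class(p) <- "kr_params"
  p
}

#' @export
print.kr_params <- function(x, ...) {
  cat("kresolve parameters:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-16s %s\n", nm, if (is.null(v)) "AUTO" else format(v)))
  }
  invisible(x)
}
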