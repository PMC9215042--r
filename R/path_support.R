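# Sliding-window path evaluation.
#
# For a junction path in -> repeat -> out, every valid window start (the
# window must cover the whole repeat and overlap each adjacent node by at
# least `margin` bases) is a membership test against the read index. The
# evaluator performs the planned number of tests at the leftmost valid
# starts; a path reaching `t` positive queries is supported. When the
# window outreaches short flanking nodes, the flanks are expanded through
# their own neighbours ("complex repeats"), every combination of left and
# right extensions is a candidate path, and support of any combination
# supports the original three-node path.

#' Count window hits over a spelled path
#'
#' Queries the index at every start in `[start_low, start_high]` (1-based,
#' step 1 bp). `NA` results (non-ACGT windows) count as misses.
#'
#' @param path_seq spelled nucleotide string.
#' @param start_low,start_high inclusive 1-based window start bounds.
#' @param index a `kr_kmer_index`.
#' @return list with `hits` and `tests_done`.
#' @export
count_window_hits <- function(path_seq, start_low, start_high, index) {
  stopifnot(start_high >= start_low, start_low >= 1,
            start_high + index$k - 1 <= nchar(path_seq))
  res <- query_starts(index, path_seq, start_low:start_high)
  list(hits = sum(res, na.rm = TRUE),
       tests_done = as.integer(start_high - start_low + 1))
}

# One-sided flank expansion, breadth-first in sorted neighbour order.
# Returns a list of extensions; each extension is a data frame (id, or)
# ordered from the anchor outwards, with attribute `extra` = bases
# contributed beyond the anchor. Expansion stops a branch as soon as it
# supplies `needed` bases or dead-ends; at most `max_side_paths` branches
# are kept.
expand_side <- function(graph, anchor_id, anchor_or, direction, needed,
                        params) {
  empty <- data.frame(id = character(), or = character(),
                      stringsAsFactors = FALSE)
  attr(empty, "extra") <- 0
  if (needed <= 0) return(list(empty))
  ov <- graph$k - 1L
  completed <- list()
  queue <- list(empty)
  while (length(queue) > 0 && length(completed) < params$max_side_paths) {
    part <- queue[[1]]
    queue <- queue[-1]
    n <- nrow(part)
    outer_id <- if (n == 0) anchor_id else part$id[n]
    outer_or <- if (n == 0) anchor_or else part$or[n]
    nbrs <- if (direction == "left") in_neighbors(graph, outer_id, outer_or)
            else out_neighbors(graph, outer_id, outer_or)
    if (nrow(nbrs) == 0) {
      completed[[length(completed) + 1L]] <- part # dead end: maximal as-is
      next
    }
    for (i in seq_len(nrow(nbrs))) {
      if (length(completed) >= params$max_side_paths) break
      ext <- rbind(part, nbrs[i, , drop = FALSE])
      rownames(ext) <- NULL
      extra <- attr(part, "extra") +
        nchar(node_seq(graph, nbrs$id[i])) - ov
      attr(ext, "extra") <- extra
      if (extra >= needed) {
        completed[[length(completed) + 1L]] <- ext
      } else {
        queue[[length(queue) + 1L]] <- ext
      }
    }
  }
  if (length(completed) == 0) completed <- list(empty)
  completed
}

#' Enumerate path combinations for a complex repeat
#'
#' Expands the three-node path `in -> repeat -> out` through predecessors
#' of `in` and successors of `out` until each side supplies
#' `needed_left`/`needed_right` extra bases (or dead-ends), capped at
#' `max_side_paths` extensions per side. Returns the cross product of
#' left and right extensions as full paths.
#'
#' @param graph a `kr_graph`.
#' @param site repeat site.
#' @param in_node,out_node single-row oriented-node data frames.
#' @param needed_left,needed_right extra bases required per side (bp);
#'   0 or less means the flank already suffices.
#' @param params [algorithm_params()].
#' @return list of paths, each a list with `ids`, `ors`.
#' @export
expand_complex_paths <- function(graph, site, in_node, out_node, needed_left,
                                 needed_right, params = algorithm_params()) {
  lefts <- expand_side(graph, in_node$id, in_node$or, "left", needed_left,
                       params)
  rights <- expand_side(graph, out_node$id, out_node$or, "right",
                        needed_right, params)
  combos <- vector("list", length(lefts) * length(rights))
  idx <- 1L
  for (le in lefts) {
    l_ids <- rev(le$id); l_ors <- rev(le$or)
    for (ri in rights) {
      combos[[idx]] <- list(
        ids = c(l_ids, in_node$id, site$repeat_id, out_node$id, ri$id),
        ors = c(l_ors, in_node$or, "+", out_node$or, ri$or),
        rep_index = length(l_ids) + 2L)
      idx <- idx + 1L
    }
  }
  combos
}

#' Randomly subsample path combinations
#'
#' Combinations beyond `max_combinations` are subsampled uniformly (using
#' the current RNG stream, seeded by the run) to bound run time and the
#' accumulation of Bloom false positives over many tested paths.
#'
#' @param paths list of path combinations.
#' @param params [algorithm_params()].
#' @return the input list, or a uniform subset of exactly
#'   `max_combinations` (input order preserved).
#' @export
subsample_combinations <- function(paths, params = algorithm_params()) {
  if (length(paths) <= params$max_combinations) return(paths)
  keep <- sort(sample.int(length(paths), params$max_combinations))
  paths[keep]
}

#' Evaluate one junction path
#'
#' Builds the test plan, expands flanks when the window outreaches them,
#' and slides the window over the first `tests` valid positions of each
#' combination (leftmost first). The path is supported when any
#' combination reaches `t` hits.
#'
#' @param graph a `kr_graph`.
#' @param site repeat site.
#' @param in_node,out_node single-row oriented-node data frames.
#' @param index a `kr_kmer_index` built from the reads.
#' @param library the `kr_read_library` the index was built from.
#' @param k_big window size.
#' @param params [algorithm_params()].
#' @return list with `in_node`, `out_node`, `verdict`, `tests_done`,
#'   `hits` (max over combinations), `supported` (`NA` on skip),
#'   `n_combinations`.
#' @export
evaluate_path <- function(graph, site, in_node, out_node, index, library,
                          k_big, params = algorithm_params()) {
  plan <- plan_tests(graph, site, in_node, out_node, library, k_big, params)
  result <- list(in_node = in_node, out_node = out_node,
                 verdict = plan$verdict, plan = plan, tests_done = 0L,
                 hits = NA_integer_, supported = NA, n_combinations = 0L)
  if (plan$verdict != "proceed") return(result)

  ov <- graph$k - 1L
  L_rep <- nchar(node_seq(graph, site$repeat_id))
  avail_left <- nchar(node_seq(graph, in_node$id)) - ov
  avail_right <- nchar(node_seq(graph, out_node$id)) - ov
  reach <- k_big - L_rep - params$margin # max window reach into one flank
  needed_left <- max(0L, reach - avail_left)
  needed_right <- max(0L, reach - avail_right)

  combos <- expand_complex_paths(graph, site, in_node, out_node, needed_left,
                                 needed_right, params)
  combos <- subsample_combinations(combos, params)
  result$n_combinations <- length(combos)

  # per-combination valid window ranges
  ranges <- vector("list", length(combos))
  avail <- integer(length(combos))
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    pre <- seq_len(cb$rep_index - 1L)
    r0 <- sum(vapply(cb$ids[pre],
                     function(id) nchar(node_seq(graph, id)) - ov, 0L))
    total <- path_length(graph, cb$ids, cb$ors)
    rng <- window_start_range(r0, L_rep, total - r0 - L_rep, k_big,
                              params$margin)
    ranges[[i]] <- list(r0 = r0, rng = rng)
    avail[i] <- if (is.null(rng)) 0L else as.integer(rng[2] - rng[1] + 1L)
  }
  if (max(avail) < plan$tests) {
    result$verdict <- "skip_too_few_positions"
    return(result)
  }

  best_hits <- 0L
  for (i in seq_along(combos)) {
    if (avail[i] < plan$tests) next # cannot complete the planned tests
    cb <- combos[[i]]
    seq <- spell_path(graph, cb$ids, cb$ors)
    r0 <- ranges[[i]]$r0
    lo_abs <- r0 + ranges[[i]]$rng[1] + 1L # to 1-based string coords
    wh <- count_window_hits(seq, lo_abs, lo_abs + plan$tests - 1L, index)
    best_hits <- max(best_hits, wh$hits)
    if (best_hits >= params$t) break
  }
  result$tests_done <- plan$tests
  result$hits <- as.integer(best_hits)
  result$supported <- best_hits >= params$t
  result
}

#' Evaluate all junction paths of a repeat site
#'
#' Evaluates every (in, out) pair. If any pair draws a skip verdict the
#' whole site is marked skipped: a repeat cannot be resolved accurately
#' without complete information, so partial knowledge is never acted on.
#'
#' @param graph a `kr_graph`.
#' @param site repeat site from [find_repeat_sites()].
#' @param index a `kr_kmer_index`.
#' @param library a `kr_read_library`.
#' @param k_big window size.
#' @param params [algorithm_params()].
#' @return object of class `kr_support_matrix`: list with `site`,
#'   `entries` (data frame: in/out ids and orientations, verdict, tests,
#'   hits, supported), `site_skipped`.
#' @export
evaluate_repeat <- function(graph, site, index, library, k_big,
                            params = algorithm_params()) {
  rows <- list()
  for (i in seq_len(nrow(site$ins))) {
    for (j in seq_len(nrow(site$outs))) {
      ev <- evaluate_path(graph, site, site$ins[i, , drop = FALSE],
                          site$outs[j, , drop = FALSE], index, library,
                          k_big, params)
      rows[[length(rows) + 1L]] <- data.frame(
        in_id = site$ins$id[i], in_or = site$ins$or[i],
        out_id = site$outs$id[j], out_or = site$outs$or[j],
        verdict = ev$verdict, tests_done = ev$tests_done,
        hits = ev$hits, supported = ev$supported,
        stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, rows)
  rownames(entries) <- NULL
  out <- list(site = site, entries = entries,
              site_skipped = any(entries$verdict != "proceed"))
  class(out) <- "kr_support_matrix"
  out
}

#' @export
print.kr_support_matrix <- function(x, ...) {
  cat(sprintf("kr_support_matrix for repeat %s (%s)\n", x$site$repeat_id,
              if (x$site_skipped) "skipped" else "evaluated"))
  print(x$entries)
  invisible(x)
}
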