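# Candidate repeat discovery and the coverage-adaptive test planner.
#
# A repeat site is a node with >= 2 in-neighbours and >= 2 out-neighbours
# (taken in "+" orientation; the condition is strand-symmetric, so each
# physical repeat yields exactly one site). For each (in, out) pair the
# planner estimates how many reads contributed to the three-node path from
# the assembly-k multiplicity sums, converts that to an expected spacing
# between read 5' ends, and derives the number of sliding-window tests
# needed to catch at least one read's k-mers:
#
#   reads_on_path  R_p = sum(cov_sum) / (l - k_assembly + 1)
#   read_spacing   s   = (L - l + 1) / R_p           (0 when L < l)
#   required tests     = ceil(max(m, s * f + t))     (skip when > M)
#
# A repeat is only evaluable if the window can overlap all three nodes by
# at least `margin` bases while still performing `tests` moves:
#   L_repeat <= k_big - (tests - 1) - 2 * margin.

#' Find candidate repeat sites
#'
#' @param graph a `kr_graph`.
#' @return list of sites, each a list with `repeat_id`, `ins`, `outs`
#'   (oriented neighbour data frames), sorted by repeat node id.
#'   Palindromic nodes and nodes with self-loops are excluded.
#' @export
find_repeat_sites <- function(graph) {
  sites <- list()
  for (id in node_ids(graph)) {
    if (has_self_loop(graph, id) || is_palindromic(graph, id)) next
    ins <- in_neighbors(graph, id, "+")
    outs <- out_neighbors(graph, id, "+")
    if (nrow(ins) >= 2L && nrow(outs) >= 2L) {
      sites[[length(sites) + 1L]] <- list(repeat_id = id, ins = ins,
                                          outs = outs)
    }
  }
  sites
}

#' Estimated number of reads contributing to a path
#'
#' Every read of length `l` contributes `l - k_assembly + 1` assembly
#' k-mers, so the multiplicity sum over the path nodes divided by that
#' count estimates the contributing reads.
#'
#' @param graph a `kr_graph`.
#' @param ids path node ids.
#' @param read_length read length `l` in bp.
#' @return non-negative numeric estimate.
#' @export
reads_on_path <- function(graph, ids, read_length) {
  if (read_length <= graph$k)
    stop(sprintf("read length %d must exceed k_assembly %d",
                 read_length, graph$k))
  cov <- sum(vapply(ids, function(i) node_cov(graph, i), 0))
  cov / (read_length - graph$k + 1)
}

#' Approximate spacing between neighbouring reads on a path
#'
#' @param L spelled path length (bp).
#' @param read_length read length `l` (bp).
#' @param r_p estimated contributing reads (must be > 0).
#' @return spacing in bp; 0 when `L < read_length` (reads overhang the
#'   path, the dense-coverage limit).
#' @export
read_spacing <- function(L, read_length, r_p) {
  stopifnot(r_p > 0)
  if (L < read_length) return(0)
  (L - read_length + 1) / r_p
}

#' Required sliding-window tests
#'
#' @param s estimated read spacing (bp).
#' @param params [algorithm_params()].
#' @return list with `tests` (integer, rounded up) and `verdict`
#'   (`"proceed"` or `"skip_exceeds_cap"` when tests exceed the maximum).
#' @export
required_tests <- function(s, params = algorithm_params()) {
  stopifnot(s >= 0)
  tests <- as.integer(ceiling(max(params$m, s * params$f + params$t)))
  verdict <- if (tests > params$M) "skip_exceeds_cap" else "proceed"
  list(tests = tests, verdict = verdict)
}

#' Number of valid window start positions over a repeat
#'
#' With the repeat occupying `[0, L_repeat)` on the spelled path and
#' `avail_left`/`avail_right` flanking bases, a window start `x` (relative
#' to the repeat start) is valid when the window covers the whole repeat
#' plus `margin` bases on each adjacent node:
#' `max(L_repeat + margin - k_big, -avail_left) <= x <=
#'  min(-margin, L_repeat + avail_right - k_big)`.
#'
#' @param avail_left,avail_right flanking bases on each side (bp).
#' @param L_repeat repeat node length (bp).
#' @param k_big window size (bp).
#' @param margin minimum overlap on each adjacent node (bp).
#' @return non-negative count of valid starts.
#' @export
window_position_count <- function(avail_left, L_repeat, avail_right, k_big,
                                  margin) {
  lo <- max(L_repeat + margin - k_big, -avail_left)
  hi <- min(-margin, L_repeat + avail_right - k_big)
  max(0L, as.integer(hi - lo + 1))
}

# the valid relative start range itself (used by the evaluator)
window_start_range <- function(avail_left, L_repeat, avail_right, k_big,
                               margin) {
  lo <- max(L_repeat + margin - k_big, -avail_left)
  hi <- min(-margin, L_repeat + avail_right - k_big)
  if (hi < lo) return(NULL)
  c(lo, hi)
}

#' Repeat eligibility for path evaluation
#'
#' @param L_repeat repeat node length (bp).
#' @param k_big window size (bp).
#' @param tests required number of window moves.
#' @param margin minimum overlap on adjacent nodes (bp).
#' @return `TRUE` iff `L_repeat <= k_big - (tests - 1) - 2 * margin`.
#' @export
repeat_eligible <- function(L_repeat, k_big, tests, margin) {
  stopifnot(tests >= 1)
  L_repeat <= k_big - (tests - 1) - 2 * margin
}

#' Plan the evaluation of one (in, out) junction path
#'
#' Composes [reads_on_path()], [read_spacing()], [required_tests()] and the
#' eligibility bound on the three-node path `in -> repeat -> out`. The
#' eligibility check here assumes flanks can be extended at need (the
#' complex-repeat expansion); the evaluator re-checks against what the
#' expansion actually supplies.
#'
#' @param graph a `kr_graph`.
#' @param site a repeat site from [find_repeat_sites()].
#' @param in_node,out_node single-row oriented-node data frames (`id`,`or`).
#' @param library a `kr_read_library`.
#' @param k_big window size.
#' @param params [algorithm_params()].
#' @return list with `tests`, `s`, `r_p`, `L`, `verdict` (one of
#'   `"proceed"`, `"skip_low_coverage"`, `"skip_exceeds_cap"`,
#'   `"skip_too_few_positions"`).
#' @export
plan_tests <- function(graph, site, in_node, out_node, library, k_big,
                       params = algorithm_params()) {
  ids <- c(in_node$id, site$repeat_id, out_node$id)
  ors <- c(in_node$or, "+", out_node$or)
  for (i in 1:2) {
    if (!has_edge(graph, ids[i], ors[i], ids[i + 1], ors[i + 1]))
      stop(sprintf("site %s: missing link %s%s -> %s%s", site$repeat_id,
                   ids[i], ors[i], ids[i + 1], ors[i + 1]))
  }
  L <- path_length(graph, ids, ors)
  r_p <- reads_on_path(graph, ids, library$read_length)
  if (r_p == 0)
    return(list(tests = NA_integer_, s = NA_real_, r_p = 0, L = L,
                verdict = "skip_low_coverage"))
  s <- read_spacing(L, library$read_length, r_p)
  rt <- required_tests(s, params)
  if (rt$verdict != "proceed")
    return(list(tests = rt$tests, s = s, r_p = r_p, L = L,
                verdict = rt$verdict))
  L_rep <- nchar(node_seq(graph, site$repeat_id))
  if (!repeat_eligible(L_rep, k_big, rt$tests, params$margin))
    return(list(tests = rt$tests, s = s, r_p = r_p, L = L,
                verdict = "skip_too_few_positions"))
  list(tests = rt$tests, s = s, r_p = r_p, L = L, verdict = "proceed")
}
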