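# Turning support matrices into graph edits, and the run driver.
#
# The support matrix of a site is read as a bipartite graph between in-
# and out-neighbours. Each connected component of supported pairs gets its
# own copy of the repeat sequence; a 1-to-1 component merges into a plain
# linear path, larger components leave a smaller, simplified repeat.
# Neighbours with no supported partner lose their link to the repeat, but
# only when something else on the site is supported - an entirely
# unsupported site is left untouched rather than risking stranding true
# sequence on index misses.

#' Plan graph edits for one evaluated repeat site
#'
#' @param site repeat site from [find_repeat_sites()].
#' @param matrix `kr_support_matrix` from [evaluate_repeat()].
#' @param params [algorithm_params()].
#' @return a resolution edit: list with `noop` and, when actionable,
#'   `repeat_id`, `components` (each with `ins`, `outs` data frames),
#'   `removed_ins`, `removed_outs`, `classification`
#'   (`"resolved"` = all components 1-to-1, else `"simplified"`) and
#'   `pairs_removed`.
#' @export
plan_resolution <- function(site, matrix, params = algorithm_params()) {
  if (matrix$site_skipped) return(list(noop = TRUE, reason = "skipped"))
  e <- matrix$entries
  sup <- e[e$supported %in% TRUE, , drop = FALSE]
  if (nrow(sup) == 0) return(list(noop = TRUE, reason = "no_support"))

  ins_all <- unique(e[, c("in_id", "in_or")])
  outs_all <- unique(e[, c("out_id", "out_or")])
  ikey <- function(df) paste0("I:", df$in_id, df$in_or)
  okey <- function(df) paste0("O:", df$out_id, df$out_or)

  # union-find over supported pairs
  parent <- new.env(parent = emptyenv())
  find <- function(x) {
    p <- get0(x, envir = parent, ifnotfound = x)
    if (p == x) return(x)
    r <- find(p)
    assign(x, r, envir = parent)
    r
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) assign(ra, rb, envir = parent)
  }
  for (r in seq_len(nrow(sup))) {
    union(ikey(sup[r, , drop = FALSE]), okey(sup[r, , drop = FALSE]))
  }

  sup_ikeys <- unique(ikey(sup))
  sup_okeys <- unique(okey(sup))
  removed_ins <- ins_all[!(ikey(ins_all) %in% sup_ikeys), , drop = FALSE]
  removed_outs <- outs_all[!(okey(outs_all) %in% sup_okeys), , drop = FALSE]

  roots_i <- vapply(sup_ikeys, find, "")
  roots_o <- vapply(sup_okeys, find, "")
  comp_roots <- sort(unique(c(roots_i, roots_o)))
  components <- lapply(comp_roots, function(root) {
    ins <- ins_all[ikey(ins_all) %in% sup_ikeys[roots_i == root], ,
                   drop = FALSE]
    outs <- outs_all[okey(outs_all) %in% sup_okeys[roots_o == root], ,
                     drop = FALSE]
    rownames(ins) <- NULL; rownames(outs) <- NULL
    names(ins) <- c("id", "or"); names(outs) <- c("id", "or")
    list(ins = ins, outs = outs)
  })

  n_removed <- nrow(removed_ins) + nrow(removed_outs)
  if (length(components) == 1L && n_removed == 0L) {
    return(list(noop = TRUE, reason = "single_component"))
  }
  pairs_before <- nrow(ins_all) * nrow(outs_all)
  pairs_after <- sum(vapply(components,
                            function(cp) nrow(cp$ins) * nrow(cp$outs), 0))
  resolved <- all(vapply(components, function(cp)
    nrow(cp$ins) == 1L && nrow(cp$outs) == 1L, NA))
  list(noop = FALSE, repeat_id = site$repeat_id, components = components,
       removed_ins = removed_ins, removed_outs = removed_outs,
       classification = if (resolved) "resolved" else "simplified",
       pairs_removed = pairs_before - pairs_after)
}

#' Apply resolution edits to a graph
#'
#' Applies each edit atomically: the repeat node is removed and replaced by
#' one copy per support component, inheriting the sequence and an equal
#' split of the multiplicity sum; component neighbours are re-linked to
#' their copy; unsupported neighbours are not re-linked. Edits whose
#' referenced nodes were consumed by an earlier edit in the same pass are
#' deferred (the next iteration re-evaluates them). Finishes with one
#' [merge_unambiguous_paths()] pass.
#'
#' @param graph a `kr_graph`.
#' @param edits list of edits from [plan_resolution()].
#' @return list with `graph`, `applied` (the edits actually applied),
#'   `deferred` (count), `merge_count`.
#' @export
apply_edits <- function(graph, edits) {
  applied <- list()
  deferred <- 0L
  for (ed in edits) {
    if (isTRUE(ed$noop)) next
    need <- c(ed$repeat_id,
              unlist(lapply(ed$components, function(cp) c(cp$ins$id,
                                                          cp$outs$id))))
    if (!all(need %in% names(graph$nodes))) {
      deferred <- deferred + 1L
      next
    }
    rep_seq <- node_seq(graph, ed$repeat_id)
    rep_cov <- node_cov(graph, ed$repeat_id)
    graph <- remove_node(graph, ed$repeat_id)
    ncomp <- length(ed$components)
    for (i in seq_len(ncomp)) {
      cid <- sprintf("%s.%d", ed$repeat_id, i)
      while (cid %in% names(graph$nodes)) cid <- paste0(cid, "c")
      graph <- add_node(graph, cid, rep_seq, rep_cov / ncomp)
      cp <- ed$components[[i]]
      for (r in seq_len(nrow(cp$ins)))
        graph <- add_edge(graph, cp$ins$id[r], cp$ins$or[r], cid, "+")
      for (r in seq_len(nrow(cp$outs)))
        graph <- add_edge(graph, cid, "+", cp$outs$id[r], cp$outs$or[r])
    }
    applied[[length(applied) + 1L]] <- ed
  }
  mg <- merge_unambiguous_paths(graph)
  list(graph = mg$graph, applied = applied, deferred = deferred,
       merge_count = mg$merge_count)
}

#' Choose the long k-mer size for a library
#'
#' The empirical heuristic `k_assembly + 60`, capped at
#' `read_length - t + 1` so that every read still yields `t` k-mers.
#' A user override is validated against the same bounds.
#'
#' @param k_assembly graph k.
#' @param read_length library read length.
#' @param params [algorithm_params()]; `params$k_big` overrides.
#' @return the long k-mer size (integer).
#' @export
choose_k_big <- function(k_assembly, read_length, params = algorithm_params()) {
  if (read_length <= k_assembly)
    stop(sprintf("read length %d must exceed k_assembly %d", read_length,
                 k_assembly))
  cap <- read_length - params$t + 1L
  k <- if (!is.null(params$k_big)) params$k_big
       else min(k_assembly + 60L, cap)
  if (k <= k_assembly)
    stop(sprintf("k_big (%d) must exceed k_assembly (%d)", k, k_assembly))
  if (k > cap)
    stop(sprintf("k_big (%d) leaves fewer than t = %d k-mers per %d bp read",
                 k, params$t, read_length))
  as.integer(k)
}

#' Resolve repeats in a unitig graph
#'
#' The full driver. For each read library, ascending by read length: pick
#' the long k-mer size, index the reads' 5'-anchored k-mers, then run
#' `iterations` passes of find sites, evaluate support, plan edits,
#' apply and merge. Fully deterministic given `params$seed`.
#'
#' @param graph a validated `kr_graph`.
#' @param libraries a `kr_read_library` or list thereof.
#' @param params [algorithm_params()].
#' @return list with `graph` (edited) and `report` (a `kr_run_report`:
#'   per-library, per-iteration counter data frame with per-library index
#'   statistics in attribute `index_stats`).
#' @export
resolve_graph <- function(graph, libraries, params = algorithm_params()) {
  if (inherits(libraries, "kr_read_library")) libraries <- list(libraries)
  if (length(libraries) == 0) stop("at least one read library is required")
  bad <- validate_graph(graph)
  if (length(bad) > 0)
    stop(sprintf("input graph fails validation: %s", bad[1]))
  libraries <- libraries[order(vapply(libraries, `[[`, 0L, "read_length"))]

  set.seed(params$seed)
  rows <- list()
  index_stats <- list()

  for (lib in libraries) {
    k_big <- choose_k_big(graph$k, lib$read_length, params)
    index <- build_read_index(lib, k_big, params)
    st <- if (inherits(index, "kr_bloom")) bloom_stats(index)
          else list(bits = NA, h = NA, k = index$k, n_inserted = NA, fpr = 0)
    index_stats[[length(index_stats) + 1L]] <- c(
      list(read_length = lib$read_length, k_big = k_big,
           reads_skipped = attr(index, "reads_skipped")), st)

    for (iter in seq_len(params$iterations)) {
      sites <- find_repeat_sites(graph)
      counters <- c(sites_found = length(sites), sites_skipped = 0L,
                    skip_low_coverage = 0L, skip_exceeds_cap = 0L,
                    skip_too_few_positions = 0L, sites_resolved = 0L,
                    sites_simplified = 0L, sites_unchanged = 0L,
                    sites_deferred = 0L, pairs_removed = 0L,
                    nodes_merged = 0L)
      edits <- list()
      for (site in sites) {
        mat <- evaluate_repeat(graph, site, index, lib, k_big, params)
        if (mat$site_skipped) {
          counters["sites_skipped"] <- counters["sites_skipped"] + 1L
          reason <- setdiff(unique(mat$entries$verdict), "proceed")[1]
          counters[reason] <- counters[reason] + 1L
          next
        }
        ed <- plan_resolution(site, mat, params)
        if (isTRUE(ed$noop)) {
          counters["sites_unchanged"] <- counters["sites_unchanged"] + 1L
        } else {
          edits[[length(edits) + 1L]] <- ed
        }
      }
      ap <- apply_edits(graph, edits)
      graph <- ap$graph
      counters["sites_deferred"] <- ap$deferred
      counters["nodes_merged"] <- ap$merge_count
      for (ed in ap$applied) {
        key <- if (ed$classification == "resolved") "sites_resolved"
               else "sites_simplified"
        counters[key] <- counters[key] + 1L
        counters["pairs_removed"] <- counters["pairs_removed"] +
          ed$pairs_removed
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read_length = lib$read_length, iteration = iter,
        as.list(counters), stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "index_stats") <- index_stats
  class(report) <- c("kr_run_report", class(report))
  list(graph = graph, report = report)
}

#' @export
print.kr_run_report <- function(x, ...) {
  cat("kresolve run report\n")
  print.data.frame(x)
  for (st in attr(x, "index_stats")) {
    cat(sprintf(
      "library %d bp: k_big = %d, %g k-mers indexed, FPR %.3g, %d reads skipped\n",
      st$read_length, st$k_big, st$n_inserted, st$fpr, st$reads_skipped))
  }
  invisible(x)
}
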