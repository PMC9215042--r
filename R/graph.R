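# Oriented unitig-graph model.
#
# A graph holds k_assembly, a named list of nodes (sequence + k-mer
# multiplicity sum) and a link table. Every link is stored once, in a
# mirror-canonical form: the link (u, uo) -> (v, vo) and its
# reverse-complement mirror (v, flip(vo)) -> (u, flip(uo)) denote the same
# physical adjacency, matching GFA semantics. Neighbour queries consult
# both readings, so strand symmetry is structural rather than enforced by
# duplicated records.

#' Reverse complement of plain character DNA
#'
#' @param x character vector of sequences over A/C/G/T (IUPAC letters other
#'   than ACGT are complemented via N-preserving rules of `chartr`).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

flip_orient <- function(or) ifelse(or == "+", "-", "+")

empty_edges <- function() {
  data.frame(from = character(), from_or = character(), to = character(),
             to_or = character(), stringsAsFactors = FALSE)
}

#' Construct a sequence graph
#'
#' @param k_assembly k-mer size the graph was built at; all link overlaps
#'   are `k_assembly - 1` bases.
#' @param ids,seqs,covs node identifiers, sequences and k-mer multiplicity
#'   sums (parallel vectors).
#' @param edges data frame with columns `from`, `from_or`, `to`, `to_or`
#'   (orientations `"+"`/`"-"`).
#' @return an object of class `kr_graph`.
#' @export
sequence_graph <- function(k_assembly, ids = character(), seqs = character(),
                           covs = numeric(), edges = empty_edges()) {
  stopifnot(length(ids) == length(seqs), length(ids) == length(covs))
  if (anyDuplicated(ids)) stop("duplicate node ids")
  nodes <- list()
  for (i in seq_along(ids)) {
    nodes[[ids[i]]] <- list(seq = toupper(seqs[i]), cov = as.numeric(covs[i]))
  }
  g <- list(k = as.integer(k_assembly), nodes = nodes, edges = empty_edges())
  class(g) <- "kr_graph"
  for (i in seq_len(nrow(edges))) {
    g <- add_edge(g, edges$from[i], edges$from_or[i], edges$to[i],
                  edges$to_or[i])
  }
  g
}

#' @export
print.kr_graph <- function(x, ...) {
  cat(sprintf("kr_graph: %d nodes, %d links, k_assembly = %d\n",
              length(x$nodes), nrow(x$edges), x$k))
  invisible(x)
}

node_ids <- function(graph) sort(names(graph$nodes))

node_seq <- function(graph, id) {
  n <- graph$nodes[[id]]
  if (is.null(n)) stop(sprintf("node '%s' not in graph", id))
  n$seq
}

node_cov <- function(graph, id) graph$nodes[[id]]$cov

oriented_seq <- function(graph, id, or) {
  s <- node_seq(graph, id)
  if (or == "+") s else revcomp(s)
}

is_palindromic <- function(graph, id) {
  s <- node_seq(graph, id)
  identical(s, revcomp(s))
}

# mirror-canonical form of one link
normalize_edge <- function(from, from_or, to, to_or) {
  a <- c(from, from_or, to, to_or)
  b <- c(to, flip_orient(to_or), from, flip_orient(from_or))
  key_a <- paste(a, collapse = "\r")
  key_b <- paste(b, collapse = "\r")
  if (key_a <= key_b) a else b
}

add_node <- function(graph, id, seq, cov = 0) {
  if (!is.null(graph$nodes[[id]])) stop(sprintf("node '%s' already exists", id))
  graph$nodes[[id]] <- list(seq = toupper(seq), cov = as.numeric(cov))
  graph
}

# drops incident links
remove_node <- function(graph, id) {
  if (is.null(graph$nodes[[id]])) stop(sprintf("node '%s' not in graph", id))
  graph$nodes[[id]] <- NULL
  e <- graph$edges
  keep <- e$from != id & e$to != id
  graph$edges <- e[keep, , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

add_edge <- function(graph, from, from_or, to, to_or) {
  if (is.null(graph$nodes[[from]]) || is.null(graph$nodes[[to]]))
    stop(sprintf("link %s%s -> %s%s references a missing node",
                 from, from_or, to, to_or))
  n <- normalize_edge(from, from_or, to, to_or)
  e <- graph$edges
  dup <- e$from == n[1] & e$from_or == n[2] & e$to == n[3] & e$to_or == n[4]
  if (!any(dup)) {
    graph$edges <- rbind(e, data.frame(from = n[1], from_or = n[2], to = n[3],
                                       to_or = n[4], stringsAsFactors = FALSE))
  }
  graph
}

remove_edge <- function(graph, from, from_or, to, to_or) {
  n <- normalize_edge(from, from_or, to, to_or)
  e <- graph$edges
  hit <- e$from == n[1] & e$from_or == n[2] & e$to == n[3] & e$to_or == n[4]
  graph$edges <- e[!hit, , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

has_edge <- function(graph, from, from_or, to, to_or) {
  n <- normalize_edge(from, from_or, to, to_or)
  e <- graph$edges
  any(e$from == n[1] & e$from_or == n[2] & e$to == n[3] & e$to_or == n[4])
}

#' Oriented out-neighbours of a node
#'
#' @param graph a `kr_graph`.
#' @param id node identifier.
#' @param or orientation, `"+"` or `"-"`.
#' @return data frame with columns `id`, `or`, sorted for determinism.
#' @export
out_neighbors <- function(graph, id, or) {
  e <- graph$edges
  fwd <- e[e$from == id & e$from_or == or, c("to", "to_or"), drop = FALSE]
  names(fwd) <- c("id", "or")
  mir <- e[e$to == id & e$to_or == flip_orient(or), c("from", "from_or"),
           drop = FALSE]
  res <- rbind(fwd, data.frame(id = mir$from, or = flip_orient(mir$from_or),
                               stringsAsFactors = FALSE))
  res <- unique(res)
  res <- res[order(res$id, res$or), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Oriented in-neighbours of a node
#'
#' In-neighbours of `(id, or)` are the mirror image of the out-neighbours
#' of `(id, flip(or))`: each is returned in the orientation in which it
#' points *into* the node.
#'
#' @inheritParams out_neighbors
#' @return data frame with columns `id`, `or`.
#' @export
in_neighbors <- function(graph, id, or) {
  res <- out_neighbors(graph, id, flip_orient(or))
  res$or <- flip_orient(res$or)
  res <- res[order(res$id, res$or), , drop = FALSE]
  rownames(res) <- NULL
  res
}

out_degree <- function(graph, id, or) nrow(out_neighbors(graph, id, or))
in_degree <- function(graph, id, or) nrow(in_neighbors(graph, id, or))

has_self_loop <- function(graph, id) {
  e <- graph$edges
  any(e$from == id & e$to == id)
}

#' Spell the sequence of a path
#'
#' Concatenates the oriented node sequences along a path, dropping the
#' `k_assembly - 1` base overlap at every junction. Consecutive steps must
#' be joined by a link.
#'
#' @param graph a `kr_graph`.
#' @param ids node identifiers along the path.
#' @param ors orientations along the path (`"+"`/`"-"`).
#' @return the spelled nucleotide string.
#' @export
spell_path <- function(graph, ids, ors) {
  stopifnot(length(ids) == length(ors), length(ids) >= 1)
  for (i in seq_len(length(ids) - 1)) {
    if (!has_edge(graph, ids[i], ors[i], ids[i + 1], ors[i + 1]))
      stop(sprintf("no link %s%s -> %s%s on path", ids[i], ors[i],
                   ids[i + 1], ors[i + 1]))
  }
  parts <- vapply(seq_along(ids),
                  function(i) oriented_seq(graph, ids[i], ors[i]), "")
  out <- parts[1]
  ov <- graph$k - 1L
  for (i in seq_along(parts)[-1]) {
    out <- paste0(out, substring(parts[i], ov + 1L))
  }
  out
}

path_length <- function(graph, ids, ors) {
  lens <- vapply(ids, function(id) nchar(node_seq(graph, id)), 0L)
  sum(lens) - (length(ids) - 1L) * (graph$k - 1L)
}

#' Validate graph invariants
#'
#' Checks that all links reference existing nodes, that oriented sequences
#' overlap by exactly `k_assembly - 1` bases across every link, and that
#' every node is at least `k_assembly` long.
#'
#' @param graph a `kr_graph`.
#' @return character vector of violation messages (empty when valid).
#' @export
validate_graph <- function(graph) {
  bad <- character()
  k <- graph$k
  for (id in names(graph$nodes)) {
    if (nchar(graph$nodes[[id]]$seq) < k)
      bad <- c(bad, sprintf("node %s shorter than k_assembly (%d < %d)",
                            id, nchar(graph$nodes[[id]]$seq), k))
  }
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    if (is.null(graph$nodes[[e$from[i]]]) || is.null(graph$nodes[[e$to[i]]])) {
      bad <- c(bad, sprintf("link %d references a missing node", i))
      next
    }
    s1 <- oriented_seq(graph, e$from[i], e$from_or[i])
    s2 <- oriented_seq(graph, e$to[i], e$to_or[i])
    if (substring(s1, nchar(s1) - k + 2L) != substring(s2, 1L, k - 1L))
      bad <- c(bad, sprintf(
        "link %s%s -> %s%s sequences do not overlap by %d bases",
        e$from[i], e$from_or[i], e$to[i], e$to_or[i], k - 1L))
  }
  bad
}

# Is the link u -> v an interior (mergeable) junction?
mergeable_link <- function(graph, uid, uor, vid, vor) {
  if (uid == vid) return(FALSE)
  if (is_palindromic(graph, uid) || is_palindromic(graph, vid)) return(FALSE)
  if (has_self_loop(graph, uid) || has_self_loop(graph, vid)) return(FALSE)
  out_degree(graph, uid, uor) == 1L && in_degree(graph, vid, vor) == 1L
}

#' Merge unambiguous chains
#'
#' Every maximal path whose interior junctions have exactly one in-link and
#' one out-link (per orientation) is collapsed into a single node. The
#' merged sequence is the spelled chain, the multiplicity sum is the sum of
#' the members', and links at the chain ends are re-attached. Palindromic
#' nodes and nodes with self-loops are never merged through. Isolated
#' unambiguous cycles are collapsed to one node carrying a self-loop.
#'
#' @param graph a `kr_graph`.
#' @return list with elements `graph` (the merged graph) and `merge_count`
#'   (number of nodes eliminated).
#' @export
merge_unambiguous_paths <- function(graph) {
  visited <- character()
  chains <- list()

  walk_chain <- function(id, or) {
    ids <- id; ors <- or
    repeat {
      cur_id <- ids[length(ids)]; cur_or <- ors[length(ors)]
      nxt <- out_neighbors(graph, cur_id, cur_or)
      if (nrow(nxt) != 1L) break
      if (!mergeable_link(graph, cur_id, cur_or, nxt$id[1], nxt$or[1])) break
      if (nxt$id[1] %in% ids) break # cycle closure
      ids <- c(ids, nxt$id[1]); ors <- c(ors, nxt$or[1])
    }
    list(ids = ids, ors = ors)
  }

  for (id in node_ids(graph)) {
    if (id %in% visited) next
    if (is_palindromic(graph, id) || has_self_loop(graph, id)) next
    for (or in c("+", "-")) {
      if (id %in% visited) break
      # chain start: cannot extend backwards through a mergeable link
      preds <- in_neighbors(graph, id, or)
      back <- nrow(preds) == 1L &&
        mergeable_link(graph, preds$id[1], preds$or[1], id, or)
      if (back) next
      ch <- walk_chain(id, or)
      if (length(ch$ids) >= 2L) {
        chains[[length(chains) + 1L]] <- ch
        visited <- c(visited, ch$ids)
      }
    }
  }
  # perfect cycles: all members 1-in-1-out, no start found above
  for (id in node_ids(graph)) {
    if (id %in% visited) next
    if (is_palindromic(graph, id) || has_self_loop(graph, id)) next
    if (out_degree(graph, id, "+") != 1L || in_degree(graph, id, "+") != 1L)
      next
    nxt <- out_neighbors(graph, id, "+")
    if (!mergeable_link(graph, id, "+", nxt$id[1], nxt$or[1])) next
    ch <- walk_chain(id, "+")
    if (length(ch$ids) >= 2L) {
      chains[[length(chains) + 1L]] <- ch
      visited <- c(visited, ch$ids)
    }
  }

  merge_count <- 0L
  for (ch in chains) {
    ids <- ch$ids; ors <- ch$ors
    m <- length(ids)
    first <- c(ids[1], ors[1]); last <- c(ids[m], ors[m])
    mid <- paste(ids, collapse = "_")
    seq <- spell_path(graph, ids, ors)
    cov <- sum(vapply(ids, function(i) node_cov(graph, i), 0))
    ext_in <- in_neighbors(graph, ids[1], ors[1])
    ext_out <- out_neighbors(graph, ids[m], ors[m])

    translate <- function(nid, nor) {
      if (!(nid %in% ids)) return(c(nid, nor))
      if ((nid == first[1] && nor == first[2]) ||
          (nid == last[1] && nor == last[2])) return(c(mid, "+"))
      if ((nid == first[1] && nor == flip_orient(first[2])) ||
          (nid == last[1] && nor == flip_orient(last[2]))) return(c(mid, "-"))
      NULL # interior reference: structurally impossible
    }

    for (id in ids) graph <- remove_node(graph, id)
    graph <- add_node(graph, mid, seq, cov)
    for (i in seq_len(nrow(ext_in))) {
      tr <- translate(ext_in$id[i], ext_in$or[i])
      if (!is.null(tr)) graph <- add_edge(graph, tr[1], tr[2], mid, "+")
    }
    for (i in seq_len(nrow(ext_out))) {
      tr <- translate(ext_out$id[i], ext_out$or[i])
      if (!is.null(tr)) graph <- add_edge(graph, mid, "+", tr[1], tr[2])
    }
    merge_count <- merge_count + m - 1L
  }
  list(graph = graph, merge_count = merge_count)
}
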