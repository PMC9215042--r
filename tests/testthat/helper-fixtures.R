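# Shared fixture builders. Everything is generated in code; no data files.

rnd_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Normalize an edge table for comparisons.
norm_edges <- function(e) {
  e <- e[do.call(order, e), , drop = FALSE]
  rownames(e) <- NULL
  e
}

# Star graph: n_in in-flanks -> repeat -> n_out out-flanks, all "+" strand,
# sequences built so every link overlaps by k-1 bases.
make_star_graph <- function(k = 5, n_in = 2, n_out = 2, rep_len = 8,
                            flank_len = 20, cov = 100) {
  ov <- k - 1
  rep_seq <- rnd_dna(rep_len)
  ids <- "R"; seqs <- rep_seq; covs <- cov
  ef <- character(); efo <- character(); et <- character(); eto <- character()
  for (i in seq_len(n_in)) {
    id <- sprintf("A%d", i)
    ids <- c(ids, id)
    seqs <- c(seqs, paste0(rnd_dna(flank_len - ov), substring(rep_seq, 1, ov)))
    covs <- c(covs, cov)
    ef <- c(ef, id); efo <- c(efo, "+"); et <- c(et, "R"); eto <- c(eto, "+")
  }
  for (i in seq_len(n_out)) {
    id <- sprintf("X%d", i)
    ids <- c(ids, id)
    seqs <- c(seqs, paste0(substring(rep_seq, rep_len - ov + 1),
                           rnd_dna(flank_len - ov)))
    covs <- c(covs, cov)
    ef <- c(ef, "R"); efo <- c(efo, "+"); et <- c(et, id); eto <- c(eto, "+")
  }
  sequence_graph(k, ids, seqs, covs,
                 data.frame(from = ef, from_or = efo, to = et, to_or = eto,
                            stringsAsFactors = FALSE))
}

# Linear chain graph spelled from one backbone string: n nodes of length
# node_len overlapping by k-1.
make_chain_graph <- function(k = 5, n = 3, node_len = 10, cov = 10) {
  step <- node_len - (k - 1)
  backbone <- rnd_dna(node_len + (n - 1) * step)
  ids <- sprintf("N%d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i)
    substring(backbone, (i - 1) * step + 1, (i - 1) * step + node_len), "")
  edges <- data.frame(from = ids[-n], from_or = "+", to = ids[-1],
                      to_or = "+", stringsAsFactors = FALSE)
  list(graph = sequence_graph(k, ids, seqs, rep(cov, n), edges),
       backbone = backbone)
}

# Branching toy for the complex-repeat caps: short in/out flanks around a
# short repeat, n_branch predecessors and successors long enough that each
# single-node extension completes the needed depth.
make_branch_toy <- function(k = 5, n_branch = 100, branch_len = 30) {
  ov <- k - 1
  A <- rnd_dna(5); R <- rnd_dna(5); B <- rnd_dna(5)
  R <- paste0(substring(A, 2, 5), substring(R, 5, 5))
  B <- paste0(substring(R, 2, 5), substring(B, 5, 5))
  ids <- c("A", "R", "B"); seqs <- c(A, R, B); covs <- c(10, 10, 10)
  ef <- c("A", "R"); et <- c("R", "B")
  for (i in seq_len(n_branch)) {
    ids <- c(ids, sprintf("P%03d", i), sprintf("S%03d", i))
    seqs <- c(seqs, paste0(rnd_dna(branch_len - ov), substring(A, 1, ov)),
              paste0(substring(B, 2, 5), rnd_dna(branch_len - ov)))
    covs <- c(covs, 10, 10)
    ef <- c(ef, sprintf("P%03d", i), "B")
    et <- c(et, "A", sprintf("S%03d", i))
  }
  g <- sequence_graph(k, ids, seqs, covs,
                      data.frame(from = ef, from_or = "+", to = et,
                                 to_or = "+", stringsAsFactors = FALSE))
  list(graph = g,
       site = list(repeat_id = "R",
                   ins = data.frame(id = "A", or = "+",
                                    stringsAsFactors = FALSE),
                   outs = data.frame(id = "B", or = "+",
                                     stringsAsFactors = FALSE)))
}

# One full synthetic instance: genome with an interspersed repeat, reads,
# baseline unitig graph. Sized down via unique_length for fast tests.
make_sim_instance <- function(seed, unique_length = 5000L,
                              repeat_length = 80L, k_assembly = 51L,
                              read_length = 151L, coverage = 40,
                              error_rate = 0) {
  gen <- make_repeat_genome(unique_length = unique_length,
                            repeat_length = repeat_length,
                            k_check = k_assembly, seed = seed)
  lib <- simulate_reads(gen$genome, read_length = read_length,
                        fold_coverage = coverage, error_rate = error_rate,
                        seed = seed + 1000L)
  graph <- build_unitig_graph(lib, k_assembly,
                              kc_min = if (error_rate > 0) 2L else 1L)
  list(gen = gen, lib = lib, graph = graph)
}

# Flip the stored strand of one node: reverse-complement its sequence and
# flip the orientation of every link touching it. The physical graph is
# unchanged.
flip_node_strand <- function(graph, id) {
  e <- graph$edges
  sel_f <- e$from == id
  sel_t <- e$to == id
  e$from_or[sel_f] <- ifelse(e$from_or[sel_f] == "+", "-", "+")
  e$to_or[sel_t] <- ifelse(e$to_or[sel_t] == "+", "-", "+")
  ids <- names(graph$nodes)
  seqs <- vapply(ids, function(i) graph$nodes[[i]]$seq, "")
  covs <- vapply(ids, function(i) graph$nodes[[i]]$cov, 0)
  seqs[ids == id] <- revcomp(seqs[ids == id])
  sequence_graph(graph$k, ids, seqs, covs, e)
}
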