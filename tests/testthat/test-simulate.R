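test_that("make_repeat_genome lays out segments and repeats as specified", {
  gen <- make_repeat_genome(unique_length = 5000, repeat_length = 80,
                            repeat_copies = 2, n_repeats = 1, seed = 9)
  expect_equal(nchar(gen$genome), 2 * 80 + 3 * 5000)
  expect_equal(nrow(gen$truth$repeats), 2)
  expect_equal(nrow(gen$truth$junctions), 2)
  # repeat intervals really hold the repeat sequence
  for (r in seq_len(2)) {
    expect_equal(substring(gen$genome, gen$truth$repeats$start[r],
                           gen$truth$repeats$end[r]),
                 gen$truth$repeat_seqs[1])
  }
  # determinism
  gen2 <- make_repeat_genome(unique_length = 5000, repeat_length = 80,
                             repeat_copies = 2, n_repeats = 1, seed = 9)
  expect_identical(gen2$genome, gen$genome)
  # no repeats: a single unique segment
  g0 <- make_repeat_genome(unique_length = 2000, n_repeats = 0, seed = 9)
  expect_equal(nchar(g0$genome), 2000)
  expect_equal(nrow(g0$truth$junctions), 0)
  # too-short repeat warns (no junction can form)
  expect_warning(make_repeat_genome(unique_length = 1000, repeat_length = 30,
                                    k_check = 51, seed = 9), "junction")
})

test_that("unique segments are k-mer-disjoint from each other and repeats", {
  gen <- make_repeat_genome(unique_length = 1000, seed = 19)
  km <- function(s) {
    st <- seq_len(nchar(s) - 50)
    unique(kresolve:::canonical_kmer(substring(s, st, st + 50)))
  }
  sets <- c(lapply(gen$truth$segments, km),
            lapply(gen$truth$repeat_seqs, km))
  for (i in seq_along(sets)) {
    for (j in seq_len(i - 1L)) {
      expect_length(intersect(sets[[i]], sets[[j]]), 0)
    }
  }
})

test_that("simulate_reads hits coverage, stays error-free at rate 0", {
  gen <- make_repeat_genome(unique_length = 1000, seed = 29)
  lib <- simulate_reads(gen$genome, 151, 40, 0, seed = 31)
  glen <- nchar(gen$genome)
  expect_gte(length(lib$reads), ceiling(40 * glen / 151))
  expect_true(all(nchar(lib$reads) == 151))
  genome2 <- paste0(gen$genome, "|", revcomp(gen$genome))
  expect_true(all(vapply(lib$reads[1:200],
                         function(r) grepl(r, genome2, fixed = TRUE),
                         NA)))
  # determinism
  lib2 <- simulate_reads(gen$genome, 151, 40, 0, seed = 31)
  expect_identical(lib2$reads, lib$reads)
  # errors appear at the requested order of magnitude
  libe <- simulate_reads(gen$genome, 151, 10, 0.01, seed = 31)
  mism <- sum(!vapply(libe$reads[1:100],
                      function(r) grepl(r, genome2, fixed = TRUE), NA))
  expect_gt(mism, 50) # P(read error-free) = 0.99^151 ~ 0.22
})

test_that("build_unitig_graph matches a brute-force DBG of the genome", {
  gen <- make_repeat_genome(unique_length = 1200, seed = 39)
  lib <- simulate_reads(gen$genome, 151, 40, 0, seed = 41)
  g_reads <- build_unitig_graph(lib, 51, 1)
  # oracle: the unitig decomposition of the genome string itself. The two
  # unitigs touching the genome ends may be truncated in the read-built
  # graph (terminal k-mers are covered only by reads anchored at the very
  # end), so each read unitig must be a substring of a truth unitig with a
  # small total deficit; counts and interior content must agree.
  g_truth <- build_unitig_graph(gen$genome, 51, 1)
  canon <- function(g) sort(unname(vapply(names(g$nodes), function(i) {
    s <- g$nodes[[i]]$seq
    min(s, revcomp(s))
  }, "")))
  cr <- canon(g_reads); ct <- canon(g_truth)
  expect_length(cr, length(ct))
  hay <- paste(c(ct, revcomp(ct)), collapse = "|")
  for (s in cr) expect_true(grepl(s, hay, fixed = TRUE))
  deficit <- sum(nchar(ct)) - sum(nchar(cr))
  expect_gte(deficit, 0)
  expect_lt(deficit, 2 * 151)
  expect_length(validate_graph(g_reads), 0)
  # the repeat collapses into one unitig containing the repeat sequence;
  # it can extend past repeat_length by the number of boundary bases the
  # flanks happen to share (coincident junction k-mers)
  rep_seq <- gen$truth$repeat_seqs[1]
  rep_node <- cr[grepl(rep_seq, cr, fixed = TRUE) |
                   grepl(revcomp(rep_seq), cr, fixed = TRUE)]
  rep_node <- rep_node[nchar(rep_node) < 500]
  expect_length(rep_node, 1)
  expect_gte(nchar(rep_node), 80)
  expect_lt(nchar(rep_node), 120)
  # repeat-free genome: a single unitig
  g1 <- build_unitig_graph(make_repeat_genome(unique_length = 500,
                                              n_repeats = 0,
                                              seed = 39)$genome, 51, 1)
  expect_length(g1$nodes, 1)
  # kc_min filtering can empty the k-mer set
  expect_error(build_unitig_graph("ACGTACGTACGTACGTACGTACGTACGTACGT", 21,
                                  1000), "no k-mers")
})

test_that("unitig multiplicity sums count member k-mers with multiplicity", {
  gen <- make_repeat_genome(unique_length = 600, seed = 49)
  g <- build_unitig_graph(gen$genome, 51, 1)
  # total cov = total k-mer instances in the input
  total_kmers <- nchar(gen$genome) - 51 + 1
  tot <- sum(vapply(names(g$nodes), function(i) g$nodes[[i]]$cov, 0))
  expect_equal(tot, total_kmers)
  # the repeat unitig's k-mers are each seen twice: cov = 2 * (len - k + 1)
  lens <- vapply(names(g$nodes), function(i) nchar(g$nodes[[i]]$seq), 0L)
  rep_id <- names(which(lens >= 80 & lens < 500))
  expect_length(rep_id, 1)
  expect_equal(g$nodes[[rep_id]]$cov, 2 * (lens[[rep_id]] - 50))
})

test_that("score_resolution reports chimeras and resolved junctions", {
  gen <- make_repeat_genome(unique_length = 800, seed = 59)
  g <- build_unitig_graph(gen$genome, 51, 1)
  base <- score_resolution(g, gen$genome, gen$truth)
  expect_equal(base$chimeric_junctions, 0)
  expect_equal(base$resolved_repeats, 0) # baseline spells no junction whole
  expect_equal(base$contig_count, length(g$nodes))

  # a deliberately cross-wired contig: left flank of copy 1 joined to the
  # right flank of copy 2's successor in the wrong order
  segs <- gen$truth$segments
  chim <- paste0(substring(segs[1], 600), gen$truth$repeat_seqs[1],
                 substring(segs[3], 1, 200))
  gc <- sequence_graph(51, "C", chim, 1)
  swrong <- score_resolution(gc, gen$genome, gen$truth)
  expect_gt(swrong$chimeric_junctions, 0)
  # ...while that same contig counts the (wrong) junction as unresolved
  expect_equal(swrong$resolved_repeats, 0)

  # the genome itself as one contig: everything resolved, no chimeras
  gall <- sequence_graph(51, "G", gen$genome, 1)
  sall <- score_resolution(gall, gen$genome, gen$truth)
  expect_equal(sall$chimeric_junctions, 0)
  expect_equal(sall$resolved_repeats, 2)
  expect_equal(sall$largest_fraction, 1)
})
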