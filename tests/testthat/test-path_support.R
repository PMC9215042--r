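test_that("count_window_hits counts positive queries over a start range", {
  set.seed(201)
  bf <- kmer_bloom(bits = 2^22, h = 7, k = 21)
  s <- rnd_dna(100)
  # empty filter: all misses
  wh <- count_window_hits(s, 1, 40, bf)
  expect_equal(wh$hits, 0)
  expect_equal(wh$tests_done, 40L)
  # insert the k-mers at 4 specific windows, find exactly those
  bloom_insert(bf, substring(s, 5:8, 25:28), n_kmers = 1)
  wh <- count_window_hits(s, 1, 40, bf)
  expect_equal(wh$hits, 4)
  # canonical symmetry: mirrored range on the reverse complement
  rc <- revcomp(s)
  wh_rc <- count_window_hits(rc, 100 - 21 + 1 - 39, 100 - 21 + 1, bf)
  expect_equal(wh_rc$hits, wh$hits)
})

test_that("flank expansion enumerates what is needed, capped per side", {
  set.seed(211)
  toy <- make_branch_toy(k = 5, n_branch = 3)
  g <- toy$graph
  inn <- toy$site$ins; outn <- toy$site$outs
  # flanks long enough: just the original triple
  c0 <- expand_complex_paths(g, toy$site, inn, outn, 0, 0)
  expect_length(c0, 1)
  expect_equal(c0[[1]]$ids, c("A", "R", "B"))
  # left side short: 3 predecessors x 1 = 3 combinations
  c3 <- expand_complex_paths(g, toy$site, inn, outn, 10, 0)
  expect_length(c3, 3)
  expect_true(all(vapply(c3, function(p) length(p$ids), 0L) == 4L))
  expect_equal(sort(vapply(c3, function(p) p$ids[1], "")),
               c("P001", "P002", "P003"))
  # both sides short: cross product
  c9 <- expand_complex_paths(g, toy$site, inn, outn, 10, 10)
  expect_length(c9, 9)
  # dead end: depth beyond what any extension supplies still returns
  # maximal paths rather than nothing
  cdeep <- expand_complex_paths(g, toy$site, inn, outn, 1000, 0)
  expect_length(cdeep, 3)
})

test_that("per-side cap limits enumeration to max_side_paths", {
  set.seed(221)
  toy <- make_branch_toy(k = 5, n_branch = 100)
  combos <- expand_complex_paths(toy$graph, toy$site, toy$site$ins,
                                 toy$site$outs, 13, 13)
  expect_length(combos, 75 * 75)
})

test_that("subsampling keeps small sets intact, large sets exactly capped", {
  p <- algorithm_params()
  paths <- as.list(1:10)
  expect_identical(subsample_combinations(paths, p), paths)
  big <- as.list(seq_len(6000))
  set.seed(7)
  kept1 <- subsample_combinations(big, p)
  expect_length(kept1, 5625)
  set.seed(7)
  kept2 <- subsample_combinations(big, p)
  expect_identical(kept1, kept2) # same seed, same subset
})

test_that("true junctions are supported, chimeric pairings are not", {
  sim <- make_sim_instance(seed = 401, unique_length = 1500L)
  g <- sim$graph
  sites <- find_repeat_sites(g)
  expect_length(sites, 1)
  site <- sites[[1]]
  p <- algorithm_params(bloom_bits = 2^24)
  k_big <- choose_k_big(g$k, sim$lib$read_length, p)
  idx <- build_read_index(sim$lib, k_big, p)
  mat <- evaluate_repeat(g, site, idx, sim$lib, k_big, p)
  expect_false(mat$site_skipped)
  e <- mat$entries
  expect_equal(nrow(e), 4)
  # every pair whose spelled junction occurs in the genome is supported
  genome2 <- paste0(sim$gen$genome, "|", revcomp(sim$gen$genome))
  for (r in seq_len(nrow(e))) {
    jn <- spell_path(g, c(e$in_id[r], site$repeat_id, e$out_id[r]),
                     c(e$in_or[r], "+", e$out_or[r]))
    core <- substring(jn,
                      nchar(node_seq(g, e$in_id[r])) - g$k,
                      nchar(node_seq(g, e$in_id[r])) +
                        nchar(node_seq(g, site$repeat_id)))
    genomic <- grepl(core, genome2, fixed = TRUE) ||
      grepl(revcomp(core), genome2, fixed = TRUE)
    expect_equal(e$supported[r], genomic,
                 label = sprintf("pair %s->%s support", e$in_id[r],
                                 e$out_id[r]))
  }
  expect_equal(sum(e$supported), 2)
})

test_that("support decisions are invariant under a strand flip", {
  sim <- make_sim_instance(seed = 411, unique_length = 1500L)
  g <- sim$graph
  site <- find_repeat_sites(g)[[1]]
  p <- algorithm_params(bloom_bits = 2^24)
  k_big <- choose_k_big(g$k, sim$lib$read_length, p)
  idx <- build_read_index(sim$lib, k_big, p)
  mat <- evaluate_repeat(g, site, idx, sim$lib, k_big, p)

  gf <- flip_node_strand(g, site$repeat_id)
  sitef <- find_repeat_sites(gf)[[1]]
  matf <- evaluate_repeat(gf, sitef, idx, sim$lib, k_big, p)

  pairs <- function(e) {
    sup <- e[e$supported %in% TRUE, ]
    sort(paste(pmin(sup$in_id, sup$out_id), pmax(sup$in_id, sup$out_id)))
  }
  expect_equal(pairs(matf$entries), pairs(mat$entries))
})

test_that("a site with any skipped path is skipped whole", {
  sim <- make_sim_instance(seed = 421, unique_length = 1500L)
  g <- sim$graph
  for (id in names(g$nodes)) g$nodes[[id]]$cov <- g$nodes[[id]]$cov / 20
  site <- find_repeat_sites(g)[[1]]
  p <- algorithm_params(bloom_bits = 2^24)
  k_big <- choose_k_big(g$k, sim$lib$read_length, p)
  idx <- build_read_index(sim$lib, k_big, p)
  mat <- evaluate_repeat(g, site, idx, sim$lib, k_big, p)
  expect_true(mat$site_skipped)
  expect_true(all(is.na(mat$entries$supported)))
  ed <- plan_resolution(site, mat, p)
  expect_true(ed$noop)
})
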