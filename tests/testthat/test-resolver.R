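fake_matrix <- function(ins, outs, supported_pairs,
                        verdict = "proceed") {
  site <- list(repeat_id = "R",
               ins = data.frame(id = ins, or = "+", stringsAsFactors = FALSE),
               outs = data.frame(id = outs, or = "+",
                                 stringsAsFactors = FALSE))
  rows <- expand.grid(i = seq_along(ins), j = seq_along(outs))
  entries <- data.frame(
    in_id = ins[rows$i], in_or = "+", out_id = outs[rows$j], out_or = "+",
    verdict = verdict, tests_done = 18L, hits = 0L, supported = NA,
    stringsAsFactors = FALSE)
  key <- paste(entries$in_id, entries$out_id)
  entries$supported <- key %in% supported_pairs
  entries$hits <- ifelse(entries$supported, 18L, 0L)
  m <- list(site = site, entries = entries,
            site_skipped = verdict != "proceed")
  class(m) <- "kr_support_matrix"
  m
}

test_that("plan_resolution splits by support components", {
  p <- algorithm_params()
  # 2x2 diagonal: two 1-to-1 components, fully resolved
  m <- fake_matrix(c("A", "B"), c("X", "Y"), c("A X", "B Y"))
  ed <- plan_resolution(m$site, m, p)
  expect_false(ed$noop)
  expect_length(ed$components, 2)
  expect_equal(ed$classification, "resolved")
  expect_equal(ed$pairs_removed, 2)

  # 3x3 with components {A,B}x{X,Y} and {C}x{Z}: partial simplification
  m2 <- fake_matrix(c("A", "B", "C"), c("X", "Y", "Z"),
                    c("A X", "A Y", "B X", "C Z"))
  ed2 <- plan_resolution(m2$site, m2, p)
  expect_false(ed2$noop)
  expect_length(ed2$components, 2)
  expect_equal(ed2$classification, "simplified")
  sizes <- sort(vapply(ed2$components,
                       function(cp) nrow(cp$ins) + nrow(cp$outs), 0L))
  expect_equal(sizes, c(2L, 4L))

  # all pairs supported: one component, no information gained
  m3 <- fake_matrix(c("A", "B"), c("X", "Y"),
                    c("A X", "A Y", "B X", "B Y"))
  expect_true(plan_resolution(m3$site, m3, p)$noop)

  # skipped site: no-op
  m4 <- fake_matrix(c("A", "B"), c("X", "Y"), character(),
                    verdict = "skip_low_coverage")
  expect_true(plan_resolution(m4$site, m4, p)$noop)

  # nothing supported anywhere: no-op (guard against stranding)
  m5 <- fake_matrix(c("A", "B"), c("X", "Y"), character())
  expect_true(plan_resolution(m5$site, m5, p)$noop)

  # an in-node with no supported partner loses its link because the other
  # side pair is supported
  m6 <- fake_matrix(c("A", "B"), c("X", "Y"), c("A X", "A Y"))
  ed6 <- plan_resolution(m6$site, m6, p)
  expect_false(ed6$noop)
  expect_equal(ed6$removed_ins$in_id, "B")
})

test_that("apply_edits duplicates the repeat per component and merges", {
  set.seed(231)
  g <- make_star_graph(k = 5, n_in = 2, n_out = 2, rep_len = 8,
                       flank_len = 20, cov = 100)
  site <- find_repeat_sites(g)[[1]]
  ins <- site$ins$id; outs <- site$outs$id
  m <- fake_matrix(ins, outs,
                   c(paste(ins[1], outs[1]), paste(ins[2], outs[2])))
  m$site <- site
  ed <- plan_resolution(site, m, algorithm_params())
  want1 <- spell_path(g, c(ins[1], "R", outs[1]), rep("+", 3))
  want2 <- spell_path(g, c(ins[2], "R", outs[2]), rep("+", 3))
  res <- apply_edits(g, list(ed))
  expect_length(res$applied, 1)
  expect_equal(res$deferred, 0L)
  expect_length(res$graph$nodes, 2)
  got <- sort(unname(vapply(names(res$graph$nodes),
                            function(i) res$graph$nodes[[i]]$seq, "")))
  norm <- function(s) pmin(s, revcomp(s))
  expect_equal(sort(norm(got)), sort(norm(c(want1, want2))))
  expect_length(validate_graph(res$graph), 0)
  # multiplicity conserved
  tot0 <- sum(vapply(names(g$nodes), function(i) g$nodes[[i]]$cov, 0))
  tot1 <- sum(vapply(names(res$graph$nodes),
                     function(i) res$graph$nodes[[i]]$cov, 0))
  expect_equal(tot1, tot0)

  # no-op edit list leaves the graph unchanged
  res0 <- apply_edits(g, list(list(noop = TRUE)))
  expect_equal(sort(names(res0$graph$nodes)), sort(names(g$nodes)))
})

test_that("edits referencing consumed nodes are deferred", {
  set.seed(241)
  g <- make_star_graph(k = 5, n_in = 2, n_out = 2)
  site <- find_repeat_sites(g)[[1]]
  ins <- site$ins$id; outs <- site$outs$id
  m <- fake_matrix(ins, outs,
                   c(paste(ins[1], outs[1]), paste(ins[2], outs[2])))
  m$site <- site
  ed <- plan_resolution(site, m, algorithm_params())
  res <- apply_edits(g, list(ed, ed)) # second edit touches removed "R"
  expect_length(res$applied, 1)
  expect_equal(res$deferred, 1L)
})

test_that("choose_k_big applies the +60 heuristic with the read-length cap", {
  expect_equal(choose_k_big(100, 250, algorithm_params()), 160L)
  expect_equal(choose_k_big(100, 151, algorithm_params()), 148L)
  expect_equal(choose_k_big(100, 250, algorithm_params(k_big = 120)), 120L)
  expect_error(choose_k_big(100, 250, algorithm_params(k_big = 90)),
               "must exceed")
  expect_error(choose_k_big(100, 250, algorithm_params(k_big = 250)),
               "fewer than")
  expect_error(choose_k_big(151, 151, algorithm_params()), "must exceed")
})

test_that("resolve_graph processes libraries shortest first, 2 passes each", {
  sim <- make_sim_instance(seed = 501, unique_length = 1000L)
  lib110 <- simulate_reads(sim$gen$genome, read_length = 110,
                           fold_coverage = 40, seed = 77)
  p <- algorithm_params(seed = 3, bloom_bits = 2^22)
  res <- resolve_graph(sim$graph, list(sim$lib, lib110), p)
  rep <- res$report
  expect_equal(rep$read_length, c(110L, 110L, 151L, 151L))
  expect_equal(rep$iteration, c(1L, 2L, 1L, 2L))
  # counter consistency per row
  expect_true(all(rep$sites_found == rep$sites_skipped + rep$sites_resolved +
                    rep$sites_simplified + rep$sites_unchanged +
                    rep$sites_deferred))
  stats <- attr(rep, "index_stats")
  expect_equal(vapply(stats, `[[`, 0L, "k_big"), c(107L, 111L))
  expect_length(validate_graph(res$graph), 0)
})

test_that("resolve_graph rejects invalid inputs", {
  set.seed(251)
  g <- make_star_graph(k = 5)
  g$nodes[["R"]]$seq <- rnd_dna(8) # break overlaps
  lib <- read_library(vapply(1:5, function(i) rnd_dna(100), ""))
  expect_error(resolve_graph(g, lib, algorithm_params(bloom_bits = 2^16)),
               "validation")
  expect_error(resolve_graph(make_star_graph(k = 5), list(),
                             algorithm_params()), "at least one")
})
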