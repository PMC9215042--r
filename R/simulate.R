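# Synthetic data: repeat-bearing genomes, uniform short-read simulation,
# a small node-centric DBG unitig builder standing in for the upstream
# assembler stage, and truth-table scoring.
#
# The generator states a simple world: a linear genome of unique segments
# alternating with exact interspersed repeat copies, uniform single-end
# read sampling from both strands (pairing is unused by the algorithm),
# i.i.d. substitution errors, and a unitig graph built by canonical k-mer
# counting plus chain compaction. Unique segments are rejection-sampled to
# share no assembly k-mer with each other or with the repeats, so the
# truth table is exact.

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a repeat-bearing genome with its truth table
#'
#' Builds `genome = U0 R U1 R U2 ...`: `n_repeats` distinct repeat
#' families, each repeated `repeat_copies` times (families interleaved),
#' separated by unique segments. All segments are rejection-checked to be
#' k-mer-disjoint at size `k_check` from each other and from every repeat
#' family, so every junction in the truth table is unambiguous.
#'
#' @param unique_length unique segment length (bp).
#' @param repeat_length repeat length (bp); must be at least `k_check` for
#'   a junction to form in the graph.
#' @param repeat_copies copies per repeat family.
#' @param n_repeats number of distinct repeat families.
#' @param k_check k-mer size used for the disjointness check (the intended
#'   `k_assembly`).
#' @param gc GC fraction of generated sequence.
#' @param seed integer seed; the generator is deterministic given it.
#' @return list with `genome` (string) and `truth`: a list holding
#'   `repeats` (data frame: family, copy, start, end, 1-based inclusive),
#'   `junctions` (data frame: family, copy, left_segment, right_segment
#'   indices into `segments`), and `segments` (the unique segments).
#' @export
make_repeat_genome <- function(unique_length = 5000L, repeat_length = 80L,
                               repeat_copies = 2L, n_repeats = 1L,
                               k_check = 51L, gc = 0.5, seed = 1L) {
  if (repeat_length < k_check)
    warning(sprintf(
      "repeat_length %d < k_check %d: repeat will not form a graph junction",
      repeat_length, k_check))
  withr::local_seed(seed)
  n_instances <- n_repeats * repeat_copies
  n_unique <- n_instances + 1L

  kmers_of <- function(s) {
    if (nchar(s) < k_check) return(character())
    starts <- seq_len(nchar(s) - k_check + 1L)
    canonical_kmer(substring(s, starts, starts + k_check - 1L))
  }
  taken <- character()
  draw_disjoint <- function(n) {
    for (attempt in 1:50) {
      s <- random_dna(n, gc)
      km <- unique(kmers_of(s))
      if (length(km) == length(kmers_of(s)) && !any(km %in% taken)) {
        taken <<- c(taken, km)
        return(s)
      }
    }
    stop("could not draw k-mer-disjoint segments; use longer/more diverse settings")
  }

  repeats <- if (n_repeats > 0)
    vapply(seq_len(n_repeats), function(i) draw_disjoint(repeat_length), "")
  else character()
  segments <- vapply(seq_len(n_unique), function(i)
    draw_disjoint(unique_length), "")

  family_order <- if (n_instances > 0) rep(seq_len(max(n_repeats, 1L)),
                                           length.out = n_instances)
                  else integer()
  genome <- segments[1]
  rep_rows <- list()
  jn_rows <- list()
  copy_counter <- integer(max(n_repeats, 1L))
  for (i in seq_len(n_instances)) {
    fam <- family_order[i]
    copy_counter[fam] <- copy_counter[fam] + 1L
    start <- nchar(genome) + 1L
    genome <- paste0(genome, repeats[fam], segments[i + 1L])
    rep_rows[[i]] <- data.frame(family = fam, copy = copy_counter[fam],
                                start = start,
                                end = start + repeat_length - 1L)
    jn_rows[[i]] <- data.frame(family = fam, copy = copy_counter[fam],
                               left_segment = i, right_segment = i + 1L)
  }
  truth <- list(
    repeats = if (length(rep_rows)) do.call(rbind, rep_rows) else
      data.frame(family = integer(), copy = integer(), start = integer(),
                 end = integer()),
    junctions = if (length(jn_rows)) do.call(rbind, jn_rows) else
      data.frame(family = integer(), copy = integer(),
                 left_segment = integer(), right_segment = integer()),
    segments = segments,
    repeat_seqs = repeats,
    k_check = as.integer(k_check))
  list(genome = genome, truth = truth)
}

#' Simulate uniform single-end reads
#'
#' Start positions are drawn uniformly over the genome, strands
#' equiprobably, until total bases reach `fold_coverage` times the genome
#' length. Substitution errors are applied i.i.d. per base.
#'
#' @param genome genome string.
#' @param read_length read length (bp).
#' @param fold_coverage target fold coverage.
#' @param error_rate per-base substitution probability (< 0.05).
#' @param seed integer seed.
#' @return a `kr_read_library`.
#' @export
simulate_reads <- function(genome, read_length = 151L, fold_coverage = 40,
                           error_rate = 0, seed = 1L) {
  stopifnot(fold_coverage > 0, error_rate >= 0, error_rate < 0.05)
  glen <- nchar(genome)
  read_length <- as.integer(read_length)
  if (read_length > glen) stop("read length exceeds genome length")
  withr::local_seed(seed)
  n_reads <- ceiling(fold_coverage * glen / read_length)
  starts <- sample.int(glen - read_length + 1L, n_reads, replace = TRUE)
  strands <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
  reads <- substring(genome, starts, starts + read_length - 1L)
  reads[!strands] <- revcomp(reads[!strands])
  if (error_rate > 0) {
    n_err <- rbinom(n_reads, read_length, error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(read_length, n_err[i])
      ch <- strsplit(reads[i], "")[[1]]
      for (p in pos) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      }
      reads[i] <- paste(ch, collapse = "")
    }
  }
  read_library(reads, source = "simulated")
}

#' Build a unitig graph from reads
#'
#' Counts canonical `k_assembly`-mers over the reads, drops those with
#' multiplicity below `kc_min` (the erroneous-k-mer filter), builds the
#' node-centric DBG and compacts maximal unambiguous chains into unitigs.
#' Each unitig's multiplicity sum is the sum of its member k-mer counts.
#'
#' @param reads a `kr_read_library` (or plain character vector).
#' @param k_assembly k-mer size; odd values recommended (no palindromic
#'   k-mers).
#' @param kc_min minimum k-mer multiplicity (default 2 suppresses most
#'   singleton error k-mers; use 1 for error-free reads).
#' @return a `kr_graph` that passes [validate_graph()].
#' @export
build_unitig_graph <- function(reads, k_assembly = 51L, kc_min = 1L) {
  seqs <- if (inherits(reads, "kr_read_library")) reads$reads else reads
  if (inherits(reads, "kr_read_library") &&
      k_assembly >= reads$read_length)
    stop("k_assembly must be smaller than the read length")
  res <- cpp_build_unitigs(seqs, as.integer(k_assembly), as.integer(kc_min))
  n <- length(res$seq)
  ids <- sprintf("U%0*d", nchar(as.character(n)), seq_len(n))
  edges <- data.frame(from = ids[res$from], from_or = res$from_or,
                      to = ids[res$to], to_or = res$to_or,
                      stringsAsFactors = FALSE)
  sequence_graph(k_assembly, ids, res$seq, res$cov, edges)
}

#' Score a resolved graph against the truth table
#'
#' Desk-scale stand-in for reference-based assembly assessment:
#' \itemize{
#'  \item `contig_count`: number of graph nodes;
#'  \item `largest_fraction`: longest node length / genome length;
#'  \item `chimeric_junctions`: count of contig windows of length
#'    `2 * k_assembly` that do not occur in the genome (either strand) -
#'    adjacencies the graph spells but the genome does not contain;
#'  \item `resolved_repeats`: true junctions (left flank + repeat + right
#'    flank, `k_assembly` bases of context each side) spelled contiguously
#'    by some contig.
#' }
#'
#' @param graph a `kr_graph`.
#' @param genome the genome string the truth refers to.
#' @param truth truth table from [make_repeat_genome()].
#' @return list of metrics.
#' @export
score_resolution <- function(graph, genome, truth) {
  k <- graph$k
  w <- 2L * k
  genome_kmers <- function(s, width) {
    if (nchar(s) < width) return(character())
    starts <- seq_len(nchar(s) - width + 1L)
    substring(s, starts, starts + width - 1L)
  }
  truth_set <- unique(c(genome_kmers(genome, w),
                        genome_kmers(revcomp(genome), w)))
  chimeras <- 0L
  contigs <- vapply(node_ids(graph), function(id) node_seq(graph, id), "")
  for (ctg in contigs) {
    wins <- genome_kmers(ctg, w)
    chimeras <- chimeras + sum(!(wins %in% truth_set))
  }
  resolved <- 0L
  jn <- truth$junctions
  for (i in seq_len(nrow(jn))) {
    left <- truth$segments[jn$left_segment[i]]
    right <- truth$segments[jn$right_segment[i]]
    rep_seq <- truth$repeat_seqs[jn$family[i]]
    probe <- paste0(substring(left, nchar(left) - k + 1L),
                    rep_seq, substring(right, 1L, k))
    hit <- any(vapply(contigs, function(ctg)
      grepl(probe, ctg, fixed = TRUE) ||
        grepl(revcomp(probe), ctg, fixed = TRUE), NA))
    resolved <- resolved + as.integer(hit)
  }
  list(contig_count = length(contigs),
       largest_fraction = if (length(contigs))
         max(nchar(contigs)) / nchar(genome) else 0,
       chimeric_junctions = chimeras,
       resolved_repeats = resolved)
}

#' Write a simulation fixture set
#'
#' Writes genome FASTA, reads FASTQ (dummy qualities), the truth table
#' (BED-like repeat intervals and a junction TSV) and the baseline unitig
#' graph GFA under a common prefix.
#'
#' @param prefix output path prefix.
#' @param genome genome string.
#' @param truth truth table.
#' @param library a `kr_read_library`.
#' @param graph baseline `kr_graph`.
#' @return character vector of the files written, invisibly.
#' @export
write_fixture_set <- function(prefix, genome, truth, library, graph) {
  fa <- paste0(prefix, ".genome.fa")
  writeLines(c(">genome", genome), fa)
  fq <- paste0(prefix, ".reads.fq")
  write_reads_fastq(library, fq)
  bed <- paste0(prefix, ".repeats.bed")
  rr <- truth$repeats
  write.table(data.frame(chrom = "genome", start = rr$start - 1L,
                         end = rr$end,
                         name = sprintf("fam%d_copy%d", rr$family, rr$copy)),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  tsv <- paste0(prefix, ".junctions.tsv")
  write.table(truth$junctions, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  gfa <- paste0(prefix, ".gfa")
  write_graph_gfa(graph, gfa)
  invisible(c(fa, fq, bed, tsv, gfa))
}
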