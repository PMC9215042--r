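# kresolve

Repeat resolution for de Bruijn unitig assembly graphs, using k-mers close
to the read length.

## The problem

Short-read de Bruijn graph (DBG) assemblers pick one k-mer size
`k_assembly`. Any genomic sequence repeated at two or more loci that is at
least `k_assembly - 1` bases long collapses into a single graph node with
several in-neighbours and several out-neighbours, and the assembler cannot
tell which in-flank continues into which out-flank. Larger k would resolve
the junction but lose connectivity in poorly covered regions, and
rebuilding the graph over a ladder of k values does not scale.

kresolve operates directly on the unitig graph with a second, much larger
k-mer size `k_big` (by default `k_assembly + 60`, capped by read length).
For every repeat node `R` with in-neighbours `{A, B, ...}` and
out-neighbours `{X, Y, ...}` it evaluates each three-node junction path
`A -> R -> X` by sliding a `k_big`-sized window along the spelled path,
1 bp at a time, and querying each window k-mer against a Bloom filter
holding the `t = 4` k-mers anchored at the 5' end of every read. A path
with at least `t` positive windows is supported; unsupported paths are
removed, the repeat sequence is duplicated once per group of supported
paths, and unambiguous chains are merged.

Coverage-awareness: for each path the expected spacing between read
5' ends is estimated from the unitig multiplicity sums (`KC` tags),

```
R_p   = sum(cov_sum) / (l - k_assembly + 1)      # reads on the path
s     = (L - l + 1) / R_p                        # spacing, bp
tests = ceil(max(m, s * f + t)),  m = 18, f = 4, t = 4
```

and a repeat is only evaluated if the window can make `tests` moves while
overlapping all three nodes by at least `margin = 2` bases:
`L_repeat <= k_big - (tests - 1) - 2 * margin`. If any path of a repeat
needs more than `M = 40` tests, or has too few window positions even
after expanding short flanks through their neighbours (at most 75
extension paths per side, 5625 combinations, randomly subsampled beyond
that), the whole repeat is skipped - partial information is never acted
on. Two evaluation/resolution passes are run per read-length library,
shortest library first.

## Worked example

Everything below is generated in code - no external data. Simulate a
15,160 bp genome with one 80 bp interspersed repeat (2 copies, 5 kb unique
flanks), 40x error-free 151 bp reads, and the unitig graph an assembler
would build at `k_assembly = 51`:

```r
library(kresolve)
gen   <- make_repeat_genome(unique_length = 5000, repeat_length = 80, seed = 42)
lib   <- simulate_reads(gen$genome, read_length = 151, fold_coverage = 40, seed = 43)
graph <- build_unitig_graph(lib, k_assembly = 51)
graph
#> kr_graph: 4 nodes, 4 links, k_assembly = 51
```

The four nodes are the two outer flanks, the middle
flank-repeat-boundary chain, and the single collapsed 80 bp repeat node
(in-degree 2, out-degree 2). Resolve it:

```r
res <- resolve_graph(graph, lib, algorithm_params(seed = 7))
res$report
#>   read_length iteration sites_found ... sites_resolved ... pairs_removed nodes_merged
#> 1         151         1           1                  1                2            4
#> 2         151         2           0                  0                0            0
#> library 151 bp: k_big = 111, 16064 k-mers indexed, FPR 1.77e-26, 0 reads skipped
res$graph
#> kr_graph: 1 nodes, 0 links, k_assembly = 51
```

One repeat site was found; of its 4 junction pairings the 2 genomic ones
were supported and the 2 chimeric ones removed (`pairs_removed = 2`), the
repeat was duplicated per supported path and the whole graph merged into a
single contig. Scoring against the known truth:

```r
score_resolution(res$graph, gen$genome, gen$truth)
#> $contig_count        1
#> $largest_fraction    0.999   # terminal k-mers are uncovered at the genome ends
#> $chimeric_junctions  0
#> $resolved_repeats    2
```

The same run is available from the command line:

```sh
Rscript -e 'kresolve::kr_main()' simulate --out sim --seed 42
Rscript -e 'kresolve::kr_main()' resolve --graph sim.gfa --reads sim.reads.fq \
    --k-assembly 51 --out run --seed 7
```

which writes `run.gfa`, `run.fa` and `run.report.tsv`.

## Layout

- `R/`, `src/` - implementation (graph model, I/O, Bloom/hash core,
  planner, evaluator, resolver, simulator, CLI)
- `tests/testthat/` - unit, property and acceptance suites
- `vignettes/repeat-resolution.Rmd` - methods notes: model, parameters,
  numerical choices, what the simulator does and does not emulate
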