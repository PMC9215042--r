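# FASTA/FASTQ read input, read-library grouping, and GFA1 graph I/O.
#
# GFA1 dialect: S lines carry the unitig sequence and a KC:i tag with the
# k-mer multiplicity sum; L lines carry the fixed overlap CIGAR
# "(k_assembly-1)M". Qualities in FASTQ input are discarded: the algorithm
# only uses 5'-anchored k-mers, which is itself the concession to the 3'
# quality drop of short reads.

#' Read sequences from FASTA/FASTQ files
#'
#' @param paths character vector of file paths.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return data frame with columns `id`, `seq` (uppercase), `source`.
#' @export
read_sequences <- function(paths, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  out <- list()
  for (p in paths) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
    if (file.size(p) == 0) next
    fmt <- format
    if (fmt == "auto") {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", p, ignore.case = TRUE))
        "fastq" else "fasta"
    }
    set <- tryCatch(
      Biostrings::readDNAStringSet(p, format = fmt),
      error = function(e) stop(sprintf("failed to parse %s as %s: %s",
                                       p, fmt, conditionMessage(e))))
    if (length(set) == 0) next
    ids <- names(set)
    if (is.null(ids)) ids <- as.character(seq_along(set))
    ids <- sub("\\s.*$", "", ids)
    out[[length(out) + 1L]] <- data.frame(
      id = ids, seq = toupper(as.character(set)), source = p,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(id = character(), seq = character(),
                      source = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Construct a read library
#'
#' @param reads character vector of equal-length ACGT reads.
#' @param source optional label.
#' @return object of class `kr_read_library` with fields `read_length`,
#'   `reads`, `source`.
#' @export
read_library <- function(reads, source = "memory") {
  lens <- unique(nchar(reads))
  if (length(reads) == 0) stop("empty read library")
  if (length(lens) != 1) stop("reads in a library must share one length")
  lib <- list(read_length = as.integer(lens), reads = reads, source = source)
  class(lib) <- "kr_read_library"
  lib
}

#' @export
print.kr_read_library <- function(x, ...) {
  cat(sprintf("kr_read_library: %d reads x %d bp (%s)\n",
              length(x$reads), x$read_length,
              paste(unique(x$source), collapse = ",")))
  invisible(x)
}

#' Group reads into per-length libraries
#'
#' Reads containing any non-ACGT symbol are dropped whole (the algorithm
#' only consumes the 5'-anchored k-mers, so splitting around ambiguous
#' bases buys nothing); the drop count is attached as attribute `dropped`.
#'
#' @param records data frame from [read_sequences()].
#' @return list of `kr_read_library`, ascending by read length, with
#'   attribute `dropped` (number of excluded reads).
#' @export
group_reads_by_length <- function(records) {
  ok <- grepl("^[ACGT]+$", records$seq)
  dropped <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  lens <- nchar(records$seq)
  libs <- lapply(sort(unique(lens)), function(l) {
    sel <- lens == l
    read_library(records$seq[sel],
                 source = unique(records$source[sel]))
  })
  attr(libs, "dropped") <- dropped
  libs
}

#' Load a unitig graph from GFA1
#'
#' Expects S lines with sequences and integer `KC:i` multiplicity-sum tags
#' and L lines whose CIGAR is exactly `(k_assembly-1)M`. A missing KC tag
#' yields multiplicity 0 with a warning; an overlap that disagrees with
#' `k_assembly` or a link to an undeclared segment is an error.
#'
#' @param path GFA1 file.
#' @param k_assembly the k the graph was built at.
#' @return a `kr_graph`.
#' @export
load_graph_gfa <- function(path, k_assembly) {
  if (!file.exists(path)) stop(sprintf("GFA file not found: %s", path))
  k_assembly <- as.integer(k_assembly)
  lines <- readLines(path)
  ids <- character(); seqs <- character(); covs <- numeric()
  ef <- character(); efo <- character(); et <- character(); eto <- character()
  missing_kc <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "H")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "S") {
      if (length(f) < 3)
        stop(sprintf("%s line %d: malformed S record", path, i))
      ids <- c(ids, f[2]); seqs <- c(seqs, toupper(f[3]))
      kc <- grep("^KC:i:", f, value = TRUE)
      if (length(kc) >= 1) {
        covs <- c(covs, as.numeric(sub("^KC:i:", "", kc[1])))
      } else {
        covs <- c(covs, 0)
        missing_kc <- missing_kc + 1L
      }
    } else if (f[1] == "L") {
      if (length(f) < 6)
        stop(sprintf("%s line %d: malformed L record", path, i))
      want <- sprintf("%dM", k_assembly - 1L)
      if (f[6] != want)
        stop(sprintf("%s line %d: link overlap '%s' != expected '%s'",
                     path, i, f[6], want))
      ef <- c(ef, f[2]); efo <- c(efo, f[3]); et <- c(et, f[4])
      eto <- c(eto, f[5])
    }
  }
  if (missing_kc > 0)
    warning(sprintf("%d S line(s) lack a KC:i tag; multiplicity sum set to 0",
                    missing_kc))
  dangling <- setdiff(c(ef, et), ids)
  if (length(dangling) > 0)
    stop(sprintf("link endpoint(s) not declared as segments: %s",
                 paste(unique(dangling), collapse = ", ")))
  sequence_graph(k_assembly, ids, seqs, covs,
                 data.frame(from = ef, from_or = efo, to = et, to_or = eto,
                            stringsAsFactors = FALSE))
}

#' Write a unitig graph to GFA1
#'
#' Inverse of [load_graph_gfa()]: a written graph loads back identically
#' (nodes, multiplicity sums, mirror-canonical links).
#'
#' @param graph a `kr_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graph_gfa <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (id in node_ids(graph)) {
    n <- graph$nodes[[id]]
    writeLines(sprintf("S\t%s\t%s\tKC:i:%d", id, n$seq, round(n$cov)), con)
  }
  e <- graph$edges
  if (nrow(e) > 0) {
    ord <- order(e$from, e$from_or, e$to, e$to_or)
    e <- e[ord, , drop = FALSE]
    ov <- sprintf("%dM", graph$k - 1L)
    writeLines(sprintf("L\t%s\t%s\t%s\t%s\t%s",
                       e$from, e$from_or, e$to, e$to_or, ov), con)
  }
  invisible(path)
}

#' Write graph nodes as FASTA contigs
#'
#' One record per node, sorted by id for determinism.
#'
#' @param graph a `kr_graph`.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(graph, path) {
  ids <- node_ids(graph)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in ids) {
    writeLines(c(paste0(">", id), graph$nodes[[id]]$seq), con)
  }
  invisible(path)
}

#' Write a read library as FASTQ with dummy qualities
#'
#' @param lib a `kr_read_library`.
#' @param path output FASTQ file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  qual <- strrep("I", lib$read_length)
  ids <- sprintf("@r%d", seq_along(lib$reads))
  writeLines(rbind(ids, lib$reads, "+", qual), con)
  invisible(path)
}
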