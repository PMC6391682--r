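# Independent brute-force references used to cross-check the package's
# interval and matching machinery, plus small fixture builders.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

# Quadratic scan for all exact occurrences of `read` on both strands of
# every contig (named character vector). 1-based coordinates.
oracle_scan <- function(read, contigs) {
  L <- nchar(read)
  rc <- as.character(reverseComplement(DNAStringSet(read)))
  out <- list()
  for (nm in names(contigs)) {
    s <- contigs[[nm]]
    n <- nchar(s)
    if (n < L) next
    starts <- seq_len(n - L + 1L)
    win <- substring(s, starts, starts + L - 1L)
    for (st in starts[win == read])
      out[[length(out) + 1L]] <- data.frame(
        contig = nm, start = st, end = st + L - 1L, strand = "+")
    for (st in starts[win == rc])
      out[[length(out) + 1L]] <- data.frame(
        contig = nm, start = st, end = st + L - 1L, strand = "-")
  }
  if (!length(out))
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character()))
  d <- do.call(rbind, out)
  d[order(d$contig, d$start, d$strand), , drop = FALSE]
}

# Brute-force cluster caller: explicit pairwise-overlap graph ->
# connected components -> RPM filter -> exhaustive left-to-right join
# scan. Intervals are 1-based closed; join when the 0-based gap
# (start2 - end1 - 1) is <= join_distance.
oracle_clusters <- function(starts, ends, weights, denominator,
                            rpm_threshold = 3, join_distance = 50) {
  n <- length(starts)
  if (n == 0L)
    return(data.frame(start = integer(), end = integer(),
                      count = numeric()))
  adj <- outer(starts, ends, "<=") & outer(ends, starts, ">=")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  regions <- do.call(rbind, lapply(unique(comp), function(k) {
    m <- comp == k
    data.frame(start = min(starts[m]), end = max(ends[m]),
               count = sum(weights[m]))
  }))
  regions <- regions[order(regions$start), , drop = FALSE]
  regions <- regions[regions$count / denominator * 1e6 >= rpm_threshold, ,
                     drop = FALSE]
  if (nrow(regions) <= 1L) return(regions)
  merged <- regions[1L, , drop = FALSE]
  for (i in 2:nrow(regions)) {
    last <- nrow(merged)
    if (regions$start[i] - merged$end[last] - 1L <= join_distance) {
      merged$end[last] <- max(merged$end[last], regions$end[i])
      merged$count[last] <- merged$count[last] + regions$count[i]
    } else {
      merged <- rbind(merged, regions[i, ])
    }
  }
  merged
}

# Assemble a small_rna_library directly from an alignment table
# (contig, start, end, strand, n_hits), bypassing the aligner.
make_library <- function(df, denominator, sample_id = "s1",
                         group = "g", replicate = 1L) {
  gr <- GRanges(df$contig, IRanges(df$start, df$end),
                strand = if (!is.null(df$strand)) df$strand else "*")
  nh <- if (!is.null(df$n_hits)) df$n_hits else rep(1L, nrow(df))
  mcols(gr)$read_id <- if (!is.null(df$read_id)) df$read_id
                       else paste0("rd", seq_len(nrow(df)))
  mcols(gr)$read_length <- width(gr)
  mcols(gr)$n_hits <- nh
  mcols(gr)$weight <- 1 / nh
  small_rna_library(gr, sample_id = sample_id, group = group,
                    replicate = replicate, denominator = denominator)
}

# A deliberately tiny hairpin description used by unit tests: hairpin
# occupies positions 101..303 of contig "pIR" (arm 89, loop 25, arm 89;
# stem+loop = 203 = 9*22 + 5).
toy_hairpin <- function() {
  hairpin_spec("pIR", 101L, 303L,
               arm5 = c(101L, 189L), loop = c(190L, 214L),
               arm3 = c(215L, 303L), reporter_antisense_strand = "-")
}
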