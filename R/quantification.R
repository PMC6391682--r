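#' Read-length abundance histogram
#'
#' Sums fractional weights of alignments per read length and normalizes
#' to RPM, optionally restricted to alignments lying fully within a
#' region (e.g. one plasmid's hairpin). Lengths outside the requested
#' range are omitted; lengths with no reads report 0.
#'
#' @param library a [small_rna_library()].
#' @param lengths inclusive length range, e.g. `c(21, 23)` or
#'   `c(19, 24)`.
#' @param region optional [GenomicRanges::GRanges] filter; alignments
#'   must lie entirely within it.
#' @return A data.frame with columns `length` and `rpm`.
#' @export
length_histogram <- function(library, lengths = c(19, 24), region = NULL) {
  stopifnot(inherits(library, "small_rna_library"))
  if (!is.null(region) && length(region) == 0L)
    stop("empty filter region")
  aln <- filter_alignments(library, lengths = lengths, region = region)
  bins <- seq(lengths[1L], lengths[2L])
  w <- S4Vectors::mcols(aln)$weight
  rl <- S4Vectors::mcols(aln)$read_length
  counts <- vapply(bins, function(L) sum(w[rl == L]), numeric(1))
  data.frame(length = bins, rpm = rpm(counts, library))
}

#' Aggregate 21-23-nt reads by transposable element class
#'
#' Assigns the fractional weight of each alignment overlapping a repeat
#' interval to that repeat's class and reports per-class RPM. A
#' multimapping read with placements in different classes contributes
#' `1/n` per placement to each placement's class; a placement
#' overlapping repeats of several classes is assigned to the repeat
#' with the largest overlap. Overlap is strand-agnostic and requires at
#' least 1 bp.
#'
#' @param library a [small_rna_library()].
#' @param annotations an [annotation_set()] with repeats.
#' @param lengths inclusive read-length range (default 21-23 nt).
#' @param exclusive if `TRUE`, reads with any placement overlapping a
#'   miRNA or exon annotation are excluded before aggregation.
#' @return A data.frame with columns `class`, `count` (fractional) and
#'   `rpm`, one row per class present in the annotation (0 where no
#'   reads map).
#' @export
aggregate_by_repeat_class <- function(library, annotations,
                                      lengths = c(21, 23),
                                      exclusive = FALSE) {
  stopifnot(inherits(library, "small_rna_library"),
            inherits(annotations, "annotation_set"))
  reps <- annotations$repeats
  classes <- unique(S4Vectors::mcols(reps)$class)
  aln <- filter_alignments(library, lengths = lengths)
  if (exclusive && length(aln)) {
    other <- c(GenomicRanges::granges(annotations$mirna),
               GenomicRanges::granges(annotations$exons))
    bad <- IRanges::overlapsAny(aln, other, ignore.strand = TRUE)
    bad_reads <- unique(S4Vectors::mcols(aln)$read_id[bad])
    aln <- aln[!S4Vectors::mcols(aln)$read_id %in% bad_reads]
  }
  counts <- setNames(numeric(length(classes)), classes)
  if (length(aln) && length(reps)) {
    ov <- quiet_overlap(
      GenomicRanges::findOverlaps(aln, reps, ignore.strand = TRUE))
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      inter <- pmin(GenomicRanges::end(aln)[q], GenomicRanges::end(reps)[s]) -
        pmax(GenomicRanges::start(aln)[q], GenomicRanges::start(reps)[s]) + 1L
      # one repeat per placement: largest overlap wins, ties by order
      ord <- order(q, -inter, s)
      q <- q[ord]; s <- s[ord]
      first <- !duplicated(q)
      cls <- S4Vectors::mcols(reps)$class[s[first]]
      w <- S4Vectors::mcols(aln)$weight[q[first]]
      agg <- tapply(w, cls, sum)
      counts[names(agg)] <- agg
    }
  }
  data.frame(class = names(counts), count = as.numeric(counts),
             rpm = rpm(as.numeric(counts), library),
             row.names = NULL)
}

#' Compare per-class abundances between two groups of replicates
#'
#' Two-sided Welch t-test on per-replicate RPM values for each class,
#' with a significance flag at 0.05. Classes whose values are constant
#' within both groups are handled without error: equal means give
#' p = 1, unequal means with zero variance give p = 0.
#'
#' @param values_a,values_b numeric matrices or data.frames of RPM
#'   values with classes in rows and replicates in columns (>= 2
#'   replicates each).
#' @return A data.frame with columns `class`, `mean_a`, `mean_b`, `p`
#'   and `significant`.
#' @export
compare_groups <- function(values_a, values_b) {
  values_a <- as.matrix(values_a); values_b <- as.matrix(values_b)
  if (ncol(values_a) < 2L || ncol(values_b) < 2L)
    stop("need >= 2 replicates per group")
  if (!identical(rownames(values_a), rownames(values_b)))
    stop("class rows must match between groups")
  p <- vapply(seq_len(nrow(values_a)), function(i) {
    a <- values_a[i, ]; b <- values_b[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  }, numeric(1))
  data.frame(class = rownames(values_a),
             mean_a = rowMeans(values_a), mean_b = rowMeans(values_b),
             p = p, significant = p < 0.05, row.names = NULL)
}
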