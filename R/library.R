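#' A sample's perfect-match alignment set
#'
#' Container for one sequencing library after alignment: all
#' perfect-match placements (with multimapper hit counts and fractional
#' weights), the normalization denominator, and replicate/group labels.
#'
#' The default denominator is the number of distinct reads with at
#' least one perfect-match placement on the genome or a transfected
#' plasmid; reads-per-million (RPM, used interchangeably with CPM here)
#' values are fractional counts divided by this denominator times 1e6,
#' so the whole library sums to exactly 1e6 RPM.
#'
#' @param alignments a [GenomicRanges::GRanges] with metadata columns
#'   `read_id`, `read_length`, `n_hits`, `weight` (as produced by
#'   [align_library()] or [import_sam()]).
#' @param sample_id,group,replicate sample metadata; `replicate` must be
#'   a positive integer.
#' @param denominator mapped-read count used for RPM; defaults to the
#'   number of distinct `read_id`s in `alignments`.
#' @param n_reads_total optional total record count before mapping.
#' @return An object of class `small_rna_library`.
#' @export
small_rna_library <- function(alignments, sample_id = "sample",
                              group = "group", replicate = 1L,
                              denominator = NULL, n_reads_total = NA_integer_) {
  stopifnot(is(alignments, "GRanges"))
  need <- c("read_id", "read_length", "n_hits", "weight")
  if (!all(need %in% colnames(S4Vectors::mcols(alignments))))
    stop("alignments must carry metadata columns: ",
         paste(need, collapse = ", "))
  if (!is_count(replicate)) stop("replicate must be a positive integer")
  n_mapped <- length(unique(S4Vectors::mcols(alignments)$read_id))
  if (is.null(denominator)) denominator <- n_mapped
  structure(list(sample_id = sample_id, group = group,
                 replicate = as.integer(replicate),
                 alignments = alignments,
                 denominator = as.numeric(denominator),
                 n_mapped = n_mapped,
                 n_reads_total = n_reads_total),
            class = "small_rna_library")
}

#' @export
print.small_rna_library <- function(x, ...) {
  cat("small_rna_library", x$sample_id,
      sprintf("(group %s, replicate %d):", x$group, x$replicate),
      length(x$alignments), "placements of", x$n_mapped,
      "mapped reads; denominator", format(x$denominator), "\n")
  invisible(x)
}

#' Reads-per-million normalization
#'
#' Converts a (possibly fractional) read count into reads per million
#' mapped reads: `count / denominator * 1e6`. CPM in per-position
#' density profiles is the same normalization.
#'
#' @param count fractional read count(s).
#' @param library a [small_rna_library()], or a single numeric
#'   denominator.
#' @return Numeric RPM value(s).
#' @examples
#' rpm(3, 1e6)    # the cluster discard threshold scale
#' @export
rpm <- function(count, library) {
  denom <- if (inherits(library, "small_rna_library"))
    library$denominator else as.numeric(library)
  if (length(denom) != 1L || is.na(denom) || denom <= 0)
    stop("library denominator must be a single positive number")
  count / denom * 1e6
}

#' Fractional weight of a multimapping read
#'
#' A read with `n` perfect-match placements contributes weight `1/n` at
#' each placement, conserving total read mass across loci.
#'
#' @param n_hits number of placements (positive integer, vectorized).
#' @return `1 / n_hits`.
#' @examples
#' fractional_weight(c(1, 4))
#' @export
fractional_weight <- function(n_hits) {
  if (any(is.na(n_hits)) || any(n_hits < 1) || any(n_hits != round(n_hits)))
    stop("n_hits must be positive integers")
  1 / n_hits
}

# Subset a library's alignments by read length range and optional
# region (alignment interval fully within the region).
filter_alignments <- function(library, lengths = NULL, region = NULL,
                              within = TRUE) {
  aln <- library$alignments
  if (!is.null(lengths)) {
    rl <- S4Vectors::mcols(aln)$read_length
    aln <- aln[rl >= lengths[1L] & rl <= lengths[2L]]
  }
  if (!is.null(region)) {
    keep <- quiet_overlap(
      IRanges::overlapsAny(aln, region,
                           type = if (within) "within" else "any",
                           ignore.strand = TRUE))
    aln <- aln[keep]
  }
  aln
}
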