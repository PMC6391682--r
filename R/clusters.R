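#' Parameters for 21-23-nt small RNA cluster discovery
#'
#' @param read_lengths inclusive read-length range used for clustering
#'   (default 21-23 nt).
#' @param rpm_threshold minimum cluster abundance; regions below this
#'   RPM are discarded (default 3).
#' @param join_distance maximum gap (bp) between retained clusters that
#'   are joined into one (default 50). The gap between clusters is
#'   `start(next) - end(prev)` in 0-based half-open terms; clusters
#'   with gap <= `join_distance` are joined.
#' @param floor pseudo-RPM used in place of 0 when taking log10 for
#'   cluster summaries (default 0.1).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(read_lengths = c(21L, 23L), rpm_threshold = 3,
                           join_distance = 50L, floor = 0.1) {
  if (rpm_threshold <= 0) stop("rpm_threshold must be > 0")
  if (join_distance < 0) stop("join_distance must be >= 0")
  structure(list(read_lengths = as.integer(read_lengths),
                 rpm_threshold = rpm_threshold,
                 join_distance = as.integer(join_distance),
                 floor = floor),
            class = "cluster_params")
}

#' Collapse overlapping alignments into regions with summed counts
#'
#' Maximal sets of transitively overlapping alignment intervals
#' (strand-agnostic) become one region spanning their union; the
#' region's fractional count is the sum of its members' weights.
#' Abutting intervals that share no base are not merged.
#'
#' @param alignments a [GenomicRanges::GRanges]; if it has no `weight`
#'   metadata column every alignment counts 1.
#' @return A [GenomicRanges::GRanges] with metadata column
#'   `fractional_count`, sorted by coordinate.
#' @export
collapse_regions <- function(alignments) {
  stopifnot(is(alignments, "GRanges"))
  if (length(alignments) == 0L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$fractional_count <- numeric()
    return(out)
  }
  w <- S4Vectors::mcols(alignments)$weight
  if (is.null(w)) w <- rep(1, length(alignments))
  regions <- GenomicRanges::reduce(alignments, min.gapwidth = 0L,
                                   ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(alignments, regions,
                                    ignore.strand = TRUE)
  cnt <- numeric(length(regions))
  agg <- tapply(w[S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov), sum)
  cnt[as.integer(names(agg))] <- agg
  S4Vectors::mcols(regions)$fractional_count <- cnt
  regions
}

#' Call small RNA clusters in one sample
#'
#' The per-sample cluster pipeline: (1) weight each read placement by
#' 1/n, (2) collapse overlapping 21-23-nt placements into regions and
#' sum their fractional counts, (3) discard regions below the RPM
#' threshold, (4) join surviving clusters separated by at most
#' `join_distance` bp, summing counts and re-deriving RPM.
#'
#' @param library a [small_rna_library()] with a positive denominator.
#' @param params a [cluster_params()].
#' @return A coordinate-sorted [GenomicRanges::GRanges] with metadata
#'   columns `fractional_count` and `rpm`.
#' @export
call_sample_clusters <- function(library, params = cluster_params()) {
  stopifnot(inherits(library, "small_rna_library"))
  if (library$denominator <= 0)
    stop("library denominator must be positive for RPM filtering")
  aln <- filter_alignments(library, lengths = params$read_lengths)
  regions <- collapse_regions(aln)
  keep <- rpm(S4Vectors::mcols(regions)$fractional_count, library) >=
    params$rpm_threshold
  kept <- regions[keep]
  if (length(kept) == 0L) {
    S4Vectors::mcols(kept)$rpm <- numeric()
    return(kept)
  }
  joined <- GenomicRanges::reduce(kept,
                                  min.gapwidth = params$join_distance + 1L,
                                  ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(kept, joined, ignore.strand = TRUE)
  cnt <- as.numeric(tapply(
    S4Vectors::mcols(kept)$fractional_count[S4Vectors::queryHits(ov)],
    S4Vectors::subjectHits(ov), sum))
  S4Vectors::mcols(joined)$fractional_count <- cnt
  S4Vectors::mcols(joined)$rpm <- rpm(cnt, library)
  GenomicRanges::sort(joined, ignore.strand = TRUE)
}

#' Intersect clusters across replicates of one group
#'
#' Keeps a cluster region only if every replicate contributes at least
#' one overlapping cluster (>= 1 bp, strand-agnostic). Retained
#' coordinates are, by default, the union of the overlapping replicate
#' clusters; `coordinates = "intersection"` restricts to bases covered
#' in every replicate.
#'
#' @param cluster_sets a list of per-replicate cluster GRanges from
#'   [call_sample_clusters()].
#' @param coordinates `"union"` (default) or `"intersection"`.
#' @return A [GenomicRanges::GRanges] with one metadata column per
#'   replicate (`rpm_rep<k>`) carrying the summed RPM of that
#'   replicate's member clusters.
#' @export
intersect_replicates <- function(cluster_sets,
                                 coordinates = c("union", "intersection")) {
  coordinates <- match.arg(coordinates)
  if (length(cluster_sets) == 0L) stop("need >= 1 replicate cluster set")
  k <- length(cluster_sets)
  pooled <- GenomicRanges::reduce(
    do.call(c, unname(lapply(cluster_sets, GenomicRanges::granges))),
    min.gapwidth = 0L, ignore.strand = TRUE)
  present <- vapply(cluster_sets, function(cs)
    IRanges::overlapsAny(pooled, cs, ignore.strand = TRUE),
    logical(length(pooled)))
  present <- matrix(present, nrow = length(pooled))
  keep <- rowSums(present) == k
  out <- pooled[keep]
  for (r in seq_len(k)) {
    cs <- cluster_sets[[r]]
    v <- numeric(length(out))
    if (length(out) && length(cs)) {
      ov <- GenomicRanges::findOverlaps(cs, out, ignore.strand = TRUE)
      agg <- tapply(S4Vectors::mcols(cs)$rpm[S4Vectors::queryHits(ov)],
                    S4Vectors::subjectHits(ov), sum)
      v[as.integer(names(agg))] <- agg
    }
    S4Vectors::mcols(out)[[paste0("rpm_rep", r)]] <- v
  }
  if (coordinates == "intersection" && length(out)) {
    pieces <- lapply(cluster_sets, function(cs)
      GenomicRanges::reduce(GenomicRanges::granges(cs),
                            ignore.strand = TRUE))
    common <- Reduce(function(a, b)
      GenomicRanges::intersect(a, b, ignore.strand = TRUE), pieces)
    hits <- GenomicRanges::findOverlaps(common, out, ignore.strand = TRUE)
    mc <- S4Vectors::mcols(out)[S4Vectors::subjectHits(hits), , drop = FALSE]
    out <- common[S4Vectors::queryHits(hits)]
    S4Vectors::mcols(out) <- mc
  }
  out
}

#' Merge cluster sets between samples by coordinate union
#'
#' Overlapping clusters from different groups are merged into one
#' region spanning the union of their coordinates (transitively). Each
#' merged cluster carries an RPM for every sample: recomputed from the
#' sample's 21-23-nt reads over the merged region when libraries are
#' supplied, 0 where the sample has no reads there.
#'
#' @param cluster_sets a named list of cluster GRanges (one per group
#'   or sample).
#' @param libraries optional named list of [small_rna_library()]
#'   objects; per-sample RPMs over merged regions are recomputed from
#'   their reads.
#' @param lengths read-length range used when recomputing from reads.
#' @param floor pseudo-RPM replacing 0 in the log10 summary.
#' @return A [GenomicRanges::GRanges] with per-sample `rpm_<sample>`
#'   columns and `median_log10_rpm`.
#' @export
merge_between_samples <- function(cluster_sets, libraries = NULL,
                                  lengths = c(21, 23), floor = 0.1) {
  if (length(cluster_sets) == 0L) stop("no cluster sets supplied")
  if (is.null(names(cluster_sets)))
    names(cluster_sets) <- paste0("set", seq_along(cluster_sets))
  merged <- GenomicRanges::reduce(
    do.call(c, unname(lapply(cluster_sets, GenomicRanges::granges))),
    min.gapwidth = 0L, ignore.strand = TRUE)
  rpms <- matrix(0, nrow = length(merged), ncol = 0)
  if (!is.null(libraries)) {
    for (nm in names(libraries)) {
      lib <- libraries[[nm]]
      aln <- filter_alignments(lib, lengths = lengths)
      v <- numeric(length(merged))
      if (length(aln) && length(merged)) {
        ov <- GenomicRanges::findOverlaps(aln, merged, ignore.strand = TRUE)
        agg <- tapply(
          S4Vectors::mcols(aln)$weight[S4Vectors::queryHits(ov)],
          S4Vectors::subjectHits(ov), sum)
        v[as.integer(names(agg))] <- agg
      }
      rpms <- cbind(rpms, as.numeric(rpm(v, lib)))
      colnames(rpms)[ncol(rpms)] <- nm
    }
  } else {
    for (nm in names(cluster_sets)) {
      cs <- cluster_sets[[nm]]
      v <- numeric(length(merged))
      if (length(cs) && length(merged)) {
        ov <- GenomicRanges::findOverlaps(cs, merged, ignore.strand = TRUE)
        agg <- tapply(S4Vectors::mcols(cs)$rpm[S4Vectors::queryHits(ov)],
                      S4Vectors::subjectHits(ov), sum)
        v[as.integer(names(agg))] <- agg
      }
      rpms <- cbind(rpms, as.numeric(v))
      colnames(rpms)[ncol(rpms)] <- nm
    }
  }
  for (j in seq_len(ncol(rpms)))
    S4Vectors::mcols(merged)[[paste0("rpm_", colnames(rpms)[j])]] <-
      unname(rpms[, j])
  S4Vectors::mcols(merged)$median_log10_rpm <-
    apply(rpms, 1, summarize_cluster, floor = floor)
  GenomicRanges::sort(merged, ignore.strand = TRUE)
}

#' Median log10 RPM cluster summary
#'
#' Summarizes a cluster's abundance across samples as the median of
#' log10(RPM). Zero RPMs (cluster absent from a sample) are floored at
#' a pseudovalue so absent clusters plot at the axis floor;
#' `policy = "drop"` instead drops zeros, returning `NA` when nothing
#' remains.
#'
#' @param sample_rpms numeric vector of per-sample RPM values.
#' @param floor pseudo-RPM replacing 0 (default 0.1).
#' @param policy `"floor"` (default) or `"drop"`.
#' @return Median log10 RPM (possibly `NA` under `"drop"`).
#' @examples
#' summarize_cluster(c(1, 10, 100))   # 1
#' summarize_cluster(c(0, 10))        # median of c(-1, 1) = 0
#' @export
summarize_cluster <- function(sample_rpms, floor = 0.1,
                              policy = c("floor", "drop")) {
  policy <- match.arg(policy)
  if (length(sample_rpms) == 0L) stop("need >= 1 sample RPM")
  if (policy == "floor") {
    stats::median(log10(pmax(sample_rpms, floor)))
  } else {
    v <- sample_rpms[sample_rpms > 0]
    if (length(v) == 0L) NA_real_ else stats::median(log10(v))
  }
}

# category levels in hierarchy order (highest priority first)
cluster_categories <- c("miRNA", "transposable_elements", "mRNA",
                        "misc_RNA", "other")

#' Annotate clusters by the fixed classification hierarchy
#'
#' Each cluster receives the highest-priority category among the
#' annotation intervals it overlaps (>= 1 bp, strand-agnostic):
#' miRNA > transposable elements > mRNA (protein-coding exons) >
#' misc RNA > other (no overlap).
#'
#' @param clusters a [GenomicRanges::GRanges] of clusters.
#' @param annotations an [annotation_set()].
#' @return `clusters` with a `category` factor metadata column.
#' @export
annotate_clusters <- function(clusters, annotations) {
  stopifnot(is(clusters, "GRanges"), inherits(annotations, "annotation_set"))
  sources <- list(miRNA = annotations$mirna,
                  transposable_elements = annotations$repeats,
                  mRNA = annotations$exons,
                  misc_RNA = annotations$misc_rna)
  cat <- rep("other", length(clusters))
  for (nm in rev(names(sources))) {   # ascending priority; best wins last
    g <- sources[[nm]]
    if (length(g))
      cat[quiet_overlap(
        IRanges::overlapsAny(clusters, g, ignore.strand = TRUE))] <- nm
  }
  S4Vectors::mcols(clusters)$category <-
    factor(cat, levels = cluster_categories)
  clusters
}

#' Write final clusters as BED and TSV
#'
#' BED6 output (0-based half-open) with score = round(median log10 RPM
#' x 100) and strand "."; a companion TSV carries the category and all
#' per-sample RPM columns.
#'
#' @param clusters annotated, merged clusters.
#' @param bed_path,tsv_path output paths (either may be `NULL`).
#' @return Invisibly, the TSV data.frame.
#' @export
export_clusters <- function(clusters, bed_path = NULL, tsv_path = NULL) {
  mc <- as.data.frame(S4Vectors::mcols(clusters))
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(clusters)),
                  start = GenomicRanges::start(clusters) - 1L,
                  end = GenomicRanges::end(clusters),
                  name = paste0("cluster_", seq_along(clusters)),
                  stringsAsFactors = FALSE)
  score <- if ("median_log10_rpm" %in% colnames(mc))
    as.integer(round(mc$median_log10_rpm * 100)) else 0L
  if (!is.null(bed_path)) {
    bed <- cbind(d, score = score, strand = ".")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  tsv <- cbind(d, mc)
  if (!is.null(tsv_path))
    utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(tsv)
}
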