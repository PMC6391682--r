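#' Genomic annotation set for cluster classification
#'
#' Bundles the four annotation sources used for hierarchical locus
#' classification: miRNA loci, protein-coding exons, transposable
#' element (repeat) intervals with class/family labels, and
#' miscellaneous structural RNA. Categories are distinguished by
#' source; positional conflicts are resolved at annotation time by the
#' fixed hierarchy miRNA > transposable elements > mRNA > misc RNA >
#' other.
#'
#' @param mirna,exons,misc_rna [GenomicRanges::GRanges] of the
#'   respective features (may be empty).
#' @param repeats a [GenomicRanges::GRanges] with metadata columns
#'   `name` (family) and `class` (e.g. SINE_B2, LINE1, ERVK, ERVL).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(mirna = GenomicRanges::GRanges(),
                           exons = GenomicRanges::GRanges(),
                           repeats = GenomicRanges::GRanges(),
                           misc_rna = GenomicRanges::GRanges()) {
  for (g in list(mirna, exons, repeats, misc_rna)) stopifnot(is(g, "GRanges"))
  if (length(repeats) &&
      !all(c("name", "class") %in% colnames(S4Vectors::mcols(repeats))))
    stop("repeats must carry 'name' and 'class' metadata columns")
  structure(list(mirna = mirna, exons = exons, repeats = repeats,
                 misc_rna = misc_rna),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$mirna), "miRNA,", length(x$exons),
      "exon,", length(x$repeats), "repeat,", length(x$misc_rna),
      "misc RNA intervals\n")
  invisible(x)
}

#' Read annotations from GFF3 and BED files
#'
#' Loads an [annotation_set()] from standard files: GFF3 for miRNA
#' (features of type `miRNA`), exons (`exon`) and misc RNA
#' (`misc_RNA`/`ncRNA`), and a RepeatMasker-style tab-separated repeat
#' file with columns chrom, start (0-based), end, name (family), class,
#' strand.
#'
#' @param gff3 path to a GFF3 file, or `NULL`.
#' @param repeat_bed path to the repeat BED6-like file, or `NULL`.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(gff3 = NULL, repeat_bed = NULL) {
  mirna <- exons <- misc <- GenomicRanges::GRanges()
  if (!is.null(gff3)) {
    g <- rtracklayer::import(gff3, format = "gff3")
    ty <- as.character(g$type)
    mirna <- g[ty == "miRNA"]
    exons <- g[ty == "exon"]
    misc <- g[ty %in% c("misc_RNA", "ncRNA")]
  }
  reps <- if (!is.null(repeat_bed)) read_repeat_bed(repeat_bed)
          else GenomicRanges::GRanges()
  annotation_set(mirna = mirna, exons = exons, repeats = reps,
                 misc_rna = misc)
}

# RepeatMasker-style BED6-like table: chrom, start(0-based), end, name
# (family), class, strand. The class column replaces the BED score, so
# this is parsed directly rather than as strict BED.
read_repeat_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "class", "strand"))
  GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start + 1L, end = d$end),
    strand = ifelse(d$strand %in% c("+", "-"), d$strand, "*"),
    name = d$name, class = d$class)
}

write_repeat_bed <- function(gr, path) {
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  name = S4Vectors::mcols(gr)$name,
                  class = S4Vectors::mcols(gr)$class,
                  strand = as.character(GenomicRanges::strand(gr)))
  d$strand[d$strand == "*"] <- "."
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
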