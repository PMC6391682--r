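#' Build a combined genome + plasmid reference
#'
#' Loads genome contigs and appends transfected plasmid sequences as
#' additional contigs, flagged so that downstream normalization can
#' include plasmid-mapped reads in the library denominator.
#'
#' @param genome a FASTA path or [Biostrings::DNAStringSet] of genome
#'   contigs.
#' @param plasmids a FASTA path (or vector of paths) or
#'   [Biostrings::DNAStringSet] of plasmid sequences; may be empty.
#' @return An object of class `reference_set`: a list with `seqs`
#'   (a [Biostrings::DNAStringSet], genome contigs first in file order,
#'   then plasmids) and `is_plasmid` (named logical).
#' @examples
#' gen <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGT"))
#' pls <- Biostrings::DNAStringSet(c(pCAG = "TTTTGGGG"))
#' build_reference(gen, pls)
#' @export
build_reference <- function(genome, plasmids = NULL) {
  load_fa <- function(x) {
    if (is.null(x)) return(Biostrings::DNAStringSet())
    if (is(x, "DNAStringSet")) return(x)
    do.call(c, lapply(x, Biostrings::readDNAStringSet))
  }
  g <- load_fa(genome)
  p <- load_fa(plasmids)
  if (length(g) == 0L) stop("reference genome has no contigs")
  nm <- c(names(g), names(p))
  if (is.null(nm) || any(!nzchar(nm)) || length(nm) < length(g) + length(p))
    stop("all reference contigs must be named")
  nm <- sub("\\s.*$", "", nm)  # FASTA headers: keep first token
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate contig name(s): ", paste(unique(dup), collapse = ", "))
  seqs <- c(g, p)
  names(seqs) <- nm
  check_alphabet(seqs, "reference sequence")
  structure(list(seqs = seqs,
                 is_plasmid = setNames(rep(c(FALSE, TRUE),
                                           c(length(g), length(p))), nm)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", length(x$seqs), "contigs (",
      sum(x$is_plasmid), "plasmid ),",
      sum(Biostrings::width(x$seqs)), "bp total\n")
  invisible(x)
}

#' Find all exact placements of a read on a reference
#'
#' Reports every perfect-match occurrence of the read sequence on
#' either strand of every contig. The hit count `n_hits` (the number of
#' loci, shared by all placements of the read) drives fractional 1/n
#' counting downstream. Reads containing N yield no hits.
#'
#' @param read a single read sequence (character or
#'   [Biostrings::DNAString]).
#' @param ref a [build_reference()] object.
#' @param read_id identifier stored with the placements.
#' @return A [GenomicRanges::GRanges] with metadata columns `read_id`,
#'   `read_length`, `n_hits` and `weight` (= 1/`n_hits`); empty when the
#'   read is absent.
#' @examples
#' ref <- build_reference(Biostrings::DNAStringSet(
#'   c(chrA = "AAACCCGGGTTTAAACCCGGGTTT")))
#' align_exact("AAACCCGGGTTT", ref)
#' @export
align_exact <- function(read, ref, read_id = "read") {
  seq <- as.character(read)
  stopifnot(length(seq) == 1L)
  align_read_set(setNames(seq, read_id), ref)
}

# Bulk exact matcher: named character vector of read sequences ->
# GRanges of all placements with per-read n_hits. Reads are grouped by
# length and matched with an Aho-Corasick dictionary (PDict) against
# both strands of every contig.
align_read_set <- function(seqs, ref) {
  stopifnot(inherits(ref, "reference_set"))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  empty <- GenomicRanges::GRanges(
    seqnames = character(), ranges = IRanges::IRanges(), strand = character(),
    read_id = character(), read_length = integer(),
    n_hits = integer(), weight = numeric())
  if (length(seqs) == 0L) return(empty)
  clean <- grepl("^[ACGT]+$", seqs)   # N-containing reads: zero hits
  useq <- unique(seqs[clean])
  if (length(useq) == 0L) return(empty)
  hit_chr <- list(); hit_start <- list(); hit_strand <- list()
  hit_seq <- list(); k <- 0L
  lens <- nchar(useq)
  for (L in unique(lens)) {
    sub <- useq[lens == L]
    fwd <- Biostrings::DNAStringSet(sub)
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (ci in seq_along(ref$seqs)) {
      contig <- ref$seqs[[ci]]
      cname <- names(ref$seqs)[ci]
      for (sgn in c("+", "-")) {
        m <- Biostrings::matchPDict(if (sgn == "+") pd_f else pd_r, contig)
        st <- Biostrings::startIndex(m)
        nz <- which(lengths(st) > 0L)
        for (j in nz) {
          k <- k + 1L
          hit_chr[[k]] <- rep(cname, length(st[[j]]))
          hit_start[[k]] <- st[[j]]
          hit_strand[[k]] <- rep(sgn, length(st[[j]]))
          hit_seq[[k]] <- rep(sub[j], length(st[[j]]))
        }
      }
    }
  }
  if (k == 0L) return(empty)
  placements <- data.frame(
    seq = unlist(hit_seq), chr = unlist(hit_chr),
    start = unlist(hit_start), strand = unlist(hit_strand),
    stringsAsFactors = FALSE)
  n_hits_per_seq <- table(placements$seq)
  # expand placements to every read record carrying that sequence
  rd <- data.frame(read_id = ids, seq = as.character(seqs),
                   stringsAsFactors = FALSE)
  rd <- rd[rd$seq %in% placements$seq, , drop = FALSE]
  if (nrow(rd) == 0L) return(empty)
  idx <- split(seq_len(nrow(placements)), placements$seq)
  ord <- unlist(idx[rd$seq], use.names = FALSE)
  reps <- lengths(idx[rd$seq])
  out_read <- rep(rd$read_id, reps)
  pl <- placements[ord, , drop = FALSE]
  len <- nchar(pl$seq)
  gr <- GenomicRanges::GRanges(
    seqnames = pl$chr,
    ranges = IRanges::IRanges(start = pl$start, width = len),
    strand = pl$strand,
    read_id = out_read,
    read_length = len,
    n_hits = as.integer(n_hits_per_seq[pl$seq]),
    weight = 1 / as.integer(n_hits_per_seq[pl$seq]))
  names(gr) <- NULL
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Align a trimmed read library and assemble a sample object
#'
#' Places every read by exact matching on both strands of the combined
#' genome + plasmid reference and assembles a [small_rna_library()].
#' Each FASTQ record is a counting unit: duplicated sequences are
#' counted once per record. Under the default denominator policy the
#' normalization denominator is the number of distinct reads with at
#' least one perfect-match placement (reads mapping only to plasmids
#' included); `denominator_policy = "all-reads"` uses the total record
#' count instead.
#'
#' @param reads trimmed reads: FASTQ path, [Biostrings::DNAStringSet],
#'   or named character vector.
#' @param ref a [build_reference()] object.
#' @param sample_id,group,replicate sample metadata.
#' @param denominator_policy `"mapped"` (default) or `"all-reads"`.
#' @return A [small_rna_library()].
#' @export
align_library <- function(reads, ref, sample_id = "sample",
                          group = "group", replicate = 1L,
                          denominator_policy = c("mapped", "all-reads")) {
  denominator_policy <- match.arg(denominator_policy)
  seqs <- read_sequences(reads)
  raw <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_along(raw))
  names(raw) <- ids
  aln <- align_read_set(raw, ref)
  n_mapped <- length(unique(S4Vectors::mcols(aln)$read_id))
  denom <- if (denominator_policy == "mapped") n_mapped else length(raw)
  small_rna_library(aln, sample_id = sample_id, group = group,
                    replicate = replicate, denominator = denom,
                    n_reads_total = length(raw))
}

#' Import perfect-match alignments from a SAM/BAM file
#'
#' Ingests externally produced alignments (e.g. from a spliced or
#' colorspace mapper), keeping only ungapped, unclipped records with at
#' most `max_mismatch` mismatches (from the NM tag). Hit counts are
#' recomputed as the number of retained placements per read, so
#' fractional weights reflect the perfect-match placements only.
#'
#' @param sam_path path to a SAM or BAM file.
#' @param ref a [build_reference()] object; records on contigs absent
#'   from it are an error.
#' @param max_mismatch maximum NM value retained (default 0, perfect
#'   match).
#' @return A list with `alignments` (GRanges as in [align_exact()]) and
#'   `report` (records in, kept, skipped_clipped_or_gapped,
#'   skipped_mismatch).
#' @export
import_sam <- function(sam_path, ref, max_mismatch = 0L) {
  stopifnot(inherits(ref, "reference_set"))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "qwidth"),
    tag = "NM")
  path <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE))
    path <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  mapped <- !bitwAnd(b$flag, 4L)
  n_in <- length(b$qname)
  qname <- b$qname[mapped]; flag <- b$flag[mapped]
  rname <- as.character(b$rname)[mapped]; pos <- b$pos[mapped]
  cigar <- b$cigar[mapped]; nm <- b$tag$NM[mapped]
  unknown <- setdiff(unique(rname), names(ref$seqs))
  if (length(unknown))
    stop("SAM contigs absent from reference: ",
         paste(unknown, collapse = ", "))
  simple <- grepl("^[0-9]+M$", cigar)     # no indels, no clipping
  if (is.null(nm) || (any(simple) && anyNA(nm[simple])))
    stop("SAM records lack NM tags; cannot enforce mismatch limit")
  keep <- simple & nm <= max_mismatch
  n_clip <- sum(!simple)
  n_mm <- sum(simple & nm > max_mismatch)
  qname <- qname[keep]; flag <- flag[keep]; rname <- rname[keep]
  pos <- pos[keep]
  len <- as.integer(sub("M$", "", cigar[keep]))
  n_hits <- table(qname)
  gr <- GenomicRanges::GRanges(
    seqnames = rname,
    ranges = IRanges::IRanges(start = pos, width = len),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    read_id = qname,
    read_length = len,
    n_hits = as.integer(n_hits[qname]),
    weight = 1 / as.integer(n_hits[qname]))
  list(alignments = GenomicRanges::sort(gr, ignore.strand = TRUE),
       report = data.frame(n_records = n_in, n_kept = sum(keep),
                           n_skipped_clipped_or_gapped = n_clip,
                           n_skipped_mismatch = n_mm))
}
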