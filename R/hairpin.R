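#' Describe an expressed inverted-repeat hairpin on its plasmid
#'
#' Coordinates (1-based, inclusive) of a hairpin transcript on a
#' plasmid contig: the 5' arm, loop and 3' arm of the inverted repeat,
#' and which plasmid strand yields siRNAs antisense to the targeted
#' reporter.
#'
#' @param plasmid_contig contig name of the plasmid in the reference.
#' @param hairpin_start,hairpin_end transcript region of the inverted
#'   repeat on the plasmid.
#' @param arm5,loop,arm3 length-2 integer vectors `c(start, end)` of
#'   the hairpin segments, in order within the hairpin region.
#' @param reporter_antisense_strand `"+"` or `"-"`: the strand whose
#'   reads are antisense to (and may cleave) the targeted reporter.
#' @param arm_tolerance allowed difference (nt) between arm lengths.
#' @return An object of class `hairpin_spec`.
#' @export
hairpin_spec <- function(plasmid_contig, hairpin_start, hairpin_end,
                         arm5, loop, arm3,
                         reporter_antisense_strand = "-",
                         arm_tolerance = 5L) {
  stopifnot(length(arm5) == 2L, length(loop) == 2L, length(arm3) == 2L)
  segs <- rbind(arm5, loop, arm3)
  if (any(segs[, 1] > segs[, 2]))
    stop("segment starts must not exceed ends")
  if (!(arm5[2] < loop[1] && loop[2] < arm3[1]))
    stop("segments must be ordered arm5 < loop < arm3")
  if (arm5[1] < hairpin_start || arm3[2] > hairpin_end)
    stop("segments must lie within [hairpin_start, hairpin_end]")
  len5 <- arm5[2] - arm5[1] + 1L
  len3 <- arm3[2] - arm3[1] + 1L
  if (abs(len5 - len3) > arm_tolerance)
    stop("arm lengths differ by more than arm_tolerance (",
         len5, " vs ", len3, ")")
  if (!reporter_antisense_strand %in% c("+", "-"))
    stop("reporter_antisense_strand must be '+' or '-'")
  structure(list(plasmid_contig = plasmid_contig,
                 hairpin_start = as.integer(hairpin_start),
                 hairpin_end = as.integer(hairpin_end),
                 arm5 = as.integer(arm5), loop = as.integer(loop),
                 arm3 = as.integer(arm3),
                 reporter_antisense_strand = reporter_antisense_strand),
            class = "hairpin_spec")
}

#' @export
print.hairpin_spec <- function(x, ...) {
  cat("hairpin_spec on", x$plasmid_contig,
      sprintf("[%d-%d]; arm5 %d-%d, loop %d-%d, arm3 %d-%d;",
              x$hairpin_start, x$hairpin_end, x$arm5[1], x$arm5[2],
              x$loop[1], x$loop[2], x$arm3[1], x$arm3[2]),
      "reporter-antisense strand", x$reporter_antisense_strand, "\n")
  invisible(x)
}

#' Read a hairpin description from YAML
#'
#' Expected keys: `plasmid_contig`, `hairpin_start`, `hairpin_end`,
#' `arm5`, `loop`, `arm3` (each `[start, end]`),
#' `reporter_antisense_strand`.
#'
#' @param path YAML file path.
#' @return A [hairpin_spec()].
#' @export
read_hairpin_spec <- function(path) {
  y <- yaml::read_yaml(path)
  hairpin_spec(plasmid_contig = y$plasmid_contig,
               hairpin_start = y$hairpin_start,
               hairpin_end = y$hairpin_end,
               arm5 = unlist(y$arm5), loop = unlist(y$loop),
               arm3 = unlist(y$arm3),
               reporter_antisense_strand = y$reporter_antisense_strand)
}

# biological 5' end of each alignment on its own strand
five_prime_pos <- function(aln) {
  ifelse(as.character(GenomicRanges::strand(aln)) == "-",
         GenomicRanges::end(aln), GenomicRanges::start(aln))
}

# alignments of a library on the hairpin, length-filtered; reads are
# kept when their biological 5' end lies within the hairpin region
hairpin_alignments <- function(library, spec, lengths = c(21, 23)) {
  aln <- filter_alignments(library, lengths = lengths)
  aln <- aln[as.character(GenomicRanges::seqnames(aln)) ==
               spec$plasmid_contig]
  fp <- five_prime_pos(aln)
  aln[fp >= spec$hairpin_start & fp <= spec$hairpin_end]
}

#' Per-position siRNA density over hairpin arms
#'
#' Sums fractional weights of length-filtered reads covering each
#' hairpin position, separately for reads whose biological 5' end lies
#' in the 5' arm (plotted up) versus the 3' arm (plotted down, negative
#' sign), and normalizes to CPM with the library denominator. Reads
#' whose 5' end falls in the loop are not assigned to either arm.
#'
#' @param library a [small_rna_library()].
#' @param spec a [hairpin_spec()]; its contig must be present in the
#'   reference the library was aligned to.
#' @param lengths inclusive read-length range (default 21-23 nt).
#' @return A data.frame with columns `position` (plasmid coordinate),
#'   `offset` (1-based position within the hairpin), `up_cpm` and
#'   `down_cpm` (<= 0).
#' @export
arm_density <- function(library, spec, lengths = c(21, 23)) {
  stopifnot(inherits(library, "small_rna_library"),
            inherits(spec, "hairpin_spec"))
  aln <- filter_alignments(library, lengths = lengths)
  aln <- aln[as.character(GenomicRanges::seqnames(aln)) ==
               spec$plasmid_contig]
  fp <- five_prime_pos(aln)
  in5 <- fp >= spec$arm5[1] & fp <= spec$arm5[2]
  in3 <- fp >= spec$arm3[1] & fp <= spec$arm3[2]
  pos <- spec$hairpin_start:spec$hairpin_end
  cov_of <- function(sub) {
    v <- numeric(length(pos))
    for (i in seq_along(sub)) {
      s <- max(GenomicRanges::start(sub)[i], spec$hairpin_start)
      e <- min(GenomicRanges::end(sub)[i], spec$hairpin_end)
      if (s <= e) {
        idx <- (s - spec$hairpin_start + 1L):(e - spec$hairpin_start + 1L)
        v[idx] <- v[idx] + S4Vectors::mcols(sub)$weight[i]
      }
    }
    rpm(v, library)
  }
  data.frame(position = pos,
             offset = seq_along(pos),
             up_cpm = cov_of(aln[in5]),
             down_cpm = -cov_of(aln[in3]))
}

#' Select hairpin reads antisense to the targeted reporter
#'
#' Returns the hairpin alignments on the strand that is antisense to
#' the reporter (the cleavage-competent guide candidates).
#'
#' @inheritParams arm_density
#' @return A [GenomicRanges::GRanges] subset of the library alignments.
#' @export
select_reporter_targeting <- function(library, spec, lengths = c(21, 23)) {
  aln <- hairpin_alignments(library, spec, lengths)
  aln[as.character(GenomicRanges::strand(aln)) ==
        spec$reporter_antisense_strand]
}

#' Modulo-period phasing registers of hairpin-derived siRNAs
#'
#' Scales each read's biological 5'-end position to the hairpin start
#' (first hairpin nucleotide = scaled position 1) and bins scaled
#' positions modulo the Dicer step size into registers 1..period;
#' register proportions are fractional read sums divided by the total
#' over all registers. Concentration in register 1 indicates processive
#' Dicer cleavage entering from the hairpin end.
#'
#' @inheritParams arm_density
#' @param period register period in nt (default 22, the canonical
#'   Dicer step for these hairpins).
#' @return An object of class `phasing_profile`: list with
#'   `proportions` (length `period`, named by register), `n_reads`
#'   (total fractional reads) and `period`. With zero hairpin reads the
#'   proportions are `NA`.
#' @export
phasing_profile <- function(library, spec, lengths = c(21, 23),
                            period = 22L) {
  stopifnot(period >= 2L)
  aln <- hairpin_alignments(library, spec, lengths)
  fp <- five_prime_pos(aln)
  scaled <- fp - spec$hairpin_start + 1L
  register <- ((scaled - 1L) %% period) + 1L
  w <- S4Vectors::mcols(aln)$weight
  totals <- setNames(numeric(period), seq_len(period))
  if (length(register)) {
    agg <- tapply(w, register, sum)
    totals[names(agg)] <- agg
  }
  n <- sum(totals)
  structure(list(
    proportions = if (n > 0) totals / n else setNames(rep(NA_real_, period),
                                                      seq_len(period)),
    n_reads = n, period = as.integer(period)),
    class = "phasing_profile")
}

#' @export
print.phasing_profile <- function(x, ...) {
  cat("phasing_profile: period", x$period, ",",
      format(x$n_reads), "fractional reads\n")
  if (x$n_reads > 0) {
    top <- which.max(x$proportions)
    cat(sprintf("  register %d carries %.1f%% of reads\n",
                top, 100 * x$proportions[top]))
  }
  invisible(x)
}

#' Hairpin read abundance by length
#'
#' RPM of reads perfectly mapping within the hairpin region, per read
#' length (default 19-24 nt), with fractional weighting of reads placed
#' more than once (e.g. on both arms of the inverted repeat).
#'
#' @inheritParams arm_density
#' @param lengths inclusive length range (default 19-24 nt).
#' @return A data.frame with columns `length` and `rpm`.
#' @export
hairpin_length_abundance <- function(library, spec, lengths = c(19, 24)) {
  region <- GenomicRanges::GRanges(
    spec$plasmid_contig,
    IRanges::IRanges(spec$hairpin_start, spec$hairpin_end))
  length_histogram(library, lengths = lengths, region = region)
}
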