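#' Configuration for the synthetic small RNA-seq generator
#'
#' Defines a toy genome with planted miRNA-like loci and repeat
#' families, a plasmid carrying a long inverted-repeat hairpin, and a
#' sequencing library drawn from them with NEXTflex-style read
#' structure (4 randomized nt on each side of the insert plus a 3'
#' adapter). Identical configurations produce byte-identical outputs.
#'
#' Hairpin reads come in two positional modes mirroring the two
#' promoter classes whose processing differs: `"terminal"` plants
#' phased 5' ends on the register-1 lattice (scaled positions 1 + 22k)
#' with geometrically decaying abundance per phase step, plus a
#' `noise_fraction` of uniform starts; `"distributed"` draws all 5'
#' ends uniformly along the hairpin. Because the 3' arm is the exact
#' reverse complement of the 5' arm, every arm-internal read maps twice
#' (n = 2, weight 1/2 per placement); the default stem + loop length
#' (2 x 400 + 15 = 815 = 1 mod 22) makes the mirrored placement of a
#' phased read fall in register 1 as well, so noise-free terminal
#' libraries concentrate all fractional mass in register 1.
#'
#' @param seed integer RNG seed; fixed seed gives identical bytes.
#' @param n_contigs,contig_length toy genome dimensions.
#' @param n_mirna_loci number of planted miRNA-like loci (fixed 5'
#'   ends, unique mappers).
#' @param mirna_meanlog,mirna_sdlog log-normal parameters of relative
#'   miRNA locus abundance.
#' @param mirna_expected_rpm optional numeric vector (length
#'   `n_mirna_loci`) of target per-locus RPM; overrides the log-normal
#'   abundances. The remaining miRNA read mass is spread over
#'   `n_background_loci` additional planted loci (the bulk miRNA
#'   transcriptome), so each target locus realizes close to its stated
#'   RPM in the finished library.
#' @param n_background_loci background miRNA loci planted when
#'   `mirna_expected_rpm` is given.
#' @param n_repeat_families,copies_per_family,repeat_length planted
#'   repeat families: identical copies so reads from them multimap with
#'   known hit count.
#' @param repeat_classes class labels cycled over the families.
#' @param repeat_mutation_rate per-base substitution probability
#'   applied independently to each planted copy (default 0: exact
#'   copies).
#' @param n_exons,n_misc random exon / misc RNA annotation intervals.
#' @param min_locus_spacing minimum distance (nt) kept between planted
#'   miRNA loci and any other planted feature. Distinct ground-truth
#'   loci must sit further apart than the cluster join distance, or
#'   "two loci" and "one cluster" would describe the same truth.
#' @param arm_length,loop_length hairpin arm and loop sizes (nt); the
#'   defaults give a >400-bp stem and phase-coherent mirror placements.
#' @param hairpin_mode `"terminal"` or `"distributed"`.
#' @param strand_bias probability that a hairpin read derives from the
#'   plus strand.
#' @param decay abundance decay per 22-nt phase step in terminal mode.
#' @param noise_fraction fraction of terminal-mode hairpin reads with
#'   uniform (unphased) 5' ends.
#' @param library_size total reads per library.
#' @param hairpin_fraction,repeat_fraction,unmappable_fraction read
#'   composition; the remainder is miRNA reads.
#' @param adapter 3' adapter appended to every read.
#' @param randomized_end_length length of the randomized ends (nt).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 3L, contig_length = 50000L,
                       n_mirna_loci = 30L,
                       mirna_meanlog = log(300), mirna_sdlog = 1,
                       mirna_expected_rpm = NULL,
                       n_background_loci = 20L,
                       n_repeat_families = 4L, copies_per_family = 4L,
                       repeat_length = 300L,
                       repeat_classes = c("SINE_B2", "LINE1", "ERVK",
                                          "ERVL"),
                       repeat_mutation_rate = 0,
                       n_exons = 20L, n_misc = 10L,
                       min_locus_spacing = 100L,
                       arm_length = 400L, loop_length = 15L,
                       hairpin_mode = c("terminal", "distributed"),
                       strand_bias = 0.5, decay = 0.5,
                       noise_fraction = 0.1,
                       library_size = 100000L,
                       hairpin_fraction = 0.2, repeat_fraction = 0.05,
                       unmappable_fraction = 0.02,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       randomized_end_length = 4L) {
  hairpin_mode <- match.arg(hairpin_mode)
  fracs <- c(hairpin_fraction, repeat_fraction, unmappable_fraction,
             noise_fraction, strand_bias, repeat_mutation_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (hairpin_fraction + repeat_fraction + unmappable_fraction > 1)
    stop("read fractions exceed 1")
  if (!is.null(mirna_expected_rpm) &&
      length(mirna_expected_rpm) != n_mirna_loci)
    stop("mirna_expected_rpm must have length n_mirna_loci")
  check_alphabet(adapter, "adapter")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a reference with planted loci, repeats and a hairpin plasmid
#'
#' Builds random-composition genome contigs; plants `n_mirna_loci`
#' unique 23-nt miRNA-like loci (re-drawn deterministically if a locus
#' sequence is not unique in the reference), `n_repeat_families`
#' families of near-identical repeat copies, random exon and misc RNA
#' annotation intervals, and a plasmid contig `pIR` carrying an
#' inverted repeat (arm, loop, reverse-complement arm) flanked by
#' backbone sequence.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; writes `genome.fa`, `plasmid.fa`,
#'   `annotations.gff3`, `repeats.bed` and truth tables.
#' @return A list of class `sim_reference` with elements `reference`
#'   (a [build_reference()] object), `annotations`
#'   (an [annotation_set()]), `hairpin` (a [hairpin_spec()]) and
#'   `truth` (planted miRNA loci and repeat intervals as GRanges).
#' @export
simulate_reference <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    contigs <- vapply(seq_len(config$n_contigs), function(i)
      random_dna(config$contig_length), character(1))
    names(contigs) <- paste0("chr", seq_len(config$n_contigs))
    # fixed seqlevels so planted GRanges combine silently
    lvls <- c(names(contigs), "pIR")
    gr_on <- function(chr, start, end, strand = "*")
      GenomicRanges::GRanges(factor(chr, levels = lvls),
                             IRanges::IRanges(start, end),
                             strand = rep(strand, length.out = length(start)))

    # plant repeat families first (they overwrite genome sequence)
    rep_list <- list()
    occupied <- gr_on(character(), integer(), integer())
    classes <- rep_len(config$repeat_classes, config$n_repeat_families)
    for (f in seq_len(config$n_repeat_families)) {
      consensus <- random_dna(config$repeat_length)
      for (cp in seq_len(config$copies_per_family)) {
        repeat {
          chr <- sample(names(contigs), 1L)
          st <- sample.int(config$contig_length - config$repeat_length, 1L)
          cand <- gr_on(chr, st, st + config$repeat_length - 1L)
          if (!any(IRanges::overlapsAny(cand, occupied))) break
        }
        seq_cp <- consensus
        if (config$repeat_mutation_rate > 0) {
          b <- strsplit(seq_cp, "")[[1]]
          mut <- runif(length(b)) < config$repeat_mutation_rate
          b[mut] <- vapply(b[mut], function(x)
            sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
          seq_cp <- paste(b, collapse = "")
        }
        substr(contigs[chr], st, st + config$repeat_length - 1L) <- seq_cp
        S4Vectors::mcols(cand)$name <- sprintf("fam%d_copy%d", f, cp)
        S4Vectors::mcols(cand)$class <- classes[f]
        rep_list[[length(rep_list) + 1L]] <- cand
        occupied <- c(occupied, GenomicRanges::granges(cand))
      }
    }
    repeats <- if (length(rep_list)) do.call(c, rep_list)
               else GenomicRanges::GRanges()

    # plasmid with inverted repeat: backbone + arm + loop + rc(arm)
    A <- config$arm_length; G <- config$loop_length
    flank <- 500L
    arm_seq <- random_dna(A)
    plasmid <- paste0(random_dna(flank), arm_seq, random_dna(G),
                      revcomp(arm_seq), random_dna(flank))
    hp <- hairpin_spec(
      plasmid_contig = "pIR",
      hairpin_start = flank + 1L, hairpin_end = flank + 2L * A + G,
      arm5 = c(flank + 1L, flank + A),
      loop = c(flank + A + 1L, flank + A + G),
      arm3 = c(flank + A + G + 1L, flank + 2L * A + G),
      reporter_antisense_strand = "-")

    ref <- build_reference(Biostrings::DNAStringSet(contigs),
                           Biostrings::DNAStringSet(c(pIR = plasmid)))

    # miRNA-like loci: 23-nt windows outside repeats whose sequence is
    # unique in the whole reference (both strands)
    targeted <- !is.null(config$mirna_expected_rpm)
    n_loci <- config$n_mirna_loci +
      if (targeted) config$n_background_loci else 0L
    mir_list <- list()
    for (i in seq_len(n_loci)) {
      repeat {
        chr <- sample(names(contigs), 1L)
        st <- sample.int(config$contig_length - 23L, 1L)
        cand <- gr_on(chr, st, st + 22L, strand = sample(c("+", "-"), 1L))
        pad <- gr_on(chr, max(1L, st - config$min_locus_spacing),
                     min(config$contig_length,
                         st + 22L + config$min_locus_spacing))
        if (any(IRanges::overlapsAny(pad, occupied, ignore.strand = TRUE)))
          next
        s <- substr(contigs[chr], st, st + 22L)
        n_occ <- sum(Biostrings::vcountPattern(s, ref$seqs) +
                       Biostrings::vcountPattern(revcomp(s), ref$seqs))
        if (n_occ == 1L) break
      }
      S4Vectors::mcols(cand)$name <-
        if (i <= config$n_mirna_loci) sprintf("sim-mir-%d", i)
        else sprintf("sim-mir-bg-%d", i - config$n_mirna_loci)
      mir_list[[i]] <- cand
      occupied <- c(occupied, GenomicRanges::granges(cand))
    }
    mirna <- do.call(c, mir_list)
    S4Vectors::mcols(mirna)$background <-
      seq_len(n_loci) > config$n_mirna_loci

    rand_intervals <- function(n, w_min, w_max, prefix) {
      if (n == 0L) return(GenomicRanges::GRanges())
      chr <- sample(names(contigs), n, replace = TRUE)
      w <- sample(w_min:w_max, n, replace = TRUE)
      st <- vapply(w, function(wi)
        sample.int(config$contig_length - wi, 1L), integer(1))
      g <- gr_on(chr, st, st + w - 1L,
                 strand = sample(c("+", "-"), n, TRUE))
      S4Vectors::mcols(g)$name <- paste0(prefix, seq_len(n))
      g
    }
    exons <- rand_intervals(config$n_exons, 100L, 1000L, "exon")
    misc <- rand_intervals(config$n_misc, 80L, 300L, "misc")

    # relative miRNA abundances (expected reads per locus). With target
    # RPMs, weights are in RPM units: the miRNA read budget is
    # (1 - other fractions) of the library, so giving the targeted loci
    # weight = target RPM and the background the remaining mass out of
    # 1e6 * mirna_fraction makes each target realize ~its stated RPM.
    mir_w <- if (targeted) {
      mir_frac <- 1 - config$hairpin_fraction - config$repeat_fraction -
        config$unmappable_fraction
      total_w <- 1e6 * mir_frac
      spent <- sum(config$mirna_expected_rpm)
      if (spent > total_w)
        stop("mirna_expected_rpm sums beyond the miRNA read budget")
      c(config$mirna_expected_rpm,
        rep((total_w - spent) / config$n_background_loci,
            config$n_background_loci))
    } else {
      rlnorm(n_loci, config$mirna_meanlog, config$mirna_sdlog)
    }
    S4Vectors::mcols(mirna)$abundance <- mir_w

    ann <- annotation_set(mirna = mirna, exons = exons, repeats = repeats,
                          misc_rna = misc)
    out <- structure(list(reference = ref, annotations = ann,
                          hairpin = hp,
                          truth = list(mirna_loci = mirna,
                                       repeats = repeats),
                          config = config),
                     class = "sim_reference")
    if (!is.null(out_dir)) write_sim_reference(out, out_dir)
    out
  })
}

write_sim_reference <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- sim$reference
  Biostrings::writeXStringSet(ref$seqs[!ref$is_plasmid],
                              file.path(out_dir, "genome.fa"))
  Biostrings::writeXStringSet(ref$seqs[ref$is_plasmid],
                              file.path(out_dir, "plasmid.fa"))
  ann <- sim$annotations
  gff <- c(ann$mirna, ann$exons, ann$misc_rna)
  S4Vectors::mcols(gff)$type <- rep(c("miRNA", "exon", "misc_RNA"),
                                    c(length(ann$mirna), length(ann$exons),
                                      length(ann$misc_rna)))
  S4Vectors::mcols(gff)$ID <- S4Vectors::mcols(gff)$name
  rtracklayer::export(gff, file.path(out_dir, "annotations.gff3"),
                      format = "gff3")
  write_repeat_bed(ann$repeats, file.path(out_dir, "repeats.bed"))
  hy <- sim$hairpin
  yaml::write_yaml(list(plasmid_contig = hy$plasmid_contig,
                        hairpin_start = hy$hairpin_start,
                        hairpin_end = hy$hairpin_end,
                        arm5 = as.list(hy$arm5), loop = as.list(hy$loop),
                        arm3 = as.list(hy$arm3),
                        reporter_antisense_strand =
                          hy$reporter_antisense_strand),
                   file.path(out_dir, "hairpin.yaml"))
  invisible(out_dir)
}

#' Simulate one sequencing library with ground truth
#'
#' Draws reads from the planted sources (miRNA loci with fixed 5' ends
#' and multinomial 21-23-nt lengths; hairpin reads in the configured
#' positional mode; repeat-family reads that multimap across copies;
#' unmappable random sequences), wraps each insert as
#' `4N + insert + 4N + adapter`, and returns the raw reads together
#' with an exact per-read truth table.
#'
#' @param config a [sim_config()].
#' @param sim_ref a [simulate_reference()] result built from the same
#'   config.
#' @param seed_offset added to `config$seed` for the library draw
#'   (replicates use offsets 1..k).
#' @param exclude_loci character vector of miRNA locus names to omit
#'   from this library (used to test replicate intersection).
#' @param fastq_out optional FASTQ output path.
#' @return A list of class `sim_library` with `reads` (named
#'   [Biostrings::DNAStringSet] of raw reads) and `truth` (data.frame:
#'   `read_id`, `source`, `locus`, `insert`, `insert_length`, `strand`,
#'   `scaled_start`).
#' @export
simulate_library <- function(config, sim_ref, seed_offset = 0L,
                             exclude_loci = character(),
                             fastq_out = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(sim_ref, "sim_reference"))
  with_seed(config$seed + seed_offset, {
    N <- config$library_size
    n_hp <- round(N * config$hairpin_fraction)
    n_rep <- round(N * config$repeat_fraction)
    n_rand <- round(N * config$unmappable_fraction)
    n_mir <- N - n_hp - n_rep - n_rand
    lens <- c(21L, 22L, 23L); lprob <- c(0.25, 0.5, 0.25)
    contig_str <- setNames(as.character(sim_ref$reference$seqs),
                           names(sim_ref$reference$seqs))
    # vectorized strand-aware sequence extraction
    get_seqs <- function(contig, st, en, strand) {
      s <- substring(contig_str[contig], st, en)
      neg <- strand == "-"
      if (any(neg)) s[neg] <- revcomp(s[neg])
      unname(s)
    }

    rows <- vector("list", 4L)

    ## miRNA reads: fixed 5' end at the locus 5' end
    mir <- sim_ref$truth$mirna_loci
    keep <- !S4Vectors::mcols(mir)$name %in% exclude_loci
    mir <- mir[keep]
    if (n_mir > 0L && length(mir)) {
      w <- S4Vectors::mcols(mir)$abundance
      locus_idx <- sample.int(length(mir), n_mir, replace = TRUE,
                              prob = w / sum(w))
      L <- sample(lens, n_mir, replace = TRUE, prob = lprob)
      chr <- as.character(GenomicRanges::seqnames(mir))[locus_idx]
      std <- as.character(GenomicRanges::strand(mir))[locus_idx]
      st <- ifelse(std == "+", GenomicRanges::start(mir)[locus_idx],
                   GenomicRanges::end(mir)[locus_idx] - L + 1L)
      insert <- get_seqs(chr, st, st + L - 1L, std)
      rows[[1]] <- data.frame(
        source = "mirna",
        locus = S4Vectors::mcols(mir)$name[locus_idx],
        insert = insert, insert_length = L, strand = std,
        scaled_start = NA_integer_, stringsAsFactors = FALSE)
    }

    ## hairpin reads
    if (n_hp > 0L) {
      hp <- sim_ref$hairpin
      TT <- hp$hairpin_end - hp$hairpin_start + 1L  # stem + loop length
      L <- sample(lens, n_hp, replace = TRUE, prob = lprob)
      std <- ifelse(runif(n_hp) < config$strand_bias, "+", "-")
      phased <- if (config$hairpin_mode == "terminal")
        runif(n_hp) >= config$noise_fraction else rep(FALSE, n_hp)
      scaled5 <- integer(n_hp)
      A <- config$arm_length
      if (any(phased)) {
        # register-1 lattice within the arms; abundance decays per step
        kmax <- (A - max(lens)) %/% 22L
        kk <- sample(0:kmax, sum(phased), replace = TRUE,
                     prob = config$decay^(0:kmax))
        plus_pos <- 1L + 22L * kk            # + strand 5' end in arm5
        minus_pos <- TT - 22L * kk           # - strand 5' end in arm3
        scaled5[phased] <- ifelse(std[phased] == "+", plus_pos, minus_pos)
      }
      if (any(!phased)) {
        nn <- sum(!phased)
        Ln <- L[!phased]
        # uniform 5' ends such that the read lies within the hairpin
        scaled5[!phased] <- ifelse(
          std[!phased] == "+",
          vapply(Ln, function(l) sample.int(TT - l + 1L, 1L), integer(1)),
          vapply(Ln, function(l) sample.int(TT - l + 1L, 1L), integer(1)) +
            Ln - 1L)
      }
      pos5 <- hp$hairpin_start + scaled5 - 1L
      st <- ifelse(std == "+", pos5, pos5 - L + 1L)
      insert <- get_seqs(rep(hp$plasmid_contig, n_hp), st, st + L - 1L, std)
      rows[[2]] <- data.frame(
        source = ifelse(phased, "hairpin_phased", "hairpin_noise"),
        locus = "hairpin", insert = insert, insert_length = L,
        strand = std, scaled_start = scaled5, stringsAsFactors = FALSE)
    }

    ## repeat-derived reads (interior positions so all copies match)
    reps <- sim_ref$truth$repeats
    if (n_rep > 0L && length(reps)) {
      idx <- sample.int(length(reps), n_rep, replace = TRUE)
      L <- sample(lens, n_rep, replace = TRUE, prob = lprob)
      std <- sample(c("+", "-"), n_rep, replace = TRUE)
      off <- vapply(seq_len(n_rep), function(i)
        sample.int(IRanges::width(reps)[idx[i]] - L[i] + 1L, 1L),
        integer(1))
      chr <- as.character(GenomicRanges::seqnames(reps))[idx]
      st <- GenomicRanges::start(reps)[idx] + off - 1L
      insert <- get_seqs(chr, st, st + L - 1L, std)
      rows[[3]] <- data.frame(
        source = "repeat", locus = S4Vectors::mcols(reps)$name[idx],
        insert = insert, insert_length = L, strand = std,
        scaled_start = NA_integer_, stringsAsFactors = FALSE)
    }

    ## random (unmappable) reads
    if (n_rand > 0L) {
      L <- sample(lens, n_rand, replace = TRUE, prob = lprob)
      insert <- vapply(L, random_dna, character(1))
      rows[[4]] <- data.frame(
        source = "random", locus = NA_character_, insert = insert,
        insert_length = L, strand = NA_character_,
        scaled_start = NA_integer_, stringsAsFactors = FALSE)
    }

    truth <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    n <- nrow(truth)
    truth$read_id <- sprintf("r%06d", seq_len(n))
    truth <- truth[, c("read_id", "source", "locus", "insert",
                       "insert_length", "strand", "scaled_start")]
    wrap_n <- function(k) {
      w <- config$randomized_end_length
      m <- matrix(sample(c("A", "C", "G", "T"), k * w, replace = TRUE),
                  nrow = k)
      do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
    raw <- paste0(wrap_n(n), truth$insert, wrap_n(n), config$adapter)
    reads <- Biostrings::DNAStringSet(setNames(raw, truth$read_id))
    if (!is.null(fastq_out))
      Biostrings::writeXStringSet(reads, fastq_out, format = "fastq")
    structure(list(reads = reads, truth = truth), class = "sim_library")
  })
}

#' Simulate replicate libraries
#'
#' Draws `k` libraries from the same planted reference with independent
#' sampling (seed offset by the replicate index).
#'
#' @inheritParams simulate_library
#' @param k number of replicates (>= 1).
#' @param dropout_locus,dropout_replicate optionally omit one miRNA
#'   locus from one replicate, for testing replicate-intersection
#'   behaviour.
#' @return A list of `k` [simulate_library()] results.
#' @export
make_replicates <- function(config, sim_ref, k,
                            dropout_locus = NULL,
                            dropout_replicate = NULL) {
  stopifnot(k >= 1L)
  lapply(seq_len(k), function(r) {
    excl <- if (!is.null(dropout_locus) &&
                !is.null(dropout_replicate) && r == dropout_replicate)
      dropout_locus else character()
    simulate_library(config, sim_ref, seed_offset = r,
                     exclude_loci = excl)
  })
}
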