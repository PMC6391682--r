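test_that("reference construction merges genome and plasmids", {
  gen <- Biostrings::DNAStringSet(
    c(chr1 = strrep("ACGT", 100), chr2 = strrep("GATC", 100),
      chr3 = strrep("TTGA", 100)))
  pls <- Biostrings::DNAStringSet(c(p1 = strrep("AC", 50),
                                    p2 = strrep("GT", 50)))
  ref <- build_reference(gen, pls)
  expect_length(ref$seqs, 5L)
  expect_identical(names(ref$seqs), c("chr1", "chr2", "chr3", "p1", "p2"))
  expect_equal(sum(ref$is_plasmid), 2L)
  expect_false(any(ref$is_plasmid[1:3]))

  expect_error(build_reference(gen, Biostrings::DNAStringSet(
    c(chr1 = "ACGT"))), "duplicate contig")
  expect_length(build_reference(gen)$seqs, 3L)
})

test_that("exact alignment reports every placement with shared n_hits", {
  withr::with_seed(5, {
    mer <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(mer)))
    a <- paste0(strrep("A", 50), mer, strrep("C", 50))
    b <- paste0(strrep("G", 30), rc, strrep("T", 30))
    ref <- build_reference(Biostrings::DNAStringSet(c(cA = a, cB = b)))
    hits <- align_exact(mer, ref)
    expect_length(hits, 2L)
    expect_setequal(as.character(GenomicRanges::seqnames(hits)),
                    c("cA", "cB"))
    expect_identical(S4Vectors::mcols(hits)$n_hits, c(2L, 2L))
    expect_equal(S4Vectors::mcols(hits)$weight, c(0.5, 0.5))
    expect_identical(
      as.character(GenomicRanges::strand(hits))[
        as.character(GenomicRanges::seqnames(hits)) == "cB"], "-")

    # absent read: empty result, not an error
    expect_length(align_exact(strrep("A", 21), build_reference(
      Biostrings::DNAStringSet(c(x = strrep("G", 100))))), 0L)

    # repeat family: 4 identical loci -> 4 placements, n_hits = 4
    fam <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    genome <- paste0(fam, strrep("T", 40), fam, strrep("C", 40),
                     fam, strrep("G", 40), fam)
    ref4 <- build_reference(Biostrings::DNAStringSet(c(g = genome)))
    sub <- substr(fam, 10, 30)
    hits4 <- align_exact(sub, ref4)
    expect_length(hits4, 4L)
    expect_true(all(S4Vectors::mcols(hits4)$n_hits == 4L))
  })
})

test_that("alignments match a quadratic brute-force scan", {
  withr::with_seed(2024, {
    for (trial in 1:30) {
      contigs <- setNames(
        vapply(sample(200:2000, 2), function(n)
          paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
          character(1)),
        c("c1", "c2"))
      ref <- build_reference(Biostrings::DNAStringSet(contigs))
      L <- sample(15:30, 1)
      read <- if (trial %% 2 == 0) {
        # sample from the reference so hits exist
        src <- sample(names(contigs), 1)
        st <- sample.int(nchar(contigs[[src]]) - L, 1)
        s <- substr(contigs[[src]], st, st + L - 1L)
        if (runif(1) < 0.5)
          s <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(s)))
        s
      } else paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
      got <- align_exact(read, ref)
      want <- oracle_scan(read, contigs)
      expect_equal(length(got), nrow(want))
      if (length(got)) {
        gd <- data.frame(
          contig = as.character(GenomicRanges::seqnames(got)),
          start = GenomicRanges::start(got),
          end = GenomicRanges::end(got),
          strand = as.character(GenomicRanges::strand(got)))
        gd <- gd[order(gd$contig, gd$start, gd$strand), ]
        rownames(gd) <- rownames(want) <- NULL
        expect_identical(gd, want)
        expect_true(all(S4Vectors::mcols(got)$n_hits == nrow(want)))
      }
    }
  })
})

test_that("aligning a reverse complement flips strands at the same loci", {
  withr::with_seed(31, {
    contig <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                    collapse = "")
    ref <- build_reference(Biostrings::DNAStringSet(c(g = contig)))
    for (trial in 1:10) {
      st <- sample.int(2950, 1)
      read <- substr(contig, st, st + 21L)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(read)))
      fwd <- align_exact(read, ref)
      rev <- align_exact(rc, ref)
      expect_identical(GenomicRanges::start(fwd), GenomicRanges::start(rev))
      expect_identical(as.character(GenomicRanges::strand(fwd)),
                       chartr("+-", "-+",
                              as.character(GenomicRanges::strand(rev))))
    }
  })
})

test_that("reads with N and duplicate records are handled", {
  ref <- build_reference(Biostrings::DNAStringSet(
    c(g = strrep("ACGTTGCA", 50))))
  expect_length(align_exact(paste0("ACGTTGCAACGTTGCANACGT"), ref), 0L)
  # duplicate read sequences: each record is a counting unit
  seq22 <- paste0(strrep("ACGTTGCA", 2), "ACGTTG")
  lib <- align_library(c(r1 = seq22, r2 = seq22), ref)
  expect_equal(lib$n_mapped, 2L)
  expect_equal(lib$denominator, 2)
})

test_that("SAM import keeps only perfect ungapped matches", {
  ref <- build_reference(Biostrings::DNAStringSet(
    c(chr1 = strrep("ACGT", 100))))
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:400",
    # perfect 22M on +
    "r1\t0\tchr1\t11\t255\t22M\t*\t0\t0\tCGTACGTACGTACGTACGTACG\t*\tNM:i:0",
    # one mismatch: excluded at max_mismatch 0
    "r2\t0\tchr1\t31\t255\t22M\t*\t0\t0\tCGTACGTACGTACGTACGTACG\t*\tNM:i:1",
    # soft-clipped: skipped
    "r3\t0\tchr1\t51\t255\t2S20M\t*\t0\t0\tCGTACGTACGTACGTACGTACG\t*\tNM:i:0",
    # multimapper: three perfect placements
    "r4\t0\tchr1\t71\t255\t22M\t*\t0\t0\tCGTACGTACGTACGTACGTACG\t*\tNM:i:0",
    "r4\t256\tchr1\t91\t255\t22M\t*\t0\t0\tCGTACGTACGTACGTACGTACG\t*\tNM:i:0",
    "r4\t272\tchr1\t111\t255\t22M\t*\t0\t0\tCGTACGTACGTACGTACGTACG\t*\tNM:i:0")
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  imp <- import_sam(path, ref)
  expect_equal(imp$report$n_kept, 4L)
  expect_equal(imp$report$n_skipped_clipped_or_gapped, 1L)
  expect_equal(imp$report$n_skipped_mismatch, 1L)
  r4 <- imp$alignments[S4Vectors::mcols(imp$alignments)$read_id == "r4"]
  expect_length(r4, 3L)
  expect_true(all(S4Vectors::mcols(r4)$n_hits == 3L))
  expect_true("-" %in% as.character(GenomicRanges::strand(r4)))
  expect_equal(import_sam(path, ref, max_mismatch = 1)$report$n_kept, 5L)

  bad <- sub("chr1", "chrX", sam)
  path2 <- withr::local_tempfile(fileext = ".sam")
  writeLines(bad, path2)
  expect_error(import_sam(path2, ref), "chrX")
})

test_that("library assembly computes denominators by policy", {
  withr::with_seed(12, {
    contig <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                    collapse = "")
    ref <- build_reference(Biostrings::DNAStringSet(c(g = contig)))
    st <- sample.int(4950, 40)
    reads <- setNames(substring(contig, st, st + 21L),
                      paste0("r", 1:40))
    junk <- setNames(rep(strrep("AN", 11), 10), paste0("x", 1:10))
    lib <- align_library(c(reads, junk), ref)
    expect_equal(lib$n_mapped, 40L)
    expect_equal(lib$denominator, 40)
    lib2 <- align_library(c(reads, junk), ref,
                          denominator_policy = "all-reads")
    expect_equal(lib2$denominator, 50)
    # all-unmappable input: empty library refuses RPM
    lib0 <- align_library(junk, ref)
    expect_equal(lib0$denominator, 0)
    expect_error(rpm(1, lib0), "positive")
  })
})
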