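gr <- function(start, end, contig = "chr1", strand = "*", weight = 1) {
  g <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                              strand = strand)
  S4Vectors::mcols(g)$weight <- rep(weight, length.out = length(g))
  g
}

test_that("region collapse unions transitive overlaps and sums weights", {
  r <- collapse_regions(gr(c(101, 111), c(122, 132)))
  expect_length(r, 1L)
  expect_equal(GenomicRanges::start(r), 101)
  expect_equal(GenomicRanges::end(r), 132)
  expect_equal(S4Vectors::mcols(r)$fractional_count, 2)

  # abutting intervals share no base: two regions
  r2 <- collapse_regions(gr(c(101, 123), c(122, 144)))
  expect_length(r2, 2L)

  # opposite strands still collapse (clusters are strand-agnostic)
  r3 <- collapse_regions(gr(c(101, 111), c(122, 132),
                            strand = c("+", "-")))
  expect_length(r3, 1L)

  expect_length(collapse_regions(GenomicRanges::GRanges()), 0L)
})

test_that("cluster calling applies RPM threshold then gap join", {
  # 10 unique 22-nt reads at one locus of a 1e6-read library: 10 RPM
  lib <- make_library(data.frame(contig = "chr1",
                                 start = rep(1001, 10),
                                 end = rep(1022, 10), strand = "+"),
                      denominator = 1e6)
  cl <- call_sample_clusters(lib)
  expect_length(cl, 1L)
  expect_equal(S4Vectors::mcols(cl)$rpm, 10)

  # 2 reads = 2 RPM: discarded; 3 reads = 3 RPM: retained
  two <- make_library(data.frame(contig = "chr1", start = rep(1001, 2),
                                 end = rep(1022, 2), strand = "+"),
                      denominator = 1e6)
  expect_length(call_sample_clusters(two), 0L)
  three <- make_library(data.frame(contig = "chr1", start = rep(1001, 3),
                                   end = rep(1022, 3), strand = "+"),
                        denominator = 1e6)
  expect_length(call_sample_clusters(three), 1L)

  # two retained clusters, 0-based gap 50: joined; gap 51: separate.
  # cluster A covers 1001..1022; B starts at 1022 + gap + 1.
  for (gap in c(50L, 51L)) {
    libg <- make_library(data.frame(
      contig = "chr1",
      start = c(rep(1001, 5), rep(1023 + gap, 5)),
      end = c(rep(1022, 5), rep(1044 + gap, 5)), strand = "+"),
      denominator = 1e6)
    clg <- call_sample_clusters(libg)
    expect_length(clg, if (gap == 50L) 1L else 2L)
    if (gap == 50L)
      expect_equal(S4Vectors::mcols(clg)$rpm, 10)
  }
  expect_error(call_sample_clusters(
    make_library(data.frame(contig = "chr1", start = 1, end = 22,
                            strand = "+"), denominator = 0)),
    "denominator")
})

test_that("collapse conserves total fractional count before filtering", {
  withr::with_seed(77, {
    for (trial in 1:20) {
      n <- sample(1:200, 1)
      st <- sample.int(3000, n, replace = TRUE)
      w <- 1 / sample(c(1L, 2L, 4L), n, replace = TRUE)
      regions <- collapse_regions(gr(st, st + 21, weight = w))
      expect_equal(sum(S4Vectors::mcols(regions)$fractional_count),
                   sum(w))
    }
  })
})

test_that("raising threshold or join distance never adds clusters", {
  withr::with_seed(88, {
    for (trial in 1:10) {
      n <- sample(50:300, 1)
      st <- sample.int(4000, n, replace = TRUE)
      lib <- make_library(data.frame(contig = "chr1", start = st,
                                     end = st + 21, strand = "+"),
                          denominator = 1e6)
      n_at <- function(thr, jd) length(call_sample_clusters(
        lib, cluster_params(rpm_threshold = thr, join_distance = jd)))
      expect_true(n_at(3, 50) >= n_at(6, 50))
      expect_true(n_at(3, 50) >= n_at(3, 200))
    }
  })
})

test_that("replicate intersection keeps only regions present in all", {
  mk <- function(starts) {
    g <- gr(starts, starts + 50)
    S4Vectors::mcols(g)$fractional_count <- rep(5, length(g))
    S4Vectors::mcols(g)$rpm <- rep(5, length(g))
    g
  }
  r1 <- mk(c(100, 1000, 5000))
  r2 <- mk(c(120, 1010))          # misses the 5000 cluster
  r3 <- mk(c(90, 1020, 5000))
  kept <- intersect_replicates(list(r1, r2, r3))
  expect_length(kept, 2L)
  # union coordinates of the overlapping replicate clusters
  expect_equal(GenomicRanges::start(kept), c(90, 1000))
  expect_equal(GenomicRanges::end(kept), c(170, 1070))
  expect_equal(S4Vectors::mcols(kept)$rpm_rep2, c(5, 5))

  # single replicate: vacuous intersection
  solo <- intersect_replicates(list(r1))
  expect_length(solo, 3L)
  expect_error(intersect_replicates(list()), "replicate")

  # intersection coordinates on request
  kept2 <- intersect_replicates(list(r1, r3),
                                coordinates = "intersection")
  expect_equal(GenomicRanges::start(kept2)[1], 100)
  expect_equal(GenomicRanges::end(kept2)[1], 140)
})

test_that("between-sample merge unions overlapping clusters transitively", {
  mk <- function(starts, ends, rpms) {
    g <- gr(starts, ends)
    S4Vectors::mcols(g)$rpm <- rpms
    g
  }
  a <- mk(100, 150, 20)
  b <- mk(140, 190, 8)
  m <- merge_between_samples(list(A = a, B = b))
  expect_length(m, 1L)
  expect_equal(GenomicRanges::start(m), 100)
  expect_equal(GenomicRanges::end(m), 190)
  expect_equal(S4Vectors::mcols(m)$rpm_A, 20)
  expect_equal(S4Vectors::mcols(m)$rpm_B, 8)

  # non-overlapping clusters stay separate, absent sample reports 0
  m2 <- merge_between_samples(list(A = mk(100, 150, 20),
                                   B = mk(500, 560, 9)))
  expect_length(m2, 2L)
  expect_equal(S4Vectors::mcols(m2)$rpm_B, c(0, 9))

  # three-way chained overlap collapses into a single region
  m3 <- merge_between_samples(list(A = mk(100, 150, 1),
                                   B = mk(140, 200, 1),
                                   C = mk(190, 260, 1)))
  expect_length(m3, 1L)
  expect_equal(GenomicRanges::end(m3), 260)

  # with libraries, per-sample RPM is recomputed from reads
  lib <- make_library(data.frame(contig = "chr1", start = rep(120, 4),
                                 end = rep(141, 4), strand = "+"),
                      denominator = 1e6)
  m4 <- merge_between_samples(list(A = a), libraries = list(s1 = lib))
  expect_equal(S4Vectors::mcols(m4)$rpm_s1, 4)
})

test_that("cluster summaries take median log10 RPM with a zero floor", {
  expect_equal(summarize_cluster(c(1, 10, 100)), 1)
  expect_equal(summarize_cluster(1000), 3)
  expect_equal(summarize_cluster(c(0, 10)), 0)    # median of -1, 1
  expect_true(is.na(summarize_cluster(c(0, 0), policy = "drop")))
  expect_error(summarize_cluster(numeric(0)), ">= 1")
})

test_that("annotation hierarchy resolves every pairwise conflict", {
  at <- function(cat) {
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
    if (cat == "transposable_elements") {
      S4Vectors::mcols(g)$name <- "r"; S4Vectors::mcols(g)$class <- "LINE1"
    }
    g
  }
  build_ann <- function(cats) {
    args <- list()
    if ("miRNA" %in% cats) args$mirna <- at("miRNA")
    if ("transposable_elements" %in% cats)
      args$repeats <- at("transposable_elements")
    if ("mRNA" %in% cats) args$exons <- at("mRNA")
    if ("misc_RNA" %in% cats) args$misc_rna <- at("misc_RNA")
    do.call(annotation_set, args)
  }
  cluster <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 172))
  prio <- c("miRNA", "transposable_elements", "mRNA", "misc_RNA")
  for (i in seq_along(prio)) for (j in seq_along(prio)) {
    if (i >= j) next
    ann <- build_ann(prio[c(i, j)])
    got <- annotate_clusters(cluster, ann)
    expect_identical(as.character(S4Vectors::mcols(got)$category),
                     prio[i], label = paste(prio[i], "vs", prio[j]))
  }
  # no overlap at all -> other
  none <- annotate_clusters(
    GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 50)),
    build_ann(prio))
  expect_identical(as.character(S4Vectors::mcols(none)$category), "other")
})
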