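# toy_hairpin(): hairpin at pIR:101-303, arm5 101-189, loop 190-214,
# arm3 215-303 (see helper-oracles.R)

test_that("hairpin descriptions are validated", {
  expect_s3_class(toy_hairpin(), "hairpin_spec")
  expect_error(hairpin_spec("p", 101, 303, arm5 = c(101, 220),
                            loop = c(190, 214), arm3 = c(215, 303),
                            "-"), "ordered")
  expect_error(hairpin_spec("p", 101, 303, arm5 = c(101, 150),
                            loop = c(160, 170), arm3 = c(180, 303),
                            "-"), "arm length")
  expect_error(hairpin_spec("p", 101, 303, arm5 = c(50, 138),
                            loop = c(190, 214), arm3 = c(215, 303),
                            "-"), "within")
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("plasmid_contig: pIR", "hairpin_start: 101",
               "hairpin_end: 303", "arm5: [101, 189]",
               "loop: [190, 214]", "arm3: [215, 303]",
               "reporter_antisense_strand: '-'"), y)
  hp <- read_hairpin_spec(y)
  expect_identical(hp$arm3, c(215L, 303L))
})

test_that("arm density is per-position CPM split by arm of origin", {
  hp <- toy_hairpin()
  # 10 unique 22-nt reads starting at the first arm5 base
  lib <- make_library(data.frame(contig = "pIR", start = rep(101, 10),
                                 end = rep(122, 10), strand = "+"),
                      denominator = 1e6)
  d <- arm_density(lib, hp)
  expect_equal(d$up_cpm[1:22], rep(10, 22))
  expect_true(all(d$up_cpm[-(1:22)] == 0))
  expect_true(all(d$down_cpm == 0))
  expect_equal(d$position[1], 101)

  # 3' arm reads appear in the down profile with negative sign
  lib3 <- make_library(data.frame(contig = "pIR", start = 215,
                                  end = 236, strand = "-"),
                       denominator = 1e6)
  d3 <- arm_density(lib3, hp)
  expect_true(all(d3$up_cpm == 0))
  expect_equal(sum(d3$down_cpm < 0), 22)
  expect_equal(min(d3$down_cpm), -1)

  # a read whose 5' end sits in the loop joins neither arm profile
  loopy <- make_library(data.frame(contig = "pIR", start = 200,
                                   end = 221, strand = "+"),
                        denominator = 1e6)
  dl <- arm_density(loopy, hp)
  expect_true(all(dl$up_cpm == 0) && all(dl$down_cpm == 0))

  # no hairpin reads at all: zero profiles of full hairpin length
  empty <- make_library(data.frame(contig = "chr9", start = 1000,
                                   end = 1021, strand = "+"),
                        denominator = 1e6)
  de <- arm_density(empty, hp)
  expect_equal(nrow(de), 203)
  expect_true(all(de$up_cpm == 0) && all(de$down_cpm == 0))
})

test_that("reporter-targeting selection filters by antisense strand", {
  hp <- toy_hairpin()
  lib <- make_library(data.frame(
    contig = "pIR", start = c(101, 130, 215, 240),
    end = c(122, 151, 236, 261),
    strand = c("+", "-", "-", "+")), denominator = 1e6)
  sel <- select_reporter_targeting(lib, hp)
  expect_length(sel, 2L)
  expect_true(all(as.character(GenomicRanges::strand(sel)) == "-"))
  expect_length(select_reporter_targeting(
    make_library(data.frame(contig = "pIR", start = 101, end = 122,
                            strand = "+"), denominator = 1e6), hp), 0L)
})

test_that("phasing registers follow the modulo rule on scaled 5' ends", {
  hp <- toy_hairpin()
  lib_at <- function(scaled, strand = "+", L = 22L) {
    strand <- rep(strand, length.out = length(scaled))
    pos5 <- hp$hairpin_start + scaled - 1L
    st <- ifelse(strand == "+", pos5, pos5 - L + 1L)
    make_library(data.frame(contig = "pIR", start = st, end = st + L - 1L,
                            strand = rep(strand, length.out = length(st))),
                 denominator = 1e6)
  }
  # scaled starts 1, 23, 45 all reduce to register 1
  p <- phasing_profile(lib_at(c(1, 23, 45)), hp)
  expect_equal(unname(p$proportions[1]), 1)
  expect_equal(sum(p$proportions), 1)
  expect_equal(p$n_reads, 3)

  # one read in each register: uniform
  p2 <- phasing_profile(lib_at(1:22), hp)
  expect_equal(unname(p2$proportions), rep(1 / 22, 22))

  # weights: starts {1, 1, 2}
  p3 <- phasing_profile(lib_at(c(1, 1, 2)), hp)
  expect_equal(unname(p3$proportions[1:2]), c(2 / 3, 1 / 3))

  # minus-strand reads use their biological 5' end (alignment end)
  pm <- phasing_profile(lib_at(23, strand = "-"), hp)
  expect_equal(unname(pm$proportions[1]), 1)

  # other periods
  p7 <- phasing_profile(lib_at(c(1, 8, 15)), hp, period = 7)
  expect_equal(unname(p7$proportions[1]), 1)
  expect_error(phasing_profile(lib_at(1), hp, period = 1), "period")

  # no hairpin reads: flagged, proportions undefined
  p0 <- phasing_profile(make_library(
    data.frame(contig = "chr5", start = 100, end = 121, strand = "+"),
    denominator = 1e6), hp)
  expect_equal(p0$n_reads, 0)
  expect_true(all(is.na(p0$proportions)))
})

test_that("hairpin length abundance counts fractional reads in region", {
  hp <- toy_hairpin()
  # multimapper placed on both arms of the inverted repeat: one read
  mm <- make_library(data.frame(contig = "pIR", start = c(101, 282),
                                end = c(122, 303), strand = c("+", "-"),
                                n_hits = 2L, read_id = "m1"),
                     denominator = 1e6)
  h <- hairpin_length_abundance(mm, hp)
  expect_equal(h$rpm[h$length == 22], 1)
  expect_equal(sum(h$rpm), 1)
  empty <- make_library(data.frame(contig = "chr1", start = 1,
                                   end = 22, strand = "+"),
                        denominator = 1e6)
  expect_true(all(hairpin_length_abundance(empty, hp)$rpm == 0))
})
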