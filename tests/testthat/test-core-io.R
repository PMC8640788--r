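test_that("FASTA reading normalises case and ambiguity codes", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgt"), p)
  expect_identical(read_fasta(p), c(s1 = "ACGT"))

  writeLines(c(">s1", "acgtRYWSn"), p)
  expect_identical(read_fasta(p), c(s1 = "ACGTNNNNN"))
})

test_that("FASTA errors: duplicates, missing and empty files", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), p)
  expect_error(read_fasta(p), "duplicate.*a")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
  writeLines(character(0), p)
  expect_error(read_fasta(p))
})

test_that("FASTA round-trips losslessly and write is byte-stable", {
  fx <- local_fixture()
  genome <- read_fasta(fx$fasta)
  p <- withr::local_tempfile(fileext = ".fa")
  write_fasta(genome, p)
  expect_identical(read_fasta(p), genome)
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(read_fasta(p), p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("BED parsing keeps 0-based half-open coordinates and labels", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t10000\tP1", p)
  b <- read_bed(p)
  expect_equal(b$chrom, "chr1")
  expect_equal(b$start, 0)
  expect_equal(b$end, 10000)
  expect_equal(b$label, "P1")

  writeLines("chr1\t5\t5", p)
  expect_error(read_bed(p), "start >= end")
  writeLines("chr1\t1.5\t7", p)
  expect_error(read_bed(p), "non-integer")
})

test_that("fixture pause BED round-trips with all labels intact", {
  fx <- local_fixture()
  b <- read_bed(fx$bed)
  expect_equal(nrow(b), 4L)
  expect_setequal(b$label, paste0("P", 1:4))
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(b, p)
  expect_equal(read_bed(p), b)
})

test_that("VCF reading keeps biallelic SNVs and counts skips", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t101\t.\tA\tG\t.\tPASS\t.",
               "chr1\t150\t.\tA\tAT\t.\tPASS\t.",   # insertion
               "chr1\t160\t.\tAT\tA\t.\tPASS\t.",   # deletion
               "chr1\t170\t.\tA\tC,G\t.\tPASS\t.",  # multiallelic
               "chr1\t180\t.\tT\tC\t.\tPASS\t."), p)
  s <- suppressMessages(read_snvs(p))
  expect_equal(nrow(s), 2L)
  expect_equal(attr(s, "skipped"), 3L)
  expect_equal(s$pos, c(101, 180))
  expect_equal(s$ref[1], "A")
  expect_equal(s$alt[1], "G")
})

test_that("fixture VCF kept + skipped equals total records", {
  fx <- local_fixture()
  s <- suppressMessages(read_snvs(fx$vcf))
  n_records <- sum(!startsWith(readLines(fx$vcf), "#"))
  expect_equal(nrow(s) + attr(s, "skipped"), n_records)
  expect_gt(nrow(s), 0L)
})

test_that("window tiling drops trailing remainders", {
  r <- genomic_interval("c", 0, 10000)
  expect_equal(nrow(tile_windows(r, 500)), 20L)
  expect_equal(nrow(tile_windows(genomic_interval("c", 0, 305000), 10000)),
               30L)
  expect_equal(nrow(tile_windows(genomic_interval("c", 0, 499), 500)), 0L)
})

test_that("window grids partition: disjoint, in-bounds, floor count", {
  set.seed(401)
  for (i in 1:20) {
    len <- sample(100:5000, 1)
    width <- sample(50:700, 1)
    g <- tile_windows(genomic_interval("c", 0, len), width)
    expect_equal(nrow(g), len %/% width)
    if (nrow(g) > 0) {
      expect_true(all(g$start >= 0 & g$end <= len))
      expect_true(all(diff(g$start) == width))
      expect_true(all(g$end - g$start == width))
    }
  }
})

test_that("window composition matches brute-force tallies", {
  w4 <- genomic_interval("s", 0, 4)
  expect_equal(window_composition(c(s = "GGCC"), w4)$gc_fraction, 1.0)
  expect_equal(window_composition(c(s = "GGCC"), w4)$tt_count, 0L)
  expect_equal(window_composition(c(s = "TTTT"), w4)$gc_fraction, 0.0)
  expect_equal(window_composition(c(s = "TTTT"), w4)$tt_count, 3L)

  set.seed(77)
  s <- random_dna(500, gc = 0.45)
  comp <- window_composition(c(s = s), genomic_interval("s", 0, 500))
  x <- strsplit(s, "")[[1]]
  expect_equal(comp$gc_fraction, sum(x %in% c("G", "C")) / 500)
  expect_equal(comp$tt_count, sum(x[-500] == "T" & x[-1] == "T"))

  # N excluded from the GC denominator; all-N windows undefined
  comp <- window_composition(c(s = "GGNN"), genomic_interval("s", 0, 4))
  expect_equal(comp$gc_fraction, 1.0)
  expect_equal(comp$n_count, 2L)
  expect_true(is.na(window_composition(c(s = "NNNN"),
                                       genomic_interval("s", 0, 4))$gc_fraction))
})

test_that("reverse complement is a correct involution", {
  expect_equal(reverse_complement("GGGT"), "ACCC")
  expect_equal(reverse_complement("N"), "N")
  set.seed(42)
  for (i in 1:200) {
    s <- random_dna(sample(1:60, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})
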