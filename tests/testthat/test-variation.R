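test_that("all twelve substitutions collapse two-to-one onto six classes", {
  expect_equal(classify_snp("T", "C"), "T>C")
  expect_equal(classify_snp("G", "A"), "C>T")
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_snp(pairs$ref, pairs$alt)
  expect_equal(sort(unique(cls)), c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  expect_true(all(table(cls) == 2L))
  # strand collapse: complementing both alleles leaves the class unchanged
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(cls, classify_snp(comp[pairs$ref], comp[pairs$alt]))
  expect_error(classify_snp("N", "A"), "ambiguous")
  expect_error(classify_snp("A", "A"), "differ")
})

test_that("window variation conserves counts and spectra", {
  grid <- tile_windows(genomic_interval("c", 0, 10000), 500)
  set.seed(701)
  snps <- data.frame(chrom = "c", pos = sort(sample(1:10000, 10)),
                     ref = "T", alt = "C")
  wv <- window_variation(snps, grid)
  expect_equal(sum(wv$n_snps), 10L)
  expect_equal(sum(wv$T.C), 10L)
  expect_equal(wv$n_per_10kb, wv$n_snps * 20)

  snps3 <- data.frame(chrom = "c", pos = c(10, 20, 30),
                      ref = c("T", "T", "C"), alt = c("C", "G", "T"))
  wv3 <- window_variation(snps3, grid)
  expect_equal(wv3$t_to_cg[1], 2L)
  expect_equal(wv3$c_to_at[1], 1L)

  # SNVs in the dropped remainder are discarded with a count
  grid9 <- tile_windows(genomic_interval("c", 0, 9800), 500)
  expect_message(
    wv9 <- window_variation(data.frame(chrom = "c", pos = 9700,
                                       ref = "T", alt = "A"), grid9),
    "discarded")
  expect_equal(attr(wv9, "dropped"), 1L)
  expect_error(window_variation(data.frame(chrom = "zz", pos = 1,
                                           ref = "T", alt = "A"), grid),
               "unknown sequence: zz")
})

test_that("Mann-Whitney comparisons: degenerate, exact, and power cases", {
  same <- compare_groups(rep(3, 10), rep(3, 12))
  expect_equal(same$p_value, 1)

  sep <- compare_groups(1:20, 21:40)
  expect_equal(unname(sep$statistic), 0)
  expect_lt(sep$p_value, 0.001)
  expect_equal(sep$method, "exact")

  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("pause-effect detection has power at the planted multiplier", {
  spec <- small_spec(plants = list())
  g <- suppressMessages(generate_genome(spec, seed = 55))
  grid <- tile_regions(g$genome, 500)
  hits <- 0
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    sim <- suppressMessages(simulate_snps(g$genome, g$truth, seed = 9000 + s))
    wv <- window_variation(sim$snps, grid, g$truth$pause)
    p <- compare_groups(wv$n_per_10kb[wv$pause],
                        wv$n_per_10kb[!wv$pause])$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("energy bins partition windows into equal-count quantiles", {
  set.seed(702)
  n <- 1000
  folds <- data.frame(chrom = "c", start = (0:(n - 1)) * 500,
                      end = (1:n) * 500,
                      delta_g = -round(runif(n, 0, 40), 3))
  variation <- folds[, c("chrom", "start", "end")]
  variation$n_per_10kb <- -2 * folds$delta_g     # exact linear relation
  b <- bin_by_energy(folds, variation, n_bins = 10)
  expect_equal(nrow(b), 10L)
  expect_equal(unique(b$n), 100L)
  expect_false(is.unsorted(b$mean_delta_g))
  expect_true(all(abs(b$r - (-1)) < 1e-12))
  # partition invariant: every window in exactly one bin
  asg <- attr(b, "bin_assignment")
  expect_equal(sort(paste(asg$chrom, asg$start)),
               sort(paste(folds$chrom, folds$start)))
  expect_equal(as.vector(table(asg$bin)), rep(100L, 10))

  expect_error(bin_by_energy(folds[1:5, ], variation[1:5, ], n_bins = 10),
               "smaller n_bins")
  # bins differ in size by at most one when n is not divisible
  b2 <- bin_by_energy(folds[1:103, ], variation[1:103, ], n_bins = 10)
  expect_true(all(b2$n %in% c(10L, 11L)))
})

test_that("random windows are seeded, in-bounds, and respect the N policy", {
  set.seed(703)
  genome <- c(s1 = random_dna(30000), s2 = random_dna(20000))
  w1 <- random_windows(genome, n = 50, width = 5000, seed = 9)
  w2 <- random_windows(genome, n = 50, width = 5000, seed = 9)
  expect_identical(w1, w2)
  expect_true(all(w1$end <= nchar(genome)[w1$chrom]))
  expect_true(all(w1$start >= 0))

  # N-heavy region is avoided
  genome_n <- c(s1 = paste0(strrep("N", 10000), random_dna(5000)))
  wn <- random_windows(genome_n, n = 20, width = 4000, seed = 10)
  nf <- .n_fraction(genome_n, wn)
  expect_true(all(nf <= 0.1))
  expect_error(random_windows(c(s = "ACGT"), n = 5, width = 100),
               "long enough")
})

test_that("pause window arithmetic deduplicates shared intervals", {
  # fifteen distinct 10-kb intervals, one of them annotated twice
  iv <- genomic_interval("c", (0:14) * 20000, (0:14) * 20000 + 10000,
                         label = paste0("P", 1:15))
  iv_dup <- rbind(iv, iv[3, ])     # same interval found in two cell types
  expect_equal(pause_window_count(iv_dup, width = 500), 300)
  expect_equal(pause_window_count(iv[1, ], width = 500), 20)
  expect_equal(pause_window_count(iv[0, ]), 0L)
})

test_that("spectrum reports aggregate counts, rates, and ratios", {
  grid <- tile_windows(genomic_interval("c", 0, 1000), 500)
  snps <- data.frame(chrom = "c", pos = c(10, 20, 30, 40, 600),
                     ref = c("T", "T", "T", "C", "C"),
                     alt = c("C", "C", "G", "T", "A"))
  wv <- window_variation(snps, grid,
                         pause_labels = genomic_interval("c", 0, 500))
  rep <- spectrum_report(wv)
  p <- rep$counts[rep$counts$group == "pause", ]
  expect_equal(p$t_to_cg, 3)
  expect_equal(p$rate10kb_t_to_cg, 3 * 10000 / 500)
  expect_equal(sum(rep$counts$total), nrow(snps))
  expect_equal(length(rep$ratios), 9L)
})
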