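test_that("inverted repeats: worked examples", {
  cfg <- motif_config("at_cruciform_census")
  at12 <- find_inverted_repeats(strrep("AT", 12), cfg)
  expect_equal(nrow(at12), 1L)
  expect_equal(at12$arm_len, 12L)
  expect_equal(at12$spacer_len, 0L)

  # hairpin with random GC-balanced arm, no internal self-complementarity
  s <- "GCATGCCTAGCTAAC"
  hp <- paste0(s, "TTTT", reverse_complement(s))
  h <- find_inverted_repeats(hp, motif_config(ir_min_arm = 6L,
                                              ir_spacer_max = 10L))
  expect_equal(nrow(h), 1L)
  expect_equal(h$arm_len, 15L)
  expect_equal(h$spacer_len, 4L)

  expect_equal(nrow(find_inverted_repeats("AAAAAAAAAA", motif_config())), 0L)
})

test_that("mirror/triplex: the TTCTT tract and the purine exemplar", {
  m <- find_mirror_triplex(strrep("TTCTT", 15))
  expect_equal(nrow(m), 1L)
  expect_equal(m$end - m$start, 75)
  expect_equal(m$arm_len, 37L)
  expect_equal(m$spacer_len, 1L)
  expect_equal(m$arm_class, "pyrimidine")

  cfg <- motif_config(mr_min_arm = 7L, mr_spacer_max = 2L)
  m2 <- find_mirror_triplex("AGGGAGGCTGGAGGGA", cfg)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$arm_len, 7L)
  expect_equal(m2$spacer_len, 2L)
  expect_equal(m2$arm_class, "purine")

  expect_equal(nrow(find_mirror_triplex("ACGTACGTACGT")), 0L)
})

test_that("tandem repeats: units, copies, and containment collapse", {
  t1 <- find_tandem_repeats(strrep("TTCTT", 15))
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$copies, 15L)
  # unit reported as canonical rotation of the primitive period
  rot <- vapply(0:4, function(k) paste0(substr("TTCTT", k + 1, 5),
                                        substr("TTCTT", 1, k)), character(1))
  expect_true(t1$unit %in% rot)
  expect_equal(nchar(t1$unit), 5L)

  t2 <- find_tandem_repeats(strrep("AT", 12))
  expect_equal(nrow(t2), 1L)
  expect_equal(t2$unit, "AT")
  expect_equal(t2$copies, 12L)
})

test_that("direct repeats require long units and two copies", {
  unit <- "GATTACAGATCA"  # 12-mer
  d <- find_direct_repeats(strrep(unit, 2))
  expect_equal(nrow(d), 1L)
  expect_equal(d$copies, 2L)
  # short units never qualify as direct repeats
  expect_equal(nrow(find_direct_repeats(strrep("AT", 12))), 0L)
})

test_that("Z-DNA tracts follow the allowed-step rule", {
  z <- find_zdna("TGTGTGCGCG")
  expect_equal(nrow(z), 1L)
  expect_equal(z$end - z$start, 10)
  expect_equal(nrow(find_zdna("ATATATATAT")), 0L)
  # GA step breaks alternation: no tract of length >= 10
  expect_equal(nrow(find_zdna("TGTGAGTGTGTG")), 0L)
  # AT steps allowed when configured
  expect_equal(nrow(find_zdna("ATATATATAT",
                              motif_config(z_allow_at = TRUE))), 1L)
})

test_that("G4: four runs on either strand, three runs rejected", {
  g <- find_g4("GGGTGGGTGGGTGGG")
  expect_equal(nrow(g), 1L)
  expect_equal(g$strand, "+")
  expect_equal(nrow(find_g4("GGGTGGGTGGG")), 0L)
  gm <- find_g4("CCCACCCACCCACCC")
  expect_equal(nrow(gm), 1L)
  expect_equal(gm$strand, "-")
})

test_that("AT-cruciform census flags pure [AT]n hits", {
  a <- find_at_cruciforms(strrep("AT", 13))
  expect_equal(nrow(a), 1L)
  expect_true(a$pure_at)

  s <- "GCATGCATATGCAT"          # 12-bp-arm hairpin with G/C content
  hp <- paste0(s, "TT", reverse_complement(s))
  h <- find_at_cruciforms(hp)
  expect_gte(nrow(h), 1L)
  expect_false(any(h$pure_at))
})

test_that("scanners agree with brute-force enumeration on random sequences", {
  cfg <- motif_config(ir_min_arm = 4L, ir_spacer_max = 8L,
                      mr_min_arm = 5L, mr_min_tract = 10L,
                      mr_spacer_max = 4L, z_min_tract = 8L,
                      tr_unit_max = 6L, tr_min_copies = 3L,
                      dr_unit_min = 5L, dr_unit_max = 10L)
  set.seed(501)
  for (i in 1:25) {
    s <- random_dna(sample(80:400, 1), gc = sample(c(0.3, 0.5), 1))
    ir <- find_inverted_repeats(s, cfg)
    o_ir <- oracle_ir(s, cfg$ir_min_arm, cfg$ir_spacer_min,
                      cfg$ir_spacer_max)
    expect_equal(ir[, c("start", "end", "arm_len", "spacer_len")],
                 o_ir, ignore_attr = TRUE)

    mr <- find_mirror_triplex(s, cfg)
    o_mr <- oracle_mirror(s, cfg$mr_min_arm, cfg$mr_spacer_min,
                          cfg$mr_spacer_max, cfg$mr_min_tract)
    expect_equal(mr[, c("start", "end", "arm_len", "spacer_len",
                        "arm_class")], o_mr, ignore_attr = TRUE)

    tr <- find_tandem_repeats(s, cfg)
    o_tr <- oracle_tandem(s, cfg$tr_unit_min, cfg$tr_unit_max,
                          cfg$tr_min_copies)
    expect_equal(tr[, c("start", "end", "copies")],
                 o_tr[, c("start", "end", "copies")], ignore_attr = TRUE)

    z <- find_zdna(s, cfg)
    o_z <- oracle_zdna(s, cfg$z_min_tract)
    expect_equal(z[, c("start", "end")], o_z, ignore_attr = TRUE)

    g <- find_g4(s, cfg)
    o_g <- oracle_g4(s, cfg$g4_min_run, cfg$g4_min_runs,
                     cfg$g4_spacer_min, cfg$g4_spacer_max)
    expect_equal(g[, c("start", "end", "strand")], o_g, ignore_attr = TRUE)
  }
})

test_that("scanners respect strand symmetries", {
  set.seed(502)
  cfg <- motif_config(ir_min_arm = 4L, ir_spacer_max = 8L, mr_min_arm = 5L,
                      mr_min_tract = 10L, mr_spacer_max = 4L)
  for (i in 1:10) {
    s <- random_dna(300)
    n <- nchar(s)
    rc <- reverse_complement(s)
    # inverted repeats: hits on the reverse complement mirror in coordinates
    h1 <- find_inverted_repeats(s, cfg)
    h2 <- find_inverted_repeats(rc, cfg)
    mirrored <- data.frame(start = n - h2$end, end = n - h2$start,
                           arm_len = h2$arm_len, spacer_len = h2$spacer_len)
    mirrored <- mirrored[order(mirrored$start, mirrored$end), ]
    expect_equal(h1[, c("start", "end", "arm_len", "spacer_len")],
                 mirrored, ignore_attr = TRUE)
    # mirror repeats: invariant under literal reversal
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    m1 <- find_mirror_triplex(s, cfg)
    m2 <- find_mirror_triplex(rev_s, cfg)
    m2m <- data.frame(start = n - m2$end, end = n - m2$start)
    m2m <- m2m[order(m2m$start, m2m$end), ]
    expect_equal(m1[, c("start", "end")], m2m, ignore_attr = TRUE)
    # G4: strand-flipped hit set on the reverse complement
    g1 <- find_g4(s)
    g2 <- find_g4(rc)
    g2m <- data.frame(start = n - g2$end, end = n - g2$start,
                      strand = as.character(ifelse(g2$strand == "+",
                                                   "-", "+")))
    g2m <- g2m[order(g2m$start, g2m$end, g2m$strand), ]
    expect_equal(g1[, c("start", "end", "strand")], g2m,
                 ignore_attr = TRUE)
  }
})

test_that("scan_all concatenates the per-class scans deterministically", {
  set.seed(503)
  s <- paste0(random_dna(200), strrep("AT", 13), random_dna(50),
              "GGGTGGGTGGGTGGG", random_dna(200))
  all_hits <- scan_all(s)
  per_class <- table(all_hits$motif_class)
  expect_equal(unname(per_class["g4"]), nrow(find_g4(s)))
  expect_equal(unname(per_class["inverted_repeat"]),
               nrow(find_inverted_repeats(s)))
  expect_false(is.unsorted(all_hits$start))
  expect_identical(scan_all(s), scan_all(s))
  expect_equal(nrow(scan_all("")), 0L)
})

test_that("interval summaries count by leftmost base and clip base unions", {
  grid <- tile_windows(genomic_interval("c", 0, 2000), 1000)
  hits <- data.frame(
    chrom = "c",
    start = c(100, 150, 900),
    end = c(200, 250, 1100),
    motif_class = "inverted_repeat",
    arm_len = 0L, spacer_len = 0L, unit = NA, copies = NA,
    strand = "+", footprint = c(100, 100, 200))
  s <- summarize_by_interval(hits, grid)
  # two overlapping motifs 100-200/150-250 -> union 150 bases; boundary
  # motif 900-1100 counted once (left window) but bases split
  expect_equal(s$count_inverted_repeat, c(3L, 0L))
  expect_equal(s$bases_inverted_repeat, c(150 + 100, 100))
  expect_equal(s$composite_bases, c(250, 100))
  expect_equal(s$longest_inverted_repeat, c(200, 0))
})

test_that("interval summaries attach pause labels by overlap", {
  grid <- tile_windows(genomic_interval("c", 0, 30000), 10000)
  pause <- genomic_interval("c", 10000, 20000, "P1")
  s <- summarize_by_interval(.empty <- scan_all(""), grid, pause)
  expect_equal(s$pause, c(FALSE, TRUE, FALSE))
})

test_that("enrichment flags exceed mean + k * population SD strictly", {
  grid <- tile_windows(genomic_interval("c", 0, 31 * 100), 100)
  s <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                  count_inverted_repeat = c(rep(0L, 30), 10L))
  f <- flag_enriched(s, "count_inverted_repeat", k = 3)
  expect_equal(sum(f$flagged), 1L)
  expect_true(f$flagged[31])
  expect_equal(f$threshold[1], mean(s$count_inverted_repeat) +
                 3 * sqrt(mean((s$count_inverted_repeat -
                                  mean(s$count_inverted_repeat))^2)))
  # all-equal counts: SD = 0 and the strict inequality never fires
  s$count_inverted_repeat <- 2L
  expect_equal(sum(flag_enriched(s, "count_inverted_repeat")$flagged), 0L)
  expect_error(flag_enriched(s[1, ], "count_inverted_repeat"), ">= 2")
})

test_that("removing a planted motif lowers its class count by one", {
  set.seed(504)
  bg <- random_dna(4000, gc = 0.5)
  arm <- "GCTTAGCCATAGAC"
  plant <- paste0(arm, "TTTT", reverse_complement(arm))
  with_plant <- paste0(substr(bg, 1, 1000), plant,
                       substr(bg, 1001 + nchar(plant), 4000))
  cfg <- motif_config("at_cruciform_census")
  grid <- tile_windows(genomic_interval("seq", 0, nchar(bg)), 2000)
  n_with <- sum(summarize_by_interval(
    find_inverted_repeats(with_plant, cfg), grid)$count_inverted_repeat)
  n_without <- sum(summarize_by_interval(
    find_inverted_repeats(bg, cfg), grid)$count_inverted_repeat)
  expect_equal(n_with, n_without + 1L)
})
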