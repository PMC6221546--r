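genome10k <- GenomeInfoDb::Seqinfo("chr1", 10000)

test_that("extension spans 150 bp downstream of the 5' end and clips", {
  # + read at 1-based 101..150 (0-based [100,150)) -> 101..250
  plus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 150),
                                 strand = "+")
  ext <- extend_alignments(plus, genome10k)
  expect_equal(GenomicRanges::start(ext), 101)
  expect_equal(GenomicRanges::end(ext), 250)
  expect_equal(GenomicRanges::width(ext), 150)

  # + read at the chromosome edge: clipped to 50 bp
  edge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9951, 10000),
                                 strand = "+")
  ext <- extend_alignments(edge, genome10k)
  expect_equal(GenomicRanges::start(ext), 9951)
  expect_equal(GenomicRanges::end(ext), 10000)
  expect_equal(GenomicRanges::width(ext), 50)

  # - read at 1-based 251..300 (0-based [250,300)) -> 151..300
  minus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(251, 300),
                                  strand = "-")
  ext <- extend_alignments(minus, genome10k)
  expect_equal(GenomicRanges::start(ext), 151)
  expect_equal(GenomicRanges::end(ext), 300)

  # - read near the start clips at position 1
  m2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(31, 80),
                               strand = "-")
  expect_equal(GenomicRanges::start(extend_alignments(m2, genome10k)), 1)

  un <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50),
                               strand = "*")
  expect_error(extend_alignments(un, genome10k), "stranded")
  off <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 50),
                                strand = "+")
  expect_error(extend_alignments(off, genome10k), "chrX")
})

test_that("coverage counts every base exactly once per fragment", {
  one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 250))
  tr <- coverage_profile(one, genome10k, bin = NULL)
  v <- as.numeric(tr$raw[["chr1"]])
  expect_equal(sum(v), 150)
  expect_equal(unique(v[101:250]), 1)
  expect_equal(sum(v[-(101:250)]), 0)

  two <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 201), c(250, 350)))
  v2 <- as.numeric(coverage_profile(two, genome10k,
                                    bin = NULL)$raw[["chr1"]])
  expect_equal(unique(v2[201:250]), 2)   # 50 shared bp
  expect_equal(sum(v2), sum(GenomicRanges::width(two)))

  expect_error(coverage_profile(GenomicRanges::GRanges(), genome10k),
               "no reads")
})

test_that("1,000 random fragments match the per-position oracle exactly", {
  set.seed(500)
  st <- sample.int(9800, 1000, replace = TRUE)
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(st, width = sample(50:150, 1000, replace = TRUE)))
  gr <- GenomicRanges::trim(`seqinfo<-`(gr, value = genome10k))
  tr <- coverage_profile(gr, genome10k, bin = NULL)
  oracle <- coverage_oracle(GenomicRanges::start(gr),
                            GenomicRanges::end(gr), 10000)
  expect_identical(as.integer(tr$raw[["chr1"]]), oracle)
  # integer mass-conservation identity
  expect_identical(sum(as.numeric(tr$raw[["chr1"]])),
                   sum(as.numeric(GenomicRanges::width(gr))))
})

test_that("normalization and binning scale without moving mass", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 11), c(20, 20)))
  tr <- coverage_profile(gr, genome10k, total_reads = 2e6, bin = 10)
  expect_equal(tr$scale, 0.5)
  expect_equal(as.numeric(track_values(tr)[["chr1"]][1:10]), rep(0.5, 10))
  b <- track_values(tr, normalized = FALSE, binned = TRUE)[["chr1"]]
  expect_equal(as.numeric(b[1]), 1)    # mean of 10 x depth 1
  expect_equal(as.numeric(b[11]), 2)   # second bin fully depth 2
})

test_that("a uniform library yields no enriched windows", {
  set.seed(8)
  g <- GenomeInfoDb::Seqinfo("chrSim", 200000)
  cfg <- sim_config(seed = 8, enrich_fold = 1, n_domains = 2,
                    chip_depth = 0.4, chrom_lengths = c(chrSim = 200000))
  ch <- simulate_chip_libraries(cfg, g)
  pk <- call_enriched_regions(ch$chip$control, ch$input, g)
  expect_equal(length(pk), 0)
})

test_that("planted domains are called with input-corrected significance", {
  g <- GenomeInfoDb::Seqinfo("chrSim", 300000)
  cfg <- sim_config(seed = 15, enrich_fold = 10, n_domains = 5,
                    chip_depth = 0.5, chrom_lengths = c(chrSim = 300000))
  ch <- simulate_chip_libraries(cfg, g)
  pk <- call_enriched_regions(ch$chip$control, ch$input, g)
  dom <- ch$truth$domains
  hit <- GenomicRanges::countOverlaps(dom, pk) > 0
  expect_true(all(hit))
  expect_true(all(pk$p_value < 1e-5))
  # summits sit inside their regions
  expect_true(all(pk$summit >= GenomicRanges::start(pk) &
                    pk$summit <= GenomicRanges::end(pk)))
  # no call far from any planted domain
  far <- GenomicRanges::countOverlaps(pk, dom + 1000) == 0
  expect_lte(sum(far), 1)
})

test_that("condition comparison is depth-aware and antisymmetric", {
  g <- GenomeInfoDb::Seqinfo("chrSim", 300000)
  cfg <- sim_config(seed = 23, enrich_fold = 10, n_domains = 6,
                    frac_reduced = 0.5, reduce_fold = 4,
                    chip_depth = 0.5, chrom_lengths = c(chrSim = 300000))
  ch <- simulate_chip_libraries(cfg, g)
  pk1 <- call_enriched_regions(ch$chip$control, ch$input, g)
  pk2 <- call_enriched_regions(ch$chip$kd, ch$input, g)

  # identical read sets: rescaled M identically 0, nothing changed
  same <- compare_conditions(pk1, pk1, ch$chip$control, ch$chip$control)
  expect_equal(same$M_rescaled, rep(0, length(same)))
  expect_false(any(same$changed))

  # pure depth doubling: intercept ~ 1, rescaled M ~ 0
  dup <- c(ch$chip$control, ch$chip$control)
  dd <- compare_conditions(pk1, pk1, ch$chip$control, dup)
  expect_equal(unname(attr(dd, "fit")["intercept"]), 1, tolerance = 0.05)
  expect_lt(max(abs(dd$M_rescaled)), 0.1)
  expect_false(any(dd$changed))

  # reduced domains flag "down"; swapping conditions flips direction
  cmp <- compare_conditions(pk1, pk2, ch$chip$control, ch$chip$kd)
  red <- ch$truth$domains[ch$truth$domains$reduced]
  down <- cmp[cmp$direction == "down"]
  expect_true(all(GenomicRanges::countOverlaps(red, down) > 0))
  rev <- compare_conditions(pk2, pk1, ch$chip$kd, ch$chip$control)
  expect_equal(rev$M_rescaled, -cmp$M_rescaled, tolerance = 1e-9)
  expect_equal(sum(rev$direction == "up"), sum(cmp$direction == "down"))
})

test_that("gene-level deltas flag planted reductions and only those", {
  cfg <- sim_config(seed = 33)
  sim <- simulate_annotation_and_candidates(cfg)
  ch <- simulate_chip_libraries(cfg, sim$genome,
                                annotation = sim$reference)
  trk <- lapply(ch$chip, function(r)
    coverage_profile(extend_alignments(r, sim$genome), sim$genome))

  # identical tracks: all ratios zero, nothing reduced
  d0 <- gene_h3k27me3_delta(trk$control, trk$control, sim$reference)
  expect_equal(d0$log2_ratio, rep(0, nrow(d0)))
  expect_false(any(d0$reduced))

  d <- gene_h3k27me3_delta(trk$control, trk$kd, sim$reference)
  red_truth <- ch$truth$domains$gene_id[ch$truth$domains$reduced]
  expect_setequal(d$gene_id[d$reduced], red_truth)
})

test_that("hand-built quarter-coverage gives a -2 log ratio", {
  mk_track <- function(vals) {
    structure(list(
      raw = methods::as(list(chr1 = S4Vectors::Rle(vals)),
                        "SimpleRleList"),
      total_reads = 1e6, scale = 1, bin = NULL, binned = NULL),
      class = "CoverageTrack")
  }
  ctrl <- mk_track(rep(400, 5000))
  kd <- mk_track(rep(100, 5000))
  ann <- make_annotation(
    list(list(id = "t1", gene = "g1", chrom = "chr1", strand = "+",
              exons = cbind(3001, 4000))),
    c(g1 = "protein_coding"))
  d <- gene_h3k27me3_delta(ctrl, kd, ann, flank = 500, pseudocount = 0.1)
  expect_equal(d$log2_ratio, -2, tolerance = 1e-3)
  expect_true(d$reduced)
})
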