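test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9, n_cand_per_class = 5)
  a1 <- simulate_annotation_and_candidates(cfg)
  a2 <- simulate_annotation_and_candidates(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_gtf(a1$reference, f1); write_gtf(a2$reference, f2)
  expect_identical(readLines(f1), readLines(f2))

  c1 <- simulate_counts(cfg, names(a1$reference$exons))
  c2 <- simulate_counts(cfg, names(a2$reference$exons))
  expect_identical(c1$counts, c2$counts)

  m1 <- simulate_microarray(cfg, paste0("g", 1:200))
  m2 <- simulate_microarray(cfg, paste0("g", 1:200))
  expect_identical(m1$matrices, m2$matrices)

  g <- a1$genome
  ch1 <- simulate_chip_libraries(cfg, g)
  ch2 <- simulate_chip_libraries(cfg, g)
  expect_identical(GenomicRanges::start(ch1$chip$control),
                   GenomicRanges::start(ch2$chip$control))
})

test_that("candidate truth table has the constructed class counts", {
  cfg <- sim_config(seed = 2, n_cand_per_class = 20)
  sim <- simulate_annotation_and_candidates(cfg)
  expect_equal(nrow(sim$truth), 80)
  expect_equal(sum(sim$truth$expected_verdict == "novel"), 20)
  expect_equal(as.integer(table(sim$truth$class)), rep(20L, 4))
})

test_that("unplanted counts have equal stage means within sampling error", {
  cfg <- sim_config(seed = 21, n_specific = 0, nb_dispersion = 0.05,
                    reps_per_stage = 6, lib_size_cv = 0)
  cs <- simulate_counts(cfg, paste0("f", 1:300))
  prof <- stage_mean_profile(cs$counts, cs$design)
  # per-gene spread of stage means stays within 3 SE of the grand mean
  mu <- rowMeans(prof)
  se <- sqrt((mu + cfg$nb_dispersion * mu^2) / cfg$reps_per_stage)
  frac_out <- mean(abs(prof - mu) > 3 * se)
  expect_lt(frac_out, 0.02)
})

test_that("a planted 8-fold stage effect lands in the NB sampling band", {
  cfg <- sim_config(seed = 4, n_specific = 30, stage_fold = 8,
                    nb_dispersion = 0.1, lib_size_cv = 0)
  cs <- simulate_counts(cfg, paste0("f", 1:500))
  prof <- stage_mean_profile(cs$counts, cs$design)
  pl <- cs$truth$planted[cs$truth$planted$stage == "MN", ]
  ratios <- vapply(pl$feature_id, function(f)
    prof[f, "MN"] / mean(prof[f, setdiff(colnames(prof), "MN")]), 0)
  expect_gt(mean(ratios >= 4 & ratios <= 16), 0.9)
})

test_that("ChIP libraries carry the planted enrichment structure", {
  g <- GenomeInfoDb::Seqinfo("chrSim", 1e6)
  # null: fold 1 means domain density matches background
  cfg0 <- sim_config(seed = 6, enrich_fold = 1, chip_depth = 0.3,
                     n_domains = 5)
  ch0 <- simulate_chip_libraries(cfg0, g)
  dom <- ch0$truth$domains
  frag <- extend_alignments(ch0$chip$control, g)
  in_dom <- sum(GenomicRanges::countOverlaps(
    GenomicRanges::resize(frag, 1, fix = "start"), dom))
  w_tot <- sum(GenomicRanges::width(dom))
  expected <- cfg0$chip_depth * w_tot
  expect_lt(abs(in_dom - expected), 3 * sqrt(expected) + 3)

  # fold 10 at 0.5/bp: in-domain 5' density ~ 5 reads/bp
  cfg1 <- sim_config(seed = 6, enrich_fold = 10, chip_depth = 0.5,
                     n_domains = 5)
  ch1 <- simulate_chip_libraries(cfg1, g)
  dom1 <- ch1$truth$domains
  starts1 <- GenomicRanges::resize(ch1$chip$control, 1, fix = "start")
  dens <- GenomicRanges::countOverlaps(dom1, starts1) /
    GenomicRanges::width(dom1)
  expect_true(all(abs(dens - 5) <
                    3 * sqrt(5 / GenomicRanges::width(dom1)) + 0.2))

  # bookkeeping: emitted totals equal the recorded draws
  expect_identical(unname(ch1$truth$n_reads["control"]),
                   length(ch1$chip$control))
  expect_identical(unname(ch1$truth$n_reads["input"]),
                   length(ch1$input))
})

test_that("every emitted file validates under the package readers", {
  cfg <- sim_config(seed = 13, n_cand_per_class = 5, n_domains = 3,
                    chip_depth = 0.05)
  sim <- simulate_annotation_and_candidates(cfg)
  d <- tempfile(); dir.create(d)
  write_gtf(sim$reference, file.path(d, "ref.gtf"))
  write_gtf(sim$candidates, file.path(d, "cand.gtf"))
  expect_s3_class(read_gtf(file.path(d, "ref.gtf")), "AnnotationSet")
  expect_s3_class(read_gtf(file.path(d, "cand.gtf")), "AnnotationSet")

  ch <- simulate_chip_libraries(cfg, sim$genome)
  write_alignments_bed(ch$chip$control, file.path(d, "chip.bed"))
  expect_length(read_alignments_bed(file.path(d, "chip.bed")),
                length(ch$chip$control))

  cs <- simulate_counts(cfg, names(sim$reference$exons))
  write_counts_tsv(cs$counts, file.path(d, "counts.tsv"))
  expect_equal(read_counts_tsv(file.path(d, "counts.tsv")), cs$counts)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(read_length = 200), "read_length")
  expect_error(
    simulate_annotation_and_candidates(
      sim_config(chrom_lengths = c(chrTiny = 20000), n_ref_pc = 60)),
    "chromosome too short")
  expect_error(
    simulate_microarray(sim_config(ma_n_planted = 10), paste0("g", 1:5)),
    "planted")
})
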