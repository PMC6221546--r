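#!/usr/bin/env Rscript
# Simulate H3K27me3 ChIP/input libraries with planted domains (reduced
# in the knockdown), build fragment-extension coverage tracks, call
# enriched regions against the input, compare conditions over merged
# peaks, and summarize the per-gene H3K27me3 change.

source(file.path("analysis", "00_config.R"))

reference <- read_gtf(path("reference.gtf"))
genome <- read_chrom_sizes(path("genome.chrom.sizes"))

chip <- simulate_chip_libraries(cfg, genome, annotation = reference)
write_alignments_bed(chip$chip$control, path("chip_control.bed"))
write_alignments_bed(chip$chip$kd, path("chip_kd.bed"))
write_alignments_bed(chip$input, path("chip_input.bed"))
dom <- as.data.frame(chip$truth$domains)
tsv(dom, "truth_domains.tsv")
message(sprintf("libraries: control %d, kd %d, input %d reads; %d domains (%d reduced)",
                chip$truth$n_reads["control"], chip$truth$n_reads["kd"],
                chip$truth$n_reads["input"], nrow(dom), sum(dom$reduced)))

tracks <- lapply(chip$chip, function(r)
  coverage_profile(extend_alignments(r, genome), genome))
write_bedgraph(tracks$control, path("h3k27me3_control.bedgraph"))
write_bedgraph(tracks$kd, path("h3k27me3_kd.bedgraph"))

peaks <- lapply(chip$chip, call_enriched_regions,
                input_reads = chip$input, genome = genome)
tsv(as.data.frame(peaks$control), "peaks_control.tsv")
tsv(as.data.frame(peaks$kd), "peaks_kd.tsv")
recovered <- sum(GenomicRanges::countOverlaps(chip$truth$domains,
                                              peaks$control) > 0)
message(sprintf("control peaks: %d regions; %d / %d planted domains recovered",
                length(peaks$control), recovered, nrow(dom)))

cmp <- compare_conditions(peaks$control, peaks$kd,
                          chip$chip$control, chip$chip$kd)
tsv(as.data.frame(cmp), "region_comparison.tsv")
message(sprintf("merged regions: %d; flagged down in KD: %d",
                length(cmp), sum(cmp$direction == "down")))

deltas <- gene_h3k27me3_delta(tracks$control, tracks$kd, reference)
tsv(deltas, "gene_k27_delta.tsv")
red <- deltas$gene_id[deltas$reduced]
writeLines(red, path("k27_reduced_genes.txt"))
truth_red <- dom$gene_id[dom$reduced]
message(sprintf("H3K27me3-reduced genes: %d (exact truth match: %s)",
                length(red), setequal(red, truth_red)))
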