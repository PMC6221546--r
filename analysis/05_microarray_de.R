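#!/usr/bin/env Rscript
# Simulate the two perturbation-vs-control microarray experiments with
# up-regulation planted around the ChIP reduction truth, then call
# differential genes with the moderated t-test (fold >= 2, p < 0.001).

source(file.path("analysis", "00_config.R"))

reference <- read_gtf(path("reference.gtf"))
genome <- read_chrom_sizes(path("genome.chrom.sizes"))
# deterministic generators: the same config reproduces the ChIP truth
chip <- simulate_chip_libraries(cfg, genome, annotation = reference)

plan <- plant_perturbations(chip$truth$domains, reference, cfg$seed)
writeLines(sort(plan$up1), path("truth_up_meg3kd.txt"))
writeLines(sort(plan$up2), path("truth_up_igdmr.txt"))
writeLines(plan$concordant, path("truth_concordant.txt"))

genes <- names(reference$gene_biotype)
arr <- simulate_microarray(cfg, genes, up1 = plan$up1, up2 = plan$up2)
for (cond in names(arr$matrices))
  write_counts_tsv(arr$matrices[[cond]],
                   path(sprintf("microarray_%s.tsv", cond)),
                   id_col = "gene_id")

for (cond in names(arr$matrices)) {
  d <- arr$designs[[cond]]
  res <- moderated_t_test(arr$matrices[[cond]],
                          groupA = d$sample_id[d$condition == cond],
                          groupB = d$sample_id[d$condition == "control"])
  tsv(res, sprintf("modt_%s.tsv", cond))
  up <- sort(res$gene_id[res$significant & res$delta > 0])
  writeLines(up, path(sprintf("up_%s.txt", cond)))
  pr <- attr(res, "prior")
  truth_up <- sort(if (cond == "meg3kd") plan$up1 else plan$up2)
  message(sprintf(
    "%s: %d up-regulated (truth %d, recall %.2f); prior d0=%.1f s0^2=%.3f",
    cond, length(up), length(truth_up), mean(truth_up %in% up),
    pr$d0, pr$s02))
}
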