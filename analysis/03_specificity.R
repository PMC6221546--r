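#!/usr/bin/env Rscript
# TMM-normalize the stage counts, drop minimally expressed transcripts,
# score Jensen-Shannon stage specificity, pick stage signatures, compare
# specificity across gene classes, and call postmitotic-MN-enriched
# lncRNAs from the two MA comparisons.

source(file.path("analysis", "00_config.R"))

counts <- read_counts_tsv(path("counts.tsv"))
design <- read.delim(path("design.tsv"))
merged <- read_gtf(path("merged_annotation.gtf"))
planted <- read.delim(path("truth_planted_stage_specific.tsv"))

# restrict to the pooled annotation (reference + accepted novel lncRNAs)
counts <- counts[rownames(counts) %in% names(merged$exons), ]
classes <- tx_classes(merged)

tmm <- compute_tmm_factors(counts)
tsv(tmm$samples, "tmm_factors.tsv")
message(sprintf("TMM factors (ref %s): %s", tmm$ref_sample,
                paste(sprintf("%.3f", tmm$samples$factor), collapse = " ")))

norm <- normalize_counts(counts, tmm)
write_counts_tsv(norm, path("normalized_counts.tsv"))
kept <- filter_min_expression(norm, threshold = 10)
message(sprintf("%d / %d features pass the normalized-count >= 10 filter",
                length(kept), nrow(norm)))

spec <- score_all(norm[kept, ], design, classes[kept])
tsv(spec, "specificity_scores.tsv")
sigs <- select_stage_signatures(spec, top_n_per_stage = 8)
tsv(sigs, "stage_signatures.tsv")
message(sprintf("%d stage-signature features selected", nrow(sigs)))

ks <- compare_class_specificity(spec)
tsv(ks$tests, "ks_class_tests.tsv")
tsv(ks$ecdf, "specificity_ecdf.tsv")
print(ks$tests)

# MA enrichment: MN vs pMN (developmental) and MN vs IN (cell type)
grp <- function(s) design$sample_id[design$stage == s]
ma_dev <- ma_compare(norm, grp("MN"), grp("pMN"))
ma_typ <- ma_compare(norm, grp("MN"), grp("IN"))
tsv(ma_dev, "ma_mn_vs_pmn.tsv")
tsv(ma_typ, "ma_mn_vs_in.tsv")
lnc_tx <- names(classes)[classes %in% c("annotated_lncRNA", "novel_lncRNA")]
mn_cand <- intersect_enriched(ma_dev, ma_typ, lnc_tx)
writeLines(mn_cand, path("mn_enriched_lncRNAs.txt"))

mn_truth <- sort(planted$feature_id[planted$stage == "MN" &
                                      planted$feature_id %in% lnc_tx])
message(sprintf("MN-enriched lncRNA candidates: %d (truth %d, recall %.2f)",
                length(mn_cand), length(mn_truth),
                ifelse(length(mn_truth) > 0,
                       mean(mn_truth %in% mn_cand), NA)))
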