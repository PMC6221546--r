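#!/usr/bin/env Rscript
# Generate the synthetic study: a reference annotation with assembled
# candidate transcripts, a five-stage replicated RNA-seq count matrix
# with planted stage-specific lncRNAs, and the recorded ground truth.

source(file.path("analysis", "00_config.R"))

sim <- simulate_annotation_and_candidates(cfg)
write_gtf(sim$reference, path("reference.gtf"))
write_gtf(sim$candidates, path("candidates.gtf"))
write_chrom_sizes(sim$genome, path("genome.chrom.sizes"))
tsv(sim$truth, "truth_candidates.tsv")

classes <- tx_classes(sim$reference)
message(sprintf("reference: %d genes (%d protein-coding, %d lncRNA); %d candidates",
                length(sim$reference$gene_biotype),
                sum(sim$reference$gene_biotype == "protein_coding"),
                sum(sim$reference$gene_biotype == "lncRNA"),
                length(sim$candidates$exons)))

# counts are simulated over reference + all candidates so that the novel
# transcripts kept by the discovery step have expression downstream
feature_ids <- c(names(sim$reference$exons), names(sim$candidates$exons))
lnc_tx <- c(names(classes)[classes == "annotated_lncRNA"],
            sim$truth$transcript_id[sim$truth$expected_verdict == "novel"])
cs <- simulate_counts(cfg, feature_ids, lnc_ids = lnc_tx)
write_counts_tsv(cs$counts, path("counts.tsv"))
tsv(cs$design, "design.tsv")
tsv(cs$truth$planted, "truth_planted_stage_specific.tsv")

message(sprintf("counts: %d features x %d samples; %d planted stage-specific lncRNAs",
                nrow(cs$counts), ncol(cs$counts), nrow(cs$truth$planted)))
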