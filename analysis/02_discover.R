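#!/usr/bin/env Rscript
# Classify the assembled candidates with the three novelty rules
# (>200 bp spliced, multi-exon, no overlap with known genes), pool the
# novel lncRNAs with the reference annotation, and check the calls
# against the generator's truth.

source(file.path("analysis", "00_config.R"))

reference <- read_gtf(path("reference.gtf"))
candidates <- read_gtf(path("candidates.gtf"))
truth <- read.delim(path("truth_candidates.tsv"))

calls <- classify_novel_lncRNAs(candidates, reference)
tsv(calls, "novelty_calls.tsv")

merged <- merge_with_annotation(calls, candidates, reference)
write_gtf(merged, path("merged_annotation.gtf"))

agree <- mean(calls$verdict == truth$expected_verdict)
message(sprintf("novelty calls: %d novel / %d candidates; %.1f%% agree with truth",
                sum(calls$verdict == "novel"), nrow(calls), 100 * agree))
print(attr(merged, "class_counts"))
stopifnot(agree == 1)
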