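# Shared settings for the analysis drivers.  Source()d by every numbered
# script; all randomness descends from this one master seed.

library(lncstage)

master_seed <- 42
cfg <- sim_config(seed = master_seed)

res_dir <- file.path("results", "synthetic_run")
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
path <- function(...) file.path(res_dir, ...)

tsv <- function(df, file) {
  write.table(df, path(file), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
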