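#' Plan microarray up-regulation truth around the ChIP reduction truth
#'
#' Chooses the planted up-regulated gene sets of the two perturbations so
#' that every Venn region of the integration has known members: a
#' concordant core of genes carrying reduced H3K27me3 domains planted in
#' BOTH perturbations, reduced genes planted in one arm only, and
#' "far" filler genes whose scoring window cannot touch a reduced domain
#' (so they can never enter the triple intersection via the ChIP arm).
#'
#' @param domains the \code{truth$domains} GRanges from
#'   \code{\link{simulate_chip_libraries}} run with an annotation
#' @param annotation the same \code{AnnotationSet}
#' @param seed master seed (a dedicated stream is derived from it)
#' @param n_concordant reduced-domain genes planted in both arms
#' @param n_shared_far far genes planted in both arms
#' @param n_only far genes planted in one arm each
#' @return list: \code{up1}, \code{up2} (planted sets for the two
#'   perturbations), \code{concordant} (the expected triple
#'   intersection)
#' @export
plant_perturbations <- function(domains, annotation, seed,
                                n_concordant = 6, n_shared_far = 8,
                                n_only = 6) {
  set.seed(.op_seed(seed, "planting"))
  red_genes <- domains$gene_id[domains$reduced]
  spans <- gene_spans(annotation)
  win <- GenomicRanges::resize(spans, GenomicRanges::width(spans) + 2000,
                               fix = "end")
  red_dom <- domains[domains$reduced]
  far <- names(spans)[GenomicRanges::countOverlaps(
    win + 500, red_dom, ignore.strand = TRUE) == 0]
  far <- setdiff(far, domains$gene_id)

  concordant <- sort(sample(red_genes, min(n_concordant,
                                           length(red_genes))))
  red_rest <- setdiff(red_genes, concordant)
  one_arm_red <- if (length(red_rest) >= 2) red_rest[1:2] else character()
  shared_far <- sample(far, n_shared_far)
  far2 <- setdiff(far, shared_far)
  only1 <- sample(far2, n_only)
  only2 <- sample(setdiff(far2, only1), n_only)
  up1 <- c(concordant, shared_far, only1, one_arm_red[1])
  up2 <- c(concordant, shared_far, only2, one_arm_red[-1])
  list(up1 = up1[!is.na(up1)], up2 = up2[!is.na(up2)],
       concordant = concordant)
}

#' Run the full pipeline end-to-end on one synthetic dataset
#'
#' Executes simulate -> discover -> normalize -> specificity -> MA
#' enrichment -> ChIP-seq -> microarray differential -> integration on a
#' single seeded synthetic dataset and compares every stage's result with
#' the generator's recorded truth.  The microarray planting is arranged
#' around the ChIP truth so the final integrated list has a well-defined
#' expected value: a set of genes carrying reduced H3K27me3 domains is
#' planted up-regulated in both perturbations (the concordant truth),
#' other planted genes populate the remaining Venn regions.
#'
#' @param config a \code{\link{sim_config}}
#' @param out_dir optional directory; when given, all intermediate tables
#'   (GTF, TSV, bedGraph) are written there
#' @param top_n_per_stage signatures per stage for the demo (default 8;
#'   the synthetic gene count is far below genome scale)
#' @return list with all stage results, the truths, and \code{summary}
#'   (stage-by-stage counts and truth-recovery metrics)
#' @export
run_demo <- function(config = sim_config(), out_dir = NULL,
                     top_n_per_stage = 8) {
  # -- discovery ----------------------------------------------------------
  sim <- simulate_annotation_and_candidates(config)
  calls <- classify_novel_lncRNAs(sim$candidates, sim$reference)
  merged <- merge_with_annotation(calls, sim$candidates, sim$reference)
  discovery_ok <- identical(calls$verdict, sim$truth$expected_verdict)

  # -- expression + specificity ------------------------------------------
  classes <- tx_classes(merged)
  lnc_tx <- names(classes)[classes %in% c("annotated_lncRNA",
                                          "novel_lncRNA")]
  csim <- simulate_counts(config, names(merged$exons), lnc_ids = lnc_tx)
  tmm <- compute_tmm_factors(csim$counts)
  norm <- normalize_counts(csim$counts, tmm)
  kept <- filter_min_expression(norm)
  spec <- score_all(norm[kept, , drop = FALSE], csim$design,
                    classes[kept])
  sigs <- withCallingHandlers(
    select_stage_signatures(spec, top_n_per_stage = top_n_per_stage),
    warning = function(w) invokeRestart("muffleWarning"))
  ks <- compare_class_specificity(spec)

  # -- MA enrichment of postmitotic-MN lncRNAs ---------------------------
  mn <- csim$design$sample_id[csim$design$stage == "MN"]
  pmn <- csim$design$sample_id[csim$design$stage == "pMN"]
  inn <- csim$design$sample_id[csim$design$stage == "IN"]
  ma_dev <- ma_compare(norm, mn, pmn)
  ma_type <- ma_compare(norm, mn, inn)
  mn_candidates <- intersect_enriched(ma_dev, ma_type, lnc_tx)
  mn_truth <- sort(csim$truth$planted$feature_id[
    csim$truth$planted$stage == "MN" &
      csim$truth$planted$feature_id %in% lnc_tx])

  # -- ChIP-seq ----------------------------------------------------------
  chip <- simulate_chip_libraries(config, sim$genome,
                                  annotation = sim$reference)
  frag <- lapply(c(chip$chip, list(input = chip$input)),
                 extend_alignments, genome = sim$genome)
  tracks <- lapply(frag, coverage_profile, genome = sim$genome)
  peaks <- lapply(chip$chip, call_enriched_regions,
                  input_reads = chip$input, genome = sim$genome)
  region_cmp <- compare_conditions(peaks$control, peaks$kd,
                                   chip$chip$control, chip$chip$kd)
  deltas <- gene_h3k27me3_delta(tracks$control, tracks$kd, sim$reference)
  k27_reduced <- deltas$gene_id[deltas$reduced]

  # -- microarray perturbations, planted around the ChIP truth -----------
  plan <- plant_perturbations(chip$truth$domains, sim$reference,
                              config$seed)
  genes <- names(sim$reference$gene_biotype)
  red_genes <- chip$truth$domains$gene_id[chip$truth$domains$reduced]
  up1_truth <- plan$up1
  up2_truth <- plan$up2

  arr <- simulate_microarray(config, genes, up1 = up1_truth,
                             up2 = up2_truth)
  de <- lapply(c("meg3kd", "igdmr"), function(cond) {
    d <- arr$designs[[cond]]
    moderated_t_test(arr$matrices[[cond]],
                     groupA = d$sample_id[d$condition == cond],
                     groupB = d$sample_id[d$condition == "control"])
  })
  names(de) <- c("meg3kd", "igdmr")
  up_sets <- lapply(de, function(r)
    sort(r$gene_id[r$significant & r$delta > 0]))

  # -- integration -------------------------------------------------------
  integ <- integrate_gene_sets(up_sets$meg3kd, up_sets$igdmr, k27_reduced)
  # with no planted shift there is no true up-regulation to recover
  concordant_truth <- if (config$ma_fold > 1)
    sort(intersect(intersect(up1_truth, up2_truth), red_genes))
  else character()

  summary <- list(
    n_candidates = nrow(calls),
    n_novel = sum(calls$verdict == "novel"),
    discovery_matches_truth = discovery_ok,
    class_counts = attr(merged, "class_counts"),
    n_features = nrow(csim$counts),
    n_expressed = length(kept),
    n_signatures = nrow(sigs),
    ks = ks$tests,
    n_mn_candidates = length(mn_candidates),
    mn_candidate_recall = if (length(mn_truth) > 0)
      mean(mn_truth %in% mn_candidates) else NA_real_,
    n_peaks = vapply(peaks, length, 0L),
    n_regions_down = sum(region_cmp$direction == "down"),
    n_k27_reduced = length(k27_reduced),
    integrated = integ$final,
    integrated_truth = concordant_truth,
    integration_exact = identical(integ$final, concordant_truth),
    venn = integ$venn)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_gtf(sim$reference, p("reference.gtf"))
    write_gtf(sim$candidates, p("candidates.gtf"))
    write_gtf(merged, p("merged_annotation.gtf"))
    write_chrom_sizes(sim$genome, p("genome.chrom.sizes"))
    utils::write.table(calls, p("novelty_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_counts_tsv(csim$counts, p("counts.tsv"))
    write_counts_tsv(norm, p("normalized_counts.tsv"))
    utils::write.table(csim$design, p("design.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(tmm$samples, p("tmm_factors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(spec, p("specificity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sigs, p("stage_signatures.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ks$tests, p("ks_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_bedgraph(tracks$control, p("h3k27me3_control.bedgraph"))
    write_bedgraph(tracks$kd, p("h3k27me3_kd.bedgraph"))
    utils::write.table(as.data.frame(region_cmp), p("region_compare.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(deltas, p("gene_k27_delta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (cond in names(de))
      utils::write.table(de[[cond]], p(paste0("modt_", cond, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(integ$membership, p("integration_membership.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(integ$final, p("integrated_genes.txt"))
  }

  list(annotation = sim, calls = calls, merged = merged, counts = csim,
       tmm = tmm, norm = norm, expressed = kept, specificity = spec,
       signatures = sigs, ks = ks, ma = list(dev = ma_dev, type = ma_type),
       mn_candidates = mn_candidates, mn_truth = mn_truth,
       chip = chip, tracks = tracks, peaks = peaks,
       region_compare = region_cmp, gene_deltas = deltas,
       microarray = arr, de = de, up_sets = up_sets,
       integration = integ, summary = summary)
}
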