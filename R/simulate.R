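#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with defaults that
#' emulate the study design the pipeline targets: five differentiation
#' stages with replicated bulk RNA-seq counts, an assembled candidate set
#' spanning every novelty-rule class, H3K27me3-like ChIP/input libraries
#' with planted enriched domains partially reduced in a knockdown, and
#' two perturbation-vs-control microarray experiments.
#'
#' @param seed master seed; each generator derives its own stream from it
#'   so adding one simulation never perturbs another.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param stages stage labels in differentiation order.
#' @param reps_per_stage RNA-seq replicates per stage.
#' @param n_ref_pc,n_ref_lnc reference protein-coding / annotated-lncRNA
#'   gene counts.
#' @param n_cand_per_class candidate transcripts per novelty class
#'   (novel, short, monoexonic, gene-overlapping).
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance mu + phi mu^2).
#' @param stage_fold expression fold planted in one stage for
#'   stage-specific transcripts.
#' @param n_specific number of planted stage-specific lncRNAs.
#' @param lib_size_cv library sizes drawn uniform in 1 +/- this fraction.
#' @param comp_bias_frac,comp_bias_fold fraction of genes and fold for the
#'   composition-bias perturbation (applied to samples named in
#'   \code{comp_bias_samples}).
#' @param comp_bias_samples sample ids receiving the composition bias.
#' @param chip_depth ChIP background rate, fragments per bp.
#' @param read_length sequenced read length (bp, < fragment length 150).
#' @param n_domains,domain_width planted enriched-domain count and width.
#' @param enrich_fold in-domain rate multiplier in the control ChIP.
#' @param frac_reduced fraction of domains whose enrichment is reduced in
#'   the knockdown ChIP.
#' @param reduce_fold fold by which reduced domains lose enrichment.
#' @param ma_baseline_mean,ma_baseline_sd microarray baseline log2
#'   intensity distribution across genes.
#' @param ma_noise_s0,ma_noise_d0 scaled inverse-chi-squared prior for the
#'   per-gene noise SD (exercises variance moderation).
#' @param ma_n_planted planted up-regulated genes per perturbation.
#' @param ma_overlap planted genes shared between the two perturbations.
#' @param ma_fold planted expression fold (linear scale).
#' @param ma_reps arrays per arm.
#' @return a \code{SimulationConfig} list.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chrSim = 1e6),
                       stages = c("ESC", "NE", "pMN", "MN", "IN"),
                       reps_per_stage = 3,
                       n_ref_pc = 60, n_ref_lnc = 20,
                       n_cand_per_class = 20,
                       nb_dispersion = 0.1,
                       stage_fold = 8,
                       n_specific = 50,
                       lib_size_cv = 0.3,
                       comp_bias_frac = 0, comp_bias_fold = 1,
                       comp_bias_samples = character(),
                       chip_depth = 0.5, read_length = 50,
                       n_domains = 20, domain_width = 4000,
                       enrich_fold = 10, frac_reduced = 0.5,
                       reduce_fold = 4,
                       ma_baseline_mean = 8, ma_baseline_sd = 1.5,
                       ma_noise_s0 = 0.2, ma_noise_d0 = 10,
                       ma_n_planted = 40, ma_overlap = 25,
                       ma_fold = 4, ma_reps = 3) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$chrom_lengths > 0), cfg$reps_per_stage >= 1,
            cfg$nb_dispersion > 0, cfg$stage_fold > 0,
            cfg$enrich_fold > 0, cfg$reduce_fold > 0,
            cfg$read_length < 150, cfg$domain_width >= 150,
            cfg$ma_overlap <= cfg$ma_n_planted)
  structure(cfg, class = "SimulationConfig")
}

# Derive a deterministic per-operation seed from the master seed, so each
# generator owns an independent stream.  Kept below 2^31 - 1.
.op_seed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_len(nchar(op)))
  as.integer((as.numeric(seed) * 100003 + h * 7919) %% 2147483629)
}

# ---- annotation + candidates -------------------------------------------

# One synthetic multi-exon transcript starting at `at`.
.make_tx <- function(chrom, at, n_exons, exon_w, intron_w, strand) {
  starts <- at + cumsum(c(0, rep(exon_w + intron_w, n_exons - 1)))
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(starts, width = exon_w),
                         strand = strand)
}

#' Simulate a reference annotation and assembled candidate transcripts
#'
#' Reference genes (protein-coding and annotated lncRNA) are laid
#' left-to-right with random intergenic gaps.  Candidates are planted in
#' controlled proportions for every clause of the novelty rule:
#' multi-exon >200 bp intergenic (truth \code{novel}), spliced length
#' <= 200 bp (\code{rejected:length}), single exon
#' (\code{rejected:monoexonic}), and exon inside a known gene span
#' (\code{rejected:overlap}).
#'
#' @param config a \code{\link{sim_config}}
#' @return list with \code{reference} (AnnotationSet), \code{candidates}
#'   (AnnotationSet with placeholder gene ids), \code{genome}
#'   (\code{Seqinfo}) and \code{truth} (data.frame: transcript_id, class,
#'   expected verdict/reason).
#' @export
simulate_annotation_and_candidates <- function(config) {
  set.seed(.op_seed(config$seed, "annotation"))
  chrom <- names(config$chrom_lengths)[1]
  L <- unname(config$chrom_lengths[1])

  n_genes <- config$n_ref_pc + config$n_ref_lnc
  exon_w <- sample(200:600, n_genes, replace = TRUE)
  n_ex <- sample(2:4, n_genes, replace = TRUE)
  intron_w <- sample(150:400, n_genes, replace = TRUE)
  span_w <- n_ex * exon_w + (n_ex - 1) * intron_w
  gaps <- sample(2500:5000, n_genes + 1, replace = TRUE)
  starts <- cumsum(gaps[seq_len(n_genes)] + c(0, span_w[-n_genes]))
  if (starts[n_genes] + span_w[n_genes] + gaps[n_genes + 1] > L)
    stop("chromosome too short for the requested gene count; ",
         "increase chrom_lengths")

  biotype <- sample(rep(c("protein_coding", "lncRNA"),
                        c(config$n_ref_pc, config$n_ref_lnc)))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  tx_ids <- sprintf("T%04d", seq_len(n_genes))
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  exons <- GenomicRanges::GRangesList(lapply(seq_len(n_genes), function(i)
    .make_tx(chrom, starts[i], n_ex[i], exon_w[i], intron_w[i], strands[i])))
  names(exons) <- tx_ids
  tx2gene <- stats::setNames(gene_ids, tx_ids)
  reference <- AnnotationSet(exons, tx2gene,
                             stats::setNames(biotype, gene_ids))

  # candidate placement: intergenic classes go into gaps between genes,
  # with a safety margin; the overlap class sits inside a random gene span
  gap_start <- c(1, starts + span_w + 200)
  gap_end <- c(starts - 200, L)
  ok <- which((gap_end - gap_start) > 1500)
  ncl <- config$n_cand_per_class
  classes <- rep(c("novel", "short", "monoexonic", "overlap"), each = ncl)
  cand_list <- vector("list", length(classes))
  gi <- rep_len(ok, length(classes))  # cycle usable gaps
  for (i in seq_along(classes)) {
    cl <- classes[i]
    st <- sample(c("+", "-"), 1)
    if (cl == "overlap") {
      g <- sample(n_genes, 1)
      at <- starts[g] + sample.int(max(span_w[g] - 1200, 1), 1)
      cand_list[[i]] <- .make_tx(chrom, at, 2, 500, 200, st)
    } else {
      lo <- gap_start[gi[i]]
      hi <- gap_end[gi[i]] - 1400
      at <- lo + sample.int(max(hi - lo, 1), 1)
      cand_list[[i]] <- switch(cl,
        novel = .make_tx(chrom, at, sample(2:3, 1), 300, 200, st),
        short = .make_tx(chrom, at, 2, 80, 150, st),      # 160 bp spliced
        monoexonic = .make_tx(chrom, at, 1, 600, 0, st))
    }
  }
  cand_ids <- sprintf("CAND%04d", seq_along(classes))
  cand_genes <- sprintf("CG%s", cand_ids)   # sprintf keeps zero length
  cand <- GenomicRanges::GRangesList(cand_list)
  names(cand) <- cand_ids
  candidates <- AnnotationSet(
    cand, stats::setNames(cand_genes, cand_ids),
    stats::setNames(rep("other", length(cand_ids)), cand_genes))

  truth <- data.frame(
    transcript_id = cand_ids,
    class = classes,
    expected_verdict = ifelse(classes == "novel", "novel", "rejected"),
    expected_reason = c(novel = "", short = "length",
                        monoexonic = "monoexonic",
                        overlap = "overlap")[classes],
    stringsAsFactors = FALSE)

  genome <- GenomeInfoDb::Seqinfo(seqnames = names(config$chrom_lengths),
                                  seqlengths = unname(config$chrom_lengths))
  list(reference = reference, candidates = candidates,
       genome = genome, truth = truth)
}

# ---- RNA-seq counts -----------------------------------------------------

#' Simulate a replicated stage count matrix with planted specific lncRNAs
#'
#' Counts are negative binomial with variance mu + phi mu^2.  A chosen set
#' of lncRNA features gets its mean multiplied by \code{stage_fold} in
#' exactly one stage (round-robin over stages); an optional gene subset is
#' multiplied by \code{comp_bias_fold} in designated samples to create a
#' composition bias; library sizes vary by \code{lib_size_cv}.
#'
#' @param config a \code{\link{sim_config}}
#' @param feature_ids character vector of feature (transcript) ids
#' @param lnc_ids ids eligible for stage-specific planting (defaults to
#'   all features)
#' @return list with \code{counts} (matrix), \code{design} (data.frame:
#'   sample_id, stage, condition, replicate) and \code{truth}
#'   (\code{planted}: feature/stage/fold; \code{bias_genes},
#'   \code{lib_factors}).
#' @export
simulate_counts <- function(config, feature_ids, lnc_ids = NULL) {
  if (config$nb_dispersion <= 0) stop("dispersion must be > 0")
  set.seed(.op_seed(config$seed, "counts"))
  stages <- config$stages
  reps <- config$reps_per_stage
  if (reps < 2) warning("fewer than 2 replicates per stage")
  n <- length(feature_ids)
  if (is.null(lnc_ids)) lnc_ids <- feature_ids
  n_spec <- min(config$n_specific, length(lnc_ids))

  design <- data.frame(
    sample_id = paste0(rep(stages, each = reps), "_r", seq_len(reps)),
    stage = rep(stages, each = reps),
    condition = "control",
    replicate = rep(seq_len(reps), length(stages)),
    stringsAsFactors = FALSE)

  base_mu <- stats::rlnorm(n, meanlog = log(100), sdlog = 0.6)
  names(base_mu) <- feature_ids
  planted <- if (n_spec > 0) sample(lnc_ids, n_spec) else character()
  planted_stage <- rep_len(stages, length(planted))

  mu <- matrix(base_mu, n, length(stages),
               dimnames = list(feature_ids, stages))
  for (i in seq_along(planted))
    mu[planted[i], planted_stage[i]] <-
      mu[planted[i], planted_stage[i]] * config$stage_fold

  lib <- stats::runif(nrow(design), 1 - config$lib_size_cv,
                      1 + config$lib_size_cv)
  bias_genes <- character()
  if (config$comp_bias_frac > 0 && config$comp_bias_fold != 1)
    bias_genes <- sample(feature_ids, round(n * config$comp_bias_frac))

  counts <- matrix(0, n, nrow(design),
                   dimnames = list(feature_ids, design$sample_id))
  for (k in seq_len(nrow(design))) {
    m <- mu[, design$stage[k]] * lib[k]
    if (design$sample_id[k] %in% config$comp_bias_samples)
      m[bias_genes] <- m[bias_genes] * config$comp_bias_fold
    counts[, k] <- stats::rnbinom(n, mu = m, size = 1 / config$nb_dispersion)
  }

  truth <- list(
    planted = data.frame(feature_id = planted, stage = planted_stage,
                         fold = rep(config$stage_fold, length(planted)),
                         stringsAsFactors = FALSE),
    bias_genes = bias_genes,
    lib_factors = stats::setNames(lib, design$sample_id))
  list(counts = counts, design = design, truth = truth)
}

# ---- ChIP libraries -----------------------------------------------------

# Draw n stranded reads whose 150-bp downstream extension reconstructs a
# fragment uniform in [lo, hi]; reads are read_length bp, 5' end = fragment
# start (+) or fragment end (-).
.place_reads <- function(chrom, lo, hi, n, read_length) {
  if (n == 0)
    return(GenomicRanges::GRanges())
  frag_start <- lo + sample.int(hi - lo - 150 + 2, n, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- ifelse(strand == "+", frag_start, frag_start + 150L - read_length)
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start, width = read_length),
                         strand = strand)
}

#' Simulate ChIP and input alignment libraries with planted domains
#'
#' Background fragments are uniform along the genome at \code{chip_depth}
#' per bp; inside each planted domain the control ChIP rate is multiplied
#' by \code{enrich_fold}, and in the knockdown library the flagged domains
#' lose \code{reduce_fold} of that extra enrichment.  Reads are emitted as
#' fixed-length stranded alignments whose 5' ends are fragment starts, so
#' the standard 150-bp downstream extension reconstructs fragment pileup.
#' When an annotation is supplied, each domain coincides with the
#' H3K27me3 scoring window (gene span + 2-kb upstream flank) of one
#' sampled gene, chosen so no other gene's window touches it -- making
#' the gene-level reduction truth an all-or-nothing overlap; without an
#' annotation, fixed-width (\code{domain_width}) domains are placed
#' uniformly.
#'
#' @param config a \code{\link{sim_config}}
#' @param genome a \code{Seqinfo}
#' @param annotation optional \code{AnnotationSet} to centre domains on
#' @return list with \code{chip} (list of control/kd \code{GRanges}),
#'   \code{input} (\code{GRanges}), and \code{truth} (\code{domains}
#'   GRanges with \code{reduced} flag and \code{gene_id} when centred;
#'   per-library emitted read totals).
#' @export
simulate_chip_libraries <- function(config, genome, annotation = NULL) {
  if (config$domain_width < config$read_length)
    stop("domain width must exceed read length")
  set.seed(.op_seed(config$seed, "chip"))
  chrom <- GenomeInfoDb::seqnames(genome)[1]
  L <- unname(GenomeInfoDb::seqlengths(genome)[1])
  w <- config$domain_width

  if (!is.null(annotation)) {
    # each domain covers exactly one gene's H3K27me3 scoring window (gene
    # span + 2-kb strand-aware upstream flank), sampled among genes whose
    # window clears every other gene's window by > 200 bp -- so the
    # gene-level reduction truth is an all-or-nothing overlap
    spans <- gene_spans(annotation)
    win <- GenomicRanges::resize(spans,
                                 GenomicRanges::width(spans) + 2000,
                                 fix = "end")
    clear <- GenomicRanges::countOverlaps(win + 200, win,
                                          ignore.strand = TRUE) == 1
    eligible <- which(clear & GenomicRanges::start(win) > 500 &
                        GenomicRanges::end(win) < L - 500)
    if (length(eligible) < config$n_domains)
      stop("cannot place ", config$n_domains, " isolated gene-window ",
           "domains; reduce n_domains or space genes further apart")
    pick <- sort(sample(eligible, config$n_domains))
    dom <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(GenomicRanges::start(win)[pick],
                       GenomicRanges::end(win)[pick]))
    dom$gene_id <- names(spans)[pick]
  } else {
    st <- sort(sample.int(L - w, config$n_domains))
    while (any(diff(st) < w))   # redraw until disjoint
      st <- sort(sample.int(L - w, config$n_domains))
    dom <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, width = w))
    dom$gene_id <- NA_character_
  }
  n_red <- round(config$frac_reduced * config$n_domains)
  dom$reduced <- seq_along(dom) %in% sample(length(dom), n_red)

  rl <- config$read_length
  dom_w <- GenomicRanges::width(dom)
  extra_rate <- function(fold) config$chip_depth * (fold - 1)
  emit_library <- function(domain_folds) {
    n_bg <- stats::rpois(1, config$chip_depth * L)
    reads <- list(.place_reads(chrom, 1L, L, n_bg, rl))
    for (i in seq_along(dom)) {
      nd <- stats::rpois(1, extra_rate(domain_folds[i]) * dom_w[i])
      reads[[i + 1]] <- .place_reads(chrom, GenomicRanges::start(dom)[i],
                                     GenomicRanges::end(dom)[i], nd, rl)
    }
    gr <- suppressWarnings(do.call(c, reads))
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
    gr
  }

  ctrl_folds <- rep(config$enrich_fold, length(dom))
  kd_folds <- ifelse(dom$reduced, 1 + (config$enrich_fold - 1) /
                       config$reduce_fold, config$enrich_fold)
  chip_ctrl <- emit_library(ctrl_folds)
  chip_kd <- emit_library(kd_folds)
  input <- emit_library(rep(1, length(dom)))

  truth <- list(domains = dom,
                n_reads = c(control = length(chip_ctrl),
                            kd = length(chip_kd),
                            input = length(input)))
  list(chip = list(control = chip_ctrl, kd = chip_kd),
       input = input, truth = truth)
}

# ---- microarray ---------------------------------------------------------

#' Simulate two perturbation-vs-control log2-intensity matrices
#'
#' Baseline intensities are normal across genes; per-gene noise SDs are
#' drawn from a scaled inverse-chi-squared prior so that variance
#' moderation has something to moderate; planted up-regulated genes are
#' shifted by log2(fold) in the perturbation arms, with a configurable
#' overlap between the two perturbations.
#'
#' @param config a \code{\link{sim_config}}
#' @param genes gene ids to simulate
#' @param up1,up2 optional explicit planted gene sets for the two
#'   perturbations (default: sampled with \code{ma_overlap} shared genes)
#' @return list with \code{matrices} (list of two gene x array matrices,
#'   columns \code{ctrl_*} then \code{cond_*}), \code{designs}, and
#'   \code{truth} (\code{up1}, \code{up2}, per-gene noise SD).
#' @export
simulate_microarray <- function(config, genes, up1 = NULL, up2 = NULL) {
  set.seed(.op_seed(config$seed, "microarray"))
  n <- length(genes)
  need <- config$ma_overlap + 2 * (config$ma_n_planted - config$ma_overlap)
  if (is.null(up1) && need > n)
    stop("planted gene demand (", need, ") exceeds gene count (", n, ")")
  baseline <- stats::rnorm(n, config$ma_baseline_mean, config$ma_baseline_sd)
  sd_g <- config$ma_noise_s0 *
    sqrt(config$ma_noise_d0 / stats::rchisq(n, config$ma_noise_d0))
  names(sd_g) <- genes

  if (is.null(up1) || is.null(up2)) {
    shared <- sample(genes, config$ma_overlap)
    rest <- setdiff(genes, shared)
    k <- config$ma_n_planted - config$ma_overlap
    only1 <- sample(rest, k)
    only2 <- sample(setdiff(rest, only1), k)
    up1 <- c(shared, only1)
    up2 <- c(shared, only2)
  }
  shift <- log2(config$ma_fold)

  one_experiment <- function(up, tag) {
    reps <- config$ma_reps
    m <- matrix(stats::rnorm(n * 2 * reps, mean = baseline, sd = sd_g),
                n, 2 * reps,
                dimnames = list(genes, c(paste0("ctrl_", seq_len(reps)),
                                         paste0(tag, "_", seq_len(reps)))))
    m[up, reps + seq_len(reps)] <- m[up, reps + seq_len(reps)] + shift
    design <- data.frame(
      sample_id = colnames(m),
      condition = rep(c("control", tag), each = reps),
      stringsAsFactors = FALSE)
    list(matrix = m, design = design)
  }
  e1 <- one_experiment(up1, "meg3kd")
  e2 <- one_experiment(up2, "igdmr")
  list(matrices = list(meg3kd = e1$matrix, igdmr = e2$matrix),
       designs = list(meg3kd = e1$design, igdmr = e2$design),
       truth = list(up1 = sort(up1), up2 = sort(up2), noise_sd = sd_g))
}
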