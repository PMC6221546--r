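#' Extend alignments downstream to fixed-length fragments
#'
#' Each read is extended 3'-ward from its 5' end to span exactly
#' \code{length} bp (fragment-reconstruction semantics for single-end
#' ChIP-seq); extensions exceeding chromosome ends are clipped, so edge
#' fragments may be shorter.
#'
#' @param reads stranded \code{GRanges} (strand must be + or -)
#' @param genome a \code{Seqinfo} carrying chromosome lengths
#' @param length fragment length in bp (default 150)
#' @return \code{GRanges} of extended, clipped fragments
#' @export
extend_alignments <- function(reads, genome, length = 150) {
  if (any(GenomicRanges::strand(reads) == "*"))
    stop("alignments must be stranded (+/-)")
  missing <- setdiff(GenomeInfoDb::seqlevelsInUse(reads),
                     GenomeInfoDb::seqnames(genome))
  if (length(missing) > 0)
    stop("chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "))
  GenomeInfoDb::seqlevels(reads) <- GenomeInfoDb::seqnames(genome)
  GenomeInfoDb::seqinfo(reads) <- genome
  # resize flags out-of-bound ranges that the very next step clips
  ext <- suppressWarnings(
    GenomicRanges::resize(reads, width = length, fix = "start"))
  GenomicRanges::trim(ext)
}

#' Base-resolution coverage track with mappable-read normalization
#'
#' Raw depth is the number of fragments covering each position; the
#' normalized track scales it per million mappable reads.  A binned track
#' (mean depth within fixed-width bins) is kept alongside to reveal major
#' trends.
#'
#' @param fragments extended fragment \code{GRanges} (clipped)
#' @param genome a \code{Seqinfo}
#' @param total_reads mappable read count (default: number of fragments)
#' @param bin bin width in bp for the binned view (default 10)
#' @return a \code{CoverageTrack}: list(raw \code{RleList}, total_reads,
#'   scale = 1e6/total_reads, bin, binned \code{RleList} at bin
#'   resolution)
#' @export
coverage_profile <- function(fragments, genome, total_reads = NULL,
                             bin = 10) {
  if (length(fragments) == 0) stop("no reads: cannot build a coverage track")
  if (is.null(total_reads)) total_reads <- length(fragments)
  GenomeInfoDb::seqlevels(fragments) <- GenomeInfoDb::seqnames(genome)
  GenomeInfoDb::seqinfo(fragments) <- genome
  raw <- GenomicRanges::coverage(fragments)
  binned <- NULL
  if (!is.null(bin) && bin > 1) {
    binned <- methods::as(lapply(raw, function(r) {
      n <- length(r)
      starts <- seq(1, n, by = bin)
      v <- IRanges::Views(r, start = starts,
                          end = pmin(starts + bin - 1, n))
      S4Vectors::Rle(IRanges::viewMeans(v),
                     lengths = pmin(starts + bin - 1, n) - starts + 1)
    }), "SimpleRleList")
  }
  structure(list(raw = raw, total_reads = total_reads,
                 scale = 1e6 / total_reads, bin = bin, binned = binned),
            class = "CoverageTrack")
}

#' Extract track values
#' @param track a \code{CoverageTrack}
#' @param normalized scale per million mappable reads (default TRUE)
#' @param binned return the binned view (default FALSE)
#' @return numeric \code{RleList}
#' @export
track_values <- function(track, normalized = TRUE, binned = FALSE) {
  v <- if (binned) track$binned else track$raw
  if (normalized) v * track$scale else v
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf(
    "CoverageTrack: %d chromosome(s), %d mappable reads, bin %s\n",
    length(x$raw), x$total_reads,
    if (is.null(x$bin)) "none" else x$bin))
  invisible(x)
}

# 5' positions of stranded reads as width-1 GRanges
.five_prime <- function(reads) {
  GenomicRanges::resize(reads, width = 1, fix = "start")
}

#' Call enriched regions by Poisson sliding windows against an input
#'
#' Read 5' positions are counted in sliding windows; the local expected
#' count is the larger of the genome-wide ChIP rate and the input window
#' count rescaled by the library-depth ratio, and window significance is
#' the Poisson upper-tail probability.  Significant windows within
#' \code{merge_gap} are merged; per merged region the count, local lambda
#' and p are recomputed and the summit is the maximum of the
#' fragment-extension coverage.  This is a deliberately simple
#' input-corrected thresholding scheme (no duplicate filtering or model
#' building), preserving only the p < 1e-5 local-lambda semantics of
#' standard peak callers.
#'
#' @param chip_reads,input_reads stranded alignment \code{GRanges}
#' @param genome a \code{Seqinfo}
#' @param extend fragment-extension length for the summit track
#' @param window,step sliding-window width and step (bp)
#' @param p_cut significance cutoff (default 1e-5)
#' @param merge_gap merge significant windows within this gap (bp)
#' @return \code{GRanges} of peaks with mcols: summit, count, lambda,
#'   p_value
#' @export
call_enriched_regions <- function(chip_reads, input_reads, genome,
                                  extend = 150, window = 200, step = 50,
                                  p_cut = 1e-5, merge_gap = 100) {
  if (window < 1) stop("window must be >= 1")
  chip5 <- .five_prime(chip_reads)
  in5 <- .five_prime(input_reads)
  GenomeInfoDb::seqlevels(chip5) <- GenomeInfoDb::seqnames(genome)
  GenomeInfoDb::seqinfo(chip5) <- genome
  G <- sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
  depth_ratio <- length(chip5) / length(in5)
  lambda_bg <- length(chip5) / G

  cov_track <- GenomicRanges::coverage(
    extend_alignments(chip_reads, genome, extend))

  peaks <- list()
  for (chr in GenomeInfoDb::seqnames(genome)) {
    L <- GenomeInfoDb::seqlengths(genome)[[chr]]
    if (L < window) next
    starts <- seq(1, L - window + 1, by = step)
    win <- GenomicRanges::GRanges(chr,
      IRanges::IRanges(starts, width = window))
    cc <- GenomicRanges::countOverlaps(win, chip5, ignore.strand = TRUE)
    ic <- GenomicRanges::countOverlaps(win, in5, ignore.strand = TRUE)
    lam <- pmax(lambda_bg * window, ic * depth_ratio)
    p <- stats::ppois(cc - 1, lam, lower.tail = FALSE)
    sig <- win[p < p_cut & cc > 0]
    if (length(sig) == 0) next
    merged <- GenomicRanges::reduce(sig, min.gapwidth = merge_gap + 1)
    mc <- GenomicRanges::countOverlaps(merged, chip5, ignore.strand = TRUE)
    mi <- GenomicRanges::countOverlaps(merged, in5, ignore.strand = TRUE)
    mlam <- pmax(lambda_bg * GenomicRanges::width(merged),
                 mi * depth_ratio)
    mp <- stats::ppois(mc - 1, mlam, lower.tail = FALSE)
    covr <- cov_track[[chr]]
    v <- IRanges::Views(covr, start = GenomicRanges::start(merged),
                        end = GenomicRanges::end(merged))
    merged$summit <- GenomicRanges::start(merged) +
      (IRanges::viewWhichMaxs(v) - GenomicRanges::start(merged))
    merged$count <- mc
    merged$lambda <- mlam
    merged$p_value <- mp
    peaks[[chr]] <- merged
  }
  if (length(peaks) == 0)
    return(GenomicRanges::GRanges(seqinfo = genome,
      summit = integer(), count = integer(), lambda = numeric(),
      p_value = numeric()))
  out <- unname(do.call(c, unname(peaks)))
  out
}

#' Compare ChIP enrichment between two conditions over merged peaks
#'
#' Peaks from both conditions are merged into a union region set; regions
#' overlapping a peak in BOTH conditions are marked "common".  Each
#' region's M = log2((count2 + pc)/(count1 + pc)) is rescaled to absorb
#' global depth/efficiency differences and regions whose rescaled M
#' exceeds \code{m_cut} in magnitude are flagged changed
#' (\code{direction = "down"} means lower in condition 2).
#'
#' Two rescaling anchors are offered.  The default, \code{"background"},
#' subtracts the log2 ratio of read counts falling outside all merged
#' regions — an anchor that stays valid even when a large fraction of
#' the common regions has genuinely changed.  \code{"common_ls"} fits
#' M = a + b A by least squares over the common regions and subtracts the
#' fitted line; it assumes the common regions are mostly unchanged and is
#' driven off course when they are not (see the methods vignette).
#'
#' @param peaks1,peaks2 peak \code{GRanges} from the two conditions
#' @param reads1,reads2 the alignment \code{GRanges} of the two conditions
#' @param pseudocount added to region read counts (default 0.5)
#' @param m_cut |rescaled M| cutoff for a changed region (default 1)
#' @param rescale \code{"background"} (default) or \code{"common_ls"}
#' @return \code{GRanges} of merged regions with mcols: count1, count2,
#'   A, M_raw, M_rescaled, common, changed, direction; the fitted
#'   coefficients are in the \code{"fit"} attribute.
#' @export
compare_conditions <- function(peaks1, peaks2, reads1, reads2,
                               pseudocount = 0.5, m_cut = 1,
                               rescale = c("background", "common_ls")) {
  rescale <- match.arg(rescale)
  merged <- GenomicRanges::reduce(c(GenomicRanges::granges(peaks1),
                                    GenomicRanges::granges(peaks2)))
  common <- GenomicRanges::countOverlaps(merged, peaks1) > 0 &
            GenomicRanges::countOverlaps(merged, peaks2) > 0
  if (sum(common) < 5)
    stop("fewer than 5 common regions; rescaling not identifiable")
  p1 <- .five_prime(reads1)
  p2 <- .five_prime(reads2)
  c1 <- GenomicRanges::countOverlaps(merged, p1,
                                     ignore.strand = TRUE) + pseudocount
  c2 <- GenomicRanges::countOverlaps(merged, p2,
                                     ignore.strand = TRUE) + pseudocount
  M <- log2(c2 / c1)
  A <- 0.5 * log2(c2 * c1)
  if (rescale == "background") {
    bg1 <- sum(GenomicRanges::countOverlaps(p1, merged,
                                            ignore.strand = TRUE) == 0)
    bg2 <- sum(GenomicRanges::countOverlaps(p2, merged,
                                            ignore.strand = TRUE) == 0)
    b <- c(log2(bg2 / bg1), 0)
  } else {
    fit <- stats::lm.fit(cbind(1, A[common]), M[common])
    b <- fit$coefficients
  }
  Mr <- M - (b[1] + b[2] * A)
  merged$count1 <- c1 - pseudocount
  merged$count2 <- c2 - pseudocount
  merged$A <- A
  merged$M_raw <- M
  merged$M_rescaled <- Mr
  merged$common <- common
  merged$changed <- abs(Mr) >= m_cut
  merged$direction <- ifelse(!merged$changed, "unchanged",
                             ifelse(Mr > 0, "up", "down"))
  attr(merged, "fit") <- c(intercept = unname(b[1]), slope = unname(b[2]))
  merged
}

#' Gene-level H3K27me3 change between control and knockdown tracks
#'
#' Mean normalized depth over each gene's span plus a strand-aware
#' upstream flank, compared as log2((kd + pc)/(ctrl + pc)); genes at or
#' below \code{-reduce_cut} (default 0.585, a 1.5-fold loss) are flagged
#' reduced.  Both tracks must carry their own mappable-read normalization.
#'
#' @param track_ctrl,track_kd \code{CoverageTrack}s of the two conditions
#' @param annotation an \code{AnnotationSet}
#' @param flank upstream flank in bp (default 2000)
#' @param pseudocount added to mean depths (default 0.1)
#' @param reduce_cut |log2| reduction threshold (default 0.585)
#' @return data.frame: gene_id, mean_ctrl, mean_kd, log2_ratio, reduced
#' @export
gene_h3k27me3_delta <- function(track_ctrl, track_kd, annotation,
                                flank = 2000, pseudocount = 0.1,
                                reduce_cut = 0.585) {
  spans <- gene_spans(annotation)
  win <- GenomicRanges::resize(spans, GenomicRanges::width(spans) + flank,
                               fix = "end")   # strand-aware upstream
  ctrl <- track_values(track_ctrl, normalized = TRUE)
  kd <- track_values(track_kd, normalized = TRUE)
  chroms <- as.character(GenomicRanges::seqnames(win))
  bad <- !(chroms %in% names(ctrl))
  if (any(bad)) stop("gene chromosome(s) missing from track")
  mean_over <- function(cov, w) {
    vapply(seq_along(w), function(i) {
      r <- cov[[chroms[i]]]
      s <- max(1, GenomicRanges::start(w)[i])
      e <- min(length(r), GenomicRanges::end(w)[i])
      if (e < s) return(0)
      IRanges::viewMeans(IRanges::Views(r, start = s, end = e))
    }, 0)
  }
  if (any(GenomicRanges::start(win) < 1))
    warning("flank extends past chromosome start; clipped")
  mc <- mean_over(ctrl, win)
  mk <- mean_over(kd, win)
  lr <- log2((mk + pseudocount) / (mc + pseudocount))
  data.frame(gene_id = names(spans), mean_ctrl = mc, mean_kd = mk,
             log2_ratio = lr, reduced = lr <= -reduce_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}
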