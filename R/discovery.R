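#' Classify assembled candidate transcripts as novel lncRNAs
#'
#' A candidate is called novel iff it satisfies all three rules: spliced
#' (exon-sum) length > 200 bp, more than one exon, and no overlap with any
#' known gene.  Overlap defaults to any candidate exon intersecting any
#' reference gene's genomic span on either strand; \code{overlap_mode =
#' "exon"} restricts to reference exons and \code{stranded = TRUE} to
#' same-strand hits.  All failing rules are reported together and the
#' output order matches the input order.
#'
#' @param candidates an \code{AnnotationSet} (or named \code{GRangesList}
#'   of exons) of candidate transcripts
#' @param reference the known-gene \code{AnnotationSet}
#' @param overlap_mode \code{"span"} (default) or \code{"exon"}
#' @param stranded require same-strand overlap (default FALSE)
#' @return data.frame (one row per candidate, input order):
#'   \code{transcript_id}, \code{verdict}, \code{reasons} (comma-joined,
#'   subset of \code{length,monoexonic,overlap}), \code{overlapping_genes}
#'   (comma-joined gene ids), \code{spliced_length}, \code{exon_count}.
#' @export
classify_novel_lncRNAs <- function(candidates, reference,
                                   overlap_mode = c("span", "exon"),
                                   stranded = FALSE) {
  overlap_mode <- match.arg(overlap_mode)
  exons <- if (methods::is(candidates, "AnnotationSet"))
    candidates$exons else candidates
  ids <- names(exons)

  spl_len <- sum(GenomicRanges::width(exons))
  n_exon <- lengths(exons)

  target <- if (overlap_mode == "span") gene_spans(reference)
            else unlist(reference$exons)
  target_gene <- if (overlap_mode == "span") names(target)
                 else unname(reference$tx2gene[rep(names(reference$exons),
                                       lengths(reference$exons))])

  flat <- unlist(exons, use.names = FALSE)
  flat_tx <- rep(ids, lengths(exons))
  missing_chr <- !(as.character(GenomicRanges::seqnames(flat)) %in%
                     as.character(GenomicRanges::seqnames(target)))
  if (any(missing_chr))
    warning("candidate chromosome(s) absent from reference: ",
            paste(unique(as.character(
              GenomicRanges::seqnames(flat))[missing_chr]), collapse = ", "))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    flat, target, ignore.strand = !stranded))
  ov_map <- split(target_gene[S4Vectors::subjectHits(hits)],
                  flat_tx[S4Vectors::queryHits(hits)])
  ov_genes <- lapply(stats::setNames(ids, ids), function(id)
    sort(unique(ov_map[[id]])))

  reasons <- lapply(seq_along(ids), function(i) {
    r <- character()
    if (spl_len[i] <= 200) r <- c(r, "length")
    if (n_exon[i] <= 1) r <- c(r, "monoexonic")
    if (length(ov_genes[[i]]) > 0) r <- c(r, "overlap")
    r
  })
  data.frame(
    transcript_id = ids,
    verdict = ifelse(lengths(reasons) == 0, "novel", "rejected"),
    reasons = vapply(reasons, paste, "", collapse = ","),
    overlapping_genes = vapply(ov_genes, paste, "", collapse = ","),
    spliced_length = unname(spl_len),
    exon_count = unname(n_exon),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Pool novel lncRNAs with the reference annotation
#'
#' Novel candidates are added to the reference with fresh gene ids
#' (prefix \code{NOVEL}) and biotype \code{lncRNA}; the class counts used
#' for specificity grouping are attached as the \code{"class_counts"}
#' attribute.
#'
#' @param calls output of \code{\link{classify_novel_lncRNAs}}
#' @param candidates the candidate set the calls were computed on
#' @param reference the reference \code{AnnotationSet}
#' @return merged \code{AnnotationSet}
#' @export
merge_with_annotation <- function(calls, candidates, reference) {
  exons <- if (methods::is(candidates, "AnnotationSet"))
    candidates$exons else candidates
  novel_tx <- calls$transcript_id[calls$verdict == "novel"]
  if (any(novel_tx %in% names(reference$exons)))
    stop("novel transcript id collides with reference")
  new_gene <- stats::setNames(sprintf("NOVEL%04d", seq_along(novel_tx)),
                              novel_tx)
  if (any(new_gene %in% names(reference$gene_biotype)))
    stop("novel gene id collides with reference")

  merged_exons <- suppressWarnings(c(reference$exons, exons[novel_tx]))
  tx2gene <- c(reference$tx2gene, new_gene)
  biotype <- c(reference$gene_biotype,
               stats::setNames(rep("lncRNA", length(novel_tx)),
                               unname(new_gene)))
  out <- AnnotationSet(merged_exons, tx2gene, biotype)
  attr(out, "class_counts") <- table(factor(gene_classes(out),
    levels = c("protein_coding", "annotated_lncRNA", "novel_lncRNA",
               "other")))
  out
}
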