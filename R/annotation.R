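#' Transcript annotation set
#'
#' Lightweight container for transcript models: a named \code{GRangesList}
#' of exons (one element per transcript, exons sorted 5'-agnostic by
#' position), a transcript-to-gene map, and a per-gene biotype in
#' \code{protein_coding}, \code{lncRNA} or \code{other}.  Genes whose id
#' carries the \code{NOVEL} prefix are treated as novel lncRNAs by
#' \code{\link{gene_classes}}.
#'
#' @param exons named \code{GRangesList}, one element per transcript.
#' @param tx2gene named character vector, transcript id -> gene id.
#' @param gene_biotype named character vector, gene id -> biotype.
#' @return An object of class \code{AnnotationSet}.
#' @export
AnnotationSet <- function(exons, tx2gene, gene_biotype) {
  stopifnot(methods::is(exons, "GRangesList"))
  ids <- names(exons)
  if (length(exons) > 0 && (is.null(ids) || anyDuplicated(ids)))
    stop("transcript ids must be unique and non-missing")
  if (length(exons) == 0) ids <- character()
  if (!all(ids %in% names(tx2gene)))
    stop("every transcript needs a gene id")
  tx2gene <- tx2gene[ids]
  if (!all(tx2gene %in% names(gene_biotype)))
    stop("every gene needs a biotype")
  exons <- GenomicRanges::GRangesList(lapply(exons, function(gr) {
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    if (length(gr) > 1 &&
        any(GenomicRanges::start(gr)[-1] <= GenomicRanges::end(gr)[-length(gr)]))
      stop("exons of one transcript must not overlap")
    if (length(unique(as.character(GenomicRanges::seqnames(gr)))) != 1 ||
        length(unique(as.character(GenomicRanges::strand(gr)))) != 1)
      stop("exons of one transcript must share chromosome and strand")
    gr
  }))
  names(exons) <- ids
  structure(
    list(exons = exons, tx2gene = tx2gene,
         gene_biotype = gene_biotype[unique(tx2gene)]),
    class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d transcripts, %d genes\n",
              length(x$exons), length(x$gene_biotype)))
  print(table(x$gene_biotype))
  invisible(x)
}

#' Spliced transcript lengths (sum of exon widths)
#' @param ann an \code{AnnotationSet}
#' @return named integer vector per transcript.
#' @export
tx_spliced_length <- function(ann) {
  sum(GenomicRanges::width(ann$exons))
}

#' Exon counts per transcript
#' @param ann an \code{AnnotationSet}
#' @return named integer vector per transcript.
#' @export
tx_exon_count <- function(ann) {
  lengths(ann$exons)
}

#' Genomic span of each gene (range over its transcripts' exons)
#' @param ann an \code{AnnotationSet}
#' @return \code{GRanges} named by gene id.
#' @export
gene_spans <- function(ann) {
  ex <- unlist(ann$exons, use.names = FALSE)
  gene <- unname(ann$tx2gene[rep(names(ann$exons), lengths(ann$exons))])
  g <- factor(gene, levels = unique(gene))
  st <- tapply(GenomicRanges::start(ex), g, min)
  en <- tapply(GenomicRanges::end(ex), g, max)
  chr <- tapply(as.character(GenomicRanges::seqnames(ex)), g, `[`, 1)
  strd <- tapply(as.character(GenomicRanges::strand(ex)), g, `[`, 1)
  out <- GenomicRanges::GRanges(unname(chr),
                                IRanges::IRanges(unname(st), unname(en)),
                                strand = unname(strd))
  names(out) <- levels(g)
  out
}

#' Gene classes for specificity grouping
#'
#' Maps biotypes onto the three-way grouping used for class-wise
#' specificity comparisons: \code{protein_coding}, \code{annotated_lncRNA}
#' (biotype lncRNA without the NOVEL gene-id prefix), \code{novel_lncRNA}
#' (NOVEL prefix), everything else \code{other}.
#'
#' @param ann an \code{AnnotationSet}
#' @return named character vector per gene id.
#' @export
gene_classes <- function(ann) {
  bt <- ann$gene_biotype
  cls <- ifelse(bt == "protein_coding", "protein_coding",
         ifelse(bt == "lncRNA" & startsWith(names(bt), "NOVEL"), "novel_lncRNA",
         ifelse(bt == "lncRNA", "annotated_lncRNA", "other")))
  names(cls) <- names(bt)
  cls
}

#' Transcript-level classes (gene class carried down to transcripts)
#' @param ann an \code{AnnotationSet}
#' @return named character vector per transcript id.
#' @export
tx_classes <- function(ann) {
  g <- gene_classes(ann)
  cls <- g[ann$tx2gene]
  names(cls) <- names(ann$tx2gene)
  cls
}
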