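#' Read a two-column chrom.sizes file into a Seqinfo
#'
#' @param path chrom.sizes file: chromosome name, length in bp, tab-separated.
#' @return a \code{Seqinfo} object.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (anyDuplicated(tab$chrom)) stop("duplicate chromosome name in ", path)
  if (any(tab$length <= 0)) stop("non-positive chromosome length in ", path)
  GenomeInfoDb::Seqinfo(seqnames = tab$chrom, seqlengths = tab$length)
}

#' Write a Seqinfo as a chrom.sizes file
#' @param genome a \code{Seqinfo}
#' @param path output path
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(GenomeInfoDb::seqnames(genome),
               GenomeInfoDb::seqlengths(genome)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GTF file into an AnnotationSet
#'
#' Exon features are grouped per transcript; the gene biotype is taken from
#' the \code{gene_biotype} or \code{gene_type} attribute and defaults to
#' \code{"other"} when absent.  GTF's 1-based inclusive coordinates map
#' directly onto the internal \code{GRanges} convention.
#'
#' @param path GTF file path
#' @return an \code{AnnotationSet}
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("exon feature without transcript_id in ", path)
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("exon feature without gene_id in ", path)
  bt <- gr$gene_biotype
  if (is.null(bt)) bt <- gr$gene_type
  if (is.null(bt)) bt <- rep("other", length(gr))
  bt[is.na(bt)] <- "other"
  tx2gene <- vapply(split(gr$gene_id, gr$transcript_id), `[`, "", 1)
  gene_biotype <- vapply(split(bt, gr$gene_id), `[`, "", 1)
  exons <- GenomicRanges::split(
    GenomicRanges::granges(gr), factor(gr$transcript_id,
                                       levels = unique(gr$transcript_id)))
  AnnotationSet(exons, tx2gene, gene_biotype)
}

#' Write an AnnotationSet as GTF
#' @param ann an \code{AnnotationSet}
#' @param path output path
#' @param source source field for column 2
#' @export
write_gtf <- function(ann, path, source = "lncstage") {
  ex <- unlist(ann$exons)
  tx <- rep(names(ann$exons), lengths(ann$exons))
  gene <- unname(ann$tx2gene[tx])
  ex$source <- source
  ex$type <- "exon"
  ex$gene_id <- gene
  ex$transcript_id <- tx
  ex$gene_biotype <- unname(ann$gene_biotype[gene])
  rtracklayer::export(ex, path, format = "gtf")
  invisible(path)
}

#' Read single-end alignments from BED6
#'
#' Returns stranded single-read alignments as a \code{GRanges}; the strand
#' column is mandatory because downstream fragment extension is
#' strand-directional.
#'
#' @param path BED6 file path
#' @return \code{GRanges} with strand in \{+, -\}
#' @export
read_alignments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::strand(gr) == "*"))
    stop("BED alignments must carry a +/- strand (column 6) in ", path)
  gr
}

#' Write alignments as BED6
#' @param reads stranded \code{GRanges}
#' @param path output path
#' @export
write_alignments_bed <- function(reads, path) {
  if (is.null(reads$name)) reads$name <- sprintf("r%d", seq_along(reads))
  if (is.null(reads$score)) reads$score <- 0L
  rtracklayer::export(reads, path, format = "bed")
  invisible(path)
}

#' Read a TSV count matrix
#'
#' First column holds feature ids, header row the sample ids.  Counts must
#' be nonnegative; duplicate feature ids are rejected.
#'
#' @param path TSV path
#' @return numeric matrix, features x samples
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate feature id in ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m)) stop("non-numeric count in ", path)
  if (any(m < 0)) stop("negative count in ", path)
  rownames(m) <- ids
  m
}

#' Write a count (or any numeric feature x sample) matrix as TSV
#' @param m numeric matrix with rownames
#' @param path output path
#' @param id_col header for the feature-id column
#' @export
write_counts_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT path (name, description, members per row)
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued positions are emitted as single intervals
#' (bedGraph's native 0-based half-open run-length encoding); zero runs are
#' omitted unless \code{keep_zeros}.
#'
#' @param track a \code{CoverageTrack} (see \code{\link{coverage_profile}})
#'   or a numeric \code{RleList}
#' @param path output path
#' @param normalized write the depth-normalized values (ignored for a bare
#'   \code{RleList})
#' @param keep_zeros also emit zero-valued runs
#' @export
write_bedgraph <- function(track, path, normalized = TRUE, keep_zeros = FALSE) {
  cov <- if (methods::is(track, "CoverageTrack"))
    track_values(track, normalized = normalized) else track
  gr <- methods::as(cov, "GRanges")
  if (!keep_zeros) gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
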