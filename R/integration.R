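#' Venn-style integration of de-repressed genes with H3K27me3 loss
#'
#' Intersects the genes up-regulated in each of two perturbations with
#' the genes showing a reduced H3K27me3 landscape; the final candidate
#' list is the triple intersection.  Counts for all seven nonempty Venn
#' regions are reported and sum to the size of the union.
#'
#' @param up_meg3kd,up_igdmr,k27_reduced character gene sets sharing one
#'   namespace
#' @return list: \code{final} (sorted triple intersection),
#'   \code{venn} (named counts for regions A, B, C, AB, AC, BC, ABC with
#'   A = up_meg3kd, B = up_igdmr, C = k27_reduced; exclusive regions),
#'   \code{membership} data.frame of per-gene booleans
#' @export
integrate_gene_sets <- function(up_meg3kd, up_igdmr, k27_reduced) {
  a <- unique(up_meg3kd)
  b <- unique(up_igdmr)
  c_ <- unique(k27_reduced)
  genes <- sort(unique(c(a, b, c_)))
  m <- data.frame(
    gene_id = genes,
    up_meg3kd = genes %in% a,
    up_igdmr = genes %in% b,
    k27_reduced = genes %in% c_,
    stringsAsFactors = FALSE)
  key <- paste0(ifelse(m$up_meg3kd, "A", ""),
                ifelse(m$up_igdmr, "B", ""),
                ifelse(m$k27_reduced, "C", ""))
  venn <- vapply(c("A", "B", "C", "AB", "AC", "BC", "ABC"),
                 function(k) sum(key == k), 0L)
  list(final = m$gene_id[key == "ABC"], venn = venn, membership = m)
}

#' Gene-set over-representation by the hypergeometric test
#'
#' One-sided upper-tail hypergeometric p-value per set (overlap k of a
#' size-n query with a size-K set in a size-N universe, P(X >= k)), with
#' Benjamini-Hochberg adjustment across all tested sets.  Sets are
#' intersected with the universe before testing; the query must lie
#' within the universe.
#'
#' @param query character gene set of interest
#' @param sets named list of character gene sets (e.g. from
#'   \code{\link{read_gmt}})
#' @param universe character background gene set
#' @param q_cut BH q-value cutoff for the flag (default 0.05)
#' @return data.frame sorted by p: set, overlap k, set_size K,
#'   query_size n, universe_size N, p_value, q_value, significant
#' @export
gene_set_enrichment <- function(query, sets, universe, q_cut = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  query <- unique(query)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    K <- length(s)
    k <- length(intersect(s, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= q_cut
  out[order(out$p_value, out$set), , drop = FALSE]
}
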