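# Independent oracles and tiny fixture builders.  Every oracle here is a
# deliberately naive re-computation (loops, exact sums, per-position
# counting) kept separate from the package's optimized paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Build an AnnotationSet from a compact spec: list of transcripts, each
# list(id, gene, chrom, strand, exons = matrix of (start, end) 1-based).
make_annotation <- function(tx_list, biotypes) {
  exons <- GenomicRanges::GRangesList(lapply(tx_list, function(t)
    GRanges(t$chrom, IRanges(t$exons[, 1], t$exons[, 2]),
            strand = t$strand)))
  names(exons) <- vapply(tx_list, `[[`, "", "id")
  tx2gene <- vapply(tx_list, `[[`, "", "gene")
  names(tx2gene) <- names(exons)
  AnnotationSet(exons, tx2gene, biotypes)
}

# O(n*m) all-pairs novelty classification oracle: plain vectors, no
# interval index.  Span-level, strand-agnostic (the package default).
brute_force_classify <- function(candidates, reference) {
  spans <- gene_spans(reference)
  s_chr <- as.character(seqnames(spans))
  s_lo <- start(spans)
  s_hi <- end(spans)
  vapply(seq_along(candidates$exons), function(i) {
    ex <- candidates$exons[[i]]
    len <- sum(end(ex) - start(ex) + 1)
    nex <- length(ex)
    ov <- FALSE
    for (j in seq_along(ex)) {
      for (k in seq_along(spans)) {
        if (as.character(seqnames(ex))[j] == s_chr[k] &&
            start(ex)[j] <= s_hi[k] && end(ex)[j] >= s_lo[k]) {
          ov <- TRUE
          break
        }
      }
      if (ov) break
    }
    if (len > 200 && nex > 1 && !ov) "novel" else "rejected"
  }, "")
}

# Direct entropy-formula Jensen-Shannon specificity oracle (scalar).
js_oracle <- function(e) {
  if (sum(e) == 0) return(NA_real_)
  p <- e / sum(e)
  H <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  sig <- vapply(seq_along(p), function(s) {
    u <- rep(0, length(p))
    u[s] <- 1
    jsd <- H((p + u) / 2) - (H(p) + H(u)) / 2
    1 - sqrt(max(jsd, 0))
  }, 0)
  max(sig)
}

# Independent trimmed-weighted-mean TMM oracle for one sample against a
# fixed reference column; straightforward sort-based trimming.
tmm_factor_oracle <- function(counts, k, r, trim_M = 0.30, trim_A = 0.05) {
  N <- colSums(counts)
  yk <- counts[, k]
  yr <- counts[, r]
  use <- yk > 0 & yr > 0
  yk <- yk[use]
  yr <- yr[use]
  M <- log2((yk / N[k]) / (yr / N[r]))
  A <- 0.5 * log2((yk / N[k]) * (yr / N[r]))
  w <- 1 / ((N[k] - yk) / (N[k] * yk) + (N[r] - yr) / (N[r] * yr))
  n <- length(M)
  keep <- rank(M) > n * trim_M & rank(M) <= n * (1 - trim_M) &
          rank(A) > n * trim_A & rank(A) <= n * (1 - trim_A)
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

# O(n^2)-ish two-sample KS statistic by explicit ECDF scan at all points.
ks_D_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t)
    abs(mean(x <= t) - mean(y <= t)), 0))
}

# Per-position coverage counting oracle over one chromosome.
coverage_oracle <- function(starts, ends, L) {
  depth <- integer(L)
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# Exact hypergeometric upper-tail by summation.
hyper_oracle <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Grid-search moment-equation solver for the variance prior d0.
d0_grid_oracle <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  target <- var(e) - trigamma(df / 2)
  grid <- seq(0.1, 100, by = 0.001)
  2 * grid[which.min(abs(trigamma(grid) - target))]
}
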