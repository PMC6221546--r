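#' MA-style pairwise enrichment between two sample groups
#'
#' Per-feature M (log2 fold-change) and A (mean abundance) from group
#' means with a pseudocount:
#' \deqn{M = \log_2\frac{\bar x_1 + c}{\bar x_2 + c},\qquad
#'       A = \tfrac12\log_2\big((\bar x_1 + c)(\bar x_2 + c)\big)}
#' A feature is flagged enriched in group 1 when \eqn{M \ge} the M
#' threshold and \eqn{A \ge} the A floor.
#'
#' @param norm normalized matrix
#' @param group1,group2 sample id vectors
#' @param pseudocount c (default 1)
#' @param m_threshold minimum M for enrichment (default 1)
#' @param a_floor minimum A for enrichment (default 0)
#' @return data.frame: feature_id, mean1, mean2, M, A, enriched
#' @export
ma_compare <- function(norm, group1, group2, pseudocount = 1,
                       m_threshold = 1, a_floor = 0) {
  if (length(group1) == 0 || length(group2) == 0)
    stop("both groups must be nonempty")
  if (!all(c(group1, group2) %in% colnames(norm)))
    stop("unknown sample id in group definitions")
  x1 <- rowMeans(norm[, group1, drop = FALSE])
  x2 <- rowMeans(norm[, group2, drop = FALSE])
  M <- log2((x1 + pseudocount) / (x2 + pseudocount))
  A <- 0.5 * log2((x1 + pseudocount) * (x2 + pseudocount))
  data.frame(feature_id = rownames(norm), mean1 = unname(x1),
             mean2 = unname(x2), M = unname(M), A = unname(A),
             enriched = unname(M >= m_threshold & A >= a_floor),
             stringsAsFactors = FALSE)
}

#' Features enriched in both of two MA comparisons
#'
#' The postmitotic-MN candidate rule: a lncRNA must be enriched both in
#' the developmental comparison (e.g. MN vs pMN) and in the cell-type
#' comparison (e.g. MN vs IN).
#'
#' @param ma1,ma2 outputs of \code{\link{ma_compare}} over the same
#'   feature namespace
#' @param lnc_ids feature ids considered lncRNAs
#' @return sorted character vector of candidate ids
#' @export
intersect_enriched <- function(ma1, ma2, lnc_ids) {
  e1 <- ma1$feature_id[ma1$enriched]
  e2 <- ma2$feature_id[ma2$enriched]
  sort(intersect(intersect(e1, e2), lnc_ids))
}

# Invert the trigamma function by Newton iteration (monotone decreasing
# on (0, Inf)); used by the variance-prior moment estimator.
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    d <- (trigamma(x) - y) / psigamma(x, deriv = 2)
    x <- x - d
    if (abs(d) < 1e-10 * x) break
  }
  x
}

#' Fit the empirical-Bayes variance prior
#'
#' Moment matching on z = log(s^2) for gene-wise sample variances with
#' common residual df d: under the scaled inverse-chi-squared prior
#' s0^2 d0 / chisq(d0), \eqn{Var(z) = \psi'(d/2) + \psi'(d_0/2)} and
#' \eqn{E(z) = \log s_0^2 + [\psi(d/2) - \log(d/2)] -
#' [\psi(d_0/2) - \log(d_0/2)]}.  d0 is recovered by numeric trigamma
#' inversion; when the observed log-variance dispersion does not exceed
#' the chi-squared component, d0 = Inf (no excess dispersion) and s0^2 is
#' the digamma-corrected mean.
#'
#' @param s2 vector of gene-wise sample variances
#' @param df residual degrees of freedom (scalar or per-gene; genes with
#'   df < 1 are dropped)
#' @return list(d0, s02)
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  keep <- df >= 1 & is.finite(s2)
  s2 <- s2[keep]
  df <- df[keep]
  if (length(s2) < 10) stop("need >= 10 genes with df >= 1")
  if (all(s2 == 0)) stop("all sample variances are zero")
  # guard zeros the way limma does: they carry no usable log-variance
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-sample t-test
#'
#' Gene-wise pooled variances are shrunk toward the prior:
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
#'       \tilde t_g = \frac{\Delta_g}{\tilde s_g\sqrt{1/n_1 + 1/n_2}}}
#' with two-sided p-values from the t distribution on \eqn{d_0 + d_g}
#' degrees of freedom (normal when d0 is infinite).  With d0 = 0 the
#' statistic reduces to the ordinary two-sample t.  The significance call
#' combines a fold-change threshold with an unadjusted p cutoff
#' (defaults: fold >= 2, p < 0.001); BH-adjusted q-values are also
#' reported.
#'
#' @param mat log2-intensity matrix (genes x arrays)
#' @param groupA,groupB sample id vectors (A = condition, B = control;
#'   delta = meanA - meanB)
#' @param prior optional list(d0, s02); fitted from the data when NULL
#' @param fc fold-change threshold on 2^|delta| (default 2)
#' @param alpha p-value cutoff (default 0.001)
#' @return data.frame: gene_id, meanA, meanB, delta, s2, df, s2_post, t,
#'   p_value, q_value, significant; the prior is attached as the
#'   \code{"prior"} attribute.
#' @export
moderated_t_test <- function(mat, groupA, groupB, prior = NULL,
                             fc = 2, alpha = 0.001) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("need >= 2 samples per group")
  A <- mat[, groupA, drop = FALSE]
  B <- mat[, groupB, drop = FALSE]
  n1 <- ncol(A)
  n2 <- ncol(B)
  mA <- rowMeans(A)
  mB <- rowMeans(B)
  d <- n1 + n2 - 2
  s2 <- (rowSums((A - mA)^2) + rowSums((B - mB)^2)) / d
  if (is.null(prior)) prior <- fit_variance_prior(s2, d)
  d0 <- prior$d0
  s02 <- prior$s02
  if (!is.finite(d0)) {
    s2p <- rep(s02, length(s2))
  } else if (d0 == 0) {
    s2p <- s2
  } else {
    s2p <- (d0 * s02 + d * s2) / (d0 + d)
  }
  if (all(s2p == 0))
    stop("zero posterior variance everywhere; data are degenerate")
  delta <- mA - mB
  tstat <- delta / sqrt(s2p * (1 / n1 + 1 / n2))
  tstat[s2p == 0 & delta == 0] <- 0   # 0/0: no evidence either way
  p <- if (is.finite(d0)) 2 * stats::pt(-abs(tstat), df = d0 + d)
       else 2 * stats::pnorm(-abs(tstat))
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    gene_id = rownames(mat), meanA = unname(mA), meanB = unname(mB),
    delta = unname(delta), s2 = unname(s2), df = d,
    s2_post = unname(s2p), t = unname(tstat), p_value = unname(p),
    q_value = unname(q),
    significant = unname(abs(delta) >= log2(fc) & p < alpha),
    stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  out
}
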