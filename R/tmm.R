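#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample scaling factors computed from formulas.  For sample k
#' against the reference r, over genes expressed in both,
#' \deqn{M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r},\qquad
#'       A_g = \tfrac12 \log_2\Big(\frac{y_{gk}}{N_k}\cdot
#'             \frac{y_{gr}}{N_r}\Big)}
#' the top and bottom \code{trim_M} of genes by M and \code{trim_A} by A
#' are dropped (union of the two trims), and
#' \eqn{\log_2 f_k} is the precision-weighted mean of the retained M with
#' weights \eqn{w_g^{-1} = (N_k - y_{gk})/(N_k y_{gk}) +
#' (N_r - y_{gr})/(N_r y_{gr})} (the delta-method variance of M).
#' Factors are renormalized to geometric mean 1.  The reference sample is
#' the one whose upper quartile of counts-per-million is closest to the
#' mean upper quartile.
#'
#' @param counts nonnegative matrix, features x samples, >= 2 columns
#' @param trim_M two-sided trim fraction on M (default 0.30)
#' @param trim_A two-sided trim fraction on A (default 0.05)
#' @param ref_sample optional reference column name/index override
#' @return a \code{TmmResult}: \code{samples} data.frame (sample_id,
#'   lib_size, factor, effective_size), \code{ref_sample}, and
#'   \code{diagnostics} (per sample: retained gene ids, M, A, weights).
#' @export
compute_tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05,
                                ref_sample = NULL) {
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  N <- colSums(counts)
  if (any(N <= 0)) stop("every sample needs a positive library size")

  if (is.null(ref_sample)) {
    f75 <- apply(sweep(counts, 2, N, "/"), 2,
                 stats::quantile, probs = 0.75, names = FALSE)
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts))
           else ref_sample
    if (is.na(ref)) stop("unknown reference sample")
  }

  yr <- counts[, ref]
  Nr <- N[ref]
  logf <- numeric(ncol(counts))
  diagnostics <- vector("list", ncol(counts))
  for (k in seq_len(ncol(counts))) {
    yk <- counts[, k]
    keep <- yk > 0 & yr > 0
    M <- log2((yk[keep] / N[k]) / (yr[keep] / Nr))
    A <- 0.5 * log2((yk[keep] / N[k]) * (yr[keep] / Nr))
    w <- 1 / ((N[k] - yk[keep]) / (N[k] * yk[keep]) +
                (Nr - yr[keep]) / (Nr * yr[keep]))
    n <- length(M)
    rM <- rank(M)
    rA <- rank(A)
    retained <- rM > n * trim_M & rM <= n * (1 - trim_M) &
                rA > n * trim_A & rA <= n * (1 - trim_A)
    if (sum(retained) < 20) {
      warning("fewer than 20 genes retained after trimming for sample ",
              colnames(counts)[k], "; using untrimmed weighted mean")
      retained <- rep(TRUE, n)
    }
    logf[k] <- sum(w[retained] * M[retained]) / sum(w[retained])
    diagnostics[[k]] <- list(
      retained = rownames(counts)[keep][retained],
      M = M, A = A, weights = w, used = retained)
  }
  f <- 2^logf
  f <- f / exp(mean(log(f)))  # geometric mean 1
  res <- list(
    samples = data.frame(sample_id = colnames(counts), lib_size = unname(N),
                         factor = f, effective_size = f * unname(N),
                         stringsAsFactors = FALSE),
    ref_sample = colnames(counts)[ref],
    diagnostics = stats::setNames(diagnostics, colnames(counts)))
  structure(res, class = "TmmResult")
}

#' @export
print.TmmResult <- function(x, ...) {
  cat("TMM normalization (reference:", x$ref_sample, ")\n")
  print(x$samples, row.names = FALSE)
  invisible(x)
}

#' TMM-normalized counts
#'
#' Rescales each column to the geometric-mean effective library size G:
#' \eqn{\tilde y_{gk} = y_{gk} \cdot G / (f_k N_k)} with
#' \eqn{G = (\prod_k f_k N_k)^{1/K}}.  The result stays on a count-like
#' scale, so absolute thresholds (e.g. a minimum normalized count of 10)
#' remain interpretable.
#'
#' @param counts the matrix the factors were computed from
#' @param tmm a \code{TmmResult}
#' @return normalized numeric matrix of the same shape
#' @export
normalize_counts <- function(counts, tmm) {
  if (!identical(colnames(counts), tmm$samples$sample_id))
    stop("sample ids of counts and TmmResult differ")
  eff <- tmm$samples$effective_size
  G <- exp(mean(log(eff)))
  sweep(counts, 2, G / eff, "*")
}

#' Remove minimally expressed features
#'
#' Keeps a feature iff its normalized count reaches \code{threshold} in at
#' least one sample (i.e. drops features below threshold in all samples).
#'
#' @param norm normalized matrix
#' @param threshold minimum normalized count (default 10)
#' @return character vector of retained feature ids
#' @export
filter_min_expression <- function(norm, threshold = 10) {
  rownames(norm)[apply(norm, 1, max) >= threshold]
}

#' Per-stage mean expression profiles
#'
#' Arithmetic mean over replicates within each stage; stage order follows
#' the order of first appearance in \code{design$stage} (or the factor
#' levels if \code{design$stage} is a factor).
#'
#' @param norm normalized matrix (features x samples)
#' @param design data.frame with \code{sample_id} and \code{stage}
#' @return matrix, features x stages
#' @export
stage_mean_profile <- function(norm, design) {
  if (!all(colnames(norm) %in% design$sample_id))
    stop("every sample needs a design row")
  design <- design[match(colnames(norm), design$sample_id), ]
  stages <- if (is.factor(design$stage)) levels(design$stage)
            else unique(design$stage)
  prof <- vapply(stages, function(s) {
    cols <- design$sample_id[design$stage == s]
    if (length(cols) == 0) stop("stage without samples: ", s)
    rowMeans(norm[, cols, drop = FALSE])
  }, numeric(nrow(norm)))
  dimnames(prof) <- list(rownames(norm), stages)
  prof
}
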