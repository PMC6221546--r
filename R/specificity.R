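#' Jensen-Shannon stage-specificity score of one expression profile
#'
#' The profile e is normalized to p = e / sum(e); for each stage s with
#' unit profile u_s the Jensen-Shannon divergence
#' \deqn{JSD(p, u_s) = H\big(\tfrac{p+u_s}{2}\big) -
#'       \tfrac{H(p) + H(u_s)}{2}}
#' is computed with Shannon entropy in base 2 (0 log 0 = 0), and the
#' stage score is \eqn{\sigma_s = 1 - \sqrt{JSD(p, u_s)}}.  The score is
#' maximal (1) for a delta profile and depends only on the profile shape,
#' not its scale.  An all-zero profile has no specificity and yields
#' missing scores.
#'
#' @param e nonnegative numeric vector of per-stage expression
#' @return list: \code{scores} (per stage), \code{max}, \code{argmax}
#'   (stage name or index)
#' @export
js_specificity <- function(e) {
  if (any(e < 0)) stop("expression profile must be nonnegative")
  ns <- if (!is.null(names(e))) names(e) else as.character(seq_along(e))
  if (sum(e) == 0)
    return(list(scores = stats::setNames(rep(NA_real_, length(e)), ns),
                max = NA_real_, argmax = NA_character_))
  p <- e / sum(e)
  h <- function(x) ifelse(x > 0, -x * log2(x), 0)
  Hp <- sum(h(p))
  scores <- vapply(seq_along(p), function(s) {
    m <- p / 2
    m[s] <- (p[s] + 1) / 2
    1 - sqrt(max(sum(h(m)) - Hp / 2, 0))
  }, 0)
  names(scores) <- ns
  list(scores = scores, max = max(scores), argmax = ns[which.max(scores)])
}

#' Score every feature's stage specificity
#'
#' Applies \code{\link{stage_mean_profile}} then the Jensen-Shannon score
#' per feature (vectorized), carrying gene-class labels for the grouped
#' comparison.  Features whose class label is missing are assigned
#' \code{"other"} with a warning.
#'
#' @param norm normalized matrix (features x samples)
#' @param design data.frame with \code{sample_id}, \code{stage}
#' @param classes named character vector feature id -> class
#' @return a \code{SpecificityTable} data.frame: feature_id, class, one
#'   mean column per stage, one sigma column per stage, sigma_max,
#'   argmax_stage
#' @export
score_all <- function(norm, design, classes = NULL) {
  prof <- stage_mean_profile(norm, design)
  stages <- colnames(prof)
  tot <- rowSums(prof)
  P <- prof / ifelse(tot > 0, tot, 1)
  h <- function(x) ifelse(x > 0, -x * log2(x), 0)
  Hp <- rowSums(h(P))
  Hhalf <- rowSums(h(P / 2))
  sig <- vapply(seq_along(stages), function(s) {
    Hm <- Hhalf - h(P[, s] / 2) + h((P[, s] + 1) / 2)
    1 - sqrt(pmax(Hm - Hp / 2, 0))
  }, numeric(nrow(P)))
  colnames(sig) <- stages
  sig[tot == 0, ] <- NA_real_

  if (is.null(classes)) classes <- stats::setNames(
    rep("other", nrow(prof)), rownames(prof))
  cls <- unname(classes[rownames(prof)])
  if (anyNA(cls)) {
    warning(sum(is.na(cls)), " feature(s) without class label; ",
            "assigned 'other'")
    cls[is.na(cls)] <- "other"
  }
  amax <- apply(sig, 1, function(x)
    if (anyNA(x)) NA_character_ else stages[which.max(x)])
  out <- data.frame(
    feature_id = rownames(prof), class = cls,
    prof, sig, sigma_max = apply(sig, 1, function(x)
      if (anyNA(x)) NA_real_ else max(x)),
    argmax_stage = amax,
    stringsAsFactors = FALSE, check.names = FALSE, row.names = NULL)
  colnames(out)[2 + seq_along(stages)] <- paste0("mean_", stages)
  colnames(out)[2 + length(stages) + seq_along(stages)] <-
    paste0("sigma_", stages)
  attr(out, "stages") <- stages
  class(out) <- c("SpecificityTable", "data.frame")
  out
}

#' Select stage-signature features
#'
#' For each stage, features whose specificity argmax is that stage and
#' whose mean there reaches \code{min_stage_mean} are ranked by sigma_max
#' descending (ties: higher stage mean, then lexicographic id) and the top
#' \code{top_n_per_stage} taken.  The default of 14 per stage yields 70
#' signatures over five stages.
#'
#' @param table a \code{SpecificityTable}
#' @param top_n_per_stage signatures per stage (default 14)
#' @param min_stage_mean expression floor at the argmax stage (default 0)
#' @return data.frame subset of \code{table} rows with a \code{stage}
#'   column, ordered by stage then rank
#' @export
select_stage_signatures <- function(table, top_n_per_stage = 14,
                                    min_stage_mean = 0) {
  stages <- attr(table, "stages")
  out <- lapply(stages, function(s) {
    el <- table[!is.na(table$argmax_stage) & table$argmax_stage == s, ]
    el <- el[el[[paste0("mean_", s)]] >= min_stage_mean, ]
    if (nrow(el) < top_n_per_stage)
      warning("stage ", s, " has only ", nrow(el), " eligible features")
    o <- order(-el$sigma_max, -el[[paste0("mean_", s)]], el$feature_id)
    el <- el[o[seq_len(min(top_n_per_stage, nrow(el)))], , drop = FALSE]
    if (nrow(el) > 0) el$stage <- s
    el
  })
  res <- do.call(rbind, out[vapply(out, nrow, 0L) > 0])
  if (is.null(res)) {
    res <- table[0, , drop = FALSE]
    res$stage <- character()
  }
  res
}

#' Kolmogorov-Smirnov comparison of class specificity distributions
#'
#' Two-sample two-sided KS tests of the sigma_max distributions of
#' annotated and novel lncRNAs against protein-coding genes (asymptotic
#' p-values), plus the per-class ECDF coordinates for cumulative plots.
#'
#' @param table a \code{SpecificityTable}
#' @param reference_class class compared against (default protein_coding)
#' @param test_classes classes tested (default both lncRNA groups)
#' @return list: \code{tests} data.frame (class, n, n_ref, D, p_value) and
#'   \code{ecdf} data.frame (class, sigma, ecdf)
#' @export
compare_class_specificity <- function(table,
    reference_class = "protein_coding",
    test_classes = c("annotated_lncRNA", "novel_lncRNA")) {
  x <- table$sigma_max
  ok <- !is.na(x)
  ref <- x[ok & table$class == reference_class]
  if (length(ref) < 2) stop("reference class needs >= 2 scored features")
  rows <- lapply(test_classes, function(cl) {
    y <- x[ok & table$class == cl]
    if (length(y) < 2) {
      warning("class ", cl, " has < 2 scored features; skipped")
      return(NULL)
    }
    kt <- suppressWarnings(stats::ks.test(y, ref, exact = FALSE))
    data.frame(class = cl, n = length(y), n_ref = length(ref),
               D = unname(kt$statistic), p_value = kt$p.value,
               stringsAsFactors = FALSE)
  })
  ec <- lapply(c(reference_class, test_classes), function(cl) {
    y <- sort(x[ok & table$class == cl])
    if (length(y) == 0) return(NULL)
    data.frame(class = cl, sigma = y,
               ecdf = seq_along(y) / length(y), stringsAsFactors = FALSE)
  })
  list(tests = do.call(rbind, rows), ecdf = do.call(rbind, ec))
}
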