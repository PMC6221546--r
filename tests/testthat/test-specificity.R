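test_that("closed-form profiles score as the entropy oracle predicts", {
  # delta profile: zero divergence from its own stage's unit vector
  r <- js_specificity(c(0, 0, 12, 0, 0))
  expect_equal(r$max, 1)
  expect_equal(r$argmax, "3")

  # uniform over 5 stages: sigma identical for all stages, 0.2190 to 4 dp
  u <- js_specificity(rep(3, 5))
  expect_equal(unname(u$scores), rep(u$max, 5))
  expect_equal(u$max, 0.2190, tolerance = 1e-4)
  expect_equal(u$max, js_oracle(rep(3, 5)), tolerance = 1e-12)

  # two active stages, half-half: 0.4421 against either active stage
  h <- js_specificity(c(1, 1, 0, 0, 0))
  expect_equal(h$max, 0.4421, tolerance = 1e-4)
  expect_equal(unname(h$scores[1]), unname(h$scores[2]))
  expect_equal(h$max, js_oracle(c(1, 1, 0, 0, 0)), tolerance = 1e-12)

  expect_error(js_specificity(c(1, -1, 0)), "nonnegative")
  z <- js_specificity(c(0, 0, 0))
  expect_true(is.na(z$max))
})

test_that("score is scale-invariant and sharpening never lowers sigma*", {
  set.seed(99)
  for (i in 1:200) {
    e <- rgamma(5, shape = 0.7)
    s1 <- js_specificity(e)
    expect_equal(js_specificity(e * runif(1, 0.01, 100))$max, s1$max,
                 tolerance = 1e-12)
    # move mass from a non-argmax stage to the argmax stage
    k <- which.max(s1$scores)
    j <- setdiff(seq_along(e), k)[1]
    e2 <- e
    shift <- e2[j] * 0.5
    e2[j] <- e2[j] - shift
    e2[k] <- e2[k] + shift
    expect_gte(js_specificity(e2)$max + 1e-12, s1$max)
  }
  # permuting stages permutes scores identically
  e <- c(5, 1, 2, 0.5, 3)
  perm <- c(3, 1, 5, 2, 4)
  s <- js_specificity(e)
  sp <- js_specificity(e[perm])
  expect_equal(unname(sp$scores), unname(s$scores[perm]))
  expect_equal(sp$max, s$max)
})

test_that("vectorized scoring equals per-feature scalar calls", {
  set.seed(5)
  design <- data.frame(
    sample_id = paste0(rep(c("ESC", "NE", "pMN", "MN", "IN"), each = 2),
                       "_", 1:2),
    stage = rep(c("ESC", "NE", "pMN", "MN", "IN"), each = 2))
  m <- matrix(rpois(50 * 10, 40), 50, 10,
              dimnames = list(sprintf("f%02d", 1:50), design$sample_id))
  m[7, ] <- 0                                   # degenerate all-zero row
  m[3, ] <- rep(c(0, 0, 0, 200, 0), each = 2)   # pure MN feature
  tab <- score_all(m, design)
  prof <- stage_mean_profile(m, design)
  for (i in seq_len(nrow(prof))) {
    ref <- js_specificity(prof[i, ])
    if (is.na(ref$max)) {
      expect_true(is.na(tab$sigma_max[i]))
    } else {
      expect_equal(tab$sigma_max[i], ref$max, tolerance = 1e-12)
      expect_equal(tab$argmax_stage[i], ref$argmax)
    }
  }
  expect_equal(tab$argmax_stage[3], "MN")
  expect_equal(tab$sigma_max[3], 1)
})

test_that("signature selection is the per-stage sort-and-slice", {
  set.seed(41)
  design <- data.frame(
    sample_id = paste0(rep(c("ESC", "NE", "pMN", "MN", "IN"), each = 3),
                       "_", 1:3),
    stage = rep(c("ESC", "NE", "pMN", "MN", "IN"), each = 3))
  m <- matrix(rnbinom(400 * 15, mu = 60, size = 5), 400, 15,
              dimnames = list(sprintf("f%03d", 1:400), design$sample_id))
  tab <- score_all(m, design)
  sigs <- select_stage_signatures(tab, top_n_per_stage = 14)
  expect_equal(nrow(sigs), 70)   # 5 stages x 14 with plenty eligible
  for (s in unique(sigs$stage)) {
    el <- tab[!is.na(tab$argmax_stage) & tab$argmax_stage == s, ]
    o <- order(-el$sigma_max, -el[[paste0("mean_", s)]], el$feature_id)
    expect_equal(sigs$feature_id[sigs$stage == s],
                 el$feature_id[o][1:14])
  }
  expect_equal(nrow(select_stage_signatures(tab, top_n_per_stage = 0)), 0)
  ws <- testthat::capture_warnings(
    select_stage_signatures(tab, top_n_per_stage = 14,
                            min_stage_mean = 1e6))
  expect_true(all(grepl("eligible", ws)) && length(ws) == 5)
})

test_that("KS class comparison matches the explicit ECDF-scan oracle", {
  set.seed(12)
  tab <- data.frame(
    feature_id = sprintf("f%03d", 1:220),
    class = rep(c("protein_coding", "annotated_lncRNA", "novel_lncRNA"),
                c(100, 100, 20)),
    sigma_max = c(rbeta(100, 2, 5), rbeta(100, 4, 3), rbeta(20, 6, 2)),
    argmax_stage = "MN", stringsAsFactors = FALSE)
  attr(tab, "stages") <- "MN"
  cmp <- compare_class_specificity(tab)
  x <- tab$sigma_max[tab$class == "annotated_lncRNA"]
  y <- tab$sigma_max[tab$class == "protein_coding"]
  expect_equal(cmp$tests$D[cmp$tests$class == "annotated_lncRNA"],
               ks_D_oracle(x, y), tolerance = 1e-12)

  # identical samples: D = 0, p = 1
  same <- tab
  same$sigma_max <- rep(tab$sigma_max[1:110], 2)
  same$class <- rep(c("protein_coding", "annotated_lncRNA"), each = 110)
  cmp0 <- compare_class_specificity(same,
                                    test_classes = "annotated_lncRNA")
  expect_equal(cmp0$tests$D, 0)
  expect_equal(cmp0$tests$p_value, 1)

  # disjoint supports: D = 1
  disj <- tab
  disj$sigma_max <- c(runif(100, 0, 0.4), runif(100, 0.6, 1),
                      runif(20, 0.6, 1))
  cmpd <- compare_class_specificity(disj)
  expect_true(all(cmpd$tests$D == 1))

  # ECDF coordinates are right-continuous step heights
  ec <- cmp$ecdf[cmp$ecdf$class == "protein_coding", ]
  expect_equal(ec$ecdf, seq_len(nrow(ec)) / nrow(ec))
})
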