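test_that("responder classification applies the 10% ESV-reduction rule", {
  r <- classify_response(152, 130)
  expect_true(r$responder)
  expect_equal(r$delta_esv_pct, 100 * (130 - 152) / 152)  # -14.5%

  expect_true(classify_response(100, 90)$responder)    # boundary inclusive
  expect_false(classify_response(100, 91)$responder)
  expect_false(classify_response(100, 101)$responder)
  expect_error(classify_response(0, 90), "positive")
})

test_that("ROC AUC equals the concordant-pair fraction", {
  r <- roc_curve(c(3, 4, 5, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(roc_curve(c(1, 3, 2), c(TRUE, TRUE, FALSE))$auc, 0.5)

  # reversing the direction maps auc to 1 - auc
  set.seed(52)
  s <- rnorm(30); l <- rep(c(TRUE, FALSE), 15)
  expect_equal(roc_curve(s, l, "lower_is_positive")$auc,
               1 - roc_curve(s, l)$auc)

  expect_error(roc_curve(1:5, rep(TRUE, 5)), "positive and .* negative")

  # exhaustive pair-counting oracle, with ties
  set.seed(53)
  for (i in 1:50) {
    n_pos <- sample(1:8, 1); n_neg <- sample(1:8, 1)
    scores <- sample(1:6, n_pos + n_neg, replace = TRUE)  # many ties
    labels <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    expect_equal(roc_curve(scores, labels)$auc,
                 brute_force_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("the ROC curve is a valid monotone path from (0,0) to (1,1)", {
  set.seed(54)
  for (i in 1:10) {
    r <- roc_curve(rnorm(20), runif(20) < 0.4 | seq_len(20) <= 2)
    p <- r$points
    expect_equal(p$fpr[1], 0); expect_equal(p$tpr[1], 0)
    expect_equal(p$fpr[nrow(p)], 1); expect_equal(p$tpr[nrow(p)], 1)
    expect_true(all(diff(p$fpr) >= 0))
    expect_true(all(diff(p$tpr) >= 0))
    expect_true(r$auc >= 0 && r$auc <= 1)
  }
})

test_that("ROC results agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  s <- rnorm(40); l <- c(rep(TRUE, 15), rep(FALSE, 25))
  ours <- roc_curve(s, l)
  ref <- pROC::roc(response = l, predictor = s, direction = "<",
                   levels = c(FALSE, TRUE), quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("the Youden cutoff reproduces direct 2x2 arithmetic", {
  perfect <- roc_curve(c(3, 4, 5, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  cut <- optimal_cutoff(perfect)
  expect_equal(cut$sensitivity, 100)
  expect_equal(cut$specificity, 100)
  expect_equal(cut$ppv, 100)
  expect_equal(cut$npv, 100)

  # TP=17 FN=1 TN=7 FP=2 at the chosen cutoff
  scores <- c(rep(2, 17), 0, rep(2, 2), rep(0, 7))
  labels <- c(rep(TRUE, 18), rep(FALSE, 9))
  cut <- optimal_cutoff(roc_curve(scores, labels))
  expect_equal(cut$table, c(tp = 17, fp = 2, fn = 1, tn = 7))
  expect_equal(cut$sensitivity, 100 * 17 / 18, tolerance = 1e-9)  # 94.4
  expect_equal(cut$specificity, 100 * 7 / 9, tolerance = 1e-9)    # 77.8
  expect_equal(cut$ppv, 100 * 17 / 19, tolerance = 1e-9)          # 89.5
  expect_equal(cut$npv, 100 * 7 / 8, tolerance = 1e-9)            # 87.5

  # all scores equal: the degenerate all-positive cutoff
  cut <- optimal_cutoff(roc_curve(rep(3, 6), c(TRUE, TRUE, FALSE,
                                               FALSE, TRUE, FALSE)))
  expect_equal(cut$sensitivity, 100)
  expect_equal(cut$specificity, 0)
})

test_that("predictive values obey the Bayes identity on every 2x2 table", {
  set.seed(56)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    labels <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(labels) || all(labels)) next
    cut <- optimal_cutoff(roc_curve(rnorm(n), labels))
    tb <- cut$table
    sens <- cut$sensitivity / 100; spec <- cut$specificity / 100
    prev <- (tb["tp"] + tb["fn"]) / sum(tb)
    ppv_bayes <- sens * prev / (sens * prev + (1 - spec) * (1 - prev))
    if (is.finite(ppv_bayes) && !is.na(cut$ppv))
      expect_equal(cut$ppv / 100, unname(ppv_bayes), tolerance = 1e-9)
    expect_true(all(c(cut$sensitivity, cut$specificity) >= 0))
    expect_true(all(c(cut$sensitivity, cut$specificity) <= 100))
  }
})

test_that("paired AUC comparison behaves at the edges and matches pROC", {
  s <- c(5, 3, 4, 1, 2, 0.5)
  l <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(compare_auc_paired(s, s, l)$p_value, 1)

  set.seed(57)
  a <- rnorm(60); b <- rnorm(60)
  lbl <- c(rep(TRUE, 25), rep(FALSE, 35))
  ours <- compare_auc_paired(a, b, lbl)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(lbl, a, direction = "<", levels = c(FALSE, TRUE),
                  quiet = TRUE)
  rb <- pROC::roc(lbl, b, direction = "<", levels = c(FALSE, TRUE),
                  quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)

  # a perfectly separating marker against noise is detected
  sep <- c(rep(1, 25), rep(0, 35)) + rnorm(60, 0, 1e-3)
  expect_lt(compare_auc_paired(sep, b, lbl)$p_value, 0.01)
})

test_that("Bland-Altman reproduces hand computations", {
  ident <- bland_altman(c(3, 7, 9), c(3, 7, 9))
  expect_equal(ident$bias, 0)
  expect_equal(ident$loa_upper - ident$loa_lower, 0)

  ba <- bland_altman(c(10, 20, 30), c(12, 18, 30))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 2)
  expect_equal(ba$loa_lower, -3.92)
  expect_equal(ba$loa_upper, 3.92)
  expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * ba$sd_diff)

  # constant offset moves the bias, not the width
  ba2 <- bland_altman(c(10, 20, 30) + 5, c(12, 18, 30))
  expect_equal(ba2$bias, 5)
  expect_equal(ba2$loa_upper - ba2$loa_lower,
               ba$loa_upper - ba$loa_lower)

  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("Bland-Altman bias vanishes for zero-mean noise as n grows", {
  set.seed(58)
  x <- runif(1e4, 10, 50)
  eps <- rnorm(1e4, 0, 2)
  ba <- bland_altman(x + eps, x)
  se <- ba$sd_diff / sqrt(ba$n)
  expect_lt(abs(ba$bias), 3 * se)
})

test_that("group comparison matches a direct pooled t computation", {
  df <- data.frame(
    responder = rep(c(TRUE, FALSE), c(6, 5)),
    m_baseline = c(5.1, 6.2, 5.8, 7.0, 6.5, 5.9, 3.1, 3.8, 2.9, 3.5, 4.0),
    m_followup = c(4.0, 5.1, 4.9, 5.5, 5.2, 4.8, 3.0, 3.9, 3.1, 3.3, 4.1))
  gc <- group_compare(df, "m")
  ref <- t.test(df$m_baseline[df$responder], df$m_baseline[!df$responder],
                var.equal = TRUE)
  expect_equal(gc$p_unpaired_baseline, ref$p.value)
  # hand-computed pooled t for the same data
  x <- df$m_baseline[df$responder]; y <- df$m_baseline[!df$responder]
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(gc$p_unpaired_baseline,
               2 * pt(-abs(tstat), length(x) + length(y) - 2))

  refp <- t.test(df$m_baseline[df$responder], df$m_followup[df$responder],
                 paired = TRUE)
  expect_equal(gc$p_paired_responders, refp$p.value)

  # identical groups give p = 1
  df2 <- data.frame(responder = rep(c(TRUE, FALSE), each = 3),
                    m_baseline = rep(c(4, 5, 6), 2))
  expect_equal(group_compare(df2, "m")$p_unpaired_baseline, 1)

  expect_warning(
    group_compare(data.frame(responder = c(TRUE, TRUE, FALSE),
                             m_baseline = c(1, 2, 3)), "m"),
    "fewer than 2")
})

test_that("correlation with reverse remodelling uses Pearson r", {
  d <- c(-30, -20, -5, 2, 10)
  expect_equal(correlate_remodelling(d, d)$r, 1)
  expect_equal(correlate_remodelling(-d, d)$r, -1)
  set.seed(59)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  ref <- cor.test(x, y)
  got <- correlate_remodelling(x, y)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p_value, ref$p.value)
  expect_error(correlate_remodelling(rep(1, 5), rnorm(5)), "variance")
})
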