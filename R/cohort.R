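#' Responder classification by end-systolic volume reduction
#'
#' Response to CRT is a reduction of LV end-systolic volume at follow-up of
#' at least 10% relative to baseline (reverse remodelling). Exactly 10%
#' counts as response. The continuous measure is
#' `delta_esv_pct = 100 * (esv_followup - esv_baseline) / esv_baseline`
#' (negative = reduction).
#'
#' @param esv_base Baseline ESV, ml > 0 (vectorised).
#' @param esv_fu Follow-up ESV, ml >= 0.
#' @return List with `responder` (logical) and `delta_esv_pct` (%).
#' @export
#' @examples
#' classify_response(152, 130)  # 14.5% reduction -> responder
classify_response <- function(esv_base, esv_fu) {
  esv_base <- as.numeric(esv_base)
  esv_fu <- as.numeric(esv_fu)
  if (any(!is.finite(esv_base)) || any(esv_base <= 0))
    stop("baseline ESV must be positive")
  if (length(esv_fu) != length(esv_base))
    stop("baseline and follow-up ESV differ in length")
  delta <- 100 * (esv_fu - esv_base) / esv_base
  list(responder = delta <= -10, delta_esv_pct = delta)
}

check_binary <- function(scores, labels) {
  labels <- as.logical(labels)
  scores <- as.numeric(scores)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels))
    stop("scores/labels must not contain NA")
  if (!any(labels) || all(labels))
    stop("ROC analysis needs at least one positive and one negative case; ",
         "got ", sum(labels), " positives of ", length(labels))
  list(scores = scores, labels = labels)
}

# Mann-Whitney AUC: concordant-pair fraction with ties counted 1/2
auc_mann_whitney <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve with AUC and optimal cutoff
#'
#' Builds the empirical ROC over all distinct score thresholds (positive
#' test: score >= threshold, or <= for `lower_is_positive`). The AUC is the
#' Mann-Whitney concordant-pair fraction (ties counted one half), identical
#' to the trapezoidal area under the empirical curve; its 95% CI uses the
#' Hanley-McNeil standard error. The reported cutoff maximises the Youden
#' index (sensitivity + specificity - 1); ties are broken towards higher
#' sensitivity. The direction is never flipped automatically: a marker
#' whose AUC falls below 0.5 under the declared direction is reported as
#' such.
#'
#' @param scores Per-patient marker values.
#' @param labels Logical (or 0/1) outcome, `TRUE` = positive (responder).
#' @param direction `"higher_is_positive"` (default) or
#'   `"lower_is_positive"`.
#' @return Object of class `roc_result`: list with `points` (data.frame
#'   `fpr`, `tpr`, `threshold`), `auc`, `auc_ci_95`, `direction`, `cutoff`,
#'   `sensitivity`, `specificity`, `npv`, `ppv` (percent), `table` (2x2
#'   counts), `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_curve(c(3, 4, 5, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
roc_curve <- function(scores, labels,
                      direction = c("higher_is_positive",
                                    "lower_is_positive")) {
  direction <- match.arg(direction)
  z <- check_binary(scores, labels)
  s <- if (direction == "lower_is_positive") -z$scores else z$scores
  labels <- z$labels
  n_pos <- sum(labels)
  n_neg <- sum(!labels)

  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(s[labels] >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(s[!labels] >= t) / n_neg, numeric(1))
  points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                       threshold = c(Inf, thr))
  if (points$fpr[nrow(points)] < 1 || points$tpr[nrow(points)] < 1)
    points <- rbind(points, data.frame(fpr = 1, tpr = 1, threshold = -Inf))

  auc <- auc_mann_whitney(s, labels)
  se <- hanley_mcneil_se(auc, n_pos, n_neg)
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * se, 0), 1)

  cut <- youden_cutoff(s, labels)
  cutoff <- if (direction == "lower_is_positive") -cut$cutoff else cut$cutoff

  structure(list(points = points, auc = auc, auc_ci_95 = ci,
                 direction = direction, cutoff = cutoff,
                 sensitivity = cut$sensitivity, specificity = cut$specificity,
                 npv = cut$npv, ppv = cut$ppv, table = cut$table,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

# Youden-optimal cutoff on the "higher is positive" scale
youden_cutoff <- function(s, labels) {
  thr <- sort(unique(s), decreasing = TRUE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  best <- NULL
  for (t in thr) {
    pos_test <- s >= t
    tp <- sum(pos_test & labels); fp <- sum(pos_test & !labels)
    fn <- n_pos - tp; tn <- n_neg - fp
    sens <- tp / n_pos
    spec <- tn / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens)) {
      best <- list(j = j, sens = sens, spec = spec, cutoff = t,
                   tp = tp, fp = fp, fn = fn, tn = tn)
    }
  }
  ppv <- if (best$tp + best$fp > 0) best$tp / (best$tp + best$fp) else NA_real_
  npv <- if (best$tn + best$fn > 0) best$tn / (best$tn + best$fn) else NA_real_
  list(cutoff = best$cutoff,
       sensitivity = 100 * best$sens, specificity = 100 * best$spec,
       ppv = 100 * ppv, npv = 100 * npv,
       table = c(tp = best$tp, fp = best$fp, fn = best$fn, tn = best$tn))
}

#' @rdname roc_curve
#' @export
#' @examples
#' r <- roc_curve(c(3, 4, 5, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
#' optimal_cutoff(r)
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  roc[c("cutoff", "sensitivity", "specificity", "npv", "ppv", "table")]
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s): AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$direction, x$auc, x$auc_ci_95[1], x$auc_ci_95[2],
              x$n_pos, x$n_neg))
  cat(sprintf("  Youden cutoff %.3g: sens %.1f%%  spec %.1f%%  PPV %.1f%%  NPV %.1f%%\n",
              x$cutoff, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1),
                 main = sprintf("ROC, AUC = %.2f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# placements psi(X_i, .) for DeLong components
delong_components <- function(s, labels) {
  x <- s[labels]; y <- s[!labels]
  v10 <- vapply(x, function(xi)
    mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj)
    mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired comparison of two correlated AUCs (DeLong test)
#'
#' Tests whether two markers measured on the same patients differ in ROC
#' AUC, accounting for the correlation induced by the shared cases
#' (DeLong's nonparametric covariance of the Mann-Whitney placements).
#' Two-sided p-value.
#'
#' @param scores_a,scores_b The two markers, same patients in the same
#'   order.
#' @param labels Logical outcome.
#' @return List with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels) {
  za <- check_binary(scores_a, labels)
  zb <- check_binary(scores_b, labels)
  if (length(za$scores) != length(zb$scores))
    stop("scores_a and scores_b differ in length")
  labels <- za$labels
  a <- delong_components(za$scores, labels)
  b <- delong_components(zb$scores, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- a$auc - b$auc
  if (v <= .Machine$double.eps) {
    p <- if (abs(diff) <= .Machine$double.eps) 1 else 0
    z <- if (abs(diff) <= .Machine$double.eps) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = a$auc, auc_b = b$auc, z = z, p_value = p)
}

#' Bland-Altman agreement analysis
#'
#' Agreement between two observers (or two readings) of the same metric:
#' per-pair differences `obs1 - obs2` against per-pair means; bias is the
#' mean difference and the limits of agreement are bias +/- 1.96 x SD of
#' the differences (sample SD).
#'
#' @param obs1,obs2 Paired measurement vectors, equal length >= 2.
#' @return Object of class `bland_altman`: list with `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `n`, `points` (data.frame `mean`, `diff`).
#' @export
#' @examples
#' bland_altman(c(10, 20, 30), c(12, 18, 30))  # bias 0, LoA +/- 3.92
bland_altman <- function(obs1, obs2) {
  obs1 <- as.numeric(obs1); obs2 <- as.numeric(obs2)
  if (length(obs1) != length(obs2))
    stop("observer vectors differ in length")
  if (length(obs1) < 2L)
    stop("need at least 2 pairs")
  if (anyNA(obs1) || anyNA(obs2))
    stop("observations must not contain NA")
  d <- obs1 - obs2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_lower = bias - 1.96 * sd_diff,
                 loa_upper = bias + 1.96 * sd_diff,
                 n = length(d),
                 points = data.frame(mean = (obs1 + obs2) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, LoA [%.3f, %.3f] (SD %.3f)\n",
              x$n, x$bias, x$loa_lower, x$loa_upper, x$sd_diff))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$points$mean, x$points$diff,
                 xlab = "mean of observations",
                 ylab = "difference between observations", ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Responder vs non-responder group comparison of one metric
#'
#' Means +/- SD per group at baseline and follow-up; unpaired two-sample
#' Student t-test (pooled variance, matching the conventional reporting;
#' Welch available) between responders and non-responders at each time
#' point, and paired t-test baseline vs follow-up within each group.
#'
#' @param cohort_df Per-patient data.frame as returned by
#'   [cohort_metrics()]: needs `responder` plus `<metric>_baseline` and
#'   (optionally) `<metric>_followup` columns.
#' @param metric Metric name, e.g. `"pre_stv"`, `"sdi"`.
#' @param t_test `"student"` (pooled variance, default) or `"welch"`.
#' @return Object of class `group_comparison`: list with `metric`, `stats`
#'   (data.frame of group x timepoint mean/sd/n), `p_unpaired_baseline`,
#'   `p_unpaired_followup`, `p_paired_responders`,
#'   `p_paired_non_responders`.
#' @export
group_compare <- function(cohort_df, metric, t_test = c("student", "welch")) {
  t_test <- match.arg(t_test)
  var_equal <- t_test == "student"
  base_col <- paste0(metric, "_baseline")
  fu_col <- paste0(metric, "_followup")
  if (!base_col %in% names(cohort_df))
    stop("column '", base_col, "' not found")
  resp <- as.logical(cohort_df$responder)
  if (!any(resp) || all(resp))
    stop("need both responders and non-responders")
  has_fu <- fu_col %in% names(cohort_df)

  msd <- function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x))
  rows <- list(
    c(group = "responders", timepoint = "baseline"),
    c(group = "non_responders", timepoint = "baseline"))
  vals <- list(msd(cohort_df[[base_col]][resp]),
               msd(cohort_df[[base_col]][!resp]))
  if (has_fu) {
    rows <- c(rows, list(c(group = "responders", timepoint = "followup"),
                         c(group = "non_responders", timepoint = "followup")))
    vals <- c(vals, list(msd(cohort_df[[fu_col]][resp]),
                         msd(cohort_df[[fu_col]][!resp])))
  }
  stats_df <- cbind(do.call(rbind.data.frame, rows),
                    do.call(rbind, vals))
  names(stats_df)[1:2] <- c("group", "timepoint")

  safe_t <- function(x, y, paired = FALSE) {
    if (length(x) < 2L || length(y) < 2L) {
      warning("group with fewer than 2 observations; p-value suppressed")
      return(NA_real_)
    }
    if (paired && isTRUE(all.equal(x, y))) return(1)
    if (!paired && stats::sd(c(x, y)) == 0) return(1)
    stats::t.test(x, y, paired = paired,
                  var.equal = if (paired) FALSE else var_equal)$p.value
  }
  out <- list(
    metric = metric, t_test = t_test, stats = stats_df,
    p_unpaired_baseline = safe_t(cohort_df[[base_col]][resp],
                                 cohort_df[[base_col]][!resp]),
    p_unpaired_followup = if (has_fu)
      safe_t(cohort_df[[fu_col]][resp], cohort_df[[fu_col]][!resp])
      else NA_real_,
    p_paired_responders = if (has_fu)
      safe_t(cohort_df[[base_col]][resp], cohort_df[[fu_col]][resp],
             paired = TRUE) else NA_real_,
    p_paired_non_responders = if (has_fu)
      safe_t(cohort_df[[base_col]][!resp], cohort_df[[fu_col]][!resp],
             paired = TRUE) else NA_real_)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s (%s t-test)\n", x$metric, x$t_test))
  s <- x$stats
  s$mean <- round(s$mean, 2); s$sd <- round(s$sd, 2)
  print(s, row.names = FALSE)
  cat(sprintf("  unpaired p (baseline) = %.3g; (follow-up) = %.3g\n",
              x$p_unpaired_baseline, x$p_unpaired_followup))
  cat(sprintf("  paired p responders = %.3g; non-responders = %.3g\n",
              x$p_paired_responders, x$p_paired_non_responders))
  invisible(x)
}

#' Correlation of a baseline marker with reverse remodelling
#'
#' Pearson correlation between a baseline dyssynchrony marker and the
#' percent ESV change at follow-up (negative change = reverse remodelling),
#' with the two-sided t-transform p-value on n - 2 degrees of freedom.
#'
#' @param scores Baseline marker values.
#' @param delta_esv_pct Percent ESV change at follow-up.
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate_remodelling <- function(scores, delta_esv_pct) {
  scores <- as.numeric(scores)
  delta_esv_pct <- as.numeric(delta_esv_pct)
  if (length(scores) != length(delta_esv_pct))
    stop("scores and delta_esv_pct differ in length")
  if (length(scores) < 3L)
    stop("need at least 3 patients")
  if (stats::sd(scores) == 0 || stats::sd(delta_esv_pct) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(scores, delta_esv_pct, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(scores))
}
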